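# Variant-table I/O.  The scan consumes a minimal VCF 4.2 dialect: two
# samples (G = green pool, Y = yellow pool) with a FORMAT AD field carrying
# "ref,alt" read depths.  Reading goes through vcfR; writing is a small
# emitter for the same dialect so tables round-trip losslessly.

#' Write a pooled variant table as VCF 4.2
#'
#' Emits a minimal VCF with samples `G` and `Y` and `FORMAT/AD` per-pool
#' "ref,alt" depths, at 1-based positions.  Round-trips through
#' [read_ad_vcf()].
#'
#' @param variants data.frame with columns chrom, pos, ref, alt, g_ref,
#'   g_alt, y_ref, y_alt (as from [simulate_pool_depths()]).
#' @param path output file.
#' @param contig_lengths optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return the path, invisibly.
#' @export
write_sim_vcf <- function(variants, path, contig_lengths = NULL) {
  needed <- c("chrom", "pos", "ref", "alt", "g_ref", "g_alt", "y_ref", "y_alt")
  assert_that(all(needed %in% names(variants)),
              paste("`variants` needs columns:", paste(needed, collapse = ", ")))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsaED",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">'
  )
  if (!is.null(contig_lengths)) {
    header <- c(header,
                sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                        as.integer(contig_lengths)))
  }
  header <- c(header,
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "G", "Y"), collapse = "\t"))
  body <- character(0)
  if (nrow(variants) > 0) {
    body <- paste(variants$chrom, format(variants$pos, scientific = FALSE,
                                         trim = TRUE),
                  ".", variants$ref, variants$alt, ".", "PASS", ".", "AD",
                  paste0(variants$g_ref, ",", variants$g_alt),
                  paste0(variants$y_ref, ",", variants$y_alt),
                  sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a two-pool AD VCF into a variant table
#'
#' Parses a VCF with `FORMAT/AD` depths via vcfR and returns the flat table
#' the scan works on.  Samples named `G` and `Y` are used when present;
#' otherwise the first two samples are taken in file order (with a warning).
#' Multi-allelic records are dropped with a message (the ED statistic is
#' defined for biallelic sites).
#'
#' @param path VCF file (plain text or bgzipped).
#' @return data.frame chrom, pos, ref, alt, g_ref, g_alt, y_ref, y_alt.
#' @export
read_ad_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      g_ref = integer(0), g_alt = integer(0),
                      y_ref = integer(0), y_alt = integer(0)))
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  samples <- colnames(ad)
  if (all(c("G", "Y") %in% samples)) {
    g_col <- "G"; y_col <- "Y"
  } else {
    assert_that(length(samples) >= 2, "VCF must carry two pool samples")
    g_col <- samples[1]; y_col <- samples[2]
    warning(sprintf("samples G/Y not found; using '%s' as G-pool and '%s' as Y-pool",
                    g_col, y_col), call. = FALSE)
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " multi-allelic record(s) dropped")
  }
  keep <- !multi
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = vapply(parts, function(p) as.integer(p[1]), integer(1)),
         alt = vapply(parts, function(p) as.integer(p[2]), integer(1)))
  }
  g <- split_ad(ad[keep, g_col])
  y <- split_ad(ad[keep, y_col])
  out <- data.frame(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
                    ref = fix$REF[keep], alt = fix$ALT[keep],
                    g_ref = g$ref, g_alt = g$alt, y_ref = y$ref, y_alt = y$alt)
  rownames(out) <- NULL
  out
}

#' Read a variant table from TSV
#'
#' Equivalent flat input for the scan: tab-separated with columns chrom, pos,
#' ref, alt, g_ref, g_alt, y_ref, y_alt (extra columns such as `effect` and
#' `gene_id` are kept, for the candidate filter).
#'
#' @param path TSV file with a header row.
#' @return data.frame.
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "g_ref", "g_alt", "y_ref", "y_alt")
  assert_that(all(needed %in% names(df)),
              paste("variant TSV needs columns:", paste(needed, collapse = ", ")))
  df
}
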