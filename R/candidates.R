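# Candidate-SNP screening inside a mapped region.  Pools are sequenced, not
# genotyped, so "heterozygous in the G-pool / homozygous-alt in the Y-pool"
# is operationalised as banded calls on pooled alt-allele frequencies.

#' Zygosity call from a pooled allele frequency
#'
#' Banded rule on the pooled alt-allele frequency `f` and total depth:
#' below `min_depth` the call is `ambiguous`; `f >= hom_alt_min` is
#' `hom_alt`; `f <= 1 - hom_alt_min` is `hom_ref`; `f` inside `het_band` is
#' `het`; anything between the bands is `ambiguous`.
#'
#' @param f pooled alt-allele frequency in [0, 1] (vectorised).
#' @param depth total read depth (vectorised).
#' @param het_band two frequencies bounding the heterozygous band
#'   (default c(0.2, 0.8)).
#' @param hom_alt_min minimum frequency for a homozygous-alt call
#'   (default 0.9); homozygous-ref is its mirror at `1 - hom_alt_min`.
#' @param min_depth depth below which the call is `ambiguous` (default 10).
#' @return character vector in {hom_ref, het, hom_alt, ambiguous}.
#' @examples
#' call_pool_zygosity(c(1, 0.5, 0.85), c(80, 60, 60))
#' @export
call_pool_zygosity <- function(f, depth, het_band = c(0.2, 0.8),
                               hom_alt_min = 0.9, min_depth = 10) {
  assert_that(length(het_band) == 2 && het_band[1] < het_band[2],
              "`het_band` must be two increasing frequencies")
  assert_that(hom_alt_min > het_band[2] && (1 - hom_alt_min) < het_band[1],
              "zygosity bands overlap: require 1 - hom_alt_min < het_band < hom_alt_min")
  assert_that(all(f >= 0 & f <= 1), "`f` must lie in [0, 1]")
  out <- rep("ambiguous", length(f))
  out[f >= hom_alt_min] <- "hom_alt"
  out[f <= 1 - hom_alt_min] <- "hom_ref"
  out[f >= het_band[1] & f <= het_band[2]] <- "het"
  out[depth < min_depth] <- "ambiguous"
  out
}

#' Screen annotated variants for causal-candidate SNPs
#'
#' Retains variants that are (i) inside the mapped region, (ii)
#' heterozygous in the G-pool, (iii) homozygous for the non-reference
#' allele in the Y-pool, and (iv) of a protein-affecting effect class
#' (default nonsynonymous, splice_site, inframe_indel).  The screen is
#' monotone — each criterion only removes variants — and independent of the
#' input row order.
#'
#' @param variants data.frame with chrom, pos, g_ref, g_alt, y_ref, y_alt,
#'   effect, and (for genic effects) gene_id.
#' @param region the mapped interval: any list/row with chrom, start, end
#'   (1-based inclusive), e.g. one row of a [call_regions()] table.
#' @param effects_keep effect classes satisfying criterion (iv).
#' @param het_band,hom_alt_min,min_depth zygosity configuration, see
#'   [call_pool_zygosity()].
#' @return list with `candidates` (the retained rows, plus zygosity
#'   columns), `dropped` (named counts of variants failing each criterion,
#'   counted independently), `n_input`, `n_retained`.
#' @export
filter_candidate_snps <- function(variants, region,
                                  effects_keep = c("nonsynonymous",
                                                   "splice_site",
                                                   "inframe_indel"),
                                  het_band = c(0.2, 0.8), hom_alt_min = 0.9,
                                  min_depth = 10) {
  needed <- c("chrom", "pos", "g_ref", "g_alt", "y_ref", "y_alt", "effect")
  assert_that(all(needed %in% names(variants)),
              paste("`variants` needs columns:", paste(needed, collapse = ", ")))
  assert_that(all(c("chrom", "start", "end") %in% names(region)),
              "`region` needs chrom, start, end")
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  g_depth <- v$g_ref + v$g_alt
  y_depth <- v$y_ref + v$y_alt
  f_g <- ifelse(g_depth > 0, v$g_alt / g_depth, NA_real_)
  f_y <- ifelse(y_depth > 0, v$y_alt / y_depth, NA_real_)
  v$g_zygosity <- ifelse(is.na(f_g), "ambiguous",
                         call_pool_zygosity(ifelse(is.na(f_g), 0, f_g), g_depth,
                                            het_band, hom_alt_min, min_depth))
  v$y_zygosity <- ifelse(is.na(f_y), "ambiguous",
                         call_pool_zygosity(ifelse(is.na(f_y), 0, f_y), y_depth,
                                            het_band, hom_alt_min, min_depth))
  in_region <- v$chrom == region$chrom & v$pos >= region$start &
    v$pos <= region$end
  g_het <- v$g_zygosity == "het"
  y_hom_alt <- v$y_zygosity == "hom_alt"
  effect_ok <- v$effect %in% effects_keep
  keep <- in_region & g_het & y_hom_alt & effect_ok
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(candidates = out,
       dropped = c(outside_region = sum(!in_region),
                   g_not_het = sum(!g_het),
                   y_not_hom_alt = sum(!y_hom_alt),
                   effect_excluded = sum(!effect_ok)),
       n_input = nrow(v), n_retained = nrow(out))
}

#' Intersect candidate genes with differentially expressed genes
#'
#' Keeps candidate genes whose DEG record passes `q_value < q_max` and fold
#' change `> fc_min` in either direction (both strict, matching the usual
#' "q < 0.05 and FC > 1.5" rule).  Fold changes may be encoded either as
#' magnitudes >= 1 with a `direction` column or as raw ratios (values < 1
#' are treated as down-regulation of magnitude `1/fc`).  Duplicate gene ids
#' in the DEG table keep the smallest q with a warning.
#'
#' @param genes character vector of candidate gene ids.
#' @param degs data.frame with gene_id, fold_change (> 0), q_value in [0,1].
#' @param fc_min,q_max strict thresholds (defaults 1.5 and 0.05).
#' @return character vector: the candidate genes that are DEGs.
#' @export
deg_intersection <- function(genes, degs, fc_min = 1.5, q_max = 0.05) {
  assert_that(all(c("gene_id", "fold_change", "q_value") %in% names(degs)),
              "`degs` needs gene_id, fold_change, q_value")
  assert_that(all(degs$fold_change > 0), "fold changes must be positive")
  assert_that(all(degs$q_value >= 0 & degs$q_value <= 1),
              "q-values must lie in [0, 1]")
  if (anyDuplicated(degs$gene_id)) {
    warning("duplicate gene ids in DEG table: keeping smallest q per gene",
            call. = FALSE)
    degs <- degs[order(degs$q_value), , drop = FALSE]
    degs <- degs[!duplicated(degs$gene_id), , drop = FALSE]
  }
  fc_mag <- pmax(degs$fold_change, 1 / degs$fold_change)
  hits <- degs$gene_id[degs$q_value < q_max & fc_mag > fc_min]
  intersect(unique(genes), hits)
}

#' Variants upstream of a gene (promoter scan)
#'
#' Returns the given (already screening-condition-passing) variants lying
#' within `upstream_bp` 5' of the gene, respecting strand: for a + strand
#' gene the window is `[start - upstream_bp, start - 1]`; for a - strand
#' gene it is `[end + 1, end + upstream_bp]`.
#'
#' @param variants data.frame with chrom, pos.
#' @param gene list/row with gene_id, chrom, start, end, strand ("+"/"-").
#' @param upstream_bp promoter window size (default 2000 bp).
#' @return the subset of `variants` inside the upstream window.
#' @export
promoter_scan <- function(variants, gene, upstream_bp = 2000) {
  assert_that(all(c("chrom", "start", "end", "strand") %in% names(gene)),
              "`gene` needs chrom, start, end, strand")
  assert_that(gene$strand %in% c("+", "-"), "strand must be '+' or '-'")
  assert_that(gene$start <= gene$end, "gene start must be <= end")
  if (gene$strand == "+") {
    lo <- gene$start - upstream_bp
    hi <- gene$start - 1
  } else {
    lo <- gene$end + 1
    hi <- gene$end + upstream_bp
  }
  out <- variants[variants$chrom == gene$chrom & variants$pos >= lo &
                    variants$pos <= hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene-model table (TSV or GFF3 gene lines)
#'
#' TSV input needs columns gene_id, chrom, start, end, strand.  GFF3 input
#' (detected by the `##gff` pragma or a `.gff`/`.gff3` extension) keeps
#' `gene` feature lines and takes the id from the `ID=` attribute.
#'
#' @param path input file.
#' @return data.frame gene_id, chrom, start, end, strand.
#' @export
read_gene_models <- function(path) {
  first <- readLines(path, n = 1)
  is_gff <- grepl("^##gff", first) ||
    grepl("\\.gff3?$", path, ignore.case = TRUE)
  if (is_gff) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    parts <- parts[vapply(parts, function(p) length(p) >= 9 && p[3] == "gene",
                          logical(1))]
    assert_that(length(parts) > 0, "no gene features found in GFF3")
    df <- data.frame(
      gene_id = vapply(parts, function(p) {
        m <- regmatches(p[9], regexpr("ID=[^;]+", p[9]))
        if (length(m)) sub("^ID=", "", m) else NA_character_
      }, character(1)),
      chrom = vapply(parts, `[`, character(1), 1),
      start = as.integer(vapply(parts, `[`, character(1), 4)),
      end = as.integer(vapply(parts, `[`, character(1), 5)),
      strand = vapply(parts, `[`, character(1), 7)
    )
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    assert_that(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                      names(df)),
                "gene TSV needs gene_id, chrom, start, end, strand")
  }
  assert_that(all(df$start <= df$end), "gene start must be <= end")
  df
}

#' Read a DEG table (TSV)
#'
#' @param path TSV with columns gene_id, fold_change, q_value (an optional
#'   `direction` column is kept).
#' @return data.frame.
#' @export
read_degs_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("gene_id", "fold_change", "q_value") %in% names(df)),
              "DEG TSV needs gene_id, fold_change, q_value")
  df
}
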