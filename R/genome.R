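#' Genome model for F2 pool-seq simulation
#'
#' Describes the chromosome layout, the regular biallelic marker grid, and the
#' (optional) causal locus used by the simulator.  The default layout is a
#' desk-scale seven-chromosome cucumber-like genome: six chromosomes of
#' 30 Mb / 100 cM and chromosome 3 of 40 Mb / 130 cM, with SNP markers every
#' 50 kb (about 4,400 sites) and a recessive causal locus at
#' chr3:34,500,000.
#'
#' @param chromosomes data.frame with columns `name`, `length_bp`,
#'   `length_cm`; all lengths must be positive.
#' @param marker_spacing_bp spacing of the regular marker grid in bp.
#'   Markers sit at `marker_spacing_bp, 2*marker_spacing_bp, ...` up to the
#'   chromosome length.
#' @param causal either `NULL` (no causal locus; used for null calibration)
#'   or `list(chrom =, pos =)` with `pos` on the marker grid of its
#'   chromosome.
#' @return an object of class `genome_model`.
#' @examples
#' g <- genome_model()
#' head(marker_positions(g, "chr3"))
#' @export
genome_model <- function(chromosomes = default_chromosomes(),
                         marker_spacing_bp = 50000,
                         causal = list(chrom = "chr3", pos = 34500000)) {
  assert_that(is.data.frame(chromosomes) &&
                all(c("name", "length_bp", "length_cm") %in% names(chromosomes)),
              "`chromosomes` needs columns name, length_bp, length_cm")
  assert_that(all(chromosomes$length_bp > 0) && all(chromosomes$length_cm > 0),
              "chromosome lengths must be positive")
  assert_that(!anyDuplicated(chromosomes$name),
              "chromosome names must be unique")
  assert_scalar_number(marker_spacing_bp, "marker_spacing_bp", lower = 0,
                       strict_lower = TRUE)
  if (!is.null(causal)) {
    assert_that(is.list(causal) && all(c("chrom", "pos") %in% names(causal)),
                "`causal` must be NULL or list(chrom =, pos =)")
    i <- match(causal$chrom, chromosomes$name)
    assert_that(!is.na(i), sprintf("causal chromosome '%s' not in genome",
                                   causal$chrom))
    assert_that(causal$pos >= 1 && causal$pos <= chromosomes$length_bp[i],
                "causal position outside its chromosome")
    grid <- seq(marker_spacing_bp, chromosomes$length_bp[i],
                by = marker_spacing_bp)
    assert_that(causal$pos %in% grid,
                "causal position must lie on the marker grid")
  }
  structure(list(chromosomes = chromosomes,
                 marker_spacing_bp = marker_spacing_bp,
                 causal = causal),
            class = "genome_model")
}

#' @rdname genome_model
#' @export
default_chromosomes <- function() {
  data.frame(
    name = paste0("chr", 1:7),
    length_bp = c(30e6, 30e6, 40e6, 30e6, 30e6, 30e6, 30e6),
    length_cm = c(100, 100, 130, 100, 100, 100, 100)
  )
}

#' Marker grid of one chromosome
#'
#' @param genome a [genome_model()].
#' @param chrom chromosome name.
#' @return integer vector of 1-based marker positions.
#' @export
marker_positions <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  assert_that(!is.na(i), sprintf("unknown chromosome '%s'", chrom))
  seq(genome$marker_spacing_bp, genome$chromosomes$length_bp[i],
      by = genome$marker_spacing_bp)
}

#' @export
print.genome_model <- function(x, ...) {
  n_mark <- sum(vapply(x$chromosomes$name,
                       function(ch) length(marker_positions(x, ch)),
                       integer(1)))
  cat("Genome model:", nrow(x$chromosomes), "chromosomes,",
      n_mark, "markers (spacing", x$marker_spacing_bp, "bp)\n")
  if (is.null(x$causal)) {
    cat("  no causal locus (null model)\n")
  } else {
    cat(sprintf("  causal locus: %s:%d (recessive)\n",
                x$causal$chrom, as.integer(x$causal$pos)))
  }
  invisible(x)
}

#' F2 cross design
#'
#' @param n_f2 number of F2 individuals to simulate.  The default 150 is a
#'   field-realistic segregating population from which two 15-plant pools can
#'   always be drawn.
#' @param pool_size number of individuals per extreme-phenotype pool
#'   (default 15 per pool).
#' @param phenotype_model `"recessive"` (yellow iff homozygous mutant at the
#'   causal locus) or `"random"` (phenotype drawn independently of genotype
#'   with P(yellow) = 1/4; used for null calibration).
#' @return an object of class `cross_design`.
#' @export
cross_design <- function(n_f2 = 150, pool_size = 15,
                         phenotype_model = c("recessive", "random")) {
  phenotype_model <- match.arg(phenotype_model)
  assert_scalar_number(n_f2, "n_f2", lower = 1)
  assert_scalar_number(pool_size, "pool_size", lower = 1)
  if (n_f2 <= 4 * pool_size) {
    warning("n_f2 <= 4 * pool_size: pools of the rarer class may be ",
            "impossible to fill", call. = FALSE)
  }
  structure(list(n_f2 = as.integer(n_f2), pool_size = as.integer(pool_size),
                 phenotype_model = phenotype_model),
            class = "cross_design")
}

#' Pooled-sequencing model
#'
#' @param coverage_g,coverage_y mean per-site read depth of the green (G) and
#'   yellow (Y) pools.  Defaults 95 and 75 reflect typical pooled NovaSeq
#'   runs of this design.
#' @param error_rate per-read probability that the sampled allele is read as
#'   the other allele (symmetric flip); must be in [0, 0.5).
#' @return an object of class `seq_model`.
#' @export
seq_model <- function(coverage_g = 95, coverage_y = 75, error_rate = 0.01) {
  assert_scalar_number(coverage_g, "coverage_g", lower = 0, strict_lower = TRUE)
  assert_scalar_number(coverage_y, "coverage_y", lower = 0, strict_lower = TRUE)
  assert_scalar_number(error_rate, "error_rate", lower = 0)
  assert_that(error_rate < 0.5, "`error_rate` must be < 0.5")
  structure(list(coverage_g = coverage_g, coverage_y = coverage_y,
                 error_rate = error_rate),
            class = "seq_model")
}
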