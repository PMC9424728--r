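# Mendelian segregation tests and fine-mapping interval arithmetic.

#' Chi-square goodness of fit to a Mendelian ratio
#'
#' Pearson chi-square of observed phenotype-class counts against an expected
#' integer ratio (e.g. 3:1), without Yates continuity correction, with
#' df = classes - 1.  For a recessive monogenic trait in an F2, green:yellow
#' counts are tested against 3:1.
#'
#' @param observed non-negative counts per phenotype class.
#' @param ratio expected integer ratio, same length (default c(3, 1)).
#' @return object of class `segregation_test`: observed, expected, chi2,
#'   df, p_value.
#' @examples
#' segregation_chi_square(c(green = 59, yellow = 18))   # chi2 = 0.11, p = 0.74
#' @export
segregation_chi_square <- function(observed, ratio = c(3, 1)) {
  assert_that(is.numeric(observed) && all(observed >= 0) && sum(observed) > 0,
              "`observed` must be non-negative counts with a positive total")
  assert_that(length(ratio) == length(observed) && all(ratio > 0),
              "`ratio` must be positive and match `observed` in length")
  p_exp <- ratio / sum(ratio)
  expected <- sum(observed) * p_exp
  assert_that(all(expected > 0), "every expected class count must be positive")
  ht <- suppressWarnings(stats::chisq.test(observed, p = p_exp,
                                           correct = FALSE))
  structure(list(observed = observed, expected = expected, ratio = ratio,
                 chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value)),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("Segregation vs %s ratio: chi2 = %.2f (df = %d), p = %.2f\n",
              paste(x$ratio, collapse = ":"), x$chi2, x$df, x$p_value))
  cat("  observed:", paste(x$observed, collapse = ", "),
      " expected:", paste(format(x$expected, digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Marker polymorphism rate
#'
#' Percentage of screened markers that are polymorphic between two parents,
#' reported at one decimal (e.g. 18 of 220 SSR markers -> 8.2).
#'
#' @param n_polymorphic,n_total marker counts, `0 <= n_polymorphic <= n_total`.
#' @param digits decimals of the reported percentage (default 1).
#' @return the percentage, rounded to `digits`.
#' @export
polymorphism_rate <- function(n_polymorphic, n_total, digits = 1) {
  assert_scalar_number(n_total, "n_total", lower = 0, strict_lower = TRUE)
  assert_scalar_number(n_polymorphic, "n_polymorphic", lower = 0,
                       upper = n_total)
  round(100 * n_polymorphic / n_total, digits)
}

#' Physical interval between two flanking markers
#'
#' @param left,right markers: `list(name =, chrom =, pos =)` with 1-based
#'   physical positions.  Markers are ordered automatically.
#' @return object of class `marker_interval`: chrom, start/end positions,
#'   marker names, `length_bp = end - start` and `length_mb`.
#' @examples
#' interval_from_markers(list(name = "UW083999", chrom = "chr3", pos = 32156194),
#'                       list(name = "UW071654", chrom = "chr3", pos = 35644875))
#' @export
interval_from_markers <- function(left, right) {
  for (m in list(left, right)) {
    assert_that(all(c("chrom", "pos") %in% names(m)),
                "markers need chrom and pos")
  }
  assert_that(left$chrom == right$chrom,
              "flanking markers must lie on the same chromosome")
  if (left$pos > right$pos) {
    tmp <- left; left <- right; right <- tmp
  }
  len <- right$pos - left$pos
  structure(list(chrom = left$chrom,
                 left_name = left$name %||% NA_character_, start = left$pos,
                 right_name = right$name %||% NA_character_, end = right$pos,
                 length_bp = len, length_mb = len / 1e6),
            class = "marker_interval")
}

#' @export
print.marker_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s - %s): %s bp = %.2f Mb\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              x$left_name, x$right_name,
              format(x$length_bp, big.mark = ",", scientific = FALSE),
              x$length_mb))
  invisible(x)
}

#' Strict intersection of two marker intervals
#'
#' `[max(starts), min(ends)]` on a shared chromosome; `NULL` when the
#' intervals are disjoint.  Intervals on different chromosomes give `NULL`
#' with a warning.
#'
#' @param a,b `marker_interval` objects (or lists with chrom, start, end).
#' @return a `marker_interval` or `NULL`.
#' @export
intersect_intervals <- function(a, b) {
  for (x in list(a, b)) {
    assert_that(all(c("chrom", "start", "end") %in% names(x)),
                "intervals need chrom, start, end")
  }
  if (a$chrom != b$chrom) {
    warning("intervals lie on different chromosomes: empty intersection",
            call. = FALSE)
    return(NULL)
  }
  start <- max(a$start, b$start)
  end <- min(a$end, b$end)
  if (start > end) return(NULL)
  interval_from_markers(
    list(name = if (a$start >= b$start) a$left_name else b$left_name,
         chrom = a$chrom, pos = start),
    list(name = if (a$end <= b$end) a$right_name else b$right_name,
         chrom = a$chrom, pos = end))
}

#' Segregation test of a simulated F2 population
#'
#' Counts green and yellow individuals of an [simulate_f2_population()]
#' result and tests them against 3:1.
#'
#' @param pop an `f2_population`.
#' @return a `segregation_test`.
#' @export
population_segregation <- function(pop) {
  obs <- c(green = sum(pop$phenotype == "green"),
           yellow = sum(pop$phenotype == "yellow"))
  segregation_chi_square(obs, c(3, 1))
}
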