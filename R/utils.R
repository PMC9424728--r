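`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x),
              sprintf("`%s` must be a single finite number", name))
  if (strict_lower) {
    assert_that(x > lower, sprintf("`%s` must be > %g", name, lower))
  } else {
    assert_that(x >= lower, sprintf("`%s` must be >= %g", name, lower))
  }
  assert_that(x <= upper, sprintf("`%s` must be <= %g", name, upper))
  invisible(x)
}

# Deterministic fan-out of one user seed into per-stage child seeds so that
# pipeline stages can be rerun independently.  Child = seed * 8 + stage index;
# seeds are kept below .Machine$integer.max.
#' @noRd
stage_seed <- function(seed, stage) {
  stages <- c(population = 1L, pools = 2L, depths = 3L, annotation = 4L,
              degs = 5L)
  assert_that(stage %in% names(stages), paste("unknown stage:", stage))
  assert_that(is.numeric(seed) && length(seed) == 1L && seed >= 0 &&
                seed < 2^28, "`seed` must be an integer in [0, 2^28)")
  as.integer(seed * 8 + stages[[stage]])
}
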