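# Independent oracles and small fixtures used across the suite.

# Brute-force tricube weighted-least-squares smoother: same definition as
# loess_fit() but a separate route (sorting + stats::lm per point).
loess_oracle <- function(x, y, span) {
  n <- length(x)
  q <- max(2L, min(n, as.integer(ceiling(span * n))))
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    dmax <- sort(d)[q]
    if (dmax == 0) return(mean(y[d == 0]))
    w <- pmax(1 - pmin(d / dmax, 1)^3, 0)^3
    w[d >= dmax] <- 0
    if (sum(w > 0) < 2) w <- as.numeric(d <= dmax)
    fit <- stats::lm(y ~ x, weights = w, data = data.frame(x = x, y = y))
    unname(stats::predict(fit, newdata = data.frame(x = x[i])))
  }, numeric(1))
}

# Pearson chi-square computed directly from its definition.
chi2_oracle <- function(observed, ratio) {
  expected <- sum(observed) * ratio / sum(ratio)
  sum((observed - expected)^2 / expected)
}

# Welch two-sample t-test from first principles.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# Haldane map function: recombinant fraction at map distance d (Morgans).
haldane_r <- function(d_morgan) (1 - exp(-2 * d_morgan)) / 2

# Candidate-screen fixture: one variant passing all four criteria plus five
# violating exactly one each.
six_variant_fixture <- function() {
  data.frame(
    chrom = "chr3",
    pos = c(34500000,   # passes everything
            36000000,   # outside the region
            34510000,   # G-pool homozygous ref, not het
            34520000,   # Y-pool het, not hom alt
            34530000,   # synonymous effect
            34540000),  # Y-pool depth too low -> ambiguous call
    ref = "G", alt = "C",
    g_ref = c(30, 30, 58, 30, 30, 30),
    g_alt = c(30, 30,  2, 30, 30, 30),
    y_ref = c( 0,  0,  0, 30,  0,  0),
    y_alt = c(60, 60, 60, 30, 60,  5),
    effect = c("nonsynonymous", "nonsynonymous", "nonsynonymous",
               "nonsynonymous", "synonymous", "nonsynonymous"),
    gene_id = paste0("gene", 1:6)
  )
}

# Small single-chromosome genome for fast simulation tests: n_markers
# markers spaced 1 Mb apart.
tiny_genome <- function(n_markers = 11, length_cm = 100,
                        causal_marker = (n_markers + 1) %/% 2) {
  genome_model(
    chromosomes = data.frame(name = "chr1", length_bp = n_markers * 1e6,
                             length_cm = length_cm),
    marker_spacing_bp = 1e6,
    causal = list(chrom = "chr1", pos = causal_marker * 1e6)
  )
}
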