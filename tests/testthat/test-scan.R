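test_that("allele frequencies are alt/(ref+alt) with a per-pool depth filter", {
  v <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                  ref = "A", alt = "T",
                  g_ref = c(50, 2, 40), g_alt = c(50, 2, 20),
                  y_ref = c(0, 40, 0), y_alt = c(80, 40, 75))
  out <- allele_frequencies(v, min_depth = 10)
  expect_equal(nrow(out), 2)                         # site 2 fails in G
  expect_equal(attr(out, "n_depth_filtered"), 1)
  expect_equal(out$f_g, c(0.5, 1 / 3))
  expect_equal(out$f_y, c(1, 1))
  # zero depth in a pool can never reach division: it is filtered out
  z <- data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "T",
                  g_ref = 0, g_alt = 0, y_ref = 10, y_alt = 10)
  expect_equal(nrow(allele_frequencies(z, min_depth = 0)), 0)
})

test_that("ED is sqrt(2)|f_G - f_Y|, symmetric and bounded", {
  expect_equal(ed_statistic(0.5, 0.5), 0)
  expect_equal(ed_statistic(0, 1), sqrt(2))
  expect_equal(ed_statistic(1 / 3, 1), sqrt(2) * 2 / 3)
  expect_equal(association_value(ed_statistic(1 / 3, 1)), 8 / 9)
  expect_error(ed_statistic(-0.1, 0.5), "0, 1")
  expect_error(ed_statistic(0.5, 1.2), "0, 1")
  set.seed(1)
  f1 <- runif(200)
  f2 <- runif(200)
  ed <- ed_statistic(f1, f2)
  expect_equal(ed, ed_statistic(f2, f1))             # pool symmetry
  expect_true(all(ed >= 0 & ed <= sqrt(2)))
  expect_true(all(association_value(ed) <= 2))
  expect_equal(ed, sqrt(2) * abs(f1 - f2))
})

test_that("loess_fit reproduces constants and is exact on linear data", {
  x <- sort(runif(100, 1, 1e6))
  expect_equal(loess_fit(x, rep(3.7, 100), span = 0.3), rep(3.7, 100))
  for (span in c(0.05, 0.1, 0.5, 1)) {
    y <- 2 + 5e-6 * x
    expect_equal(loess_fit(x, y, span = span), y, tolerance = 1e-8)
  }
  expect_warning(f1 <- loess_fit(1, 5, span = 0.5), "fewer than 2")
  expect_equal(f1, 5)
})

test_that("loess_fit equals the brute-force tricube WLS oracle", {
  set.seed(20)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    x <- sort(sample(1:(n * 50), n)) * 1000
    y <- as.numeric(x > median(x)) + rnorm(n, sd = 0.3)  # noisy step
    span <- sample(c(0.1, 0.25, 0.6), 1)
    expect_equal(loess_fit(x, y, span), loess_oracle(x, y, span),
                 tolerance = 1e-8)
  }
})

test_that("sliding windows average the sites they contain", {
  # hand-built 10-site toy track, one window of 3 sites checked by hand
  track <- data.frame(chrom = "chr1", pos = (1:10) * 100,
                      fitted = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  w <- sliding_window(track, window_bp = 300, step_bp = 300)
  # window [1, 300] holds sites 100, 200, 300 -> mean 2
  expect_equal(w$mean_fitted[1], mean(c(1, 2, 3)))
  expect_equal(w$n_sites[1], 3)
  # windows tile from position 1
  expect_equal(w$start[1], 1)
  # uniform fitted value: every non-empty window mean equals it
  track$fitted <- 4.2
  w2 <- sliding_window(track, window_bp = 250, step_bp = 100)
  expect_equal(w2$mean_fitted[w2$n_sites > 0],
               rep(4.2, sum(w2$n_sites > 0)))
  # an empty window carries NA
  gap <- data.frame(chrom = "chr1", pos = c(100, 5000), fitted = c(1, 2))
  w3 <- sliding_window(gap, window_bp = 200, step_bp = 200)
  expect_true(any(is.na(w3$mean_fitted)))
  expect_equal(w3$n_sites[is.na(w3$mean_fitted)],
               rep(0L, sum(is.na(w3$mean_fitted))))
  # one site per window: mean equals that site's value
  one <- data.frame(chrom = "chr1", pos = c(150, 450), fitted = c(2.5, 7.5))
  w4 <- sliding_window(one, window_bp = 300, step_bp = 300)
  expect_equal(w4$mean_fitted, c(2.5, 7.5))
})

test_that("the top-quantile threshold selects the expected fraction", {
  vals <- 1:1000
  thr <- top_quantile_threshold(vals, 0.99)
  expect_equal(sum(vals >= thr), 10)                 # 1% of a uniform grid
  expect_equal(thr, unname(quantile(vals, 0.99)))    # type-7 interpolation
  expect_equal(top_quantile_threshold(rep(5, 8), 0.99), 5)
  expect_equal(sum(rep(5, 8) >= 5), 8)               # ties all selected
  expect_equal(top_quantile_threshold(3.2, 0.99), 3.2)
  expect_error(top_quantile_threshold(numeric(0), 0.99), "no non-missing")
})

test_that("regions merge nearby above-threshold windows and track the peak", {
  w <- data.frame(chrom = "chr1",
                  start = c(1, 10001, 30001, 200001),
                  end = c(10000, 20000, 40000, 210000),
                  mean_fitted = c(0.9, 1.2, 1.0, 0.95),
                  n_sites = c(3L, 4L, 2L, 5L))
  # single above-threshold window -> that window back
  r1 <- call_regions(w[2, ], threshold = 1.1, merge_gap_bp = 1e5)
  expect_equal(nrow(r1), 1)
  expect_equal(c(r1$start, r1$end), c(10001, 20000))
  # windows 10 kb apart merge under a 100 kb gap; the 160 kb gap does not
  r2 <- call_regions(w, threshold = 0.89, merge_gap_bp = 1e5)
  expect_equal(nrow(r2), 2)
  expect_equal(c(r2$start[1], r2$end[1]), c(1, 40000))
  expect_equal(r2$peak_fitted[1], 1.2)
  expect_true(all(r2$start <= r2$peak_pos & r2$peak_pos <= r2$end))
  # with a 10 kb merge gap only the touching pair stays together
  r3 <- call_regions(w, threshold = 0.89, merge_gap_bp = 1e4)
  expect_equal(nrow(r3), 3)
  expect_equal(c(r3$start[1], r3$end[1]), c(1, 20000))
  # nothing above threshold is a valid empty call
  expect_equal(nrow(call_regions(w, threshold = 2)), 0)
})

test_that("the scan composes deterministically and ignores row order", {
  sim <- simulate_bsa_experiment(seed = 4)
  res <- bsa_scan(sim$variants)
  shuffled <- sim$variants[sample(nrow(sim$variants)), ]
  res2 <- bsa_scan(shuffled)
  expect_equal(res$track, res2$track)
  expect_equal(res$regions, res2$regions)
  # report tracks the filter bookkeeping
  expect_equal(res$report$n_input, 4400)
  expect_true(res$report$n_depth_ok <= res$report$n_biallelic)
  # the causal position falls inside a called region on chr3
  hit <- res$regions[res$regions$chrom == "chr3" &
                       res$regions$start <= 34500000 &
                       res$regions$end >= 34500000, ]
  expect_equal(nrow(hit), 1)
})

test_that("an empty variant table yields empty track, regions and zero counts", {
  v <- data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
                  alt = character(0), g_ref = integer(0), g_alt = integer(0),
                  y_ref = integer(0), y_alt = integer(0))
  res <- bsa_scan(v)
  expect_equal(nrow(res$track), 0)
  expect_equal(nrow(res$regions), 0)
  expect_equal(res$report$n_input, 0)
  expect_equal(res$report$n_depth_ok, 0)
})

test_that("site-level thresholding is available as an alternative", {
  sim <- simulate_bsa_experiment(seed = 4)
  res <- bsa_scan(sim$variants, scan_params(threshold_on = "sites"))
  expect_true(nrow(res$regions) >= 1)
  hit <- res$regions[res$regions$chrom == "chr3" &
                       res$regions$start <= 34500000 &
                       res$regions$end >= 34500000, ]
  expect_equal(nrow(hit), 1)
})

test_that("multi-allelic records are dropped with a message", {
  v <- data.frame(chrom = "chr1", pos = c(100, 200, 300), ref = "A",
                  alt = c("T", "T,C", "G"),
                  g_ref = 30, g_alt = 30, y_ref = 30, y_alt = 30)
  expect_message(res <- bsa_scan(v), "non-biallelic")
  expect_equal(res$report$n_biallelic, 2)
})

test_that("variant tables round-trip through VCF", {
  sim <- simulate_bsa_experiment(tiny_genome(), cross_design(n_f2 = 100),
                                 seed = 2)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sim_vcf(sim$variants, path,
                contig_lengths = c(chr1 = 11e6))
  back <- read_ad_vcf(path)
  orig <- sim$variants
  orig$pos <- as.integer(orig$pos)
  expect_equal(back, orig)

  # empty table -> header-only VCF that reads back as zero rows
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_sim_vcf(orig[0, ], p2)
  lines <- readLines(p2)
  expect_true(all(startsWith(lines, "#")))
  expect_equal(nrow(read_ad_vcf(p2)), 0)

  # a site at chr3:34,500,000 keeps its 1-based coordinate
  one <- data.frame(chrom = "chr3", pos = 34500000, ref = "A", alt = "T",
                    g_ref = 10L, g_alt = 10L, y_ref = 0L, y_alt = 20L)
  p3 <- withr::local_tempfile(fileext = ".vcf")
  write_sim_vcf(one, p3)
  expect_equal(read_ad_vcf(p3)$pos, 34500000L)
})
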