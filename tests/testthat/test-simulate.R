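test_that("gametes from a zero-length chromosome copy a parental haplotype", {
  set.seed(1)
  pos <- seq(1e6, 1e7, by = 1e6)
  hap1 <- rep(0L, 10)
  hap2 <- rep(1L, 10)
  picks <- replicate(400, {
    g <- simulate_gamete(hap1, hap2, 0, pos)
    expect_true(identical(g, hap1) || identical(g, hap2))
    identical(g, hap1)
  })
  # each parental haplotype chosen with probability 1/2
  expect_gt(mean(picks), 0.5 - 3 * sqrt(0.25 / 400))
  expect_lt(mean(picks), 0.5 + 3 * sqrt(0.25 / 400))
  expect_error(simulate_gamete(hap1, hap2, -1, pos), "length_cm")
})

test_that("meiosis matches Poisson crossover counts and the Haldane map", {
  set.seed(42)
  n_rep <- 10000
  # observed haplotype switches on a dense grid; expected switch count from
  # the Haldane oracle applied per marker interval (sub-Poisson because
  # double crossovers inside an interval are invisible)
  m <- 200
  pos <- seq_len(m) * 1e4
  hap1 <- rep(0L, m)
  hap2 <- rep(1L, m)
  switches <- replicate(n_rep, {
    g <- simulate_gamete(hap1, hap2, 100, pos, length_bp = m * 1e4)
    sum(diff(g) != 0)
  })
  # each of the m-1 marker intervals spans 1/m of the 1-Morgan chromosome
  exp_switches <- (m - 1) * haldane_r(1 / m)
  se <- sd(switches) / sqrt(n_rep)
  expect_lt(abs(mean(switches) - exp_switches), 3 * se)

  # two markers 50 cM apart: recombinant fraction from the Haldane oracle
  pos2 <- c(2.5e5, 7.5e5)
  rec <- replicate(n_rep, {
    g <- simulate_gamete(c(0L, 0L), c(1L, 1L), 100, pos2, length_bp = 1e6)
    g[1] != g[2]
  })
  r_exp <- haldane_r(0.5)
  expect_lt(abs(mean(rec) - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / n_rep))
})

test_that("F2 populations segregate 3:1 with the recessive phenotype rule", {
  genome <- tiny_genome(n_markers = 3)
  design <- cross_design(n_f2 = 10000, pool_size = 15)
  pop <- simulate_f2_population(genome, design, seed = 7)
  n_yellow <- sum(pop$phenotype == "yellow")
  # inside the binomial 99% interval around 1/4
  expect_lt(abs(n_yellow / 10000 - 0.25),
            qnorm(0.995) * sqrt(0.25 * 0.75 / 10000))
  # chi-square against 3:1 does not reject
  expect_gt(population_segregation(pop)$p_value, 0.001)
  # recessive rule: every yellow individual is homozygous mutant
  g <- genotype_at(pop, genome$causal$chrom, genome$causal$pos)
  expect_true(all(g[pop$phenotype == "yellow"] == 2L))
  expect_true(all(g[pop$phenotype == "green"] < 2L))
  # among green plants the mutant-allele frequency tends to 1/3
  f_green <- mean(g[pop$phenotype == "green"]) / 2
  expect_lt(abs(f_green - 1 / 3), 0.02)
})

test_that("pools are drawn within class, disjoint, and fail loudly when short", {
  genome <- tiny_genome(n_markers = 3)
  pop <- simulate_f2_population(genome, cross_design(n_f2 = 150), seed = 11)
  pools <- build_pools(pop, seed = 1)
  expect_length(pools$yellow, 15)
  expect_length(unique(pools$yellow), 15)
  expect_true(all(pop$phenotype[pools$yellow] == "yellow"))
  expect_true(all(pop$phenotype[pools$green] == "green"))
  expect_length(intersect(pools$green, pools$yellow), 0)
  # yellow pool is fixed for the mutant allele at the causal marker
  f <- pool_allele_freq(pop, pools$yellow)
  causal <- f$pos == genome$causal$pos
  expect_identical(f$freq[causal], 1)

  # too few yellow plants: the error names the deficient class
  small <- pop
  small$phenotype[small$phenotype == "yellow"][-(1:10)] <- "green"
  expect_error(build_pools(small, cross_design(n_f2 = 150)), "yellow")
})

test_that("green-pool causal-locus frequency averages 1/3 across replicates", {
  genome <- tiny_genome(n_markers = 3)
  design <- cross_design(n_f2 = 150, pool_size = 15)
  set.seed(3)
  f_g <- replicate(50, {
    pop <- simulate_f2_population(genome, design)
    pools <- build_pools(pop)
    f <- pool_allele_freq(pop, pools$green)
    f$freq[f$pos == genome$causal$pos]
  })
  se <- sd(f_g) / sqrt(length(f_g))
  expect_lt(abs(mean(f_g) - 1 / 3), 3 * se)
})

test_that("pooled depths follow the sequencing model", {
  genome <- tiny_genome(n_markers = 3)
  pop <- simulate_f2_population(genome, cross_design(n_f2 = 150), seed = 5)
  pools <- build_pools(pop, seed = 5)

  # with no error the causal site is pure alt in the yellow pool
  v0 <- simulate_pool_depths(pop, pools, seq_model(error_rate = 0), seed = 5)
  causal <- v0$pos == genome$causal$pos
  expect_identical(v0$y_ref[causal], 0L)
  expect_gt(v0$y_alt[causal], 0)

  # mean total depth matches the Poisson mean within 3 SE over many sites
  many <- tiny_genome(n_markers = 100, causal_marker = 50)
  pop2 <- simulate_f2_population(many, cross_design(n_f2 = 150), seed = 6)
  pools2 <- build_pools(pop2, seed = 6)
  reps <- do.call(rbind, lapply(1:100, function(i)
    simulate_pool_depths(pop2, pools2, seq_model(coverage_y = 75))))
  depth_y <- reps$y_ref + reps$y_alt
  expect_lt(abs(mean(depth_y) - 75), 3 * sqrt(75 / length(depth_y)))
})

test_that("pool frequency contrast is centred on zero at unlinked sites", {
  # phenotype independent of genotype removes any causal signal
  genome <- genome_model(
    chromosomes = data.frame(name = "chr1", length_bp = 50e6, length_cm = 100),
    marker_spacing_bp = 1e4, causal = NULL)
  pop <- simulate_f2_population(genome,
                                cross_design(n_f2 = 150,
                                             phenotype_model = "random"),
                                seed = 8)
  pools <- build_pools(pop, seed = 8)
  v <- simulate_pool_depths(pop, pools, seq_model(), seed = 8)
  fr <- allele_frequencies(v, min_depth = 10)
  delta <- fr$f_g - fr$f_y
  # sites share pool individuals, so use the observed spread for the SE
  expect_lt(abs(mean(delta)), 3 * sd(delta))
})

test_that("a fixed seed reproduces the variant table bit for bit", {
  a <- simulate_bsa_experiment(tiny_genome(), cross_design(n_f2 = 100),
                               seq_model(), seed = 123)
  b <- simulate_bsa_experiment(tiny_genome(), cross_design(n_f2 = 100),
                               seq_model(), seed = 123)
  expect_identical(a$variants, b$variants)
  expect_identical(a$population$phenotype, b$population$phenotype)
})

test_that("allele frequency decays from the causal locus toward 0.5", {
  genome <- tiny_genome(n_markers = 21, length_cm = 200, causal_marker = 11)
  design <- cross_design(n_f2 = 150, pool_size = 15)
  set.seed(9)
  freq <- replicate(60, {
    pop <- simulate_f2_population(genome, design)
    pools <- build_pools(pop)
    pool_allele_freq(pop, pools$yellow)$freq
  })
  avg <- rowMeans(freq)
  dist_mb <- abs(seq_len(21) - 11)
  bins <- cut(dist_mb, breaks = c(-0.5, 0.5, 3.5, 6.5, 10.5))
  binned <- tapply(avg, bins, mean)
  expect_true(all(diff(binned) < 0))
  expect_gt(binned[1], 0.99)
  expect_lt(binned[length(binned)], 0.75)
})
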