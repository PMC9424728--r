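# F2 pool-seq simulator: Haldane (no-interference) meiosis over a regular
# marker grid, recessive phenotype model, extreme-phenotype pools, and
# read-depth sampling with a symmetric per-read error.
#
# All randomness flows from R's global RNG; the convenience wrappers accept a
# `seed` and fan it out deterministically per stage (see stage_seed()).

#' Simulate one gamete from a parent haplotype pair
#'
#' Meiosis without crossover interference: the crossover count on a
#' chromosome is Poisson with mean `length_cm / 100`, crossover positions are
#' uniform along the physical chromosome (uniform recombination is assumed,
#' so physical and genetic positions are proportional), and the gamete
#' alternates between the two parental haplotypes at each crossover, starting
#' from either haplotype with probability 1/2.  Under this model the
#' recombinant fraction between two markers follows the Haldane map function
#' r = (1 - exp(-2d)) / 2 for map distance d in Morgans.
#'
#' @param hap1,hap2 parental haplotypes: equal-length 0/1 vectors over the
#'   marker grid.
#' @param length_cm genetic length of the chromosome in centimorgans (>= 0).
#' @param marker_pos physical marker positions (bp), ascending.
#' @param length_bp physical chromosome length; defaults to the last marker.
#' @return a 0/1 vector of the same length as the parental haplotypes.
#' @examples
#' set.seed(1)
#' simulate_gamete(rep(0, 10), rep(1, 10), length_cm = 100,
#'                 marker_pos = seq(1e6, 1e7, by = 1e6))
#' @export
simulate_gamete <- function(hap1, hap2, length_cm, marker_pos,
                            length_bp = max(marker_pos)) {
  assert_that(length(hap1) == length(hap2) &&
                length(hap1) == length(marker_pos),
              "haplotypes and marker grid must have equal length")
  assert_scalar_number(length_cm, "length_cm", lower = 0)
  n_xo <- stats::rpois(1L, length_cm / 100)
  start <- stats::rbinom(1L, 1L, 0.5)
  if (n_xo == 0L) {
    return(if (start == 0L) hap1 else hap2)
  }
  xo <- sort(stats::runif(n_xo, 0, length_bp))
  segment <- findInterval(marker_pos, xo)
  ifelse((segment + start) %% 2L == 0L, hap1, hap2)
}

#' Simulate an F2 population from a fully heterozygous F1
#'
#' The founder parents are fixed for opposite alleles at every marker (an
#' inbred-line cross), so the F1 is heterozygous throughout; each F2
#' individual is the union of two independent F1 gametes.  Phenotype is
#' assigned by the recessive rule at the causal locus (yellow iff both
#' haplotypes carry the mutant allele) or, under the `"random"` phenotype
#' model, independently of genotype with P(yellow) = 1/4.
#'
#' @param genome a [genome_model()].
#' @param design a [cross_design()].
#' @param seed optional integer seed (set before any draws).
#' @return an object of class `f2_population`: per-chromosome haplotype
#'   matrices (`hap_a`, `hap_b`; individuals x markers; 1 = mutant allele),
#'   a `phenotype` factor (`green`/`yellow`), and the generating models.
#' @export
simulate_f2_population <- function(genome, design, seed = NULL) {
  assert_that(inherits(genome, "genome_model"), "`genome` must be a genome_model")
  assert_that(inherits(design, "cross_design"), "`design` must be a cross_design")
  if (design$phenotype_model == "recessive") {
    assert_that(!is.null(genome$causal),
                "recessive phenotype model needs a causal locus in the genome")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_f2
  chroms <- genome$chromosomes
  geno <- vector("list", nrow(chroms))
  names(geno) <- chroms$name
  for (i in seq_len(nrow(chroms))) {
    pos <- marker_positions(genome, chroms$name[i])
    m <- length(pos)
    hap0 <- rep(0L, m)
    hap1 <- rep(1L, m)
    hap_a <- matrix(0L, n, m)
    hap_b <- matrix(0L, n, m)
    for (j in seq_len(n)) {
      hap_a[j, ] <- simulate_gamete(hap0, hap1, chroms$length_cm[i], pos,
                                    chroms$length_bp[i])
      hap_b[j, ] <- simulate_gamete(hap0, hap1, chroms$length_cm[i], pos,
                                    chroms$length_bp[i])
    }
    geno[[i]] <- list(pos = pos, hap_a = hap_a, hap_b = hap_b)
  }
  phenotype <- if (design$phenotype_model == "recessive") {
    ci <- match(genome$causal$chrom, chroms$name)
    mi <- match(genome$causal$pos, geno[[ci]]$pos)
    g <- geno[[ci]]$hap_a[, mi] + geno[[ci]]$hap_b[, mi]
    ifelse(g == 2L, "yellow", "green")
  } else {
    ifelse(stats::runif(n) < 0.25, "yellow", "green")
  }
  structure(list(genome = genome, design = design, chrom = geno,
                 phenotype = phenotype),
            class = "f2_population")
}

#' @export
print.f2_population <- function(x, ...) {
  cat("F2 population:", x$design$n_f2, "individuals;",
      sum(x$phenotype == "green"), "green /",
      sum(x$phenotype == "yellow"), "yellow\n")
  invisible(x)
}

#' Genotype (mutant-allele dosage) at one marker
#'
#' @param pop an `f2_population`.
#' @param chrom,pos marker coordinates (must be on the grid).
#' @return integer vector in {0, 1, 2}, one per individual.
#' @export
genotype_at <- function(pop, chrom, pos) {
  ci <- match(chrom, names(pop$chrom))
  assert_that(!is.na(ci), sprintf("unknown chromosome '%s'", chrom))
  mi <- match(pos, pop$chrom[[ci]]$pos)
  assert_that(!is.na(mi), sprintf("position %s is not a marker on %s",
                                  format(pos, scientific = FALSE), chrom))
  pop$chrom[[ci]]$hap_a[, mi] + pop$chrom[[ci]]$hap_b[, mi]
}

#' Draw the two extreme-phenotype pools
#'
#' Samples `pool_size` individuals uniformly without replacement from the
#' green class and, independently, from the yellow class.  The two pools are
#' disjoint by construction (no individual belongs to both classes).
#'
#' @param pop an `f2_population`.
#' @param design a [cross_design()]; defaults to the one the population was
#'   simulated with.
#' @param seed optional integer seed.
#' @return an object of class `bsa_pools`: `list(green =, yellow =)` index
#'   vectors plus `pool_size`.
#' @export
build_pools <- function(pop, design = pop$design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- design$pool_size
  idx <- lapply(c(green = "green", yellow = "yellow"), function(cls) {
    avail <- which(pop$phenotype == cls)
    if (length(avail) < k) {
      stop(sprintf("too few %s individuals to fill the pool (have %d, need %d)",
                   cls, length(avail), k), call. = FALSE)
    }
    sample(avail, k)
  })
  structure(list(green = idx$green, yellow = idx$yellow, pool_size = k),
            class = "bsa_pools")
}

#' @noRd
pool_freq_chrom <- function(pop, idx, ci) {
  ch <- pop$chrom[[ci]]
  (colSums(ch$hap_a[idx, , drop = FALSE]) +
     colSums(ch$hap_b[idx, , drop = FALSE])) / (2 * length(idx))
}

#' True pooled mutant-allele frequencies
#'
#' @param pop an `f2_population`.
#' @param idx individual indices forming the pool.
#' @return data.frame chrom, pos, freq (frequency of the mutant allele among
#'   the pool's 2 x pool_size chromosomes, before any sequencing).
#' @export
pool_allele_freq <- function(pop, idx) {
  out <- lapply(seq_along(pop$chrom), function(ci) {
    data.frame(chrom = names(pop$chrom)[ci], pos = pop$chrom[[ci]]$pos,
               freq = pool_freq_chrom(pop, idx, ci))
  })
  do.call(rbind, out)
}

#' Simulate pooled read depths at every marker
#'
#' Per site and pool the total depth is Poisson with the pool's mean
#' coverage; each read samples one of the pool's `2 * pool_size` chromosomes
#' uniformly and is read as the opposite allele with probability
#' `error_rate`.  Equivalently the alt-read count is binomial with success
#' probability `f * (1 - e) + (1 - f) * e` where `f` is the pool's true
#' mutant-allele frequency.  The mutant allele is written as the ALT allele.
#'
#' @param pop an `f2_population`.
#' @param pools a [build_pools()] result.
#' @param seq a [seq_model()].
#' @param seed optional integer seed.
#' @return data.frame with columns chrom, pos (1-based), ref, alt, g_ref,
#'   g_alt, y_ref, y_alt.
#' @export
simulate_pool_depths <- function(pop, pools, seq = seq_model(), seed = NULL) {
  assert_that(inherits(seq, "seq_model"), "`seq` must be a seq_model")
  if (!is.null(seed)) set.seed(seed)
  e <- seq$error_rate
  out <- lapply(seq_along(pop$chrom), function(ci) {
    pos <- pop$chrom[[ci]]$pos
    m <- length(pos)
    f_g <- pool_freq_chrom(pop, pools$green, ci)
    f_y <- pool_freq_chrom(pop, pools$yellow, ci)
    d_g <- stats::rpois(m, seq$coverage_g)
    d_y <- stats::rpois(m, seq$coverage_y)
    g_alt <- stats::rbinom(m, d_g, f_g * (1 - e) + (1 - f_g) * e)
    y_alt <- stats::rbinom(m, d_y, f_y * (1 - e) + (1 - f_y) * e)
    data.frame(chrom = names(pop$chrom)[ci], pos = pos,
               ref = "A", alt = "T",
               g_ref = d_g - g_alt, g_alt = g_alt,
               y_ref = d_y - y_alt, y_alt = y_alt)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the whole pooled-sequencing simulation
#'
#' Convenience wrapper: population, pools, and read depths in one call, with
#' one user seed fanned out deterministically to the three stages so each can
#' be reproduced independently.
#'
#' @param genome a [genome_model()].
#' @param design a [cross_design()].
#' @param seq a [seq_model()].
#' @param seed integer seed in [0, 2^28).
#' @return list with elements `population`, `pools`, `variants`.
#' @examples
#' sim <- simulate_bsa_experiment(seed = 1)
#' head(sim$variants)
#' @export
simulate_bsa_experiment <- function(genome = genome_model(),
                                    design = cross_design(),
                                    seq = seq_model(), seed = 1) {
  pop <- simulate_f2_population(genome, design,
                                seed = stage_seed(seed, "population"))
  pools <- build_pools(pop, design, seed = stage_seed(seed, "pools"))
  variants <- simulate_pool_depths(pop, pools, seq,
                                   seed = stage_seed(seed, "depths"))
  list(population = pop, pools = pools, variants = variants)
}

#' Write individual phenotypes and causal-locus genotypes as TSV
#'
#' One row per F2 individual: id, phenotype, and (when the genome has a
#' causal locus) the mutant-allele dosage there — the inputs of the
#' segregation tests.
#'
#' @param pop an `f2_population`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_population_tsv <- function(pop, path) {
  df <- data.frame(id = seq_along(pop$phenotype), phenotype = pop$phenotype)
  if (!is.null(pop$genome$causal)) {
    df$causal_genotype <- genotype_at(pop, pop$genome$causal$chrom,
                                      pop$genome$causal$pos)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
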