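# End-to-end orchestration: validated configuration, deterministic seeding,
# and a run directory holding every stage's outputs plus a JSON manifest.

#' Default pipeline configuration
#'
#' Nested list mirroring the stages: `simulation` (genome layout, cross
#' design, sequencing model), `scan` (ED-scan parameters) and `candidates`
#' (zygosity bands, effect classes, DEG thresholds, promoter window).
#'
#' @return a config list accepted by [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1,
    simulation = list(
      chromosomes = default_chromosomes(),
      marker_spacing_bp = 50000,
      causal = list(chrom = "chr3", pos = 34500000),
      n_f2 = 150,
      pool_size = 15,
      phenotype_model = "recessive",
      coverage_g = 95,
      coverage_y = 75,
      error_rate = 0.01
    ),
    scan = list(
      min_depth = 10, span = 0.1, window_bp = 1e6, step_bp = 1e5,
      quantile = 0.99, merge_gap_bp = 1e5, threshold_on = "windows"
    ),
    candidates = list(
      het_band = c(0.2, 0.8), hom_alt_min = 0.9, min_depth = 10,
      effects_keep = c("nonsynonymous", "splice_site", "inframe_indel"),
      fc_min = 1.5, q_max = 0.05, upstream_bp = 2000
    )
  )
}

#' Validate a pipeline configuration
#'
#' Checks block and key names against [default_config()] (unknown keys are
#' rejected), builds the model objects, and enforces cross-level
#' constraints (in particular `pool_size <= n_f2 / 4`, so both pools can be
#' expected to fill under 3:1 segregation).
#'
#' @param config a config list (missing keys fall back to defaults).
#' @return list with validated `genome`, `design`, `seq`, `scan_params`,
#'   `candidates`, `seed`.
#' @export
validate_config <- function(config) {
  defaults <- default_config()
  bad <- setdiff(names(config), names(defaults))
  assert_that(length(bad) == 0,
              paste("unknown config key(s):", paste(bad, collapse = ", ")))
  for (blk in c("simulation", "scan", "candidates")) {
    bad <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
    assert_that(length(bad) == 0,
                sprintf("unknown key(s) in `%s`: %s", blk,
                        paste(bad, collapse = ", ")))
    config[[blk]] <- utils::modifyList(defaults[[blk]],
                                       config[[blk]] %||% list())
  }
  seed <- config$seed %||% defaults$seed
  sim <- config$simulation
  if (is.data.frame(sim$chromosomes)) {
    chroms <- sim$chromosomes
  } else {
    chroms <- do.call(rbind, lapply(sim$chromosomes, as.data.frame))
  }
  genome <- genome_model(chroms, sim$marker_spacing_bp, sim$causal)
  assert_that(sim$pool_size <= sim$n_f2 / 4,
              "pool_size must be <= n_f2 / 4 so both pools can fill")
  design <- cross_design(sim$n_f2, sim$pool_size, sim$phenotype_model)
  seqm <- seq_model(sim$coverage_g, sim$coverage_y, sim$error_rate)
  sp <- do.call(scan_params, config$scan)
  list(genome = genome, design = design, seq = seqm, scan_params = sp,
       candidates = config$candidates, seed = seed)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; keys as in [default_config()].
#' @return the validated configuration (see [validate_config()]).
#' @export
read_run_config <- function(path) {
  config <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(config)
}

# Synthetic gene annotation for the end-to-end demo: every marker inside the
# scanned region gets a 2-kb synthetic gene; the causal marker carries a
# nonsynonymous change and is differentially expressed, in-region decoys are
# synonymous or not DEGs.  Purely simulated stand-ins for a real annotation.
#' @noRd
synthetic_annotation <- function(variants, genome) {
  gene_id <- sprintf("SYNGENE_%s_%d", variants$chrom,
                     as.integer(variants$pos))
  effect <- rep("synonymous", nrow(variants))
  if (!is.null(genome$causal)) {
    causal <- variants$chrom == genome$causal$chrom &
      variants$pos == genome$causal$pos
    effect[causal] <- "nonsynonymous"
  }
  cbind(variants, data.frame(effect = effect, gene_id = gene_id))
}

#' @noRd
synthetic_degs <- function(annotated, genome, seed) {
  set.seed(seed)
  genes <- unique(annotated$gene_id)
  n_extra <- min(20L, length(genes))
  picked <- sample(genes, n_extra)
  df <- data.frame(gene_id = picked,
                   fold_change = stats::runif(n_extra, 1.6, 4),
                   q_value = stats::runif(n_extra, 0.0001, 0.04),
                   direction = sample(c("up", "down"), n_extra, replace = TRUE))
  if (!is.null(genome$causal)) {
    causal_gene <- sprintf("SYNGENE_%s_%d", genome$causal$chrom,
                           as.integer(genome$causal$pos))
    if (!causal_gene %in% df$gene_id) {
      df <- rbind(df, data.frame(gene_id = causal_gene, fold_change = 2.2,
                                 q_value = 0.003, direction = "down"))
    }
  }
  df[order(df$gene_id), , drop = FALSE]
}

#' Run the full pipeline into a directory
#'
#' Simulates the F2 pooled-sequencing experiment, runs the ED scan, tests
#' segregation, screens candidate SNPs in the top region against a
#' synthetic annotation and DEG table (labelled as such in the outputs),
#' and writes: `sim.vcf`, `population.tsv`, `track.tsv`, `windows.tsv`,
#' `regions.tsv`, `regions.bed`, `annotation.synthetic.tsv`,
#' `degs.synthetic.tsv`, `candidates.tsv` and `manifest.json`.  Identical
#' config and seed give byte-identical outputs (timestamps are confined to
#' the manifest).
#'
#' @param config a config list (see [default_config()]); validated before
#'   any stage runs.
#' @param out_dir run directory (created if needed).
#' @param seed overrides `config$seed` when given.
#' @return invisibly, a list with the in-memory stage results and file
#'   paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)

  message("stage simulate: ", cfg$design$n_f2, " F2 individuals, pools of ",
          cfg$design$pool_size)
  sim <- simulate_bsa_experiment(cfg$genome, cfg$design, cfg$seq, cfg$seed)
  contigs <- stats::setNames(cfg$genome$chromosomes$length_bp,
                             cfg$genome$chromosomes$name)
  write_sim_vcf(sim$variants, path("sim.vcf"), contigs)
  write_population_tsv(sim$population, path("population.tsv"))

  seg <- population_segregation(sim$population)
  message(sprintf("stage segregation: chi2 = %.2f, p = %.2f", seg$chi2,
                  seg$p_value))

  message("stage scan: ", nrow(sim$variants), " sites")
  res <- bsa_scan(sim$variants, cfg$scan_params)
  utils::write.table(res$track, path("track.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$windows, path("windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$regions, path("regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_regions_bed(res$regions, path("regions.bed"))
  message("stage scan: ", nrow(res$regions), " region(s) called")

  candidates <- NULL
  if (nrow(res$regions) > 0) {
    top <- res$regions[which.max(res$regions$peak_fitted), ]
    annotated <- synthetic_annotation(sim$variants, cfg$genome)
    degs <- synthetic_degs(annotated, cfg$genome,
                           stage_seed(cfg$seed, "degs"))
    utils::write.table(annotated, path("annotation.synthetic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(degs, path("degs.synthetic.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cc <- cfg$candidates
    flt <- filter_candidate_snps(annotated, top,
                                 effects_keep = cc$effects_keep,
                                 het_band = cc$het_band,
                                 hom_alt_min = cc$hom_alt_min,
                                 min_depth = cc$min_depth)
    deg_hits <- deg_intersection(flt$candidates$gene_id, degs,
                                 cc$fc_min, cc$q_max)
    candidates <- flt$candidates[flt$candidates$gene_id %in% deg_hits, ,
                                 drop = FALSE]
    utils::write.table(candidates, path("candidates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    message("stage candidates: ", flt$n_retained,
            " SNP(s) pass screening, ", nrow(candidates), " also DEG")
  }

  manifest <- list(
    package = "bsaED",
    version = as.character(utils::packageVersion("bsaED")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    parameters = list(
      simulation = list(n_f2 = cfg$design$n_f2,
                        pool_size = cfg$design$pool_size,
                        phenotype_model = cfg$design$phenotype_model,
                        coverage_g = cfg$seq$coverage_g,
                        coverage_y = cfg$seq$coverage_y,
                        error_rate = cfg$seq$error_rate,
                        marker_spacing_bp = cfg$genome$marker_spacing_bp,
                        causal = cfg$genome$causal),
      scan = unclass(cfg$scan_params),
      candidates = cfg$candidates
    ),
    segregation = list(observed = as.list(seg$observed), chi2 = seg$chi2,
                       p_value = seg$p_value),
    counts = res$report,
    threshold = res$threshold,
    regions = res$regions,
    files = list.files(out_dir)
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(config = cfg, simulation = sim, segregation = seg,
                 scan = res, candidates = candidates, out_dir = out_dir))
}
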