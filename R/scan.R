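# The ED-statistic genome scan.  For each biallelic SNP the two pools'
# alt-allele frequencies f_G, f_Y are contrasted by the Euclidean distance
# over the allele-frequency vectors,
#
#   ED = sqrt((f_G - f_Y)^2 + ((1 - f_G) - (1 - f_Y))^2) = sqrt(2) |f_G - f_Y|,
#
# squared to suppress background noise, smoothed along each chromosome by
# tricube local-linear (LOESS) regression, aggregated in sliding windows,
# and thresholded at a top genome-wide quantile to call candidate regions.

#' Scan parameters
#'
#' @param min_depth minimum total read depth per pool; sites below it in
#'   either pool are removed before frequencies are computed.  Default 10
#'   bounds the per-pool frequency standard error at roughly 0.16.
#' @param span LOESS span: fraction of a chromosome's sites forming each
#'   local neighbourhood (default 0.1, which resolves Mb-scale peaks at
#'   50 kb marker spacing).
#' @param window_bp,step_bp sliding-window width and step (defaults 1 Mb /
#'   100 kb; windows must be no wider than the peaks they should resolve).
#' @param quantile genome-wide quantile defining the association threshold
#'   (default 0.99: the "top 1%" rule).
#' @param merge_gap_bp above-threshold runs closer than this are merged into
#'   one region (default 100 kb).
#' @param threshold_on apply the top-quantile rule to `"windows"` (window
#'   means; default) or `"sites"` (per-site fitted values).
#' @return list of class `scan_params`.
#' @export
scan_params <- function(min_depth = 10, span = 0.1, window_bp = 1e6,
                        step_bp = 1e5, quantile = 0.99, merge_gap_bp = 1e5,
                        threshold_on = c("windows", "sites")) {
  threshold_on <- match.arg(threshold_on)
  assert_scalar_number(min_depth, "min_depth", lower = 0)
  assert_scalar_number(span, "span", lower = 0, strict_lower = TRUE, upper = 1)
  assert_scalar_number(window_bp, "window_bp", lower = 0, strict_lower = TRUE)
  assert_scalar_number(step_bp, "step_bp", lower = 0, strict_lower = TRUE)
  assert_that(window_bp >= step_bp, "`window_bp` must be >= `step_bp`")
  assert_scalar_number(quantile, "quantile", lower = 0, strict_lower = TRUE)
  assert_that(quantile < 1, "`quantile` must be < 1")
  assert_scalar_number(merge_gap_bp, "merge_gap_bp", lower = 0)
  structure(list(min_depth = min_depth, span = span, window_bp = window_bp,
                 step_bp = step_bp, quantile = quantile,
                 merge_gap_bp = merge_gap_bp, threshold_on = threshold_on),
            class = "scan_params")
}

#' Pool allele frequencies with a depth filter
#'
#' Computes per-pool alt-allele frequencies `f = alt / (ref + alt)` and
#' removes sites whose total depth in either pool is below `min_depth`
#' (which also removes any zero-depth pool, so no division by zero can
#' occur when `min_depth >= 1`).
#'
#' @param variants variant table (chrom, pos, g_ref, g_alt, y_ref, y_alt).
#' @param min_depth per-pool minimum total depth.
#' @return the retained rows with added columns g_depth, y_depth, f_g, f_y;
#'   attribute `n_depth_filtered` records how many sites were removed.
#' @export
allele_frequencies <- function(variants, min_depth = 10) {
  assert_that(all(c("g_ref", "g_alt", "y_ref", "y_alt") %in% names(variants)),
              "`variants` needs per-pool ref/alt depth columns")
  assert_that(all(variants$g_ref >= 0) && all(variants$g_alt >= 0) &&
                all(variants$y_ref >= 0) && all(variants$y_alt >= 0),
              "read depths must be non-negative")
  g_depth <- variants$g_ref + variants$g_alt
  y_depth <- variants$y_ref + variants$y_alt
  keep <- g_depth >= max(min_depth, 1) & y_depth >= max(min_depth, 1)
  out <- variants[keep, , drop = FALSE]
  out$g_depth <- g_depth[keep]
  out$y_depth <- y_depth[keep]
  out$f_g <- out$g_alt / out$g_depth
  out$f_y <- out$y_alt / out$y_depth
  rownames(out) <- NULL
  attr(out, "n_depth_filtered") <- sum(!keep)
  out
}

#' Euclidean-distance statistic between the two pools
#'
#' For a biallelic site with pool alt-allele frequencies `f_g`, `f_y`, the
#' distance between the pools' allele-frequency vectors (f, 1 - f) is
#' `sqrt(2) * |f_g - f_y|`, so ED lies in [0, sqrt(2)].
#'
#' @param f_g,f_y alt-allele frequencies in [0, 1] (vectorised).
#' @return ED values.
#' @examples
#' ed_statistic(1/3, 1)   # sqrt(2) * 2/3 at a recessive causal locus
#' @export
ed_statistic <- function(f_g, f_y) {
  assert_that(all(is.finite(f_g)) && all(is.finite(f_y)) &&
                all(f_g >= 0 & f_g <= 1) && all(f_y >= 0 & f_y <= 1),
              "allele frequencies must lie in [0, 1]")
  sqrt((f_g - f_y)^2 + ((1 - f_g) - (1 - f_y))^2)
}

#' Squared-ED association value
#'
#' Raising ED to its second power suppresses background noise relative to
#' true divergence; this squared value is what gets smoothed and
#' thresholded.
#'
#' @param ed ED values (>= 0).
#' @return ed squared.
#' @export
association_value <- function(ed) {
  assert_that(all(is.finite(ed)) && all(ed >= 0), "`ed` must be >= 0")
  ed^2
}

#' Tricube local-linear (LOESS) smoothing along one chromosome
#'
#' Degree-1 locally weighted regression: for each site, the
#' `ceiling(span * n)` nearest sites by genomic distance form the
#' neighbourhood, weighted by the tricube kernel `(1 - (d/dmax)^3)^3`, and a
#' weighted least-squares line is evaluated at the site.  Exact on linear
#' data for any span.  No robustness iterations.
#'
#' @param positions genomic positions (bp) of one chromosome's sites.
#' @param values values to smooth (same length).
#' @param span fraction of sites per neighbourhood, in (0, 1].
#' @return fitted values at every input site.  With fewer than 2 sites the
#'   raw values are returned with a warning.
#' @export
loess_fit <- function(positions, values, span = 0.1) {
  n <- length(positions)
  assert_that(length(values) == n, "`positions` and `values` lengths differ")
  assert_scalar_number(span, "span", lower = 0, strict_lower = TRUE, upper = 1)
  if (n < 2) {
    warning("fewer than 2 sites: returning raw values", call. = FALSE)
    return(values)
  }
  q <- max(2L, as.integer(ceiling(span * n)))
  q <- min(q, n)
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(positions - positions[i])
    dmax <- sort(d, partial = q)[q]
    if (dmax == 0) {        # all neighbours colocated: weighted mean
      w <- as.numeric(d == 0)
    } else {
      u <- d / dmax
      w <- ifelse(u < 1, (1 - u^3)^3, 0)
      w[d == dmax] <- 0     # boundary of the tricube support
      if (sum(w > 0) < 2) w <- as.numeric(d <= dmax)
    }
    xc <- positions - positions[i]
    sw <- sum(w)
    swx <- sum(w * xc)
    swy <- sum(w * values)
    swxx <- sum(w * xc * xc)
    swxy <- sum(w * xc * values)
    denom <- sw * swxx - swx^2
    fitted[i] <- if (denom <= 1e-10 * sw * max(swxx, 1)) {
      swy / sw
    } else {
      (swxx * swy - swx * swxy) / denom   # intercept of the local line at xc = 0
    }
  }
  fitted
}

#' Sliding-window aggregation of the fitted track
#'
#' Windows of width `window_bp` tile each chromosome starting at position 1
#' with step `step_bp`; each window averages the fitted values of the sites
#' it contains (`pos` in `[start, start + window_bp)`).  Empty windows carry
#' `NA` and are excluded from thresholding.
#'
#' @param track data.frame with chrom, pos, fitted.
#' @param window_bp,step_bp window width and step in bp.
#' @return data.frame chrom, start, end (1-based inclusive), mean_fitted,
#'   n_sites.
#' @export
sliding_window <- function(track, window_bp = 1e6, step_bp = 1e5) {
  assert_that(window_bp >= step_bp && step_bp > 0,
              "need window_bp >= step_bp > 0")
  assert_that(all(c("chrom", "pos", "fitted") %in% names(track)),
              "`track` needs columns chrom, pos, fitted")
  out <- lapply(unique(track$chrom), function(ch) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    ord <- order(sub$pos)
    pos <- sub$pos[ord]
    val <- sub$fitted[ord]
    starts <- seq(1, max(pos), by = step_bp)
    csum <- c(0, cumsum(val))
    lo <- findInterval(starts - 0.5, pos)
    hi <- findInterval(starts + window_bp - 0.5, pos)
    n <- hi - lo
    data.frame(chrom = ch, start = starts, end = starts + window_bp - 1,
               mean_fitted = ifelse(n > 0, (csum[hi + 1] - csum[lo + 1]) / n,
                                    NA_real_),
               n_sites = n)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top-quantile association threshold
#'
#' Genome-wide linear-interpolation quantile (R type 7) over all non-missing
#' values; selection downstream is `value >= threshold`, so ties at the
#' threshold are all selected.
#'
#' @param values window means (or site fitted values); `NA`s are dropped.
#' @param q quantile in (0, 1), default 0.99.
#' @return the threshold (scalar).
#' @export
top_quantile_threshold <- function(values, q = 0.99) {
  values <- values[!is.na(values)]
  assert_that(length(values) > 0, "no non-missing values to threshold")
  assert_scalar_number(q, "q", lower = 0, strict_lower = TRUE)
  assert_that(q < 1, "`q` must be < 1")
  stats::quantile(values, probs = q, type = 7, names = FALSE)
}

#' Call candidate regions from above-threshold windows
#'
#' Per chromosome, maximal runs of windows with `mean_fitted >= threshold`
#' are taken; runs whose gap is smaller than `merge_gap_bp` are merged.  A
#' region spans the minimum start to the maximum end of its member windows
#' (1-based inclusive); its peak is the member window with the largest mean
#' (peak position = that window's midpoint).
#'
#' @param windows a [sliding_window()] table.
#' @param threshold association threshold (see [top_quantile_threshold()]).
#' @param merge_gap_bp merge runs separated by less than this many bp.
#' @param track optional per-site track; when given, `n_sites` counts the
#'   distinct sites inside each region instead of summing (overlapping)
#'   window counts.
#' @return data.frame chrom, start, end, peak_pos, peak_fitted, n_windows,
#'   n_sites; zero rows when nothing exceeds the threshold.
#' @export
call_regions <- function(windows, threshold, merge_gap_bp = 1e5,
                         track = NULL) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), peak_pos = numeric(0),
                      peak_fitted = numeric(0), n_windows = integer(0),
                      n_sites = integer(0))
  sel <- windows[!is.na(windows$mean_fitted) &
                   windows$mean_fitted >= threshold, , drop = FALSE]
  if (nrow(sel) == 0) return(empty)
  out <- lapply(unique(sel$chrom), function(ch) {
    sub <- sel[sel$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    gap <- c(Inf, sub$start[-1] - cummax(sub$end)[-nrow(sub)] - 1)
    grp <- cumsum(gap >= merge_gap_bp)
    do.call(rbind, lapply(split(sub, grp), function(g) {
      peak <- g[which.max(g$mean_fitted), ]
      data.frame(chrom = ch, start = min(g$start), end = max(g$end),
                 peak_pos = floor((peak$start + peak$end) / 2),
                 peak_fitted = peak$mean_fitted,
                 n_windows = nrow(g), n_sites = sum(g$n_sites))
    }))
  })
  res <- do.call(rbind, out)
  if (!is.null(track)) {
    res$n_sites <- vapply(seq_len(nrow(res)), function(i) {
      sum(track$chrom == res$chrom[i] & track$pos >= res$start[i] &
            track$pos <= res$end[i])
    }, integer(1))
  }
  rownames(res) <- NULL
  res
}

#' @noRd
call_regions_sites <- function(track, threshold, merge_gap_bp) {
  pseudo <- data.frame(chrom = track$chrom, start = track$pos,
                       end = track$pos, mean_fitted = track$fitted,
                       n_sites = 1L)
  call_regions(pseudo, threshold, merge_gap_bp)
}

#' Run the full ED genome scan
#'
#' Deterministic composition: drop non-biallelic records, depth-filter and
#' compute pool frequencies, ED and squared ED per site, tricube
#' local-linear smoothing per chromosome, sliding-window aggregation, a
#' genome-wide top-quantile threshold, and region calling.  Input row order
#' never matters: sites are sorted by chromosome and position first.
#'
#' @param variants variant table (chrom, pos, ref, alt, g_ref, g_alt, y_ref,
#'   y_alt), e.g. from [read_ad_vcf()] or [simulate_pool_depths()].
#' @param params a [scan_params()].
#' @return object of class `bsa_scan`: `track` (per-site chrom, pos, f_g,
#'   f_y, ed, ed2, fitted), `windows`, `threshold`, `regions`, and a
#'   `report` of site counts at each filter stage.
#' @examples
#' sim <- simulate_bsa_experiment(seed = 1)
#' res <- bsa_scan(sim$variants)
#' res$regions
#' @export
bsa_scan <- function(variants, params = scan_params()) {
  assert_that(inherits(params, "scan_params"), "`params` must be scan_params()")
  report <- list(n_input = nrow(variants))
  empty_track <- data.frame(chrom = character(0), pos = numeric(0),
                            f_g = numeric(0), f_y = numeric(0),
                            ed = numeric(0), ed2 = numeric(0),
                            fitted = numeric(0))
  if (nrow(variants) == 0) {
    report <- c(report, list(n_biallelic = 0L, n_depth_ok = 0L,
                             n_windows = 0L, n_windows_nonempty = 0L,
                             n_regions = 0L))
    empty_windows <- data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), mean_fitted = numeric(0),
                                n_sites = integer(0))
    return(structure(list(track = empty_track, windows = empty_windows,
                          threshold = NA_real_,
                          regions = call_regions(empty_windows, Inf),
                          params = params, report = report),
                     class = "bsa_scan"))
  }
  biallelic <- !grepl(",", variants$alt %||% "", fixed = TRUE)
  if ("ref" %in% names(variants)) {
    biallelic <- biallelic & !grepl(",", variants$ref, fixed = TRUE)
  }
  if (any(!biallelic)) {
    message(sum(!biallelic), " non-biallelic record(s) dropped")
  }
  v <- variants[biallelic, , drop = FALSE]
  report$n_biallelic <- nrow(v)
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  v <- allele_frequencies(v, params$min_depth)
  report$n_depth_ok <- nrow(v)
  v$ed <- ed_statistic(v$f_g, v$f_y)
  v$ed2 <- association_value(v$ed)
  v$fitted <- NA_real_
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    v$fitted[idx] <- loess_fit(v$pos[idx], v$ed2[idx], params$span)
  }
  track <- v[, c("chrom", "pos", "f_g", "f_y", "ed", "ed2", "fitted")]
  rownames(track) <- NULL
  windows <- sliding_window(track, params$window_bp, params$step_bp)
  report$n_windows <- nrow(windows)
  report$n_windows_nonempty <- sum(!is.na(windows$mean_fitted))
  if (params$threshold_on == "windows") {
    threshold <- top_quantile_threshold(windows$mean_fitted, params$quantile)
    regions <- call_regions(windows, threshold, params$merge_gap_bp,
                            track = track)
  } else {
    threshold <- top_quantile_threshold(track$fitted, params$quantile)
    regions <- call_regions_sites(track, threshold, params$merge_gap_bp)
  }
  report$n_regions <- nrow(regions)
  structure(list(track = track, windows = windows, threshold = threshold,
                 regions = regions, params = params, report = report),
            class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  r <- x$report
  cat("ED genome scan\n")
  cat(sprintf("  sites: %d input, %d biallelic, %d after depth filter\n",
              r$n_input, r$n_biallelic %||% 0, r$n_depth_ok %||% 0))
  cat(sprintf("  windows: %d (%d non-empty); threshold (q = %.2f): %s\n",
              r$n_windows, r$n_windows_nonempty, x$params$quantile,
              format(x$threshold, digits = 4)))
  if (nrow(x$regions) == 0) {
    cat("  no region exceeds the threshold\n")
  } else {
    cat(sprintf("  %d region(s):\n", nrow(x$regions)))
    for (i in seq_len(nrow(x$regions))) {
      cat(sprintf("    %s:%s-%s (%.2f Mb), peak %s (ED2 = %.3f)\n",
                  x$regions$chrom[i],
                  format(x$regions$start[i], big.mark = ",", scientific = FALSE),
                  format(x$regions$end[i], big.mark = ",", scientific = FALSE),
                  (x$regions$end[i] - x$regions$start[i]) / 1e6,
                  format(x$regions$peak_pos[i], big.mark = ",",
                         scientific = FALSE),
                  x$regions$peak_fitted[i]))
    }
  }
  invisible(x)
}

#' Export called regions as BED
#'
#' Internally coordinates are 1-based inclusive (VCF convention); BED output
#' converts to 0-based half-open.
#'
#' @param regions a [call_regions()] table.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- character(0)
  if (nrow(regions) > 0) {
    lines <- paste(regions$chrom,
                   format(regions$start - 1, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE),
                   sprintf("region_%d", seq_len(nrow(regions))),
                   format(regions$peak_fitted, digits = 6),
                   sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
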