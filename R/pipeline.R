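# End-to-end orchestration: configuration, the full analysis pipeline, the
# ROI-vs-superpixel cross-check, and artifact writers.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline; the numeric defaults are the
#' published operating point (superpixel factor 2, despike quantile 1e-4,
#' 18-30 h notch, sigma 0.95, l = 2, spectral k = 5, top 6 clusters).
#'
#' @param dt_hours sampling interval override (`NULL`: taken from the stack).
#' @param superpixel_factor coarsening tile edge, px.
#' @param despike_quantile tail mass for spike removal.
#' @param k_policy `"auto"` (gap statistic) or `"fixed"`.
#' @param k_fixed cluster count when `k_policy = "fixed"`.
#' @param k_max largest candidate k for the gap statistic.
#' @param gap_B reference datasets for the gap statistic.
#' @param top_n amplitude-ranked clusters to keep (5 or 6).
#' @param notch_band_hours period band removed by the notch filter.
#' @param sigma similarity-kernel scale.
#' @param l spectral embedding dimension.
#' @param spectral_k number of spectral clusters.
#' @param window_hours moving window for peak/trough detection.
#' @param contiguity_min spatial-organisation flag threshold on the
#'   largest-component contiguity score.
#' @param circadian_frac_min temporal-organisation flag threshold on the
#'   fraction of top clusters with significant circadian amplitude.
#' @param seed integer master seed; all stage seeds derive from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(dt_hours = NULL, superpixel_factor = 2L,
                       despike_quantile = 1e-4, k_policy = c("auto", "fixed"),
                       k_fixed = 5L, k_max = 8L, gap_B = 50L, top_n = 6L,
                       notch_band_hours = c(18, 30), sigma = 0.95, l = 2L,
                       spectral_k = 5L, window_hours = 15,
                       contiguity_min = 0.5, circadian_frac_min = 0.5,
                       seed = 1L) {
  k_policy <- match.arg(k_policy)
  structure(list(dt_hours = dt_hours, superpixel_factor = superpixel_factor,
                 despike_quantile = despike_quantile, k_policy = k_policy,
                 k_fixed = as.integer(k_fixed), k_max = as.integer(k_max),
                 gap_B = as.integer(gap_B), top_n = as.integer(top_n),
                 notch_band_hours = notch_band_hours, sigma = sigma,
                 l = as.integer(l), spectral_k = as.integer(spectral_k),
                 window_hours = window_hours, contiguity_min = contiguity_min,
                 circadian_frac_min = circadian_frac_min,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `path` / the parsed [run_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals[!vapply(vals, is.null, logical(1))])
}

# assemble a superpixel-grid label map (0 = background/excluded)
label_map <- function(labels, coords, grid_dim) {
  m <- matrix(0L, grid_dim[1], grid_dim[2])
  m[coords] <- as.integer(labels)
  m
}

#' Run the full analysis pipeline on one stack
#'
#' Despike, coarsen to superpixels, mask, cluster by k-medoids (gap-selected
#' or fixed k), keep the top amplitude-ranked clusters, compute per-cluster
#' spectra, re-cluster the notch-filtered series, build the correlation
#' similarity graph, spectrally cluster and embed, and compute the clock-face
#' trace and embedding coherence. Deterministic for a fixed (stack, config).
#'
#' @param stack an [scn_stack()].
#' @param config a [run_config()].
#' @param user_mask optional pixel-resolution tissue mask overriding Otsu.
#' @param out_dir when given, all artifacts (label maps as TIFF, series /
#'   gap / spectra / embedding / clock-face tables as CSV, summary as JSON)
#'   are written there.
#' @return an object of class `scn_report`: the stage results plus `summary`,
#'   a list of machine-readable flags (`chosen_k`, `frac_circadian`,
#'   `temporally_organised`, `contiguity`, `spatially_organised`, `rho_mean`,
#'   `turns_per_24h`, `monotonicity`, `circ_corr`, `notch_ari`).
#' @export
run_pipeline <- function(stack, config = run_config(), user_mask = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(stack, "scn_stack"), inherits(config, "run_config"))
  if (!is.null(config$dt_hours)) stack$dt_hours <- config$dt_hours
  seed <- config$seed

  clean <- despike(stack, config$despike_quantile)
  sm <- coarsen(clean, config$superpixel_factor)
  mask <- auto_mask(sm, user_mask = user_mask)
  sm <- apply_mask(sm, mask)

  gap <- NULL
  if (config$k_policy == "auto") {
    gap <- gap_select_k(sm, k_max = config$k_max, B = config$gap_B,
                        seed = seed)
    k <- max(gap$chosen_k, 2L)
  } else {
    k <- config$k_fixed
  }
  km <- kmedoids(sm, k, seed = seed)
  top <- rank_and_trim(km, min(config$top_n, k))
  spec_set <- spectrum_set(top, dt_hours = sm$dt_hours)

  # notch out the circadian band and re-cluster: spatial organisation that
  # survives is carried by non-circadian frequencies
  valid <- valid_series_rows(sm)
  sm_notch <- sm
  sm_notch$series[valid, ] <- notch_filter(sm$series[valid, , drop = FALSE],
                                           sm$dt_hours,
                                           config$notch_band_hours)
  km_notch <- kmedoids(sm_notch, k, seed = seed)
  notch_ari <- adjusted_rand_index(km$labels, km_notch$labels)

  graph <- build_graph(sm, sigma = config$sigma)
  emb <- spectral_cluster(graph, k = config$spectral_k, l = config$l,
                          seed = seed)
  trace <- clockface(emb, sm, window_hours = config$window_hours)
  cf <- clockface_summary(trace)
  coh <- embedding_coherence(emb)
  contig <- contiguity_score(emb$labels, emb$coords, emb$grid_dim)
  frac_circ <- mean(spec_set$summary$circadian_significant)

  summary <- list(
    chosen_k = k,
    k_policy = config$k_policy,
    frac_circadian = frac_circ,
    temporally_organised = frac_circ >= config$circadian_frac_min,
    contiguity = contig,
    spatially_organised = contig >= config$contiguity_min,
    rho_mean = coh$rho_mean,
    turns_per_24h = cf$turns_per_period,
    monotonicity = cf$monotonicity,
    n_reversals = cf$n_reversals,
    circ_corr = cf$circular_correlation,
    notch_ari = notch_ari,
    n_superpixels = nrow(sm$series),
    n_in_mask = sum(sm$in_mask),
    seed = seed)

  report <- structure(list(config = config, series = sm, mask = mask,
                           gap = gap, kmedoid = km, top = top,
                           spectra = spec_set, kmedoid_notched = km_notch,
                           graph_sigma = config$sigma, embedding = emb,
                           clockface = trace, coherence = coh,
                           summary = summary),
                      class = "scn_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.scn_report <- function(x, ...) {
  s <- x$summary
  cat("<scn_report>\n")
  cat(sprintf("  k-medoid clusters: %d (%s), circadian-significant fraction %.2f\n",
              s$chosen_k, s$k_policy, s$frac_circadian))
  cat(sprintf("  spatial organisation: contiguity %.2f -> %s\n",
              s$contiguity, if (s$spatially_organised) "organised" else "disorganised"))
  cat(sprintf("  temporal organisation: %s; clock hand %.2f turns/24 h, monotonicity %.2f\n",
              if (s$temporally_organised) "rhythmic" else "arrhythmic",
              if (is.na(s$turns_per_24h)) NA else s$turns_per_24h,
              if (is.na(s$monotonicity)) NA else s$monotonicity))
  cat(sprintf("  embedding coherence rho_mean = %.3f; notch re-cluster ARI = %.2f\n",
              s$rho_mean, s$notch_ari))
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' @param report an [run_pipeline()] result.
#' @param out_dir output directory, created if missing.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "scn_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  sm <- report$series
  write_gray_tiff(ifelse(report$mask, 1L, 0L) + 0, p("mask.tif"), bits = 8L)
  write_gray_tiff(label_map(report$top$labels, sm$coords, sm$grid_dim),
                  p("kmedoid_labels.tif"), bits = 8L)
  emb <- report$embedding
  write_gray_tiff(label_map(emb$labels, emb$coords, emb$grid_dim),
                  p("spectral_labels.tif"), bits = 8L)
  utils::write.csv(data.frame(cluster = seq_len(report$top$k),
                              amplitude = report$top$amplitude,
                              report$spectra$summary[-1]),
                   p("clusters.csv"), row.names = FALSE)
  ms <- report$top$mean_series
  utils::write.csv(data.frame(time_hours = (seq_len(ncol(ms)) - 1) * sm$dt_hours,
                              t(ms)), p("cluster_mean_series.csv"),
                   row.names = FALSE)
  if (!is.null(report$gap)) {
    utils::write.csv(data.frame(k = report$gap$candidate_k,
                                gap = report$gap$gap, se = report$gap$se),
                     p("gap_curve.csv"), row.names = FALSE)
  }
  utils::write.csv(data.frame(node = emb$nodes, row = emb$coords[, 1],
                              col = emb$coords[, 2], x = emb$coordinates[, 1],
                              y = emb$coordinates[, 2], label = emb$labels,
                              rho = emb$rho),
                   p("embedding.csv"), row.names = FALSE)
  utils::write.csv(data.frame(index = seq_along(emb$eigenvalues),
                              eigenvalue = emb$eigenvalues),
                   p("eigenvalues.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$clockface), p("clockface.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  write_config(report$config, p("config.json"))
  invisible(out_dir)
}

#' Agreement between cell-ROI and superpixel clusterings
#'
#' Each ROI inherits the label of the superpixel containing its center; the
#' agreement score is the adjusted Rand index between the ROI clustering and
#' the inherited labels. ROIs whose superpixel is masked out or trimmed
#' (label 0) are excluded and counted.
#'
#' @param roi_result `cluster_result` from clustering [extract_roi_series()].
#' @param sp_result `cluster_result` from clustering the superpixel series.
#' @param roi_coords n x 2 pixel coordinates of the ROI centers.
#' @param factor coarsening factor mapping pixels to superpixels.
#' @return list with `ari`, `n_used`, `n_excluded`.
#' @export
compare_roi_vs_superpixel <- function(roi_result, sp_result, roi_coords,
                                      factor = 2L) {
  stopifnot(inherits(roi_result, "cluster_result"),
            inherits(sp_result, "cluster_result"),
            !is.null(sp_result$grid_dim))
  roi_coords <- as_coord_matrix(roi_coords)
  sp_rc <- cbind((roi_coords[, 1] - 1L) %/% factor + 1L,
                 (roi_coords[, 2] - 1L) %/% factor + 1L)
  gd <- sp_result$grid_dim
  if (any(sp_rc[, 1] > gd[1] | sp_rc[, 2] > gd[2])) {
    stop("ROI centers fall outside the superpixel grid")
  }
  sp_index <- (sp_rc[, 2] - 1L) * gd[1] + sp_rc[, 1]
  inherited <- sp_result$labels[sp_index]
  keep <- inherited != 0 & roi_result$labels != 0
  list(ari = adjusted_rand_index(roi_result$labels[keep], inherited[keep]),
       n_used = sum(keep), n_excluded = sum(!keep))
}
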