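# Similarity network from time-series correlations, normalized graph
# Laplacian, spectral clustering (relaxed N-cut), 2-D spectral embedding,
# clock-face phase traces, and embedding-coherence statistics.

#' Correlation distance between two time series
#'
#' `d(u, v) = sqrt((1 - r) / 2)` with `r` the Pearson correlation: perfectly
#' correlated pairs are at distance 0, uncorrelated pairs at sqrt(2)/2, and
#' perfectly anticorrelated pairs at 1. Invariant under per-series affine
#' rescaling with positive slope.
#'
#' @param u,v numeric vectors of equal length with nonzero variance.
#' @return distance in \[0, 1\].
#' @export
correlation_distance <- function(u, v) {
  stopifnot(length(u) == length(v))
  if (stats::var(u) == 0 || stats::var(v) == 0) {
    stop("correlation distance undefined for zero-variance series")
  }
  r <- stats::cor(u, v)
  d2 <- (1 - r) / 2
  # snap to the exact anchors: r = 1 <-> 0, r = -1 <-> 1 (floating-point cor
  # of affinely related series can miss the endpoints by ~1e-16)
  if (d2 < 1e-12) return(0)
  if (d2 > 1 - 1e-12) return(1)
  sqrt(d2)
}

#' Low-level similarity graph constructor
#'
#' Wraps a symmetric nonnegative weight matrix (and optionally the underlying
#' distances and node bookkeeping) in the structure the spectral operations
#' expect. Most users should call [build_graph()] instead.
#'
#' @param W symmetric numeric weight matrix.
#' @param nodes indices of the graph nodes into an originating
#'   [series_matrix()], if any.
#' @param coords grid coordinates of the nodes.
#' @param grid_dim superpixel grid dimensions.
#' @param sigma kernel scale used to build `W`, if any.
#' @param d distance matrix underlying `W`, if any.
#' @return an object of class `similarity_graph`.
#' @export
similarity_graph <- function(W, nodes = NULL, coords = NULL, grid_dim = NULL,
                             sigma = NULL, d = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric")
  if (any(W < 0)) stop("W must be nonnegative")
  structure(list(W = (W + t(W)) / 2, nodes = nodes, coords = coords,
                 grid_dim = grid_dim, sigma = sigma, d = d),
            class = "similarity_graph")
}

#' Build the correlation similarity graph of a series matrix
#'
#' Every pair of valid superpixels (in-mask, nonzero variance) is connected
#' with weight `W_ij = exp(-d_ij^2 / (2 sigma^2))` where `d` is the
#' correlation distance. With the default `sigma = 0.95` even uncorrelated
#' pairs (d = sqrt(2)/2) retain substantial weight (~0.76), preserving the
#' full richness of the correlation structure; `sigma ~ 0.3` would suppress
#' all nonpositive correlations to nearly zero.
#'
#' @param sm a [series_matrix()].
#' @param sigma Gaussian kernel scale (> 0).
#' @return a [similarity_graph()] with unit diagonal, dense and connected.
#' @export
build_graph <- function(sm, sigma = 0.95) {
  stopifnot(inherits(sm, "series_matrix"))
  if (sigma <= 0) stop("sigma must be positive")
  nodes <- valid_series_rows(sm, need_variance = TRUE)
  if (length(nodes) < 2) stop("need at least 2 valid nodes")
  R <- stats::cor(t(sm$series[nodes, , drop = FALSE]))
  R[R > 1] <- 1; R[R < -1] <- -1
  d <- sqrt((1 - R) / 2)
  W <- exp(-d^2 / (2 * sigma^2))
  diag(W) <- 1
  similarity_graph(W, nodes = nodes,
                   coords = sm$coords[nodes, , drop = FALSE],
                   grid_dim = sm$grid_dim, sigma = sigma, d = d)
}

#' Eigendecomposition of the symmetric normalized Laplacian
#'
#' `L = I - D^(-1/2) W D^(-1/2)` (the relaxation of the N-cut objective);
#' eigenpairs are returned in ascending order. For a connected graph the
#' smallest eigenvalue is 0 (within 1e-8) and all eigenvalues lie in \[0, 2\].
#'
#' @param graph a [similarity_graph()].
#' @return list with `values` (ascending) and `vectors` (columns matching
#'   `values`), plus `deg`, the weighted node degrees.
#' @export
laplacian_spectrum <- function(graph) {
  stopifnot(inherits(graph, "similarity_graph"))
  W <- graph$W
  deg <- rowSums(W)
  if (any(deg <= 0)) stop("isolated node: Laplacian undefined")
  dis <- 1 / sqrt(deg)
  L <- diag(nrow(W)) - W * tcrossprod(dis)
  L <- (L + t(L)) / 2
  e <- eigen(L, symmetric = TRUE)
  ord <- order(e$values)
  list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE],
       deg = deg)
}

#' Scree selection of the embedding dimension
#'
#' Counts the nonzero Laplacian eigenvalues preceding the largest spectral
#' gap (successive difference) among the leading eigenvalues: eigenvectors
#' below the gap are "separated from the bulk" and span the embedding. When
#' no gap stands out (largest difference below `ratio_min` times the mean
#' difference) the default dimension is returned with a warning.
#'
#' @param values ascending Laplacian eigenvalues (>= 4 nonzero ones).
#' @param default dimension used when no gap is discernible.
#' @param max_consider look only at the first `min(max_consider, n/2)` nonzero
#'   eigenvalues.
#' @param ratio_min a gap is discernible when the largest difference is at
#'   least this multiple of the mean difference.
#' @param zero_tol eigenvalues below this are treated as zero.
#' @return integer embedding dimension `l`.
#' @export
scree_select_l <- function(values, default = 2L, max_consider = 10L,
                           ratio_min = 1.5, zero_tol = 1e-8) {
  nz <- values[values > zero_tol]
  if (length(nz) < 4) stop("need at least 4 nonzero eigenvalues")
  m <- min(max_consider, floor(length(values) / 2), length(nz))
  nz <- nz[seq_len(m)]
  gaps <- diff(nz)
  if (max(gaps) < ratio_min * mean(gaps)) {
    warning("no discernible eigenvalue gap; returning default l = ", default)
    return(as.integer(default))
  }
  as.integer(which.max(gaps))
}

#' Spectral embedding and clustering (relaxed N-cut)
#'
#' Embeds the nodes by the `D^(-1/2)`-scaled eigenvectors associated with the
#' `l` smallest nonzero eigenvalues of the normalized Laplacian, then
#' partitions the embedded points into `k` groups by seeded k-means (10
#' restarts). For `k = 2` the classical sweep cut along each embedding
#' coordinate is also evaluated and the partition with the lowest N-cut value
#' is returned.
#'
#' @param graph a [similarity_graph()].
#' @param k number of clusters (>= 2).
#' @param l embedding dimension (>= 1); 2 gives the clock-face plane.
#' @param seed integer seed for the k-means discretization.
#' @param spec optional precomputed [laplacian_spectrum()] result.
#' @return an object of class `embedding_result`: `coordinates` (n x l),
#'   `eigenvalues`, `labels`, `center` (center of mass), `rho`
#'   (center distances normalized by half the embedding diameter), `rho_mean`,
#'   `nodes`, `coords`, `grid_dim`, `k`, `l`, `sigma`.
#' @export
spectral_cluster <- function(graph, k = 5L, l = 2L, seed = 1L, spec = NULL) {
  stopifnot(inherits(graph, "similarity_graph"), k >= 2, l >= 1)
  n <- nrow(graph$W)
  if (k > n) stop("k exceeds the number of nodes")
  spec <- spec %||% laplacian_spectrum(graph)
  nzero <- sum(spec$values < 1e-8)
  idx <- (max(nzero, 1L) + 1L):(max(nzero, 1L) + l)
  if (max(idx) > n) stop("embedding dimension too large for this graph")
  emb <- spec$vectors[, idx, drop = FALSE] / sqrt(spec$deg)
  km <- with_seed(seed, stats::kmeans(emb, centers = k, nstart = 10L,
                                      iter.max = 100L))
  labels <- km$cluster
  if (k == 2) {
    candidates <- lapply(seq_len(ncol(emb)), function(j) sweep_cut(graph, emb[, j]))
    candidates <- c(candidates, list(labels))
    vals <- vapply(candidates, function(lab) ncut_value(graph, lab), numeric(1))
    labels <- candidates[[which.min(vals)]]
  }
  coordinates <- emb
  center <- colMeans(coordinates)
  dvec <- sqrt(rowSums((coordinates - rep(center, each = n))^2))
  diam <- embedding_diameter(coordinates)
  rho <- if (diam > 0) pmin(dvec / (diam / 2), 1) else rep(NA_real_, n)
  structure(list(coordinates = coordinates, eigenvalues = spec$values,
                 labels = as.integer(labels), center = center, rho = rho,
                 rho_mean = mean(rho), nodes = graph$nodes,
                 coords = graph$coords, grid_dim = graph$grid_dim,
                 k = as.integer(k), l = as.integer(l), sigma = graph$sigma),
            class = "embedding_result")
}

# best bipartition along the sweep of an embedding coordinate; the running
# cut and volume are updated incrementally, O(n^2) overall
sweep_cut <- function(graph, v) {
  W <- graph$W
  n <- length(v)
  deg <- rowSums(W)
  vol_total <- sum(deg)
  ord <- order(v)
  a <- numeric(n)   # a[u] = sum of W[u, s] over s already in S
  cut <- 0; vol_s <- 0
  best_s <- 1L; best_val <- Inf
  for (s in seq_len(n - 1)) {
    u <- ord[s]
    cut <- cut + deg[u] - W[u, u] - 2 * a[u]
    vol_s <- vol_s + deg[u]
    a <- a + W[, u]
    val <- cut / vol_s + cut / (vol_total - vol_s)
    if (val < best_val) { best_val <- val; best_s <- s }
  }
  lab <- integer(n) + 1L
  lab[ord[seq_len(best_s)]] <- 2L
  lab
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d nodes in %d-D, k = %d, rho_mean = %.3f\n",
              nrow(x$coordinates), x$l, x$k, x$rho_mean))
  invisible(x)
}

#' @export
plot.embedding_result <- function(x, ...) {
  graphics::plot(x$coordinates[, 1], x$coordinates[, 2],
                 col = x$labels, pch = 16, cex = 0.5, asp = 1,
                 xlab = "spectral 1", ylab = "spectral 2", ...)
  graphics::points(x$center[1], x$center[2], pch = 3, cex = 2)
  invisible(x)
}

# max pairwise distance; exact via convex hull in 2-D, dist() otherwise
embedding_diameter <- function(pts) {
  if (nrow(pts) < 2) return(0)
  if (ncol(pts) == 2 && nrow(pts) > 3) {
    hull <- grDevices::chull(pts)
    if (length(hull) >= 2) pts <- pts[hull, , drop = FALSE]
  }
  d <- suppressWarnings(max(stats::dist(pts)))
  if (!is.finite(d)) 0 else d
}

#' Normalized cut value of a partition
#'
#' `sum over clusters of cut(C, complement) / vol(C)` with `vol` the summed
#' weighted degree inside the cluster. Zero for unions of disconnected
#' components (and for the trivial single cluster).
#'
#' @param graph a [similarity_graph()].
#' @param labels integer cluster labels covering all nodes.
#' @return nonnegative N-cut value.
#' @export
ncut_value <- function(graph, labels) {
  stopifnot(inherits(graph, "similarity_graph"))
  W <- graph$W
  if (length(labels) != nrow(W)) stop("labels must cover all nodes")
  deg <- rowSums(W)
  total <- 0
  for (id in unique(labels)) {
    idx <- labels == id
    if (!any(idx)) stop("empty cluster")
    vol <- sum(deg[idx])
    if (vol == 0) stop("zero-volume cluster")
    cut <- sum(W[idx, !idx])
    total <- total + cut / vol
  }
  total
}

#' Clock-face trace of the spectral embedding
#'
#' For every frame, the peak set is the group of nodes whose time series has a
#' windowed local maximum at that frame (same 15-h rule as
#' [peaks_troughs()]); the clock-hand angle is the circular mean direction of
#' the embedded peak-set nodes relative to the embedding's center of mass.
#' Angles are defined up to a global rotation/reflection of the embedding.
#'
#' @param embedding an [spectral_cluster()] result with `l = 2`.
#' @param sm the [series_matrix()] the graph was built from.
#' @param dt_hours sampling interval; taken from `sm` when missing.
#' @param window_hours moving window for peak detection.
#' @return an object of class `clockface_trace`: data.frame `frame`,
#'   `time_hours`, `theta` (radians in \[0, 2 pi), `NA` for empty peak sets),
#'   `n_peak_nodes`. Returns an all-`NA` trace with a message when no node
#'   ever peaks (non-oscillating tissue).
#' @export
clockface <- function(embedding, sm, dt_hours = NULL, window_hours = 15) {
  stopifnot(inherits(embedding, "embedding_result"),
            inherits(sm, "series_matrix"))
  if (embedding$l < 2) stop("clock face requires a 2-D embedding")
  dt_hours <- dt_hours %||% sm$dt_hours
  S <- sm$series[embedding$nodes, , drop = FALSE]
  h <- floor(window_hours / (2 * dt_hours))
  pk <- rolling_peaks(S, h)
  n_t <- ncol(S)
  tmin <- window_hours / 2
  edge_ok <- (seq_len(n_t) - 1) * dt_hours >= tmin &
    (n_t - seq_len(n_t)) * dt_hours >= tmin
  ang <- (atan2(embedding$coordinates[, 2] - embedding$center[2],
                embedding$coordinates[, 1] - embedding$center[1])) %% (2 * pi)
  theta <- rep(NA_real_, n_t)
  npk <- integer(n_t)
  for (t in which(edge_ok)) {
    idx <- which(pk[, t])
    npk[t] <- length(idx)
    if (length(idx) > 0) theta[t] <- circular_mean(ang[idx])
  }
  if (all(npk == 0)) {
    message("no peak sets found: tissue does not oscillate at this window")
  }
  structure(data.frame(frame = seq_len(n_t),
                       time_hours = (seq_len(n_t) - 1) * dt_hours,
                       theta = theta, n_peak_nodes = npk),
            class = c("clockface_trace", "data.frame"))
}

#' Summary statistics of a clock-face trace
#'
#' Unwraps the hand angle over frames with nonempty peak sets and reports how
#' orderly the hand progresses: the number of turns per `period_hours`, a
#' monotonicity index (net rotation over total rotation; 1 = never reverses),
#' the count of direction reversals larger than `reversal_tol` radians, and
#' a circular-linear phase-tracking correlation: the absolute Pearson
#' correlation between the unwrapped hand angle and the circadian phase angle
#' `2 pi t / period_hours` (absolute because the embedding orientation is
#' arbitrary; unwrapped because the hand dwells on discrete cluster
#' directions, which pure circular-circular coefficients under-score).
#'
#' @param trace a [clockface()] result.
#' @param period_hours reference period (24 h).
#' @param reversal_tol angular increments against the net direction larger
#'   than this count as reversals.
#' @return list with `turns_per_period`, `monotonicity`, `n_reversals`,
#'   `circular_correlation`, `n_defined`.
#' @export
clockface_summary <- function(trace, period_hours = 24, reversal_tol = 0.25) {
  ok <- !is.na(trace$theta)
  if (sum(ok) < 3) {
    return(list(turns_per_period = NA_real_, monotonicity = NA_real_,
                n_reversals = NA_integer_, circular_correlation = NA_real_,
                n_defined = sum(ok)))
  }
  th <- unwrap_angles(trace$theta[ok])
  tt <- trace$time_hours[ok]
  slope <- unname(stats::coef(stats::lm(th ~ tt))[2])
  d <- diff(th)
  net <- sum(d)
  mono <- if (sum(abs(d)) > 0) abs(net) / sum(abs(d)) else NA_real_
  rev <- sum(sign(d) == -sign(net) & abs(d) > reversal_tol)
  cc <- abs(stats::cor(th, 2 * pi * tt / period_hours))
  list(turns_per_period = abs(slope) * period_hours / (2 * pi),
       monotonicity = mono, n_reversals = as.integer(rev),
       circular_correlation = cc, n_defined = sum(ok))
}

#' Embedding coherence: normalized center-distance histogram
#'
#' Distances of the embedded nodes from the embedding's center of mass,
#' divided by half the embedding diameter. Ring-like embeddings (strong
#' spatiotemporal coupling) put most mass near 1; filled disks (weak coupling)
#' have mean near 2/3.
#'
#' Distances are clipped at 1: tight clusters on a ring make the half-diameter
#' marginally smaller than the ring radius.
#'
#' @param embedding an [spectral_cluster()] result, or an n x 2 coordinate
#'   matrix.
#' @param bins number of histogram bins on \[0, 1\].
#' @return list with `counts`, `breaks`, `rho`, `rho_mean`.
#' @export
embedding_coherence <- function(embedding, bins = 20L) {
  if (inherits(embedding, "embedding_result")) {
    pts <- embedding$coordinates
  } else {
    pts <- as.matrix(embedding)
  }
  if (nrow(pts) < 2) stop("need at least 2 embedded points")
  center <- colMeans(pts)
  dvec <- sqrt(rowSums((pts - rep(center, each = nrow(pts)))^2))
  diam <- embedding_diameter(pts)
  if (diam == 0) stop("all points coincident: zero embedding diameter")
  rho <- pmin(dvec / (diam / 2), 1)
  breaks <- seq(0, max(1, max(rho)), length.out = bins + 1L)
  counts <- tabulate(findInterval(rho, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), bins)
  list(counts = counts, breaks = breaks, rho = rho, rho_mean = mean(rho))
}
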