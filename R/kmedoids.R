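# k-medoids clustering of superpixel time series under the cosine distance,
# with gap-statistic selection of k, amplitude-ranked summaries, and windowed
# stability checks.

#' Cosine distance between two time series
#'
#' `D(u, v) = 1 - u.v / (|u||v|)`, in \[0, 2\]. Invariant under positive
#' rescaling of either argument, so differences in basal brightness have no
#' effect on clustering.
#'
#' @param u,v numeric vectors of equal, nonzero length.
#' @return distance in \[0, 2\].
#' @examples
#' cosine_distance(c(1, 0), c(0, 1))  # 1
#' @export
cosine_distance <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) > 0)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine distance undefined for zero-norm series")
  1 - sum(u * v) / (nu * nv)
}

#' Pairwise cosine distance matrix
#'
#' @param X n x T matrix; every row must have nonzero norm.
#' @return symmetric n x n matrix of cosine distances with zero diagonal.
#' @export
cosine_distance_matrix <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("cosine distance undefined for zero-norm series")
  D <- 1 - tcrossprod(X / nrm)
  D[D < 0] <- 0
  D[D > 2] <- 2
  diag(D) <- 0
  D
}

# k-medoids++ seeding on a precomputed distance matrix (RNG from caller)
kmpp_init <- function(D, k) {
  n <- nrow(D)
  med <- integer(k)
  med[1] <- sample.int(n, 1)
  if (k > 1) {
    for (j in 2:k) {
      dmin <- do.call(pmin, lapply(med[1:(j - 1)], function(m) D[, m]))
      w <- dmin^2
      if (sum(w) == 0) {
        med[j] <- sample(setdiff(seq_len(n), med[1:(j - 1)]), 1)
      } else {
        med[j] <- sample.int(n, 1, prob = w)
      }
    }
  }
  med
}

# core alternating k-medoids on a distance matrix; returns the best of n_init
# seeded restarts. Objective (summed distance to assigned medoid) is
# non-increasing across iterations by construction; the per-iteration trace of
# the best restart is returned for verification.
kmedoids_fit <- function(D, k, seed = 1L, n_init = 10L, max_iter = 100L) {
  n <- nrow(D)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of series")
  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      med <- sort(kmpp_init(D, k))
      trace <- numeric(0)
      for (iter in seq_len(max_iter)) {
        Dm <- D[, med, drop = FALSE]
        assign <- max.col(-Dm, ties.method = "first")
        # guard against empty clusters: give them the worst-served point
        for (c in which(tabulate(assign, k) == 0)) {
          far <- which.max(Dm[cbind(seq_len(n), assign)])
          assign[far] <- c
          med[c] <- far
          Dm <- D[, med, drop = FALSE]
        }
        new_med <- med
        for (c in seq_len(k)) {
          idx <- which(assign == c)
          sub <- D[idx, idx, drop = FALSE]
          new_med[c] <- idx[which.min(colSums(sub))]
        }
        obj <- sum(D[cbind(seq_len(n), new_med[assign])])
        trace <- c(trace, obj)
        if (identical(sort(new_med), sort(med)) && iter > 1) break
        med <- new_med
      }
      med <- sort(med)
      assign <- max.col(-D[, med, drop = FALSE], ties.method = "first")
      obj <- sum(D[cbind(seq_len(n), med[assign])])
      if (is.null(best) || obj < best$objective - 1e-12) {
        best <- list(medoids = med, labels = assign, objective = obj,
                     trace = trace)
      }
    }
  })
  best
}

#' k-medoids clustering of time series under cosine distance
#'
#' Alternates assignment to the nearest medoid and medoid update (the member
#' minimizing summed within-cluster distance) until the medoid set stabilizes,
#' keeping the best of `n_init` k-medoids++-seeded restarts. Only in-mask rows
#' with nonzero norm participate; excluded rows get label 0.
#'
#' @param x a [series_matrix()] or a plain n x T numeric matrix.
#' @param k number of clusters.
#' @param seed integer seed controlling the restarts.
#' @param n_init number of seeded restarts.
#' @param max_iter iteration cap per restart.
#' @param dist_matrix optional precomputed cosine distance matrix over the
#'   valid rows (a performance device for repeated fits).
#' @return an object of class `cluster_result`: `labels` (length n, 0 =
#'   excluded), `medoid_indices`, `k`, `mean_series` (k x T, raw brightness
#'   means), `amplitude` (max - min of each mean series), `amplitude_rank`,
#'   `objective`, `objective_trace`, `n_excluded`.
#' @export
kmedoids <- function(x, k, seed = 1L, n_init = 10L, max_iter = 100L,
                     dist_matrix = NULL) {
  if (inherits(x, "series_matrix")) {
    valid <- valid_series_rows(x)
    S <- x$series
    sm <- x
  } else {
    S <- as.matrix(x)
    valid <- which(rowSums(S^2) > 0)
    sm <- NULL
  }
  if (length(valid) < k) stop("k exceeds the number of valid series")
  D <- dist_matrix %||% cosine_distance_matrix(S[valid, , drop = FALSE])
  fit <- kmedoids_fit(D, k, seed = seed, n_init = n_init, max_iter = max_iter)
  labels <- integer(nrow(S))
  labels[valid] <- fit$labels
  mean_series <- t(vapply(seq_len(k), function(c) {
    colMeans(S[valid[fit$labels == c], , drop = FALSE])
  }, numeric(ncol(S))))
  amplitude <- apply(mean_series, 1, function(s) max(s) - min(s))
  structure(list(labels = labels, medoid_indices = valid[fit$medoids],
                 k = k, mean_series = mean_series, amplitude = amplitude,
                 amplitude_rank = order(-amplitude, seq_len(k)),
                 objective = fit$objective, objective_trace = fit$trace,
                 n_excluded = nrow(S) - length(valid),
                 coords = if (!is.null(sm)) sm$coords else NULL,
                 grid_dim = if (!is.null(sm)) sm$grid_dim else NULL,
                 dt_hours = if (!is.null(sm)) sm$dt_hours else NULL),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d over %d series (%d excluded), objective %.4f\n",
              x$k, length(x$labels), x$n_excluded, x$objective))
  cat("cluster sizes:", tabulate(x$labels[x$labels > 0], x$k), "\n")
  invisible(x)
}

# log within-cluster dispersion: sum over clusters of (sum of pairwise
# distances) / (2 * cluster size)
log_wk <- function(D, labels, k) {
  w <- 0
  for (c in seq_len(k)) {
    idx <- which(labels == c)
    if (length(idx) > 1) {
      w <- w + sum(D[idx, idx]) / (2 * length(idx))
    }
  }
  log(max(w, .Machine$double.xmin))
}

#' Gap-statistic selection of the number of clusters
#'
#' Compares the log within-cluster cosine dispersion of the data, for each
#' candidate k, with that of `B` reference datasets drawn uniformly over each
#' feature's observed range. `gap(k) = mean_b log W*_kb - log W_k`, and the
#' chosen k is the smallest with `gap(k) >= gap(k+1) - se(k+1)` (one-SE rule).
#'
#' @param x a [series_matrix()] or n x T matrix.
#' @param k_max largest candidate k (candidates are 1..k_max).
#' @param B number of uniform reference datasets (>= 10).
#' @param seed integer seed (references, restarts, subsampling).
#' @param n_init restarts per fit; references use fewer restarts than a final
#'   clustering needs.
#' @param max_n when more than `max_n` valid series are present, the gap curve
#'   is computed on a seeded random subsample of this size (a runtime device;
#'   dispersion per point is insensitive to n at these scales).
#' @return an object of class `gap_curve`: `candidate_k`, `gap`, `se`,
#'   `log_w`, `log_w_ref`, `chosen_k`, `B`.
#' @export
gap_select_k <- function(x, k_max = 8L, B = 50L, seed = 1L, n_init = 2L,
                         max_n = 1000L) {
  if (B < 10) stop("B must be >= 10")
  if (k_max < 2) stop("k_max must be >= 2")
  if (inherits(x, "series_matrix")) {
    S <- x$series[valid_series_rows(x), , drop = FALSE]
  } else {
    S <- as.matrix(x)
    S <- S[rowSums(S^2) > 0, , drop = FALSE]
  }
  if (nrow(S) < k_max) stop("k_max exceeds the number of valid series")
  if (all(apply(S, 2, function(col) diff(range(col)) == 0)) ||
      max(cosine_distance_matrix(S)) < 1e-12) {
    return(structure(list(candidate_k = 1L, gap = 0, se = 0, log_w = -Inf,
                          log_w_ref = -Inf, chosen_k = 1L, B = B),
                     class = "gap_curve"))
  }
  if (nrow(S) > max_n) {
    S <- S[with_seed(seed + 1L, sample.int(nrow(S), max_n)), , drop = FALSE]
  }
  n <- nrow(S)
  ks <- seq_len(k_max)
  D <- cosine_distance_matrix(S)
  log_w <- vapply(ks, function(k) {
    fit <- kmedoids_fit(D, k, seed = seed + k, n_init = n_init)
    log_wk(D, fit$labels, k)
  }, numeric(1))
  lo <- apply(S, 2, min); hi <- apply(S, 2, max)
  log_w_ref <- matrix(0, B, k_max)
  for (b in seq_len(B)) {
    Sb <- with_seed(seed + 1000L + b, {
      matrix(stats::runif(n * ncol(S), min = rep(lo, each = n),
                          max = rep(hi, each = n)), n, ncol(S))
    })
    Db <- cosine_distance_matrix(Sb)
    for (k in ks) {
      fit <- kmedoids_fit(Db, k, seed = seed + k, n_init = n_init)
      log_w_ref[b, k] <- log_wk(Db, fit$labels, k)
    }
  }
  gap <- colMeans(log_w_ref) - log_w
  se <- apply(log_w_ref, 2, stats::sd) * sqrt(1 + 1 / B)
  chosen <- k_max
  for (k in seq_len(k_max - 1L)) {
    if (gap[k] >= gap[k + 1] - se[k + 1]) { chosen <- k; break }
  }
  structure(list(candidate_k = ks, gap = gap, se = se, log_w = log_w,
                 log_w_ref = colMeans(log_w_ref), chosen_k = as.integer(chosen),
                 B = as.integer(B)),
            class = "gap_curve")
}

#' @export
print.gap_curve <- function(x, ...) {
  cat("<gap_curve> chosen k =", x$chosen_k, "(B =", x$B, "references)\n")
  print(data.frame(k = x$candidate_k, gap = round(x$gap, 4),
                   se = round(x$se, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.gap_curve <- function(x, ...) {
  graphics::plot(x$candidate_k, x$gap, type = "b", xlab = "k",
                 ylab = "gap statistic", ...)
  graphics::arrows(x$candidate_k, x$gap - x$se, x$candidate_k, x$gap + x$se,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(v = x$chosen_k, lty = 2)
  invisible(x)
}

#' Restrict a clustering to its highest-amplitude clusters
#'
#' Cluster amplitude is the max - min of its mean time series. The `top_n`
#' highest-amplitude clusters are kept (ties broken by original cluster id)
#' and relabeled 1..top_n in decreasing amplitude order; superpixels of
#' trimmed clusters get label 0 and are treated like background in maps. This
#' is the convention that screens out light-scatter-dominated clusters.
#'
#' @param result a `cluster_result`.
#' @param top_n how many clusters to keep (5 or 6 typical).
#' @return a `cluster_result` with `k = top_n`; `original_ids` maps the new
#'   labels to the input cluster ids.
#' @export
rank_and_trim <- function(result, top_n = 6L) {
  stopifnot(inherits(result, "cluster_result"))
  if (result$k < top_n) {
    warning("fewer clusters than top_n; returning all ", result$k,
            " clusters ranked by amplitude")
    top_n <- result$k
  }
  ord <- order(-result$amplitude, seq_len(result$k))
  keep <- ord[seq_len(top_n)]
  relabel <- integer(result$k)
  relabel[keep] <- seq_len(top_n)
  labels <- ifelse(result$labels > 0, relabel[pmax(result$labels, 1L)], 0L)
  out <- result
  out$labels <- as.integer(labels)
  out$k <- as.integer(top_n)
  out$mean_series <- result$mean_series[keep, , drop = FALSE]
  out$amplitude <- result$amplitude[keep]
  out$amplitude_rank <- seq_len(top_n)
  out$medoid_indices <- result$medoid_indices[keep]
  out$original_ids <- keep
  out
}

#' Clustering stability across time windows
#'
#' Splits the time axis into contiguous equal windows, clusters each window
#' independently, and reports all pairwise adjusted Rand indices between the
#' window clusterings (label permutations do not affect the ARI).
#'
#' @param sm a [series_matrix()].
#' @param window_count number of windows.
#' @param k number of clusters per window.
#' @param seed integer seed.
#' @param n_init restarts per window fit.
#' @return list with the ARI `matrix` (window x window) and `mean_ari` over
#'   distinct pairs.
#' @export
window_stability <- function(sm, window_count, k, seed = 1L, n_init = 10L) {
  stopifnot(inherits(sm, "series_matrix"), window_count >= 2)
  T_ <- ncol(sm$series)
  edges <- floor(seq(0, T_, length.out = window_count + 1))
  if (any(diff(edges) < 2)) stop("windows must span at least 2 frames")
  labs <- vector("list", window_count)
  for (w in seq_len(window_count)) {
    sub <- sm
    sub$series <- sm$series[, (edges[w] + 1):edges[w + 1], drop = FALSE]
    labs[[w]] <- kmedoids(sub, k, seed = seed, n_init = n_init)$labels
  }
  A <- diag(1, window_count)
  for (i in seq_len(window_count - 1)) {
    for (j in (i + 1):window_count) {
      A[i, j] <- A[j, i] <- adjusted_rand_index(labs[[i]], labs[[j]])
    }
  }
  list(matrix = A, mean_ari = mean(A[upper.tri(A)]))
}
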