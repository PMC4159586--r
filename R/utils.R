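# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves the caller's RNG state, runs `code` under `set.seed(seed)`, and
#' restores the state afterwards so library functions never perturb user
#' simulations.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Otsu threshold of a numeric vector
#'
#' Histogram-based threshold maximizing between-class variance; used for
#' automatic tissue/background masking of time-mean brightness images.
#'
#' @param x numeric vector.
#' @param nbins number of histogram bins.
#' @return threshold value; values strictly above it form the foreground.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0) {
    stop("degenerate image (all values equal): cannot threshold, supply a mask")
  }
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  # bimodal images with an empty gap give a flat maximum across the gap;
  # take the plateau midpoint (the conventional tie-break), not its edge
  best <- which(between >= max(between) - 1e-12 * max(between))
  mids[best[ceiling(length(best) / 2)]]
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two label vectors; permutation of label
#' ids leaves the value unchanged, so no explicit matching step is required.
#' Entries where either labeling is `NA` or 0 (excluded/background) are
#' dropped.
#'
#' @param a,b integer label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b) & a != 0 & b != 0
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) stop("need at least two jointly labeled items")
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "adjusted.rand")
}

# circular mean direction of angles (radians), in [0, 2*pi)
circular_mean <- function(theta) {
  atan2(mean(sin(theta)), mean(cos(theta))) %% (2 * pi)
}

# unwrap a sequence of angles: successive increments mapped to (-pi, pi]
unwrap_angles <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  d <- ((d + pi) %% (2 * pi)) - pi
  theta[1] + c(0, cumsum(d))
}

#' Circular-circular correlation coefficient
#'
#' Fisher-Lee T-linear association between two angle vectors (the
#' pairwise-difference form, stable even for near-uniform marginals); used to
#' score how faithfully the clock-hand angle tracks circadian phase. The sign
#' is arbitrary up to reflection of the spectral embedding.
#'
#' @param a,b angle vectors (radians) of equal length.
#' @return correlation in \[-1, 1\].
#' @export
circular_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  da <- sin(outer(a, a, "-"))
  db <- sin(outer(b, b, "-"))
  up <- upper.tri(da)
  sum(da[up] * db[up]) / sqrt(sum(da[up]^2) * sum(db[up]^2))
}

# connected components of TRUE cells of a logical matrix under 4-connectivity;
# returns an integer matrix (0 = FALSE cells).
grid_components <- function(mask) {
  stopifnot(is.matrix(mask))
  idx <- which(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0) return(out)
  nr <- nrow(mask)
  pos <- arrayInd(idx, dim(mask))
  key <- function(r, c) (c - 1L) * nr + r
  present <- logical(nr * ncol(mask))
  present[idx] <- TRUE
  edges <- NULL
  # horizontal + vertical adjacencies among TRUE cells
  r <- pos[, 1]; c <- pos[, 2]
  right <- c < ncol(mask) & present[key(r, pmin(c + 1L, ncol(mask)))]
  down  <- r < nr & present[key(pmin(r + 1L, nr), c)]
  e1 <- cbind(key(r, c)[right], key(r, c + 1L)[right])
  e2 <- cbind(key(r, c)[down],  key(r + 1L, c)[down])
  edges <- rbind(e1, e2)
  vids <- as.character(idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  igraph::V(g)$name <- vids
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(edges[, 1], idx),
                                    match(edges[, 2], idx)))
  }
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

# For a label vector on grid coordinates, the size-weighted mean fraction of
# each cluster's members lying in its largest 4-connected component.
contiguity_score <- function(labels, coords, grid_dim) {
  stopifnot(length(labels) == nrow(coords))
  keep <- labels != 0 & !is.na(labels)
  labels <- labels[keep]; coords <- coords[keep, , drop = FALSE]
  ids <- sort(unique(labels))
  total <- 0
  for (id in ids) {
    m <- matrix(FALSE, grid_dim[1], grid_dim[2])
    m[coords[labels == id, , drop = FALSE]] <- TRUE
    comp <- grid_components(m)
    sizes <- tabulate(comp[comp > 0])
    total <- total + max(sizes)
  }
  total / length(labels)
}

# validate a 2-column coordinate matrix
as_coord_matrix <- function(x, name = "coords") {
  x <- as.matrix(x)
  if (ncol(x) != 2) stop(name, " must have two columns (row, col)")
  storage.mode(x) <- "integer"
  x
}
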