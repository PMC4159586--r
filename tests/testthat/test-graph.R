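# Correlation distance, similarity kernel, normalized Laplacian, spectral
# clustering vs the exhaustive N-cut oracle, clock face and coherence.

test_that("correlation distance hits its anchor values", {
  u <- c(1, 2, 3, 4, 2)
  expect_equal(correlation_distance(u, u), 0)
  expect_equal(correlation_distance(u, -u), 1)
  expect_equal(correlation_distance(u, 5 - 2 * u), 1)   # affine anticorrelated
  # orthogonal residuals: r = 0 exactly -> sqrt(2)/2
  a <- c(1, -1, 1, -1); b <- c(1, 1, -1, -1)
  expect_equal(correlation_distance(a, b), sqrt(2) / 2)
  expect_error(correlation_distance(u, rep(1, 5)), "zero-variance")
})

test_that("the Gaussian kernel maps distances as the scale dictates", {
  d0 <- sqrt(2) / 2
  expect_equal(exp(-d0^2 / (2 * 0.3^2)), 0.0622, tolerance = 1e-3)
  expect_equal(exp(-d0^2 / (2 * 0.95^2)), 0.758, tolerance = 1e-3)
  S <- two_bundle_series(n_per = 5)
  g <- build_graph(series_matrix(S, cbind(1:10, 1L), dt_hours = 0.5),
                   sigma = 0.95)
  expect_true(all(diag(g$W) == 1))
  expect_true(all(g$W > 0 & g$W <= 1))
  expect_equal(g$W, t(g$W))
  # d = 0 maps to weight 1 at any sigma
  g2 <- build_graph(series_matrix(S, cbind(1:10, 1L), dt_hours = 0.5),
                    sigma = 0.3)
  expect_equal(g2$W[1, 1], 1)
  expect_error(build_graph(series_matrix(S, cbind(1:10, 1L)), sigma = 0),
               "positive")
})

test_that("Laplacian spectra match closed forms", {
  # complete graph without self-loops: nonzero eigenvalues all n/(n-1)
  n <- 6
  W <- matrix(1, n, n); diag(W) <- 0
  e <- laplacian_spectrum(similarity_graph(W))
  expect_equal(e$values[1], 0, tolerance = 1e-10)
  expect_equal(e$values[-1], rep(n / (n - 1), n - 1), tolerance = 1e-10)
  # two disconnected equal cliques: eigenvalue 0 with multiplicity 2
  W2 <- rbind(cbind(W, matrix(0, n, n)), cbind(matrix(0, n, n), W))
  e2 <- laplacian_spectrum(similarity_graph(W2))
  expect_equal(sum(e2$values < 1e-10), 2)
  # all eigenvalues within [0, 2]
  expect_true(all(e2$values > -1e-10 & e2$values < 2 + 1e-10))
  expect_error(similarity_graph(matrix(c(1, 2, 3, 1), 2)), "symmetric")
})

test_that("ncut matches brute force and vanishes on disconnected parts", {
  # 6-node barbell: two triangles joined by one weak edge
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[1, 3] <- W[2, 3] <- 1
  W[4, 5] <- W[4, 6] <- W[5, 6] <- 1
  W[3, 4] <- 0.1
  W <- W + t(W)
  g <- similarity_graph(W)
  lab <- rep(1:2, each = 3)
  # hand-computed: cut = 0.1, vol of each side = 2 + 2 + 2.1 = 6.1
  expect_equal(ncut_value(g, lab), 2 * 0.1 / 6.1)
  # brute force over all bipartitions confirms the triangles are optimal
  best <- Inf
  for (m in 1:(2^5 - 1)) {
    l <- as.integer(intToBits(m)[1:6]) + 1L
    if (length(unique(l)) == 2) best <- min(best, ncut_value(g, l))
  }
  expect_equal(best, ncut_value(g, lab))
  # spectral clustering finds that optimum
  sc <- spectral_cluster(g, k = 2, l = 2, seed = 1)
  expect_equal(ncut_value(g, sc$labels), best)
  # disconnected components cut nothing
  W2 <- W; W2[3, 4] <- W2[4, 3] <- 0
  g2 <- similarity_graph(W2)
  expect_equal(ncut_value(g2, lab), 0)
  expect_equal(ncut_value(g2, rep(1L, 6)), 0)  # single cluster, no cut
  expect_error(ncut_value(g2, rep(1L, 3)), "cover")
})

test_that("scree selection finds the eigenvalue gap or falls back", {
  expect_equal(scree_select_l(c(0, 0.01, 0.02, 0.5, 0.52, 0.54, 0.56)), 2L)
  expect_warning(l <- scree_select_l(seq(0, 1, length.out = 12)), "default")
  expect_equal(l, 2L)
  expect_error(scree_select_l(c(0, 1, 2)), "4 nonzero")
})

test_that("embedding is invariant to baseline shifts and node order", {
  S <- two_bundle_series(n_per = 8)
  sm <- series_matrix(S, cbind(1:16, 1L), dt_hours = 0.5)
  g1 <- build_graph(sm)
  sm2 <- sm; sm2$series <- sm$series + 100  # constant added to every series
  g2 <- build_graph(sm2)
  expect_equal(g1$W, g2$W, tolerance = 1e-12)
  perm <- c(16:1)
  sm3 <- sm; sm3$series <- sm$series[perm, ]; sm3$coords <- sm$coords[perm, ]
  g3 <- build_graph(sm3)
  expect_equal(g3$W, g1$W[perm, perm], tolerance = 1e-12)
})

test_that("embedding coherence reads ring vs disk geometry", {
  # equally spaced points on a circle: everything at the rim
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  ring <- cbind(cos(th), sin(th))
  expect_gte(embedding_coherence(ring)$rho_mean, 0.95)
  # uniform filled disk: analytic mean radius 2R/3
  set.seed(20)
  r <- sqrt(runif(2000)); a <- runif(2000, 0, 2 * pi)
  disk <- cbind(r * cos(a), r * sin(a))
  expect_equal(embedding_coherence(disk)$rho_mean, 2 / 3, tolerance = 0.05)
  expect_error(embedding_coherence(matrix(1, 5, 2)), "coincident")
  h <- embedding_coherence(disk, bins = 20)
  expect_length(h$counts, 20)
  expect_equal(sum(h$counts), 2000)
})

test_that("wt clock face progresses in order; cry-null bounces", {
  smw <- preset_series("wt")
  embw <- spectral_cluster(build_graph(smw), k = 5, l = 2, seed = 1)
  trw <- clockface(embw, smw)
  cw <- clockface_summary(trw)
  expect_gt(cw$monotonicity, 0.9)
  expect_gt(cw$circular_correlation, 0.9)
  expect_equal(cw$turns_per_period, 1, tolerance = 0.2)
  expect_true(all(trw$theta >= 0 & trw$theta < 2 * pi, na.rm = TRUE))
  # spatial contiguity of the wt spectral clusters
  expect_gt(contiguity_score(embw$labels, embw$coords, embw$grid_dim), 0.9)

  smc <- preset_series("cry_null")
  embc <- spectral_cluster(build_graph(smc), k = 5, l = 2, seed = 1)
  cc <- clockface_summary(clockface(embc, smc))
  expect_gt(cc$n_reversals, 0)
  expect_lt(cc$monotonicity, 0.5)
})

test_that("a non-oscillating tissue yields an empty trace with a message", {
  set.seed(33)
  S <- matrix(rep(seq(1, 2, length.out = 64), each = 12), 12) +
    matrix(rnorm(12 * 64, sd = 1e-4), 12)
  sm <- series_matrix(S, cbind(1:12, 1L), dt_hours = 1)
  emb <- spectral_cluster(build_graph(sm), k = 2, l = 2, seed = 1)
  expect_message(tr <- clockface(emb, sm), "not oscillate")
  expect_true(all(is.na(tr$theta)))
  cs <- clockface_summary(tr)
  expect_true(is.na(cs$turns_per_period))
})
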