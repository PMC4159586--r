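# Shared fixtures, built once per test run and cached: synthetic preset
# movies and their preprocessed superpixel series.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# a preset movie at test scale (64 x 64 px unless stated otherwise)
preset_movie <- function(name, seed = 1L, height = 64L, width = 64L,
                         frame_count = 288L, ...) {
  key <- paste("mv", name, seed, height, width, frame_count, sep = "_")
  cached(key, generate_movie(phenotype_preset(
    name, height = height, width = width, frame_count = frame_count,
    seed = seed, ...)))
}

# despiked, coarsened, masked superpixel series of a preset movie
preset_series <- function(name, seed = 1L, height = 64L, width = 64L,
                          frame_count = 288L, ...) {
  key <- paste("sm", name, seed, height, width, frame_count, sep = "_")
  cached(key, {
    mv <- preset_movie(name, seed, height, width, frame_count, ...)
    sm <- coarsen(despike(mv$stack))
    apply_mask(sm, auto_mask(sm))
  })
}

# ground-truth region label of each superpixel (regions are tile-aligned)
truth_labels <- function(mv, sm) {
  f <- sm$superpixel_size_px
  lab <- mv$truth$label_image[seq(1, nrow(mv$truth$label_image), f),
                              seq(1, ncol(mv$truth$label_image), f)]
  lab[sm$coords]
}

# a tiny deterministic two-phase-group series matrix for clustering tests
two_bundle_series <- function(n_per = 20L, t_n = 120L, dt = 0.5,
                              noise = 0.05, seed = 7L) {
  tt <- (seq_len(t_n) - 1) * dt
  base <- rbind(1 + cos(2 * pi * tt / 24), 1 - cos(2 * pi * tt / 24))
  with_seed <- function(s, code) {  # local, package helper is internal
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); force(code)
  }
  with_seed(seed, {
    S <- base[rep(1:2, each = n_per), ] +
      matrix(rnorm(2 * n_per * t_n, sd = noise), 2 * n_per, t_n)
    pmax(S, 0)
  })
}
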