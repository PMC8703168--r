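# Shared helpers: tiny, fast synthetic configurations used across files.

# A miniature hierarchical dataset: few origins/plants/positions on a
# short axis. Line list is trimmed to lie well apart on the tiny axis.
tiny_config <- function(n_origins = 3L, plants = 2L, positions = 2L,
                        V = 60L, noise_sd = 20, seed = 1L,
                        parts = c("underground", "aerial"), spread = 0.6,
                        jitter_sd = 0.02, baseline_fraction = 0.5) {
  lines <- data.frame(
    center = c(280, 400, 520, 656.28, 766),
    width = c(6, 6, 6, 6, 6),
    base_intensity = c(4000, 8000, 5000, 6000, 9000),
    element = c("Mg", "Ca", "C", "H", "K"),
    discriminative = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  generator_config(
    V = V, lines = lines,
    profiles = origin_profiles(lines, n_origins = n_origins, spread = spread,
                               jitter_sd = jitter_sd),
    plants_per_origin = rep(plants, n_origins),
    parts = parts,
    positions_per_tablet = positions,
    noise_sd = noise_sd,
    baseline_fraction = baseline_fraction,
    seed = seed
  )
}

tiny_dataset <- function(...) generate_dataset(tiny_config(...))

# A well-separated three-class matrix task for classifier tests:
# Gaussian blobs with class-dependent means on a handful of features.
blob_task <- function(n_per_class = 20L, n_feat = 32L, n_classes = 3L,
                      sep = 4, noise = 1, seed = 1L, centers_seed = 99L) {
  set.seed(centers_seed) # shared centers: different seeds draw new
  centers <- matrix(rnorm(n_classes * n_feat), n_classes, n_feat) * sep
  set.seed(seed)         # samples from the same class distribution
  x <- do.call(rbind, lapply(seq_len(n_classes), function(k)
    matrix(rnorm(n_per_class * n_feat, 0, noise), n_per_class, n_feat) +
      matrix(centers[k, ], n_per_class, n_feat, byrow = TRUE)))
  y <- rep(seq_len(n_classes), each = n_per_class)
  idx <- sample(length(y))
  list(x = x[idx, ], y = y[idx])
}

# Cache expensive shared fixtures (e.g., a trained small CNN) per session.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
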