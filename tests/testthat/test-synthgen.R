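test_that("clean spectrum rendering is linear and additive over lines", {
  ax <- wavelength_axis(seq(229, 878, length.out = 500))
  lines <- tiny_config()$lines[c(1, 5), ] # Mg 280 and K 766, far apart,
  # wide enough (6 nm) for the 1.3 nm grid to resolve the peak shape

  expect_equal(render_clean_spectrum(lines[0, ], 1, ax), numeric(500))

  one <- render_clean_spectrum(lines[1, ], 1, ax)
  expect_equal(render_clean_spectrum(lines[1, ], 2, ax), 2 * one)

  # integral of the two-line spectrum equals the sum of per-line integrals
  both <- render_clean_spectrum(lines, c(1, 1), ax)
  two <- render_clean_spectrum(lines[2, ], 1, ax)
  d_lambda <- diff(as.numeric(ax))[1]
  expect_equal(sum(both) * d_lambda,
               (sum(one) + sum(two)) * d_lambda, tolerance = 1e-10)
  # and matches the analytic Gaussian area height * sigma * sqrt(2*pi)
  sigma <- lines$width / sqrt(2 * log(2))
  analytic <- sum(lines$base_intensity * sigma * sqrt(2 * pi))
  expect_equal(sum(both) * d_lambda, analytic, tolerance = 1e-3)
})

test_that("generated datasets follow the declared hierarchical design", {
  cfg <- tiny_config(n_origins = 4L, plants = 2L, positions = 3L, V = 30L)
  ds <- generate_dataset(cfg)
  expect_equal(n_spectra(ds), 4 * 2 * 2 * 3) # origins x plants x parts x pos
  expect_equal(length(unique(ds$meta$tablet_id)), 4 * 2 * 2)
  expect_setequal(unique(ds$meta$origin), 1:4)
  expect_equal(ncol(ds$intensities), 30L)

  # same seed bit-identical; different seed differs
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$intensities, ds2$intensities)
  cfg3 <- tiny_config(n_origins = 4L, plants = 2L, positions = 3L, V = 30L,
                      seed = 9L)
  expect_false(identical(ds$intensities, generate_dataset(cfg3)$intensities))
})

test_that("zero noise and zero jitter collapse an origin-part to one spectrum", {
  cfg <- tiny_config(n_origins = 2L, plants = 3L, positions = 2L, V = 40L,
                     noise_sd = 0, jitter_sd = 0)
  cfg$intensity_jitter_sd <- 0
  ds <- generate_dataset(cfg)
  sub <- ds$intensities[ds$meta$origin == 1 & ds$meta$part == "underground", ]
  expect_equal(max(apply(sub, 2, function(col) diff(range(col)))), 0)
})

test_that("baseline channels sit orders of magnitude below line channels", {
  ds <- tiny_dataset(n_origins = 3L, plants = 3L, positions = 4L, V = 200L,
                     baseline_fraction = 0.6)
  truth <- attr(ds, "generator_truth")
  sds <- apply(ds$intensities, 2, sd)
  base_sd <- max(sds[truth$baseline_channels])
  line_sd <- median(sds[!truth$baseline_channels])
  expect_lt(base_sd, 1e-3 * line_sd)
})

test_that("wider origin-profile spread cannot reduce class separation", {
  lines <- tiny_config()$lines
  ax <- wavelength_axis(seq(229, 878, length.out = 100))
  sep <- function(spread) {
    prof <- origin_profiles(lines, n_origins = 6L, spread = spread, seed = 7L)
    cleans <- t(sapply(seq_len(6), function(o)
      render_clean_spectrum(lines, prof$multipliers[o, ], ax)))
    cleans <- cleans / rowSums(cleans)
    mean(dist(cleans))
  }
  expect_gte(sep(0.6), sep(0.2))
  expect_gte(sep(0.2), sep(0.05))
})

test_that("invalid generator configurations are rejected", {
  expect_error(tiny_config(baseline_fraction = 1), "baseline_fraction")
  bad <- tiny_config()
  bad$plants_per_origin <- c(1L, 1L) # profiles declare 3 origins
  expect_error(libspec:::validate_generator_config(bad), "origins")
  bad2 <- tiny_config()
  bad2$lines$center[1] <- 100 # outside the axis
  expect_error(libspec:::validate_generator_config(bad2), "axis range")
})
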