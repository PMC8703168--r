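test_that("accuracy and its reporting convention behave as stated", {
  expect_equal(accuracy(1:5, 1:5), 100)
  expect_equal(accuracy(rep(1, 4), rep(2, 4)), 0)
  expect_equal(round_half_up(100 * 354 / 384), 92.19)
  expect_equal(round_half_up(2.345, 2), 2.35) # half goes up
  expect_error(accuracy(integer(0), integer(0)), "empty")
  expect_error(accuracy(1:3, 1:4), "equal length")
})

test_that("confusion matrices agree with an independent tally", {
  cm <- confusion(c(1, 2, 3), c(1, 2, 3), 3)
  expect_equal(unclass(cm), diag(1L, 3L), ignore_attr = TRUE)

  cm1 <- confusion(3, 5, 6)
  expect_equal(sum(cm1), 1L)
  expect_equal(cm1[3, 5], 1L)

  set.seed(8)
  truth <- sample(1:4, 200, replace = TRUE)
  pred <- sample(1:4, 200, replace = TRUE)
  cm2 <- confusion(truth, pred, 4)
  tally <- matrix(0L, 4, 4)
  for (i in seq_along(truth)) {
    tally[truth[i], pred[i]] <- tally[truth[i], pred[i]] + 1L
  }
  expect_equal(unclass(cm2), tally, ignore_attr = TRUE)
  # conservation and the accuracy identity
  expect_equal(sum(cm2), 200L)
  expect_equal(sum(diag(cm2)) / 200, accuracy(truth, pred) / 100)
  expect_error(confusion(c(1, 9), c(1, 1), 4), "1..K")
})

# hand-assembled linear model: flatten + dense, so the class score is w.x
linear_model <- function(L, K, seed = 1L) {
  spec <- structure(list(name = "toy", input_shape = c(L, 1L),
                         input_kind = "1d", n_classes = K,
                         blocks = list(list(kind = "flatten"),
                                       list(kind = "dense", units = K,
                                            name = "logits"))),
                    class = "architecture_spec")
  net <- libspec:::nn_init(spec, seed)
  structure(list(kind = "cnn", net = net, spec = spec),
            class = "libspec_model")
}

test_that("saliency of a linear score is exactly the weight magnitude", {
  m <- linear_model(12L, 3L, seed = 2L)
  w <- m$net$layers[[2]]$W
  x <- rnorm(12)
  for (k in 1:3) {
    expect_equal(saliency_map(m, x, k), abs(w[, k]))
  }
  # a model that ignores its input has an all-zero map
  m0 <- m
  m0$net$layers[[2]]$W <- w * 0
  expect_equal(saliency_map(m0, x, 1), rep(0, 12))
})

test_that("saliency gradients match finite differences on a small 2-D net", {
  spec <- build_cnn2d(c(8L, 8L), 3L)
  net <- libspec:::nn_init(spec, seed = 4L)
  m <- structure(list(kind = "cnn", net = net, spec = spec),
                 class = "libspec_model")
  set.seed(5)
  x <- matrix(abs(rnorm(64)), 8, 8)
  k <- 2L
  sal <- saliency_map(m, x, k)
  expect_equal(dim(sal), c(8L, 8L))
  expect_true(all(sal >= 0))

  logit_at <- function(xx) {
    arr <- libspec:::.as_input_array(xx, "2d")
    libspec:::nn_forward(net, arr, train = FALSE)$logits[1, k]
  }
  h <- 1e-5
  for (idx in list(c(1, 1), c(3, 5), c(8, 8), c(5, 2))) {
    xp <- x; xp[idx[1], idx[2]] <- x[idx[1], idx[2]] + h
    xm <- x; xm[idx[1], idx[2]] <- x[idx[1], idx[2]] - h
    fd <- abs((logit_at(xp) - logit_at(xm)) / (2 * h))
    expect_equal(sal[idx[1], idx[2]], fd, tolerance = 1e-4)
  }
})

test_that("origin-averaged saliency averages maps and ranks wavelengths", {
  spec <- build_cnn2d(c(8L, 10L), 2L)
  net <- libspec:::nn_init(spec, seed = 6L)
  m <- structure(list(kind = "cnn", net = net, spec = spec),
                 class = "libspec_model")
  arr <- array(abs(rnorm(3 * 8 * 10)), c(3, 8, 10))
  arr[3, , ] <- arr[1, , ] # two identical spectra for origin 2
  mset <- list(array = arr, n = 8L, h = 10L,
               meta = data.frame(origin = c(1L, 2L, 2L)),
               axis = seq(300, 400, length.out = 80))
  s1 <- origin_average_saliency(m, mset, 1L)
  expect_equal(s1$weights, saliency_map(m, arr[1, , ], 1L))

  # averaging: origin 2 holds one spectrum twice under the same target
  s2 <- origin_average_saliency(m, mset, 2L)
  a <- saliency_map(m, arr[2, , ], 2L)
  expect_equal(s2$weights, (a + saliency_map(m, arr[3, , ], 2L)) / 2)

  # ranking is consistent with the pixel-variable-wavelength chain
  top <- s2$ranked_wavelengths[1, ]
  px <- variable_to_pixel(top$variable, 10L)
  expect_equal(s2$weights[px[1, "row"] + 1L, px[1, "col"] + 1L], top$weight)
  expect_true(all(diff(s2$ranked_wavelengths$weight) <= 0))
  expect_error(origin_average_saliency(m, mset, 5L), "absent")
})

test_that("t-SNE layer views are seeded, shaped, and class-separating", {
  trained <- cached("tsne_model", {
    task <- blob_task(n_per_class = 40L, n_feat = 24L, sep = 6, seed = 12L)
    sch <- train_schedule(c(0.1, 0.01), c(0.7, 0.9),
                          max_iterations_per_stage = 30L, batch_size = 16L,
                          seed = 13L)
    list(tr = train_staged(build_cnn1d_1(24L, 3L), task, task, sch),
         task = task)
  })
  tr <- trained$tr; task <- trained$task

  emb <- tsne_layer_view(tr$model_ref, task$x, "dense2", perplexity = 10,
                         seed = 3L)
  expect_equal(dim(emb), c(nrow(task$x), 2L))
  expect_identical(emb, tsne_layer_view(tr$model_ref, task$x, "dense2",
                                        perplexity = 10, seed = 3L))
  expect_error(tsne_layer_view(tr$model_ref, task$x, "nope", 10), "unknown layer")

  sil <- function(layer) {
    e <- tsne_layer_view(tr$model_ref, task$x, layer, perplexity = 10,
                         seed = 3L)
    mean(cluster::silhouette(task$y, dist(e))[, 3])
  }
  s_deep <- sil("dense2")
  expect_gt(s_deep, 0.5)
  # deeper layers separate at least as well as the first convolution
  expect_gte(s_deep + 0.05, sil("conv1"))
})
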