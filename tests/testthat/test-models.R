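test_that("architecture builders encode the declared layer plans", {
  s1 <- build_cnn1d_1(325L)
  kernels <- vapply(Filter(function(b) b$kind == "conv1d", s1$blocks),
                    function(b) b$out_ch, integer(1))
  expect_equal(kernels, c(512L, 128L, 64L, 16L))
  sizes <- vapply(Filter(function(b) b$kind == "conv1d", s1$blocks),
                  function(b) b$k, integer(1))
  expect_true(all(sizes == 3L))
  dense <- vapply(Filter(function(b) b$kind == "dense", s1$blocks),
                  function(b) b$units, integer(1))
  expect_equal(dense, c(256L, 64L, 32L, 12L))
  drops <- Filter(function(b) b$kind == "dropout", s1$blocks)
  expect_true(all(vapply(drops, function(b) b$p, numeric(1)) == 0.3))
  expect_error(build_cnn1d_1(8L), "input_length")

  s2 <- build_cnn1d_2(325L)
  res <- Filter(function(b) b$kind == "res1d", s2$blocks)
  expect_equal(vapply(res, function(b) b$channels, integer(1)),
               c(64L, 128L, 256L))
  expect_true(all(vapply(res, function(b) b$n_convs, integer(1)) == 2L))

  s3 <- build_cnn2d(c(146L, 150L))
  convs <- Filter(function(b) b$kind == "conv2d", s3$blocks)
  expect_equal(vapply(convs, function(b) b$k, integer(1)), c(7L, 3L))
  expect_equal(vapply(convs, function(b) b$out_ch, integer(1)), c(64L, 16L))
  expect_error(build_cnn2d(c(4L, 150L)), "at least 8 x 8")
})

test_that("the 2-D network is smaller than the 1-D one at full input", {
  p2d <- count_parameters(build_cnn2d(c(146L, 150L)))
  p1d <- count_parameters(build_cnn1d_1(2016L))
  expect_lt(p2d, p1d)
  # builders are pure: same config, identical spec and count
  expect_identical(build_cnn2d(c(146L, 150L)), build_cnn2d(c(146L, 150L)))
  expect_identical(p2d, count_parameters(build_cnn2d(c(146L, 150L))))
})

test_that("a residual block with a zeroed branch is the identity", {
  spec <- build_cnn1d_2(32L, 3L)
  net <- libspec:::nn_init(spec, seed = 1L)
  i_res <- which(vapply(net$layers, function(l) l$kind == "res1d",
                        logical(1)))[1]
  ly <- net$layers[[i_res]]
  expect_null(ly$proj) # first residual block keeps 64 channels
  for (j in seq_along(ly$branch)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      if (!is.null(ly$branch[[j]][[nm]])) {
        ly$branch[[j]][[nm]] <- ly$branch[[j]][[nm]] * 0
      }
    }
    if (!is.null(ly$branch[[j]]$run_var)) ly$branch[[j]]$run_var <- ly$branch[[j]]$run_var * 0 + 1
  }
  x <- array(abs(rnorm(2 * 16 * 64)), c(2, 16, 64)) # non-negative input
  out <- libspec:::.layer_fwd(ly, x, train = FALSE)$out
  expect_equal(out, x)
})

test_that("schedule validation enforces the staged protocol contract", {
  s <- train_schedule(c(0.1, 0.05, 0.01, 0.005), c(0.6, 0.75, 0.92, 0.96))
  expect_s3_class(s, "train_schedule")
  expect_equal(s$max_iterations_per_stage, 1000L)
  expect_error(train_schedule(c(0.1, 0.1), c(0.5, 0.6)), "decreasing")
  expect_error(train_schedule(c(0.1, 0.05), c(0.6, 0.6)), "increasing")
  expect_error(train_schedule(c(0.1, 0.05), c(0.6, 1.2)), "\\(0, 1\\]")
  expect_error(train_schedule(c(0.1, -0.05), c(0.6, 0.7)))
})

test_that("staged training respects thresholds, caps, and determinism", {
  task <- blob_task(n_per_class = 12L, n_feat = 32L, seed = 2L)
  val <- blob_task(n_per_class = 6L, n_feat = 32L, seed = 3L)
  spec <- build_cnn1d_1(32L, 3L)

  # a vacuous threshold ends every stage after one iteration
  sch0 <- train_schedule(c(0.1, 0.05), c(1e-9, 1e-8),
                         max_iterations_per_stage = 50L, seed = 1L)
  tr0 <- train_staged(spec, task, val, sch0)
  expect_equal(tr0$stopped_reason, c("threshold_met", "threshold_met"))
  expect_equal(nrow(tr0$history), 2L)

  # no stage ever exceeds its iteration cap
  sch1 <- train_schedule(c(0.1, 0.05), c(0.999, 1),
                         max_iterations_per_stage = 3L, seed = 1L)
  tr1 <- train_staged(spec, task, val, sch1)
  expect_true(all(table(tr1$history$stage) <= 3L))

  # seeded reproducibility of the full history
  tr2 <- train_staged(spec, task, val, sch1)
  expect_identical(tr1$history, tr2$history)

  expect_error(train_staged(spec, list(x = task$x, y = task$y * 0 + 7),
                            val, sch0), "1..n_classes")
})

test_that("staged training learns an easy separable task", {
  task <- blob_task(n_per_class = 16L, n_feat = 32L, sep = 5, seed = 4L)
  val <- blob_task(n_per_class = 8L, n_feat = 32L, sep = 5, seed = 5L)
  sch <- train_schedule(c(0.1, 0.01), c(0.7, 0.95),
                        max_iterations_per_stage = 40L, batch_size = 16L,
                        seed = 6L)
  tr <- train_staged(build_cnn1d_1(32L, 3L), task, val, sch)
  expect_gte(tail(tr$history$validation_accuracy, 1), 0.95)
  pr <- predict(tr$model_ref, task$x)
  expect_gte(mean(pr$labels == task$y), 0.95)
  expect_equal(rowSums(pr$scores), rep(1, nrow(task$x)))
})

test_that("classical baselines fit, search, and tie-break as declared", {
  task <- blob_task(n_per_class = 15L, n_feat = 8L, sep = 6, seed = 7L)
  val <- blob_task(n_per_class = 8L, n_feat = 8L, sep = 6, seed = 8L)

  lda <- fit_baseline("lda", task, val)
  expect_equal(mean(predict(lda, task$x)$labels == task$y), 1)
  expect_equal(rowSums(predict(lda, val$x)$scores), rep(1, length(val$y)))

  knn <- fit_baseline("knn", task, val)
  expect_gte(knn$hyper$k, 3L)
  expect_lte(knn$hyper$k, 20L)
  expect_equal(mean(predict(knn, val$x)$labels == val$y), 1)

  # a within-group-constant variable breaks plain LDA and triggers the
  # ridge fallback with a warning
  xc <- cbind(task$x, 1)
  expect_warning(
    lda2 <- fit_baseline("lda", list(x = xc, y = task$y),
                         list(x = cbind(val$x, 1), y = val$y)),
    "ridge"
  )
  expect_gte(mean(predict(lda2, xc)$labels == task$y), 0.95)
})

test_that("svm grid search returns the argmax of its own criterion", {
  task <- blob_task(n_per_class = 12L, n_feat = 6L, sep = 3, seed = 9L)
  val <- blob_task(n_per_class = 10L, n_feat = 6L, sep = 3, seed = 10L)
  powers <- c(-2L, 0L, 2L)
  m <- fit_baseline("svm", task, val,
                    search = list(powers = powers, method = "validation"))
  # independent exhaustive re-evaluation of the same criterion
  grid <- expand.grid(g = 10^powers, c = 10^powers)
  accs <- vapply(seq_len(nrow(grid)), function(i) {
    f <- e1071::svm(task$x, factor(task$y), kernel = "radial",
                    cost = grid$c[i], gamma = grid$g[i])
    mean(as.integer(as.character(predict(f, val$x))) == val$y)
  }, numeric(1))
  expect_equal(m$hyper$accuracy, max(accs))
  best <- grid[order(-accs, grid$c, grid$g)[1], ]
  expect_equal(m$hyper$cost, best$c)
  expect_equal(m$hyper$gamma, best$g)
})

test_that("prediction is order-equivariant and handles single records", {
  task <- blob_task(n_per_class = 10L, n_feat = 16L, seed = 11L)
  sch <- train_schedule(c(0.1, 0.05), c(1e-9, 1e-8), seed = 1L)
  tr <- train_staged(build_cnn1d_1(16L, 3L), task, task, sch)
  m <- tr$model_ref
  p_all <- predict(m, task$x)
  perm <- rev(seq_along(task$y))
  p_perm <- predict(m, task$x[perm, ])
  expect_identical(p_perm$labels, p_all$labels[perm])
  expect_equal(p_perm$scores, p_all$scores[perm, ])
  p1 <- predict(m, task$x[3, , drop = FALSE])
  expect_length(p1$labels, 1L)
  expect_identical(p1$labels, p_all$labels[3])
})
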