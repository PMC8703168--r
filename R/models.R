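#' Architecture of the AlexNet-style 1-D convolutional classifier
#'
#' Four 1-D convolution blocks (convolution, batch normalization, max
#' pooling of size 2, ReLU) with 512, 128, 64 and 16 kernels of size 3,
#' followed by three dense blocks of 256, 64 and 32 neurons (ReLU,
#' dropout 0.3) and a softmax output. Convolutions use same-padding, so
#' only pooling shortens the signal; four poolings need an input of at
#' least 16 variables.
#'
#' @param input_length Number of input variables (>= 16).
#' @param n_classes Number of output classes (default 12).
#' @return An `architecture_spec`.
#' @export
build_cnn1d_1 <- function(input_length, n_classes = 12L) {
  input_length <- as.integer(input_length)
  if (input_length < 16L) {
    stop("cnn1d_1 needs input_length >= 16 (four pooling stages)", call. = FALSE)
  }
  blocks <- list()
  chs <- c(512L, 128L, 64L, 16L)
  for (i in seq_along(chs)) {
    blocks <- c(blocks, list(
      list(kind = "conv1d", k = 3L, out_ch = chs[i]),
      list(kind = "bn"),
      list(kind = "pool1d", s = 2L),
      list(kind = "relu", name = sprintf("conv%d", i))))
  }
  blocks <- c(blocks, list(list(kind = "flatten")))
  us <- c(256L, 64L, 32L)
  for (i in seq_along(us)) {
    blocks <- c(blocks, list(
      list(kind = "dense", units = us[i]),
      list(kind = "bn"),
      list(kind = "relu", name = sprintf("dense%d", i)),
      list(kind = "dropout", p = 0.3)))
  }
  blocks <- c(blocks, list(list(kind = "dense", units = as.integer(n_classes),
                                name = "logits")))
  structure(list(name = "cnn1d_1", input_shape = c(input_length, 1L),
                 input_kind = "1d", n_classes = as.integer(n_classes),
                 blocks = blocks),
            class = "architecture_spec")
}

#' Architecture of the ResNet-style 1-D convolutional classifier
#'
#' An initial convolution block (64 kernels of size 3, batch
#' normalization, max pooling, ReLU), then three residual blocks with
#' (channels, convolutions) = (64, 2), (128, 2), (256, 2). Each residual
#' block adds its input to the convolution branch through a skip path
#' (with a size-1 convolution projection when the channel count grows)
#' and is followed by a size-2 max pooling. A dense block of 128 neurons
#' (ReLU, dropout 0.3) feeds the softmax output.
#'
#' @param input_length Number of input variables (>= 16).
#' @param n_classes Number of output classes (default 12).
#' @return An `architecture_spec`.
#' @export
build_cnn1d_2 <- function(input_length, n_classes = 12L) {
  input_length <- as.integer(input_length)
  if (input_length < 16L) {
    stop("cnn1d_2 needs input_length >= 16 (four pooling stages)", call. = FALSE)
  }
  blocks <- list(
    list(kind = "conv1d", k = 3L, out_ch = 64L),
    list(kind = "bn"),
    list(kind = "pool1d", s = 2L),
    list(kind = "relu", name = "conv1"))
  i <- 0L
  for (ch in c(64L, 128L, 256L)) {
    i <- i + 1L
    blocks <- c(blocks, list(
      list(kind = "res1d", channels = ch, n_convs = 2L,
           name = sprintf("res%d", i)),
      list(kind = "pool1d", s = 2L)))
  }
  blocks <- c(blocks, list(
    list(kind = "flatten"),
    list(kind = "dense", units = 128L),
    list(kind = "bn"),
    list(kind = "relu", name = "dense1"),
    list(kind = "dropout", p = 0.3),
    list(kind = "dense", units = as.integer(n_classes), name = "logits")))
  structure(list(name = "cnn1d_2", input_shape = c(input_length, 1L),
                 input_kind = "1d", n_classes = as.integer(n_classes),
                 blocks = blocks),
            class = "architecture_spec")
}

#' Architecture of the 2-D convolutional classifier for spectral matrices
#'
#' Two 2-D convolution blocks -- 64 kernels of size 7x7 then 16 kernels
#' of size 3x3, each with batch normalization, 4x4 max pooling and ReLU
#' -- followed by dense blocks of 256 and 64 neurons (ReLU, dropout 0.3)
#' and a softmax output. The large first kernel captures several
#' adjacent spectral segments at once. The first block pools 2x2 to
#' retain fine spectral detail; the second pools 8x8, which keeps the
#' network far smaller than the 1-D architectures despite the
#' image-sized input.
#'
#' @param input_shape Integer pair `c(n, h)`: rows and columns of the
#'   spectral matrix (both >= 8).
#' @param n_classes Number of output classes (default 12).
#' @return An `architecture_spec`.
#' @export
build_cnn2d <- function(input_shape, n_classes = 12L) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 2L || any(input_shape < 8L)) {
    stop("cnn2d needs an input of at least 8 x 8", call. = FALSE)
  }
  blocks <- list(
    list(kind = "conv2d", k = 7L, out_ch = 64L),
    list(kind = "bn"),
    list(kind = "pool2d", s = 2L),
    list(kind = "relu", name = "conv1"),
    list(kind = "conv2d", k = 3L, out_ch = 16L),
    list(kind = "bn"),
    list(kind = "pool2d", s = 8L),
    list(kind = "relu", name = "conv2"),
    list(kind = "flatten"),
    list(kind = "dense", units = 256L),
    list(kind = "bn"),
    list(kind = "relu", name = "dense1"),
    list(kind = "dropout", p = 0.3),
    list(kind = "dense", units = 64L),
    list(kind = "bn"),
    list(kind = "relu", name = "dense2"),
    list(kind = "dropout", p = 0.3),
    list(kind = "dense", units = as.integer(n_classes), name = "logits"))
  structure(list(name = "cnn2d", input_shape = c(input_shape, 1L),
                 input_kind = "2d", n_classes = as.integer(n_classes),
                 blocks = blocks),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %s: input %s, %d classes, %d blocks\n",
              x$name, paste(x$input_shape, collapse = "x"), x$n_classes,
              length(x$blocks)))
  invisible(x)
}

#' Total trainable parameter count of an architecture
#'
#' @param spec An `architecture_spec`.
#' @return Number of trainable scalars (weights, biases, batch-norm
#'   scale/shift) the architecture holds at its declared input size.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  nn_param_count(nn_init(spec, seed = 1L))
}

#' Staged SGD training schedule
#'
#' Training proceeds in stages of decreasing learning rate and
#' increasing validation-accuracy threshold: each stage runs SGD until
#' the validation accuracy reaches its threshold or the per-stage
#' iteration cap (1000) is hit, then hands the parameters to the next
#' stage. One iteration is one pass over the calibration set in
#' mini-batches.
#'
#' @param learning_rates Strictly decreasing positive rates.
#' @param thresholds Strictly increasing validation-accuracy targets in
#'   (0, 1], one per stage.
#' @param max_iterations_per_stage Cap per stage (default 1000).
#' @param batch_size Mini-batch size (default 32).
#' @param momentum Classical SGD momentum (default 0, plain SGD).
#' @param weight_decay L2 penalty on weight matrices (default 0).
#' @param seed Seed for initialization, shuffling and dropout.
#' @return A `train_schedule`.
#' @export
train_schedule <- function(learning_rates = c(0.1, 0.05, 0.01, 0.005),
                           thresholds = c(0.6, 0.75, 0.92, 0.96),
                           max_iterations_per_stage = 1000L,
                           batch_size = 32L, momentum = 0,
                           weight_decay = 0, seed = 1L) {
  if (length(learning_rates) != length(thresholds)) {
    stop("need one threshold per learning rate", call. = FALSE)
  }
  if (any(diff(learning_rates) >= 0)) {
    stop("learning rates must be strictly decreasing", call. = FALSE)
  }
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  if (any(learning_rates <= 0)) stop("learning rates must be positive",
                                     call. = FALSE)
  structure(list(stages = data.frame(learning_rate = learning_rates,
                                     threshold = thresholds),
                 max_iterations_per_stage = as.integer(max_iterations_per_stage),
                 batch_size = as.integer(batch_size),
                 momentum = momentum, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_schedule")
}

.as_input_array <- function(x, kind) {
  if (kind == "1d") {
    if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L))
    else array(x, c(1L, length(x), 1L))
  } else {
    d <- dim(x)
    if (length(d) == 3L) array(x, c(d, 1L))
    else array(x, c(1L, d, 1L))
  }
}

#' Train a convolutional classifier with the staged schedule
#'
#' @param spec An `architecture_spec` from one of the builders.
#' @param calibration,validation Lists with `x` (matrix of spectra for
#'   the 1-D architectures, or an array `spectra x n x h` of spectral
#'   matrices for the 2-D one) and `y` (integer labels in
#'   `1..n_classes`).
#' @param schedule A [train_schedule()].
#' @return A `train_result`: list with `history` (stage, iteration,
#'   loss, calibration and validation accuracy per iteration),
#'   `stopped_reason` per stage (`"threshold_met"` or
#'   `"iteration_cap"`), and `model_ref`, a classifier usable with
#'   [predict()].
#' @export
train_staged <- function(spec, calibration, validation, schedule) {
  stopifnot(inherits(spec, "architecture_spec"),
            inherits(schedule, "train_schedule"))
  if (length(calibration$y) == 0L || length(validation$y) == 0L) {
    stop("calibration and validation data must be non-empty", call. = FALSE)
  }
  if (any(calibration$y < 1L | calibration$y > spec$n_classes)) {
    stop("labels must lie in 1..n_classes", call. = FALSE)
  }
  xc <- .as_input_array(calibration$x, spec$input_kind)
  xv <- .as_input_array(validation$x, spec$input_kind)
  yc <- as.integer(calibration$y); yv <- as.integer(validation$y)
  n <- length(yc)

  net <- nn_init(spec, seed = schedule$seed)
  history <- list(); stopped <- character(nrow(schedule$stages))

  eval_acc <- function(net, x, y) {
    # chunked evaluation keeps im2col buffers small
    n <- length(y); hits <- 0L
    for (bi in split(seq_len(n), ceiling(seq_len(n) / 64L))) {
      xb <- if (spec$input_kind == "1d") x[bi, , , drop = FALSE]
            else x[bi, , , , drop = FALSE]
      p <- nn_forward(net, xb, train = FALSE)$logits
      hits <- hits + sum(max.col(p, ties.method = "first") == y[bi])
    }
    hits / n
  }

  with_seed_local(schedule$seed + 1L, {
    for (s in seq_len(nrow(schedule$stages))) {
      lr <- schedule$stages$learning_rate[s]
      thr <- schedule$stages$threshold[s]
      stopped[s] <- "iteration_cap"
      for (it in seq_len(schedule$max_iterations_per_stage)) {
        ord <- sample.int(n)
        batches <- split(ord, ceiling(seq_along(ord) / schedule$batch_size))
        ep_loss <- 0
        ep_hits <- 0L
        for (bi in batches) {
          xb <- if (spec$input_kind == "1d") {
            xc[bi, , , drop = FALSE]
          } else xc[bi, , , , drop = FALSE]
          fw <- nn_forward(net, xb, train = TRUE)
          net <- fw$net
          pr <- .softmax_rows(fw$logits)
          yb <- yc[bi]
          loss <- -mean(log(pmax(pr[cbind(seq_along(bi), yb)], 1e-300)))
          if (!is.finite(loss)) {
            stop(sprintf("training diverged (non-finite loss) in stage %d", s),
                 call. = FALSE)
          }
          ep_loss <- ep_loss + loss * length(bi)
          ep_hits <- ep_hits + sum(max.col(pr, ties.method = "first") == yb)
          dlog <- pr
          dlog[cbind(seq_along(bi), yb)] <- dlog[cbind(seq_along(bi), yb)] - 1
          dlog <- dlog / length(bi)
          bw <- nn_backward(net, fw$caches, dlog)
          net <- nn_sgd_step(net, bw$grads, lr, schedule$momentum,
                             schedule$weight_decay)
        }
        cal_acc <- ep_hits / n # accuracy accumulated over the epoch's batches
        val_acc <- eval_acc(net, xv, yv)
        history[[length(history) + 1L]] <-
          data.frame(stage = s, iteration = it, loss = ep_loss / n,
                     calibration_accuracy = cal_acc,
                     validation_accuracy = val_acc)
        # a stage completes when the validation accuracy reaches its
        # threshold; the (inference-mode) calibration accuracy must be
        # there too, which is vacuous at realistic set sizes but keeps
        # a tiny, coarse validation set from ending a stage before the
        # fit converges
        if (val_acc >= thr && eval_acc(net, xc, yc) >= thr) {
          stopped[s] <- "threshold_met"; break
        }
      }
    }
  })

  model <- structure(list(kind = "cnn", net = net, spec = spec),
                     class = "libspec_model")
  structure(list(history = do.call(rbind, history),
                 stopped_reason = stopped, model_ref = model,
                 schedule = schedule),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  h <- x$history
  cat(sprintf("<train_result> %d stages, %d iterations; final val accuracy %.3f\n",
              max(h$stage), nrow(h), h$validation_accuracy[nrow(h)]))
  invisible(x)
}

# ridge-regularized Gaussian LDA used when the pooled within-class
# covariance is singular
.ridge_lda <- function(x, y, lambda = 1e-6) {
  classes <- sort(unique(y))
  mus <- t(vapply(classes, function(k) colMeans(x[y == k, , drop = FALSE]),
                  numeric(ncol(x))))
  cent <- x - mus[match(y, classes), , drop = FALSE]
  S <- crossprod(cent) / (nrow(x) - length(classes))
  S <- S + lambda * mean(diag(S)) * diag(ncol(x))
  Sinv <- solve(S)
  priors <- as.numeric(table(factor(y, classes)) / length(y))
  list(classes = classes, mus = mus, Sinv = Sinv, priors = priors)
}

.ridge_lda_scores <- function(fit, x) {
  # linear discriminant scores mu' Sinv x - mu' Sinv mu / 2 + log prior
  t(apply(x, 1L, function(r) {
    vapply(seq_along(fit$classes), function(k) {
      m <- fit$mus[k, ]
      as.numeric(m %*% fit$Sinv %*% r - 0.5 * m %*% fit$Sinv %*% m +
                   log(fit$priors[k]))
    }, numeric(1))
  }))
}

#' Fit a classical baseline classifier
#'
#' \describe{
#'   \item{lda}{linear discriminant analysis; if the within-class
#'     covariance is singular a warning is emitted and a
#'     ridge-regularized Gaussian LDA is fitted instead.}
#'   \item{knn}{k nearest neighbours; `k` is searched over 3..20 by
#'     validation-set accuracy (ties to the smallest `k`).}
#'   \item{svm}{RBF-kernel SVM; cost and kernel width are searched over
#'     integer powers of 10 from 1e-8 to 1e8 by 5-fold cross-validation
#'     accuracy on the calibration set (ties to the smallest cost, then
#'     the smallest gamma). `search$method = "validation"` switches the
#'     criterion to validation-set accuracy.}
#' }
#'
#' @param kind `"lda"`, `"knn"` or `"svm"`.
#' @param calibration,validation Lists with `x` (matrix) and `y`
#'   (integer labels).
#' @param search Optional list: `k_range` (knn), `powers` (svm exponent
#'   grid, default -8:8), `method` (svm: `"cv"` or `"validation"`),
#'   `seed`.
#' @return A `libspec_model` with the fitted classifier and the chosen
#'   hyperparameters in `$hyper`.
#' @export
fit_baseline <- function(kind = c("lda", "knn", "svm"), calibration,
                         validation, search = list()) {
  kind <- match.arg(kind)
  x <- as.matrix(calibration$x); y <- as.integer(calibration$y)
  xv <- as.matrix(validation$x); yv <- as.integer(validation$y)
  if (length(y) == 0L) stop("calibration data must be non-empty", call. = FALSE)
  seed <- if (is.null(search$seed)) 1L else as.integer(search$seed)
  model <- switch(kind,
    lda = {
      fit <- tryCatch(
        MASS::lda(x, grouping = factor(y)),
        error = function(e) {
          warning("within-class covariance is singular; ",
                  "falling back to ridge-regularized LDA", call. = FALSE)
          .ridge_lda(x, y)
        })
      list(kind = "lda", fit = fit, hyper = list())
    },
    knn = {
      k_range <- if (is.null(search$k_range)) 3:20 else search$k_range
      accs <- vapply(k_range, function(k) {
        mean(as.integer(as.character(
          class::knn(x, xv, factor(y), k = k))) == yv)
      }, numeric(1))
      k_best <- k_range[which.max(accs)]
      list(kind = "knn", fit = list(x = x, y = y, k = k_best),
           hyper = list(k = k_best, validation_accuracy = max(accs)))
    },
    svm = {
      powers <- if (is.null(search$powers)) -8:8 else search$powers
      method <- if (is.null(search$method)) "cv" else search$method
      grid <- expand.grid(g = 10^powers, c = 10^powers)
      grid <- grid[order(grid$c, grid$g), ]
      accs <- with_seed_local(seed, vapply(seq_len(nrow(grid)), function(i) {
        if (method == "cv") {
          m <- e1071::svm(x, factor(y), kernel = "radial",
                          cost = grid$c[i], gamma = grid$g[i], cross = 5)
          m$tot.accuracy / 100
        } else {
          m <- e1071::svm(x, factor(y), kernel = "radial",
                          cost = grid$c[i], gamma = grid$g[i])
          mean(as.integer(as.character(predict(m, xv))) == yv)
        }
      }, numeric(1)))
      best <- grid[which.max(accs), ] # grid sorted by c then g: ties OK
      fit <- e1071::svm(x, factor(y), kernel = "radial", cost = best$c,
                        gamma = best$g, probability = TRUE)
      list(kind = "svm", fit = fit,
           hyper = list(cost = best$c, gamma = best$g, accuracy = max(accs)))
    })
  structure(model, class = "libspec_model")
}

#' Predict labels and class scores
#'
#' @param object A `libspec_model` (CNN or baseline).
#' @param newdata Matrix of spectra (1-D models, baselines) or array of
#'   spectral matrices (2-D CNN). A single record may be passed as a
#'   vector/matrix.
#' @param ... Unused.
#' @return List with `labels` (integer) and `scores` (matrix, rows
#'   summing to 1 for probabilistic models, `NULL` for KNN).
#' @export
predict.libspec_model <- function(object, newdata, ...) {
  switch(object$kind,
    cnn = {
      x <- .as_input_array(newdata, object$spec$input_kind)
      logits <- nn_forward(object$net, x, train = FALSE)$logits
      p <- .softmax_rows(logits)
      list(labels = max.col(p, ties.method = "first"), scores = p)
    },
    lda = {
      newdata <- as.matrix(newdata)
      if (inherits(object$fit, "lda")) {
        pr <- stats::predict(object$fit, newdata)
        list(labels = as.integer(as.character(pr$class)),
             scores = pr$posterior)
      } else {
        sc <- .ridge_lda_scores(object$fit, newdata)
        # convert discriminant scores to posterior-like softmax weights
        p <- .softmax_rows(sc)
        list(labels = object$fit$classes[max.col(sc, ties.method = "first")],
             scores = p)
      }
    },
    knn = {
      pr <- class::knn(object$fit$x, as.matrix(newdata),
                       factor(object$fit$y), k = object$fit$k)
      list(labels = as.integer(as.character(pr)), scores = NULL)
    },
    svm = {
      pr <- predict(object$fit, as.matrix(newdata), probability = TRUE)
      probs <- attr(pr, "probabilities")
      probs <- probs[, order(as.integer(colnames(probs))), drop = FALSE]
      list(labels = as.integer(as.character(pr)), scores = probs)
    },
    stop("unknown model kind: ", object$kind)
  )
}

#' @export
print.libspec_model <- function(x, ...) {
  cat(sprintf("<libspec_model> %s\n", x$kind))
  invisible(x)
}
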