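#' Discriminant accuracy in percent
#'
#' The ratio of correctly classified spectra to all spectra, times 100.
#'
#' @param truth,predicted Equal-length label vectors, non-empty.
#' @return Percentage in \[0, 100\].
#' @export
accuracy <- function(truth, predicted) {
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  if (length(truth) != length(predicted)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  100 * mean(truth == predicted)
}

#' Round half away from zero
#'
#' Reported accuracies follow the two-decimal half-up convention
#' (354/384 prints as 92.19).
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Confusion matrix with true classes in rows
#'
#' `counts[i, j]` is the number of spectra of true class `i` predicted
#' as class `j`; the diagonal holds the correctly classified counts and
#' `trace/total` equals `accuracy/100`.
#'
#' @param truth,predicted Integer label vectors with values in `1..K`.
#' @param K Number of classes.
#' @return A `confusion_matrix`: K x K integer matrix with dimnames,
#'   rows = true class, columns = predicted class.
#' @export
confusion <- function(truth, predicted, K) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (any(truth < 1L | truth > K) || any(predicted < 1L | predicted > K)) {
    stop("labels must lie in 1..K", call. = FALSE)
  }
  counts <- matrix(0L, K, K, dimnames = list(true = 1:K, predicted = 1:K))
  for (i in seq_along(truth)) {
    counts[truth[i], predicted[i]] <- counts[truth[i], predicted[i]] + 1L
  }
  structure(counts, class = c("confusion_matrix", "matrix", "array"))
}

#' Gradient saliency map of one input
#'
#' The weight of each input pixel is the absolute gradient of the
#' target class's pre-softmax score with respect to that pixel,
#' obtained by back-propagation through the trained network (dropout
#' off, batch normalization in inference mode). Large weights mark the
#' pixels the classifier's decision leans on.
#'
#' @param model_ref A CNN `libspec_model` (from [train_staged()]).
#' @param input One spectrum (vector, 1-D models) or one spectral
#'   matrix (n x h matrix, 2-D model).
#' @param target_class Class whose score is differentiated.
#' @return Non-negative weight array with the same shape as `input`.
#' @export
saliency_map <- function(model_ref, input, target_class) {
  if (!inherits(model_ref, "libspec_model") || model_ref$kind != "cnn") {
    stop("saliency needs a differentiable CNN model", call. = FALSE)
  }
  spec <- model_ref$spec
  x <- .as_input_array(input, spec$input_kind)
  fw <- nn_forward(model_ref$net, x, train = FALSE)
  dlog <- matrix(0, 1L, spec$n_classes)
  dlog[1L, target_class] <- 1
  bw <- nn_backward(model_ref$net, fw$caches, dlog)
  g <- abs(bw$dx)
  if (spec$input_kind == "1d") as.numeric(g) else g[1L, , , 1L]
}

#' Origin-averaged saliency with ranked wavelengths
#'
#' Averages the [saliency_map()] of every prediction-set spectrum whose
#' true origin matches, using that origin as the target class, then
#' maps every pixel back to its wavelength through the
#' pixel-to-variable correspondence and ranks wavelengths by weight.
#'
#' @param model_ref A trained 2-D CNN `libspec_model`.
#' @param mset Matrixized prediction set from [matrixize_set()].
#' @param origin Origin class label present in `mset$meta$origin`.
#' @return A `saliency_result`: list with `weights` (n x h matrix),
#'   `origin`, and `ranked_wavelengths` (data frame of wavelength nm
#'   and weight, sorted by decreasing weight).
#' @export
origin_average_saliency <- function(model_ref, mset, origin) {
  idx <- which(mset$meta$origin == origin)
  if (length(idx) == 0L) {
    stop("origin ", origin, " absent from the prediction set", call. = FALSE)
  }
  # per-record gradients are independent, so one batched backward pass
  # yields every record's saliency at once
  spec <- model_ref$spec
  x <- .as_input_array(mset$array[idx, , , drop = FALSE], spec$input_kind)
  fw <- nn_forward(model_ref$net, x, train = FALSE)
  dlog <- matrix(0, length(idx), spec$n_classes)
  dlog[, origin] <- 1
  g <- abs(nn_backward(model_ref$net, fw$caches, dlog)$dx)
  w <- apply(g, c(2L, 3L), mean)
  flat <- as.vector(t(w)) # pixel (r, c) -> variable r*h + c
  wl <- as.numeric(mset$axis)[seq_len(mset$n * mset$h)]
  ord <- order(flat, decreasing = TRUE)
  structure(
    list(weights = w, origin = origin,
         ranked_wavelengths = data.frame(wavelength = wl[ord],
                                         weight = flat[ord],
                                         variable = ord - 1L)),
    class = "saliency_result"
  )
}

#' Two-dimensional t-SNE view of a network layer's features
#'
#' Runs every record through the trained network, captures the
#' activations at the named layer, collapses any spatial dimensions by
#' averaging (keeping channels as features), and embeds the feature
#' vectors in 2-D with t-SNE (PCA initialization to `init_dims`
#' dimensions, Gaussian perplexity `perplexity`).
#'
#' @param model_ref A CNN `libspec_model`.
#' @param data Spectra matrix (1-D models) or spectral-matrix array
#'   (2-D model).
#' @param layer Layer name: the builders name their inspection points
#'   `conv1`, `conv2`, ..., `res1`, ..., `dense1`, `dense2`, `logits`.
#' @param perplexity t-SNE perplexity (default 30; must satisfy
#'   `3 * perplexity < n - 1`).
#' @param init_dims PCA dimensions fed to t-SNE (default 12).
#' @param seed Seed; identical seeds give identical embeddings.
#' @return Matrix with one 2-D coordinate per record.
#' @export
tsne_layer_view <- function(model_ref, data, layer, perplexity = 30,
                            init_dims = 12L, seed = 1L) {
  if (!inherits(model_ref, "libspec_model") || model_ref$kind != "cnn") {
    stop("layer features need a CNN model", call. = FALSE)
  }
  spec <- model_ref$spec
  x <- .as_input_array(data, spec$input_kind)
  fw <- nn_forward(model_ref$net, x, train = FALSE)
  if (!layer %in% names(fw$acts)) {
    stop("unknown layer '", layer, "'; available: ",
         paste(names(fw$acts), collapse = ", "), call. = FALSE)
  }
  a <- fw$acts[[layer]]
  feats <- if (length(dim(a)) == 2L) a
           else if (length(dim(a)) == 3L) apply(a, c(1L, 3L), mean)
           else apply(a, c(1L, 4L), mean)
  feats <- as.matrix(feats)
  with_seed_local(seed, {
    emb <- Rtsne::Rtsne(feats, dims = 2L, perplexity = perplexity,
                        initial_dims = min(init_dims, ncol(feats)),
                        pca = TRUE, check_duplicates = FALSE,
                        max_iter = 500L)
    emb$Y
  })
}
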