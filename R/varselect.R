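#' Construct a variable mask
#'
#' @param kept Logical vector over spectral variables; at least one `TRUE`.
#' @param stage Label describing the selection stage that produced it.
#' @return A `variable_mask`.
#' @export
variable_mask <- function(kept, stage = "manual") {
  kept <- as.logical(kept)
  if (!any(kept)) stop("a variable mask must keep at least one variable",
                       call. = FALSE)
  structure(list(kept = kept, stage = stage), class = "variable_mask")
}

#' @export
print.variable_mask <- function(x, ...) {
  cat(sprintf("<variable_mask> %d / %d variables kept (stage: %s)\n",
              sum(x$kept), length(x$kept), x$stage))
  invisible(x)
}

#' First-stage filter: drop near-zero standard deviation variables
#'
#' Channels that see no emission line carry only detector noise, whose
#' standard deviation across spectra is orders of magnitude below that
#' of signal channels; they contribute nothing to class discrimination.
#' This filter computes the per-variable SD over all spectra and keeps
#' variables above a cutoff chosen by `mode`:
#' \describe{
#'   \item{`knee`}{the point of maximum distance from the chord of the
#'     sorted-SD curve (a maximum-curvature criterion replacing manual
#'     inspection of the sorted curve); variables above that SD are kept.}
#'   \item{`threshold`}{keep variables with SD strictly above `t`.}
#'   \item{`keep_top`}{keep the `K` variables with the largest SD.}
#' }
#'
#' @param set A [spectrum_set()] with at least 2 spectra.
#' @param mode One of `"knee"`, `"threshold"`, `"keep_top"`.
#' @param t SD cutoff for `threshold` mode.
#' @param K Number of variables kept in `keep_top` mode.
#' @return A `variable_mask` with attribute `"sd"` (the per-variable SDs).
#' @export
sd_filter <- function(set, mode = c("knee", "threshold", "keep_top"),
                      t = NULL, K = NULL) {
  stopifnot(inherits(set, "spectrum_set"))
  mode <- match.arg(mode)
  x <- set$intensities
  if (nrow(x) < 2L) stop("need at least 2 spectra to compute SDs", call. = FALSE)
  n <- nrow(x)
  sds <- sqrt(pmax(colSums(x^2) - n * colMeans(x)^2, 0) / (n - 1))
  v <- length(sds)
  kept <- switch(mode,
    knee = {
      if (max(sds) == 0) stop("all variable SDs are zero; knee undefined",
                              call. = FALSE)
      s <- sort(sds)
      u <- (seq_len(v) - 1) / (v - 1)
      w <- (s - s[1L]) / (s[v] - s[1L])
      # distance from the chord (which is the line w = u after scaling)
      knee <- which.max(u - w)
      sds > s[knee]
    },
    threshold = {
      if (is.null(t)) stop("threshold mode needs t", call. = FALSE)
      if (t >= max(sds)) stop("threshold t is at or above the maximum SD; ",
                              "mask would be empty", call. = FALSE)
      sds > t
    },
    keep_top = {
      if (is.null(K)) stop("keep_top mode needs K", call. = FALSE)
      if (K > v) stop(sprintf("K = %d exceeds the %d variables", K, v),
                      call. = FALSE)
      if (K < 1L) stop("K must be >= 1", call. = FALSE)
      keep <- rep(FALSE, v)
      keep[order(sds, decreasing = TRUE)[seq_len(K)]] <- TRUE
      keep
    })
  out <- variable_mask(kept, stage = sprintf("sd_filter(%s)", mode))
  attr(out, "sd") <- sds
  out
}

#' Random-forest permutation importance with per-tree OOB errors
#'
#' Grows a classification forest on the kept variables, then scores each
#' variable as the mean over trees of the increase in that tree's
#' out-of-bag error when the variable's OOB values are randomly permuted
#' (permutation being the standard realization of "adding random noise"
#' to a variable): `Vim = sum_t(OOBerror2_t - OOBerror1_t) / N`.
#'
#' @param set A [spectrum_set()] whose `origin` labels span >= 2 classes.
#' @param mask A `variable_mask` selecting the candidate variables.
#' @param n_trees Number of trees (>= 1).
#' @param seed Seed for both forest growth and the permutations.
#' @return A `vim_scores` object: list with `scores` (one per kept
#'   variable, in mask order), `n_trees`, `oob_accuracy` (of the whole
#'   forest), and `per_tree` (per-tree baseline errors and error
#'   increases, for auditing).
#' @export
vim_scores <- function(set, mask, n_trees, seed = 1L) {
  stopifnot(inherits(set, "spectrum_set"), inherits(mask, "variable_mask"))
  if (n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  y <- droplevels(factor(set$meta$origin))
  if (nlevels(y) < 2L) stop("need at least 2 classes for importance scoring",
                            call. = FALSE)
  x <- set$intensities[, mask$kept, drop = FALSE]
  colnames(x) <- paste0("v", which(mask$kept))
  with_seed_local(seed, {
    rf <- randomForest::randomForest(x, y, ntree = n_trees,
                                     keep.inbag = TRUE, keep.forest = TRUE)
    trees <- lapply(seq_len(n_trees), function(k)
      randomForest::getTree(rf, k, labelVar = FALSE))
    r <- .vim_forest_cpp(trees, x, as.integer(y), rf$inbag)
    scores <- colSums(r$derr, na.rm = TRUE) / n_trees
    structure(list(scores = as.numeric(scores), n_trees = n_trees,
                   oob_accuracy = 1 - as.numeric(rf$err.rate[n_trees, "OOB"]),
                   per_tree = r),
              class = "vim_scores")
  })
}

#' Number of variables removed per elimination round
#'
#' Five percent of the current variables, rounded up:
#' `ceiling(0.05 * n_current)`. Rounding up is the unique convention for
#' which 2016 starting variables leave 325 after 35 rounds and 277 after
#' 38.
#'
#' @param n_current Current number of variables (>= 1).
#' @return Integer count to remove this round.
#' @export
removal_count <- function(n_current) {
  if (any(n_current < 1L)) stop("n_current must be >= 1", call. = FALSE)
  as.integer(ceiling(0.05 * n_current))
}

#' The variables-remaining sequence of the elimination schedule
#'
#' The schedule is data-independent: starting from `n0` variables, each
#' round removes [removal_count()] of them, so
#' `n_{k+1} = n_k - ceiling(0.05 n_k)`, stopping at `max_iter` rounds or
#' when a single variable remains.
#'
#' @param n0 Starting variable count.
#' @param max_iter Maximum number of rounds (default 60).
#' @return Integer vector of length `<= max_iter + 1`: counts after
#'   0, 1, 2, ... rounds.
#' @export
elimination_schedule <- function(n0, max_iter = 60L) {
  n <- as.integer(n0)
  out <- n
  for (k in seq_len(max_iter)) {
    if (n <= 1L) break
    n <- n - removal_count(n)
    out <- c(out, n)
  }
  out
}

#' Second-stage selection: iterative importance-based elimination
#'
#' Starting from the first-stage mask, each iteration (i) picks the tree
#' count in `tree_range` (grid step 10) maximizing the forest's OOB
#' accuracy on the current variables, (ii) scores the variables with
#' [vim_scores()] using that forest size, and (iii) removes the
#' [removal_count()] lowest-scoring variables (ties removed from the
#' largest variable index down). The process runs for `max_iter` rounds
#' or until one variable remains. The returned best iteration is the one
#' whose recorded OOB accuracy is highest (earliest on ties), and the
#' final mask is the variable set at that iteration.
#'
#' @param set A [spectrum_set()] (typically the calibration subset).
#' @param initial_mask A `variable_mask` from [sd_filter()].
#' @param max_iter Maximum elimination rounds (default 60).
#' @param tree_range Two-element range of tree counts (default `c(50, 110)`).
#' @param seed Seed covering all forests and permutations.
#' @return A `selection_result`: list with `final_mask`,
#'   `best_iteration`, `trace` (data frame: iteration, n_vars, n_trees,
#'   oob_accuracy), and `kept_by_iteration` (list of variable-index
#'   vectors).
#' @export
iterative_elimination <- function(set, initial_mask, max_iter = 60L,
                                  tree_range = c(50L, 110L), seed = 1L) {
  stopifnot(inherits(set, "spectrum_set"), inherits(initial_mask, "variable_mask"))
  y <- droplevels(factor(set$meta$origin))
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  grid <- seq(tree_range[1L], tree_range[2L], by = 10L)
  v <- length(initial_mask$kept)
  kept_idx <- which(initial_mask$kept)
  trace <- list(); kept_by_iter <- list()

  with_seed_local(seed, {
    for (k in 0:max_iter) {
      x <- set$intensities[, kept_idx, drop = FALSE]
      colnames(x) <- paste0("v", kept_idx)
      # tree-count optimization by OOB accuracy over the grid
      accs <- vapply(grid, function(nt) {
        rf <- randomForest::randomForest(x, y, ntree = nt)
        1 - as.numeric(rf$err.rate[nt, "OOB"])
      }, numeric(1))
      best_nt <- grid[which.max(accs)] # which.max ties -> smallest count
      rf <- randomForest::randomForest(x, y, ntree = best_nt,
                                       keep.inbag = TRUE, keep.forest = TRUE)
      acc <- 1 - as.numeric(rf$err.rate[best_nt, "OOB"])
      trace[[k + 1L]] <- data.frame(iteration = k,
                                    n_vars = length(kept_idx),
                                    n_trees = best_nt,
                                    oob_accuracy = acc)
      kept_by_iter[[k + 1L]] <- kept_idx
      if (k == max_iter || length(kept_idx) <= 1L) break
      trees <- lapply(seq_len(best_nt), function(tt)
        randomForest::getTree(rf, tt, labelVar = FALSE))
      r <- .vim_forest_cpp(trees, x, as.integer(y), rf$inbag)
      scores <- colSums(r$derr, na.rm = TRUE) / best_nt
      n_drop <- removal_count(length(kept_idx))
      # lowest score first; on equal scores drop the larger variable index
      ord <- order(scores, -kept_idx)
      kept_idx <- sort(kept_idx[-ord[seq_len(n_drop)]])
      if (length(kept_idx) == 0L) { # n_drop == n only when n == 1
        kept_idx <- integer(0); break
      }
    }
  })
  trace <- do.call(rbind, trace)
  best_k <- trace$iteration[which.max(trace$oob_accuracy)]
  final_kept <- rep(FALSE, v)
  final_kept[kept_by_iter[[best_k + 1L]]] <- TRUE
  structure(
    list(final_mask = variable_mask(final_kept,
                                    stage = sprintf("vim_elimination(iter %d)",
                                                    best_k)),
         best_iteration = best_k,
         trace = trace,
         kept_by_iteration = kept_by_iter),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d iterations; best iteration %d (OOB %.3f), %d variables kept\n",
              max(x$trace$iteration), x$best_iteration,
              max(x$trace$oob_accuracy), sum(x$final_mask$kept)))
  invisible(x)
}
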