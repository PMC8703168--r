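#' Default end-to-end run configuration
#'
#' A fully resolved configuration for [run_pipeline()], defaulting to a
#' simulated desk-scale dataset ([fixture_generator_config()]), the
#' spectral-matrix path with the 2-D CNN at segment length `h = 150`,
#' and the standard staged schedule. Any field can be overridden before
#' validation; [validate_config()] reports problems without raising.
#'
#' @param output_dir Directory for the run report and artifacts.
#' @return A `run_config` list.
#' @export
default_run_config <- function(output_dir = tempfile("libspec_run_")) {
  structure(list(
    input = NULL, axis = NULL,              # file paths; NULL -> simulate
    simulate = TRUE,
    part = "underground",
    stratify_split = TRUE, # reduced designs need every class in calibration
    output_dir = output_dir,
    preprocess = list(denoise = FALSE, wavelet = NULL), # NULL -> auto search
    selection = list(mode = "knee", max_iter = 60L, tree_range = c(50L, 110L)),
    h = 150L,
    model = "cnn2d",
    schedule = list(learning_rates = c(0.1, 0.05, 0.01, 0.005),
                    thresholds = c(0.6, 0.75, 0.92, 0.96),
                    batch_size = 32L),
    seeds = list(simulation = 1L, split = 1L, selection = 1L, training = 1L),
    report = list(saliency = FALSE, tsne = FALSE)
  ), class = "run_config")
}

.known_models <- c("cnn1d_1", "cnn1d_2", "cnn2d", "lda", "knn", "svm")

#' Validate a run configuration
#'
#' Checks the configuration without running anything. Problems are
#' returned, not raised; an empty result means the configuration is
#' runnable.
#'
#' @param config A `run_config`.
#' @return Character vector of problems, each naming the offending
#'   field; `character(0)` when valid.
#' @export
validate_config <- function(config) {
  problems <- character()
  add <- function(p) problems <<- c(problems, p)
  if (!isTRUE(config$simulate)) {
    if (is.null(config$input) || !file.exists(config$input)) {
      add("input: spectra file missing or not found")
    }
    if (is.null(config$axis) || !file.exists(config$axis)) {
      add("axis: wavelength axis file missing or not found")
    }
  }
  if (!is.numeric(config$h) || length(config$h) != 1L || config$h < 1) {
    add("h: segment length must be a single integer >= 1")
  }
  if (!config$model %in% .known_models) {
    add(sprintf("model: unknown model '%s' (known: %s)", config$model,
                paste(.known_models, collapse = ", ")))
  }
  s <- config$schedule
  if (!is.null(s)) {
    if (length(s$learning_rates) != length(s$thresholds)) {
      add("schedule: need one threshold per learning rate")
    } else {
      if (any(diff(s$learning_rates) >= 0)) {
        add("schedule: learning rates must be strictly decreasing")
      }
      if (any(diff(s$thresholds) <= 0)) {
        add("schedule: thresholds must be strictly increasing")
      }
      if (any(s$thresholds <= 0 | s$thresholds > 1)) {
        add("schedule: thresholds must lie in (0, 1]")
      }
    }
  }
  for (nm in names(config$seeds)) {
    if (!is.numeric(config$seeds[[nm]])) {
      add(sprintf("seeds: %s seed must be an integer", nm))
    }
  }
  if (!config$part %in% .valid_parts) {
    add("part: must be 'underground' or 'aerial'")
  }
  problems
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_run_config()]; missing fields keep their default, so the
#' emitted report always contains a fully resolved configuration.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  user <- yaml::read_yaml(path)
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (sub in names(user[[nm]])) cfg[[nm]][[sub]] <- user[[nm]][[sub]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

#' Run the full classification pipeline
#'
#' Executes one of the two analysis paths on a loaded or simulated
#' dataset: the variable-selection path (preprocess, near-zero-SD
#' filter, iterative importance elimination, then a 1-D CNN or a
#' classical baseline on the selected variables) or the spectral-matrix
#' path (preprocess, segment-and-recombine to n x h matrices, 2-D CNN).
#' Both end with prediction-set evaluation. A JSON report with all
#' resolved parameters, stage timings and accuracies is written to
#' `output_dir`, and the full result is returned invisibly.
#'
#' @param config A `run_config`; see [default_run_config()].
#' @return Invisibly, a list with the trained model, masks/matrices,
#'   accuracies, confusion matrix and the report.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  t_all <- proc.time()[3]
  timings <- list()
  tick <- function(stage, t0) timings[[stage]] <<- round(proc.time()[3] - t0, 3)
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  t0 <- proc.time()[3]
  set <- in_stage("load", if (isTRUE(config$simulate)) {
    generate_dataset(fixture_generator_config(seed = config$seeds$simulation))
  } else {
    read_spectra(config$input, config$axis)
  })
  if (config$part %in% set$meta$part) set <- filter_part(set, config$part)
  tick("load", t0)

  t0 <- proc.time()[3]
  split <- split_by_tablet(set, seed = config$seeds$split,
                           stratify = isTRUE(config$stratify_split))
  cal <- split_subset(set, split, "calibration")
  val <- split_subset(set, split, "validation")
  pred <- split_subset(set, split, "prediction")
  tick("split", t0)

  t0 <- proc.time()[3]
  in_stage("preprocess", {
    params <- NULL
    if (isTRUE(config$preprocess$denoise)) {
      params <- if (!is.null(config$preprocess$wavelet)) {
        wavelet_params(config$preprocess$wavelet[1], config$preprocess$wavelet[2])
      } else optimize_wavelet(cal)
    }
    cal <- preprocess_set(cal, params, denoise = isTRUE(config$preprocess$denoise))
    val <- preprocess_set(val, params, denoise = isTRUE(config$preprocess$denoise))
    pred <- preprocess_set(pred, params, denoise = isTRUE(config$preprocess$denoise))
  })
  tick("preprocess", t0)

  schedule <- train_schedule(config$schedule$learning_rates,
                             config$schedule$thresholds,
                             batch_size = config$schedule$batch_size,
                             seed = config$seeds$training)
  n_classes <- max(set$meta$origin)
  out <- list(config = config, split = split)

  if (config$model == "cnn2d") { # spectral-matrix path
    t0 <- proc.time()[3]
    mc <- matrixize_set(cal, config$h)
    mv <- matrixize_set(val, config$h)
    mp <- matrixize_set(pred, config$h)
    tick("matrixize", t0)
    t0 <- proc.time()[3]
    spec <- build_cnn2d(c(mc$n, mc$h), n_classes)
    tr <- in_stage("train",
                   train_staged(spec, list(x = mc$array, y = mc$meta$origin),
                                list(x = mv$array, y = mv$meta$origin),
                                schedule))
    tick("train", t0)
    pr <- predict(tr$model_ref, mp$array)
    out$train_result <- tr
    out$matrix_info <- mc[c("n", "h", "discarded")]
    out$prediction_mset <- mp # matrixized prediction set, for saliency
    out$prediction_meta <- mp$meta
    if (isTRUE(config$report$saliency)) {
      out$saliency <- lapply(sort(unique(mp$meta$origin)), function(o)
        origin_average_saliency(tr$model_ref, mp, o))
    }
    truth <- mp$meta$origin
  } else { # variable-selection path
    t0 <- proc.time()[3]
    mask1 <- in_stage("sd_filter",
                      sd_filter(cal, mode = config$selection$mode,
                                t = config$selection$t, K = config$selection$K))
    sel <- in_stage("elimination",
                    iterative_elimination(cal, mask1,
                                          max_iter = config$selection$max_iter,
                                          tree_range = config$selection$tree_range,
                                          seed = config$seeds$selection))
    tick("select", t0)
    keep <- sel$final_mask$kept
    out$sd_mask <- mask1; out$selection <- sel
    xc <- cal$intensities[, keep, drop = FALSE]
    xv <- val$intensities[, keep, drop = FALSE]
    xp <- pred$intensities[, keep, drop = FALSE]
    t0 <- proc.time()[3]
    model <- if (config$model %in% c("cnn1d_1", "cnn1d_2")) {
      spec <- if (config$model == "cnn1d_1") {
        build_cnn1d_1(ncol(xc), n_classes)
      } else build_cnn1d_2(ncol(xc), n_classes)
      tr <- train_staged(spec, list(x = xc, y = cal$meta$origin),
                         list(x = xv, y = val$meta$origin), schedule)
      out$train_result <- tr
      tr$model_ref
    } else {
      fit_baseline(config$model, list(x = xc, y = cal$meta$origin),
                   list(x = xv, y = val$meta$origin),
                   search = list(seed = config$seeds$training))
    }
    tick("train", t0)
    pr <- predict(model, xp)
    out$model <- model
    out$prediction_meta <- pred$meta
    truth <- pred$meta$origin
  }

  out$prediction_accuracy <- accuracy(truth, pr$labels)
  out$confusion <- confusion(truth, pr$labels, n_classes)
  timings[["total"]] <- round(proc.time()[3] - t_all, 3)
  out$timings <- timings

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  # content hash of the analyzed set, for bit-level rerun comparison
  tmp <- tempfile()
  writeBin(serialize(list(set$intensities, set$meta), NULL), tmp)
  data_md5 <- unname(tools::md5sum(tmp))
  unlink(tmp)
  report <- list(
    model = config$model, h = config$h, part = config$part,
    seeds = config$seeds,
    data_md5 = data_md5,
    n_spectra = n_spectra(set),
    n_tablets = length(unique(set$meta$tablet_id)),
    split_tablets = lapply(split[c("calibration", "validation", "prediction")],
                           length),
    selected_variables = if (!is.null(out$selection))
      which(out$selection$final_mask$kept) else NULL,
    prediction_accuracy = round_half_up(out$prediction_accuracy),
    confusion = unclass(out$confusion),
    timings = timings
  )
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$report <- report
  invisible(out)
}
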