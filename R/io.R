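#' Read a spectra table and wavelength axis from disk
#'
#' The interchange format is a plain CSV/TSV table with the metadata
#' columns `origin,plant_id,tablet_id,part,position` followed by the
#' intensity columns `v1..vV`, plus a one-column axis file of wavelengths
#' in nm. If a provenance sidecar `<path>.json` exists (written by
#' [write_spectra()]), its log is restored.
#'
#' @param path Path to the spectra CSV/TSV (delimiter auto-detected).
#' @param axis_path Path to the one-column wavelength axis file.
#' @return A [spectrum_set()], row order preserved.
#' @export
read_spectra <- function(path, axis_path) {
  if (!file.exists(path)) stop("spectra file not found: ", path, call. = FALSE)
  if (!file.exists(axis_path)) stop("axis file not found: ", axis_path, call. = FALSE)
  axis_dt <- data.table::fread(axis_path, header = TRUE)
  axis <- wavelength_axis(axis_dt[[1L]])
  v <- length(axis)
  dt <- data.table::fread(path, header = TRUE, fill = TRUE)
  missing_cols <- setdiff(.meta_cols, names(dt))
  if (length(missing_cols)) {
    stop("spectra file lacks metadata column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  int_cols <- setdiff(names(dt), .meta_cols)
  if (length(int_cols) != v) {
    stop(sprintf("spectra file has %d intensity columns but axis has %d values",
                 length(int_cols), v), call. = FALSE)
  }
  if (nrow(dt) == 0L) {
    return(spectrum_set(matrix(numeric(0), 0L, v),
                        dt[, .meta_cols, with = FALSE], axis))
  }
  intens <- as.matrix(dt[, int_cols, with = FALSE])
  bad_rows <- which(rowSums(is.na(intens)) > 0L)
  if (length(bad_rows)) {
    stop(sprintf("row %d has missing or non-numeric intensities (expected %d values)",
                 bad_rows[1L], v), call. = FALSE)
  }
  set <- spectrum_set(intens, dt[, .meta_cols, with = FALSE], axis)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    log <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(log$provenance)) set$provenance <- as.character(log$provenance)
  }
  set
}

#' Write a spectra table, axis file, and provenance sidecar
#'
#' Inverse of [read_spectra()]: numbers are serialized at full double
#' precision so that a write/read round trip reproduces the set exactly.
#' The provenance log is stored in a JSON sidecar `<path>.json`.
#'
#' @param set A [spectrum_set()].
#' @param path Output path for the spectra CSV.
#' @param axis_path Output path for the axis CSV; defaults to
#'   `<path base>_axis.csv` next to `path`.
#' @return Invisibly, `path`.
#' @export
write_spectra <- function(set, path,
                          axis_path = sub("(\\.[^.]*)?$", "_axis.csv",
                                          path)[1L]) {
  stopifnot(inherits(set, "spectrum_set"))
  v <- length(set$axis)
  dt <- data.table::data.table(set$meta)
  if (nrow(dt) == 0L && ncol(set$intensities) > 0L) {
    # header-only file still needs the intensity column names
    empty <- data.table::as.data.table(
      matrix(numeric(0), 0L, v, dimnames = list(NULL, paste0("v", seq_len(v)))))
    dt <- cbind(dt, empty)
  } else {
    im <- set$intensities
    colnames(im) <- paste0("v", seq_len(v))
    dt <- cbind(dt, data.table::as.data.table(im))
  }
  ok <- tryCatch({
    data.table::fwrite(dt, path)
    data.table::fwrite(data.table::data.table(wavelength_nm = as.numeric(set$axis)),
                       axis_path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write spectra to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  jsonlite::write_json(list(provenance = set$provenance),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' Split a spectra collection into calibration/validation/prediction sets
#'
#' The splitting unit is the pressed tablet, never the individual
#' spectrum: all 16 (or however many) ablation positions of one tablet
#' land in the same subset, so no sample leaks between training and
#' evaluation. With `T` tablets and ratio `(r1, r2, r3)`, the
#' validation and prediction sets get `round(T * r2 / sum(r))` and
#' `round(T * r3 / sum(r))` tablets and calibration takes the remainder
#' (118 tablets at 3:1:1 gives 70/24/24, i.e. 1120/384/384 spectra at 16
#' positions per tablet). Assignment is a seeded uniform permutation of
#' the tablet identifiers.
#'
#' @param set A [spectrum_set()] with at least 5 tablets.
#' @param ratio Numeric triple of positive weights, default `c(3, 1, 1)`.
#' @param seed Integer seed controlling the permutation.
#' @param stratify If `TRUE`, every origin class is guaranteed at least
#'   one calibration tablet before the validation/prediction quotas are
#'   filled. Subset sizes are unchanged. Intended for heavily reduced
#'   designs (few tablets per class), where a plain random split can
#'   drop a class from calibration entirely; with many tablets per
#'   class it coincides with the plain split in distribution.
#' @return A `dataset_split`: list with character vectors `calibration`,
#'   `validation`, `prediction` of tablet ids, plus the `ratio` used.
#' @export
split_by_tablet <- function(set, ratio = c(3, 1, 1), seed = 1L,
                            stratify = FALSE) {
  stopifnot(inherits(set, "spectrum_set"))
  if (length(ratio) != 3L || any(ratio <= 0)) {
    stop("ratio must be three positive numbers", call. = FALSE)
  }
  tablets <- unique(set$meta$tablet_id)
  n_t <- length(tablets)
  if (n_t < 5L) stop("need at least 5 tablets to split, got ", n_t, call. = FALSE)
  n_val <- round(n_t * ratio[2L] / sum(ratio))
  n_pred <- round(n_t * ratio[3L] / sum(ratio))
  n_cal <- n_t - n_val - n_pred
  if (min(n_cal, n_val, n_pred) < 1L) {
    stop("ratio leaves an empty subset for ", n_t, " tablets", call. = FALSE)
  }
  shuffled <- with_seed_local(seed, {
    if (stratify) {
      origin_of <- set$meta$origin[match(tablets, set$meta$tablet_id)]
      anchors <- vapply(split(tablets, origin_of), function(tt)
        tt[sample.int(length(tt), 1L)], character(1))
      if (length(anchors) > n_cal) {
        stop("stratified split needs at least one calibration tablet per class",
             call. = FALSE)
      }
      rest <- sample(setdiff(tablets, anchors))
      extra <- n_cal - length(anchors)
      # anchors stay in the calibration block; the rest fill the quotas
      c(sample(anchors), utils::head(rest, extra),
        utils::tail(rest, length(rest) - extra))
    } else {
      tablets[sample.int(n_t)]
    }
  })
  structure(
    list(calibration = shuffled[seq_len(n_cal)],
         validation = shuffled[n_cal + seq_len(n_val)],
         prediction = shuffled[n_cal + n_val + seq_len(n_pred)],
         ratio = ratio),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> ratio %s | tablets cal/val/pred: %d/%d/%d\n",
              paste(x$ratio, collapse = ":"),
              length(x$calibration), length(x$validation), length(x$prediction)))
  invisible(x)
}

#' Extract the records of one split subset
#'
#' @param set The [spectrum_set()] that was split.
#' @param split A `dataset_split` from [split_by_tablet()].
#' @param which One of `"calibration"`, `"validation"`, `"prediction"`.
#' @return A [spectrum_set()] restricted to that subset's tablets.
#' @export
split_subset <- function(set, split, which = c("calibration", "validation",
                                               "prediction")) {
  which <- match.arg(which)
  subset_records(set, set$meta$tablet_id %in% split[[which]])
}

# Run an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards (no hidden global side effects).
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
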