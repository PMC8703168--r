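#' Construct a wavelength axis
#'
#' A wavelength axis is the shared abscissa of every spectrum in a
#' [spectrum_set()]: a strictly increasing vector of wavelengths in
#' nanometres, one per spectral variable.
#'
#' @param values Numeric vector of wavelengths in nm, strictly increasing,
#'   all within \[100, 1000\] nm.
#' @return A numeric vector of class `wavelength_axis`.
#' @examples
#' ax <- wavelength_axis(seq(229, 878, length.out = 100))
#' @export
wavelength_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    stop("wavelength axis must contain at least one value", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("wavelength axis values must be finite", call. = FALSE)
  }
  if (any(diff(values) <= 0)) {
    stop("wavelength axis must be strictly increasing", call. = FALSE)
  }
  if (min(values) < 100 || max(values) > 1000) {
    stop("wavelength axis values must lie within [100, 1000] nm", call. = FALSE)
  }
  structure(values, class = "wavelength_axis")
}

#' Metadata columns every spectra table carries
#' @keywords internal
.meta_cols <- c("origin", "plant_id", "tablet_id", "part", "position")

.valid_parts <- c("underground", "aerial")

#' Construct a spectra collection
#'
#' A `spectrum_set` bundles an intensity matrix (one row per recorded
#' spectrum), per-spectrum metadata reflecting the sampling hierarchy
#' (origin class, plant, pressed tablet, plant part, ablation position on
#' the tablet), a shared [wavelength_axis()], and a free-text provenance
#' log of the transforms applied so far.
#'
#' @param intensities Numeric matrix, spectra in rows, variables in columns.
#' @param meta Data frame with columns `origin` (integer class label in
#'   1..12), `plant_id`, `tablet_id`, `part` (`"underground"` or
#'   `"aerial"`), `position` (integer ablation position).
#' @param axis A [wavelength_axis()] whose length equals `ncol(intensities)`.
#' @param provenance Character vector of applied-transform descriptions.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(intensities, meta, axis, provenance = character()) {
  if (!is.matrix(intensities)) intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (!inherits(axis, "wavelength_axis")) axis <- wavelength_axis(axis)
  if (ncol(intensities) != length(axis)) {
    stop(sprintf("intensity matrix has %d variables but axis has %d",
                 ncol(intensities), length(axis)), call. = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.meta_cols, names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(meta) != nrow(intensities)) {
    stop("metadata rows must match intensity rows", call. = FALSE)
  }
  meta$origin <- as.integer(meta$origin)
  meta$position <- as.integer(meta$position)
  meta$plant_id <- as.character(meta$plant_id)
  meta$tablet_id <- as.character(meta$tablet_id)
  meta$part <- as.character(meta$part)
  if (nrow(meta) > 0L) {
    if (anyNA(meta$origin) || any(meta$origin < 1L) || any(meta$origin > 12L)) {
      stop("origin labels must be integers in 1..12", call. = FALSE)
    }
    bad_part <- setdiff(unique(meta$part), .valid_parts)
    if (length(bad_part)) {
      stop("unknown part label(s): ", paste(bad_part, collapse = ", "),
           "; expected one of ", paste(.valid_parts, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(intensities = intensities, meta = meta, axis = axis,
         provenance = as.character(provenance)),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d variables (%.2f-%.2f nm)\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$axis), max(x$axis)))
  if (nrow(x$meta) > 0L) {
    cat(sprintf("  origins: %s | tablets: %d | parts: %s\n",
                paste(sort(unique(x$meta$origin)), collapse = ","),
                length(unique(x$meta$tablet_id)),
                paste(sort(unique(x$meta$part)), collapse = ",")))
  }
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Number of spectra in a set
#' @param set A [spectrum_set()].
#' @return Integer count of spectra.
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' Subset a spectrum set by record index
#'
#' @param set A [spectrum_set()].
#' @param idx Integer or logical index over spectra (rows).
#' @return A [spectrum_set()] with the selected records; axis and
#'   provenance are carried over.
#' @export
subset_records <- function(set, idx) {
  out <- spectrum_set(set$intensities[idx, , drop = FALSE],
                      set$meta[idx, , drop = FALSE],
                      set$axis, set$provenance)
  attr(out, "generator_truth") <- attr(set, "generator_truth")
  out
}

#' Restrict a spectrum set to one plant part
#'
#' Underground (root) and aerial tissues give systematically different
#' emission spectra, so the pipeline analyses them as separate sets.
#'
#' @param set A [spectrum_set()].
#' @param part `"underground"` or `"aerial"`.
#' @return A [spectrum_set()] with only that part's records.
#' @export
filter_part <- function(set, part) {
  part <- match.arg(part, .valid_parts)
  subset_records(set, set$meta$part == part)
}

#' Append a provenance entry
#' @keywords internal
add_provenance <- function(set, entry) {
  set$provenance <- c(set$provenance, entry)
  set
}
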