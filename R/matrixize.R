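#' Recombine a spectrum into an n x h spectral matrix
#'
#' Cuts the intensity vector into consecutive segments of `h` variables
#' and stacks them as rows: row `i` (0-based) holds variables
#' `[i*h, (i+1)*h)`. With `V` variables the matrix has `n = floor(V/h)`
#' rows; the trailing `V - n*h` variables cannot fill a row and are
#' discarded (their count is recorded, and a warning names the dropped
#' wavelength range when an axis is supplied). The resulting image-like
#' array is the input representation for the 2-D convolutional
#' classifier, with an exact pixel-to-variable correspondence via
#' [pixel_to_variable()].
#'
#' @param spectrum Numeric intensity vector of length `V >= h`.
#' @param h Segment length (matrix width), `>= 1`.
#' @param axis Optional [wavelength_axis()] used only to report the
#'   discarded wavelength range.
#' @return A `spectral_matrix`: list with `values` (n x h matrix), `h`,
#'   `n`, `discarded`, `source_length`.
#' @examples
#' m <- to_matrix(1:6, 3)   # 2 x 3, no variables discarded
#' @export
to_matrix <- function(spectrum, h, axis = NULL) {
  h <- as.integer(h)
  v <- length(spectrum)
  if (h < 1L) stop("segment length h must be >= 1", call. = FALSE)
  if (h > v) stop(sprintf("segment length h = %d exceeds spectrum length %d",
                          h, v), call. = FALSE)
  n <- v %/% h
  discarded <- v - n * h
  if (discarded > 0L && !is.null(axis)) {
    warning(sprintf("discarding %d trailing variables (%.2f-%.2f nm)",
                    discarded, axis[n * h + 1L], axis[v]), call. = FALSE)
  }
  structure(
    list(values = matrix(spectrum[seq_len(n * h)], nrow = n, ncol = h,
                         byrow = TRUE),
         h = h, n = n, discarded = discarded, source_length = v),
    class = "spectral_matrix"
  )
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("<spectral_matrix> %d x %d (h = %d) from %d variables, %d discarded\n",
              x$n, x$h, x$h, x$source_length, x$discarded))
  invisible(x)
}

#' Flatten a spectral matrix back to a spectrum
#'
#' Inverse of [to_matrix()] on the retained prefix: returns the `n*h`
#' variables in their original order. `from_matrix(to_matrix(x, h))`
#' equals `x[1:(n*h)]` exactly.
#'
#' @param matrix A `spectral_matrix`.
#' @return Numeric vector of length `n * h`.
#' @export
from_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "spectral_matrix"))
  as.vector(t(matrix$values))
}

#' Map a matrix pixel to its spectral variable index
#'
#' Row-major, 0-based: pixel `(row, col)` of a width-`h` spectral matrix
#' came from variable `row * h + col`. Composing with the wavelength
#' axis gives the wavelength a pixel represents, which is how saliency
#' weights are read back as wavelengths.
#'
#' @param row,col 0-based pixel coordinates; `0 <= col < h`.
#' @param h Segment length of the matrix.
#' @return 0-based variable index.
#' @export
pixel_to_variable <- function(row, col, h) {
  if (any(col < 0L) || any(col >= h)) {
    stop("column index out of range [0, h)", call. = FALSE)
  }
  if (any(row < 0L)) stop("row index must be non-negative", call. = FALSE)
  as.integer(row) * as.integer(h) + as.integer(col)
}

#' Map a spectral variable index to its matrix pixel
#'
#' Inverse of [pixel_to_variable()].
#'
#' @param variable 0-based variable index.
#' @param h Segment length of the matrix.
#' @return Integer matrix with columns `row`, `col` (0-based).
#' @export
variable_to_pixel <- function(variable, h) {
  variable <- as.integer(variable); h <- as.integer(h)
  if (any(variable < 0L)) stop("variable index must be non-negative",
                               call. = FALSE)
  cbind(row = variable %/% h, col = variable %% h)
}

#' Stack a whole spectrum set into spectral matrices
#'
#' @param set A [spectrum_set()].
#' @param h Segment length.
#' @return List with `array` (spectra x n x h), `h`, `n`, `discarded`,
#'   and the labels/metadata carried over.
#' @export
matrixize_set <- function(set, h) {
  stopifnot(inherits(set, "spectrum_set"))
  v <- ncol(set$intensities)
  proto <- to_matrix(set$intensities[1L, ], h)
  arr <- array(0, dim = c(n_spectra(set), proto$n, proto$h))
  for (i in seq_len(n_spectra(set))) {
    arr[i, , ] <- to_matrix(set$intensities[i, ], h)$values
  }
  list(array = arr, h = proto$h, n = proto$n, discarded = proto$discarded,
       source_length = v, meta = set$meta, axis = set$axis)
}
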