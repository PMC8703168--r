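# Daubechies scaling (low-pass decomposition) filters, orders 3-10.
# These are the standard orthogonal filter-bank constants; the quadrature
# high-pass and the reconstruction filters are derived from them below.
.db_filters <- list(
  "3" = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
      0.45987750211849154, 0.8068915093110925, 0.33267055295008263),
  "4" = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
      -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
      0.7148465705529157, 0.2303778133088965),
  "5" = c(0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
      0.07757149384004572, -0.032244869584638375, -0.24229488706638203,
      0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
      0.16010239797419293),
  "6" = c(-0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
      -0.03158203931748603, 0.027522865530305727, 0.09750160558732304,
      -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
      0.7511339080210954, 0.49462389039845306, 0.11154074335010947),
  "7" = c(0.00035371379997452024, -0.0018016407040474908, 0.0004295779729213665,
      0.01255099855609984, -0.01657454163066688, -0.03802993693501441,
      0.08061260915108308, 0.07130921926683026, -0.22403618499387498,
      -0.14390600392856498, 0.4697822874051931, 0.7291320908462351,
      0.3965393194819173, 0.07785205408500918),
  "8" = c(-0.00011747678412476953, 0.0006754494064505693, -0.00039174037337694705,
      -0.004870352993451574, 0.008746094047405777, 0.013981027917398282,
      -0.044088253930794755, -0.017369301001807547, 0.12874742662047847,
      0.0004724845739132828, -0.2840155429615469, -0.015829105256349306,
      0.5853546836542067, 0.6756307362972898, 0.31287159091429995,
      0.05441584224310401),
  "9" = c(3.93473203162716e-05, -0.0002519631889427101, 0.00023038576352319597,
      0.0018476468830562265, -0.00428150368246343, -0.004723204757751397,
      0.022361662123679096, 0.00025094711483145197, -0.06763282906132997,
      0.03072568147933338, 0.14854074933810638, -0.09684078322297646,
      -0.2932737832791749, 0.13319738582500756, 0.6572880780513005,
      0.6048231236901112, 0.24383467461259034, 0.038077947363878345),
  "10" = c(-1.3264202894521244e-05, 9.358867032006959e-05, -0.00011646685512928545,
      -0.0006858566949597116, 0.001992405295185056, 0.001395351747052901,
      -0.010733175483330575, 0.0036065535669561697, 0.033212674059341,
      -0.029457536821875813, -0.07139414716639708, 0.09305736460357235,
      0.12736934033579325, -0.19594627437737705, -0.24984642432731538,
      0.2811723436605775, 0.6884590394536035, 0.5272011889317256,
      0.1881768000776915, 0.026670057900555554)
)

.db_bank <- function(order) {
  lo <- .db_filters[[as.character(order)]]
  if (is.null(lo)) stop("Daubechies order must be in 3..10, got ", order,
                        call. = FALSE)
  flen <- length(lo)
  k <- seq_len(flen)
  list(dec_lo = lo,
       dec_hi = rev(lo) * (-1)^k,
       rec_lo = rev(lo),
       rec_hi = lo * (-1)^(k - 1),
       flen = flen)
}

# half-point symmetric extension by n samples on each side; reflections
# repeat when n exceeds the signal length (short coarse levels)
.symext <- function(x, n) {
  lx <- length(x)
  idx <- seq(-n + 1L, lx + n)
  period <- 2L * lx
  m <- ((idx - 1L) %% period + period) %% period # 0 .. 2*lx - 1
  sel <- ifelse(m < lx, m + 1L, 2L * lx - m)
  x[sel]
}

.conv_valid <- function(s, f) {
  # valid-mode convolution (filter flipped), via stats::filter for speed
  out <- stats::filter(s, f, method = "convolution", sides = 1)
  out[length(f):length(s)]
}

# one analysis level: returns approximation and detail coefficients,
# each of length floor((n + flen - 1) / 2)
.dwt_level <- function(x, bank) {
  ext <- .symext(x, bank$flen - 1L)
  af <- .conv_valid(ext, bank$dec_lo)
  df <- .conv_valid(ext, bank$dec_hi)
  idx <- seq(2L, length(af), 2L)
  list(a = af[idx], d = df[idx])
}

# one synthesis level, truncated to target length n
.idwt_level <- function(a, d, bank, n) {
  up <- function(v) { u <- numeric(2L * length(v)); u[seq(1L, length(u), 2L)] <- v; u }
  fullconv <- function(s, f) {
    # full convolution of s with f
    stats::convolve(s, rev(f), type = "open")
  }
  y <- fullconv(up(a), bank$rec_lo) + fullconv(up(d), bank$rec_hi)
  t0 <- bank$flen - 2L
  y[(t0 + 1L):(t0 + n)]
}

# multi-level analysis: list(a = coarsest approximation, d = list of
# detail vectors finest-to-coarsest, lengths = per-level input lengths)
.wavedec <- function(x, bank, level) {
  details <- vector("list", level)
  lengths <- integer(level)
  a <- x
  for (l in seq_len(level)) {
    lengths[l] <- length(a)
    r <- .dwt_level(a, bank)
    details[[l]] <- r$d
    a <- r$a
  }
  list(a = a, d = details, lengths = lengths)
}

.waverec <- function(dec, bank) {
  a <- dec$a
  for (l in rev(seq_along(dec$d))) {
    a <- .idwt_level(a, dec$d[[l]], bank, dec$lengths[l])
  }
  a
}

#' Wavelet parameters for denoising
#'
#' @param family_order Daubechies order, in 3..10.
#' @param level Decomposition level, in 3..10.
#' @return A `wavelet_params` list.
#' @export
wavelet_params <- function(family_order, level) {
  family_order <- as.integer(family_order); level <- as.integer(level)
  if (family_order < 3L || family_order > 10L) {
    stop("Daubechies order must be within [3, 10]", call. = FALSE)
  }
  if (level < 3L || level > 10L) {
    stop("decomposition level must be within [3, 10]", call. = FALSE)
  }
  structure(list(family_order = family_order, level = level),
            class = "wavelet_params")
}

#' Denoise a spectrum by wavelet soft thresholding
#'
#' Multi-level Daubechies decomposition with half-point symmetric
#' boundary extension, soft thresholding of every detail band at the
#' universal threshold `sigma * sqrt(2 log n)` (noise scale `sigma`
#' estimated as `median(|finest detail|) / 0.6745`), and reconstruction.
#' Output length equals input length.
#'
#' @param spectrum Numeric intensity vector of length at least `2^level`.
#' @param params A [wavelet_params()].
#' @return Denoised vector, same length as the input.
#' @export
wavelet_denoise <- function(spectrum, params) {
  stopifnot(inherits(params, "wavelet_params"))
  n <- length(spectrum)
  if (n < 2^params$level) {
    stop(sprintf("spectrum of length %d is too short for level %d (needs >= %d)",
                 n, params$level, 2^params$level), call. = FALSE)
  }
  bank <- .db_bank(params$family_order)
  dec <- .wavedec(as.numeric(spectrum), bank, params$level)
  sigma <- stats::median(abs(dec$d[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(n))
  if (thr > 0) {
    dec$d <- lapply(dec$d, function(d) sign(d) * pmax(abs(d) - thr, 0))
  }
  .waverec(dec, bank)
}

#' Signal-to-noise ratio of a denoising result
#'
#' Defined as the peak of the denoised signal over the standard
#' deviation of the removed residual: `max(denoised) / sd(original -
#' denoised)`. Larger is better. When the residual is exactly zero the
#' ratio is undefined; an error is raised advising to treat the
#' candidate as infinitely good during parameter search.
#'
#' @param original,denoised Equal-length numeric vectors.
#' @return A single numeric value.
#' @export
snr <- function(original, denoised) {
  if (length(original) != length(denoised)) {
    stop("original and denoised must have equal length", call. = FALSE)
  }
  res_sd <- stats::sd(original - denoised)
  # residuals at float-noise level mean the transform changed nothing
  if (!is.finite(res_sd) || res_sd <= 1e-12 * max(abs(original), 1e-300)) {
    stop("residual is zero: SNR undefined (treat as +Inf in a search)",
         call. = FALSE)
  }
  max(denoised) / res_sd
}

#' Grid-search wavelet order and level by mean SNR
#'
#' Exhaustively evaluates every (Daubechies order, level) pair over the
#' given ranges, denoises every spectrum in the set, and returns the
#' pair maximizing the mean [snr()] over spectra. A candidate whose
#' residual vanishes on some spectrum counts as infinitely good there.
#' Ties break to the lexicographically smallest (order, level).
#'
#' @param set A non-empty [spectrum_set()].
#' @param order_range,level_range Integer vectors within \[3, 10\].
#' @return The winning [wavelet_params()], with the searched grid and
#'   mean SNR per candidate attached as attribute `"search"`.
#' @export
optimize_wavelet <- function(set, order_range = 3:10, level_range = 3:10) {
  stopifnot(inherits(set, "spectrum_set"))
  if (n_spectra(set) == 0L) stop("cannot optimize on an empty set", call. = FALSE)
  if (any(order_range < 3L | order_range > 10L) ||
      any(level_range < 3L | level_range > 10L)) {
    stop("order and level ranges must lie within [3, 10]", call. = FALSE)
  }
  grid <- expand.grid(order = sort(unique(as.integer(order_range))),
                      level = sort(unique(as.integer(level_range))))
  grid$mean_snr <- NA_real_
  for (g in seq_len(nrow(grid))) {
    p <- wavelet_params(grid$order[g], grid$level[g])
    vals <- apply(set$intensities, 1L, function(x) {
      den <- wavelet_denoise(x, p)
      tryCatch(snr(x, den), error = function(e) Inf)
    })
    grid$mean_snr[g] <- mean(vals)
  }
  # lexicographic tie-break: grid is ordered by level-major, so re-sort
  ord <- order(-grid$mean_snr, grid$order, grid$level)
  best <- grid[ord[1L], ]
  out <- wavelet_params(best$order, best$level)
  attr(out, "search") <- grid
  out
}

#' Area-normalize a spectrum
#'
#' Divides every intensity by the spectrum's total intensity,
#' `X_i = x_i / sum_j x_j`, so the result sums to one. This removes
#' shot-to-shot fluctuations of overall plasma emission strength.
#'
#' @param spectrum Numeric vector with positive sum.
#' @return Normalized vector summing to 1 (within 1e-12).
#' @export
area_normalize <- function(spectrum) {
  s <- sum(spectrum)
  if (!is.finite(s) || s <= 0) {
    stop("cannot area-normalize: total intensity is not positive", call. = FALSE)
  }
  spectrum / s
}

#' Denoise and normalize every spectrum of a set
#'
#' Applies [wavelet_denoise()] (with parameters chosen by
#' [optimize_wavelet()] when `params` is `NULL`) and then
#' [area_normalize()] to each record, in that order, logging both steps
#' in the set's provenance.
#'
#' @param set A [spectrum_set()].
#' @param params A [wavelet_params()], or `NULL` to search.
#' @param denoise Set `FALSE` to skip the wavelet step.
#' @return The preprocessed [spectrum_set()].
#' @export
preprocess_set <- function(set, params = NULL, denoise = TRUE) {
  stopifnot(inherits(set, "spectrum_set"))
  if (denoise) {
    if (is.null(params)) params <- optimize_wavelet(set)
    set$intensities <- t(apply(set$intensities, 1L, wavelet_denoise,
                               params = params))
    set <- add_provenance(set, sprintf(
      "wavelet denoise (db%d, level %d, universal soft threshold)",
      params$family_order, params$level))
  }
  set$intensities <- pmax(set$intensities, 0) # clip denoising overshoot
  set$intensities <- t(apply(set$intensities, 1L, area_normalize))
  add_provenance(set, "area normalization")
}
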