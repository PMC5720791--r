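#' Savitzky-Golay smoothing of spectral signatures
#'
#' Smooths each signature along the wavelength axis with a sliding-window
#' least-squares polynomial fit. The defaults — a fifth-degree polynomial
#' with seven supporting points on each side (window of 15 bands) — suit
#' reflectance spectra sampled at a few nm. Near the ends of the spectrum
#' the fit window shrinks to the available points (same polynomial
#' order) instead of padding, so no values outside the measured range are
#' invented; interior bands match the classical filter exactly.
#'
#' @param x a `spectral_matrix`, or a plain numeric matrix with spectra
#'   in columns, or a single numeric spectrum.
#' @param polyorder polynomial degree (default 5).
#' @param half_window supporting points on each side (default 7; window
#'   length `2 * half_window + 1`).
#' @return same type as `x`, smoothed.
#' @export
savgol_smooth <- function(x, polyorder = 5L, half_window = 7L) {
  UseMethod("savgol_smooth")
}

#' @export
savgol_smooth.spectral_matrix <- function(x, polyorder = 5L, half_window = 7L) {
  x$X <- savgol_smooth(x$X, polyorder, half_window)
  x
}

#' @export
savgol_smooth.matrix <- function(x, polyorder = 5L, half_window = 7L) {
  S <- savgol_matrix(nrow(x), polyorder, half_window)
  S %*% x
}

#' @export
savgol_smooth.numeric <- function(x, polyorder = 5L, half_window = 7L) {
  drop(savgol_smooth(matrix(x, ncol = 1L), polyorder, half_window))
}

# m x m linear smoothing operator: row t holds the weights that evaluate,
# at band t, the least-squares polynomial fitted over the window
# max(1, t-hw) .. min(m, t+hw).
savgol_matrix <- function(m, polyorder, half_window) {
  polyorder <- as.integer(polyorder); hw <- as.integer(half_window)
  if (hw < 1L) stop("half_window must be >= 1")
  if (2L * hw + 1L <= polyorder)
    stop("window length (", 2L * hw + 1L, ") must exceed polyorder (",
         polyorder, ")")
  if (m < 2L * hw + 1L)
    stop("spectrum has ", m, " bands but the filter window needs ",
         2L * hw + 1L)
  fit_row <- function(offsets) {
    A <- outer(offsets, 0:polyorder, `^`)
    solve(crossprod(A), t(A))[1L, ]  # evaluate fitted polynomial at offset 0
  }
  S <- matrix(0, m, m)
  interior <- fit_row(-hw:hw)
  for (t in seq_len(m)) {
    lo <- max(1L, t - hw); hi <- min(m, t + hw)
    if (hi - lo == 2L * hw) S[t, lo:hi] <- interior
    else S[t, lo:hi] <- fit_row((lo:hi) - t)
  }
  S
}

#' Crop to a wavelength interval
#'
#' Retains exactly the bands whose centre wavelength lies in the closed
#' interval `[lo_nm, hi_nm]`. The defaults, 450-790 nm, drop the noisy
#' spectral extremes of a visible/NIR push-broom acquisition.
#'
#' @param x `spectral_cube` or `spectral_matrix`.
#' @param lo_nm,hi_nm interval bounds in nm (defaults 450 and 790).
#' @return same type as `x`, with bands and wavelengths cropped.
#' @export
crop_bands <- function(x, lo_nm = 450, hi_nm = 790) {
  stopifnot(lo_nm < hi_nm)
  UseMethod("crop_bands")
}

#' @export
crop_bands.spectral_cube <- function(x, lo_nm = 450, hi_nm = 790) {
  keep <- which(x$wavelengths >= lo_nm & x$wavelengths <= hi_nm)
  if (!length(keep)) stop("no bands inside [", lo_nm, ", ", hi_nm, "] nm")
  spectral_cube(x$values[, , keep, drop = FALSE], x$wavelengths[keep], x$meta)
}

#' @export
crop_bands.spectral_matrix <- function(x, lo_nm = 450, hi_nm = 790) {
  keep <- which(x$wavelengths >= lo_nm & x$wavelengths <= hi_nm)
  if (!length(keep)) stop("no bands inside [", lo_nm, ", ", hi_nm, "] nm")
  spectral_matrix(x$X[keep, , drop = FALSE], x$wavelengths[keep], x$pixel_index)
}

#' Standard preprocessing of a reflectance cube
#'
#' Applies the fixed pipeline smooth -> crop -> mask: Savitzky-Golay
#' smoothing of every pixel spectrum, cropping to the analysis
#' wavelength range, then masking of background and overexposed pixels.
#'
#' @param cube calibrated reflectance `spectral_cube`.
#' @param polyorder,half_window see [savgol_smooth()].
#' @param lo_nm,hi_nm see [crop_bands()].
#' @param background_threshold,overexposure_threshold see [build_mask()].
#' @param user_mask optional `pixel_mask` merged into the computed mask.
#' @return list with elements `cube` (smoothed, cropped) and `mask`.
#' @export
preprocess_cube <- function(cube, polyorder = 5L, half_window = 7L,
                            lo_nm = 450, hi_nm = 790,
                            background_threshold = 0.05,
                            overexposure_threshold = 1.0,
                            user_mask = NULL) {
  d <- dim(cube$values)
  flat <- t(matrix(cube$values, d[1L] * d[2L], d[3L]))  # bands x pixels
  sm <- savgol_smooth(flat, polyorder, half_window)
  cube <- spectral_cube(array(t(sm), d), cube$wavelengths, cube$meta)
  cube <- crop_bands(cube, lo_nm, hi_nm)
  mask <- build_mask(cube, background_threshold, overexposure_threshold,
                     user = user_mask)
  list(cube = cube, mask = mask)
}
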