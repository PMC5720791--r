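#' Spectral cube constructor
#'
#' A `spectral_cube` holds a hyperspectral image as a 3-D array of
#' `rows x cols x bands` together with the band-centre wavelengths in
#' nanometres. Values are unitless sensor intensity or reflectance;
#' after calibration all values must be finite (overexposed reflectance
#' above 1 is kept and handled later by masking).
#'
#' @param values numeric 3-D array, `rows x cols x bands`.
#' @param wavelengths numeric vector of band centres in nm, strictly
#'   increasing, one per band.
#' @param meta optional named list of provenance (source path,
#'   calibration status, ...).
#' @return an object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, wavelengths, meta = list()) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array (rows x cols x bands)")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(values)[3L])
    stop("length(wavelengths) must equal the band dimension (",
         dim(values)[3L], "), got ", length(wavelengths))
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(values = values, wavelengths = wavelengths, meta = meta),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("spectral_cube: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              d[1L], d[2L], d[3L], min(x$wavelengths), max(x$wavelengths)))
  if (length(x$meta)) cat("meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

stopifnot_finite_cube <- function(cube, what = "cube") {
  if (any(!is.finite(cube$values)))
    stop(what, " contains non-finite values (NaN/Inf/NA)")
  invisible(TRUE)
}

#' White/dark calibration references
#'
#' Bundles the white-reference signal (barium-sulfate standard) and the
#' dark-current signal (closed shutter) used to convert raw sensor counts
#' to reflectance. Each reference may be a full `spectral_cube` (spatially
#' resolved references) or a per-band numeric vector.
#'
#' @param white `spectral_cube` or numeric vector (one value per band).
#' @param dark `spectral_cube` or numeric vector (one value per band).
#' @return an object of class `calibration_set`.
#' @export
calibration_set <- function(white, dark) {
  nb <- function(x) if (inherits(x, "spectral_cube")) dim(x$values)[3L] else length(x)
  if (nb(white) != nb(dark))
    stop("white and dark references disagree on band count")
  structure(list(white = white, dark = dark), class = "calibration_set")
}

ref_as_array <- function(ref, d) {
  if (inherits(ref, "spectral_cube")) {
    if (!identical(dim(ref$values), d))
      stop("reference cube dimensions do not match the raw cube")
    ref$values
  } else {
    if (length(ref) != d[3L])
      stop("per-band reference length (", length(ref),
           ") does not match band count (", d[3L], ")")
    aperm(array(rep(as.numeric(ref), each = d[1L] * d[2L]), dim = d), c(1L, 2L, 3L))
  }
}

#' Calibrate raw counts to reflectance
#'
#' Computes reflectance `R = (raw - dark) / (white - dark)` per pixel and
#' band, the standard normalisation against a white reference standard
#' and a closed-shutter dark-current measurement. Values above 1
#' (overexposure, e.g. specular wound fluid) are preserved; they are
#' excluded later by [build_mask()].
#'
#' @param raw `spectral_cube` of raw sensor counts.
#' @param cal [calibration_set()] with matching band count.
#' @return a reflectance `spectral_cube`; `meta$calibrated` is set.
#' @export
calibrate_reflectance <- function(raw, cal) {
  stopifnot(inherits(raw, "spectral_cube"), inherits(cal, "calibration_set"))
  d <- dim(raw$values)
  w <- ref_as_array(cal$white, d)
  k <- ref_as_array(cal$dark, d)
  denom <- w - k
  bad <- which(apply(denom <= 0, 3L, any))
  if (length(bad))
    stop("white - dark is not strictly positive in band(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (wavelength ", raw$wavelengths[bad[1L]], " nm)")
  refl <- (raw$values - k) / denom
  meta <- raw$meta
  meta$calibrated <- TRUE
  spectral_cube(refl, raw$wavelengths, meta)
}

#' Flatten a cube to a signature matrix
#'
#' Converts a cube into the dense `m x n` matrix used by the clustering:
#' rows are wavelengths, columns are the spectra (signatures) of the
#' unmasked pixels. Columns follow a row-major scan of the image (row 1
#' left to right, then row 2, ...) so the layout is deterministic. The
#' back-map from columns to pixels is kept so label vectors can be folded
#' back into images with [matrix_to_map()].
#'
#' @param cube `spectral_cube`.
#' @param mask optional [pixel_mask()]; excluded pixels are dropped.
#' @param image_id identifier recorded in the back-map (default "image").
#' @return an object of class `spectral_matrix` with elements `X`
#'   (`m x n` matrix), `wavelengths`, and `pixel_index` (data.frame with
#'   columns `image`, `row`, `col`, 1-based).
#' @export
cube_to_matrix <- function(cube, mask = NULL, image_id = "image") {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  keep <- matrix(TRUE, d[1L], d[2L])
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "pixel_mask"))
    if (!identical(dim(mask$excluded), d[1:2]))
      stop("mask spatial dimensions do not match the cube")
    keep <- !mask$excluded
  }
  idx <- which(t(keep))  # row-major order
  if (!length(idx)) stop("all pixels are masked; empty matrix")
  rc <- cbind(row = (idx - 1L) %/% d[2L] + 1L, col = (idx - 1L) %% d[2L] + 1L)
  flat <- matrix(cube$values, d[1L] * d[2L], d[3L])  # pixel (col-major) x band
  lin <- (rc[, "col"] - 1L) * d[1L] + rc[, "row"]
  X <- t(flat[lin, , drop = FALSE])
  pixel_index <- data.frame(image = image_id, row = rc[, "row"], col = rc[, "col"],
                            stringsAsFactors = FALSE)
  spectral_matrix(X, cube$wavelengths, pixel_index)
}

#' Signature matrix constructor
#'
#' @param X numeric matrix, `m` wavelengths (rows) x `n` signatures
#'   (columns).
#' @param wavelengths numeric, length `m`.
#' @param pixel_index data.frame with columns `image`, `row`, `col`
#'   mapping each column of `X` to a pixel.
#' @return an object of class `spectral_matrix`.
#' @export
spectral_matrix <- function(X, wavelengths, pixel_index = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(wavelengths))
    stop("nrow(X) must equal length(wavelengths)")
  if (!is.null(pixel_index) && nrow(pixel_index) != ncol(X))
    stop("pixel_index must have one row per column of X")
  structure(list(X = X, wavelengths = as.numeric(wavelengths),
                 pixel_index = pixel_index),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("spectral_matrix: %d bands x %d signatures\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Combine signature matrices from several images
#'
#' Concatenates the columns of several `spectral_matrix` objects (in the
#' given order) after checking that they share the wavelength axis.
#'
#' @param mats list of `spectral_matrix`.
#' @return one `spectral_matrix`.
#' @export
bind_matrices <- function(mats) {
  stopifnot(length(mats) >= 1L)
  wl <- mats[[1L]]$wavelengths
  for (m in mats) {
    if (!isTRUE(all.equal(m$wavelengths, wl)))
      stop("signature matrices disagree on the wavelength axis")
  }
  spectral_matrix(do.call(cbind, lapply(mats, `[[`, "X")), wl,
                  do.call(rbind, lapply(mats, `[[`, "pixel_index")))
}

#' Fold per-column labels back into a label image
#'
#' Inverse of [cube_to_matrix()]: places the label of each signature at
#' its pixel; pixels without a signature (masked) carry `NA`
#' ("unlabelled").
#'
#' @param labels integer vector, one label per column of the matrix.
#' @param pixel_index the back-map produced by [cube_to_matrix()] (rows
#'   for a single image).
#' @param spatial_shape integer c(rows, cols).
#' @param k number of clusters (recorded on the map; default
#'   `max(labels)`).
#' @param image_id identifier recorded on the map.
#' @return an object of class `cluster_map`: list with `labels` (integer
#'   rows x cols matrix, `NA` = unlabelled), `k`, `image`.
#' @export
matrix_to_map <- function(labels, pixel_index, spatial_shape,
                          k = max(labels), image_id = NULL) {
  if (length(labels) != nrow(pixel_index))
    stop("labels length must equal the number of back-mapped pixels")
  r <- pixel_index$row; cc <- pixel_index$col
  if (any(r < 1L | r > spatial_shape[1L] | cc < 1L | cc > spatial_shape[2L]))
    stop("pixel_index contains coordinates outside the spatial shape")
  lin <- (cc - 1L) * spatial_shape[1L] + r
  if (anyDuplicated(lin))
    stop("pixel_index maps two signatures to the same pixel")
  grid <- matrix(NA_integer_, spatial_shape[1L], spatial_shape[2L])
  grid[lin] <- as.integer(labels)
  if (is.null(image_id))
    image_id <- if (nrow(pixel_index)) pixel_index$image[1L] else "image"
  structure(list(labels = grid, k = as.integer(k), image = image_id),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("cluster_map '%s': %d x %d, k = %d, %d labelled pixels\n",
              x$image, nrow(x$labels), ncol(x$labels), x$k,
              sum(!is.na(x$labels))))
  invisible(x)
}
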