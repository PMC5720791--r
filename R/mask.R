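#' Pixel mask constructor
#'
#' A `pixel_mask` marks pixels excluded from analysis, together with a
#' per-pixel reason code (`"background"`, `"overexposed"`, `"roi"`, or
#' `"user"`).
#'
#' @param excluded logical matrix, rows x cols; `TRUE` = excluded.
#' @param reason character matrix of the same shape (`NA` where not
#'   excluded), or a single code applied to all excluded pixels.
#' @return an object of class `pixel_mask`.
#' @export
pixel_mask <- function(excluded, reason = "user") {
  stopifnot(is.logical(excluded), is.matrix(excluded))
  if (is.character(reason) && length(reason) == 1L) {
    r <- matrix(NA_character_, nrow(excluded), ncol(excluded))
    r[excluded] <- reason
    reason <- r
  }
  stopifnot(identical(dim(reason), dim(excluded)))
  structure(list(excluded = excluded, reason = reason), class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  tab <- table(x$reason[x$excluded])
  cat(sprintf("pixel_mask: %d x %d, %d excluded", nrow(x$excluded),
              ncol(x$excluded), sum(x$excluded)))
  if (length(tab))
    cat(" (", paste(names(tab), tab, sep = ": ", collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Background and overexposure mask
#'
#' Flags pixels to exclude before clustering: *overexposed* pixels whose
#' maximum reflectance over the retained bands exceeds 1 (strictly), as
#' happens under specular fluid, and *background* pixels whose mean
#' reflectance falls below a darkness threshold (the imaging dish is far
#' darker than tissue). An optional user mask is merged in; a pixel
#' flagged by several rules keeps the highest-priority reason
#' (overexposed > background > user).
#'
#' @param cube calibrated reflectance `spectral_cube` (already smoothed
#'   and cropped to the analysis range).
#' @param background_threshold mean-reflectance threshold below which a
#'   pixel is background (default 0.05).
#' @param overexposure_threshold reflectance ceiling; a pixel is
#'   overexposed iff its max over bands is strictly greater (default 1).
#' @param user optional `pixel_mask` merged in with reason `"user"`.
#' @return a [pixel_mask()].
#' @export
build_mask <- function(cube, background_threshold = 0.05,
                       overexposure_threshold = 1.0, user = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  mx <- apply(cube$values, c(1L, 2L), max)
  mn <- apply(cube$values, c(1L, 2L), mean)
  over <- mx > overexposure_threshold
  back <- mn < background_threshold & !over
  excluded <- over | back
  reason <- matrix(NA_character_, nrow(excluded), ncol(excluded))
  reason[back] <- "background"
  reason[over] <- "overexposed"
  m <- pixel_mask(excluded, reason)
  if (!is.null(user)) m <- combine_masks(m, user)
  m
}

#' Merge pixel masks (union of exclusions)
#'
#' The union never unmasks a pixel; where several masks exclude the same
#' pixel the reason of the earliest argument wins.
#'
#' @param ... `pixel_mask` objects of identical shape.
#' @return a [pixel_mask()].
#' @export
combine_masks <- function(...) {
  masks <- list(...)
  stopifnot(length(masks) >= 1L)
  out <- masks[[1L]]
  for (m in masks[-1L]) {
    stopifnot(identical(dim(m$excluded), dim(out$excluded)))
    new <- m$excluded & !out$excluded
    out$reason[new] <- m$reason[new]
    out$excluded <- out$excluded | m$excluded
  }
  out
}

#' Circular region-of-interest mask
#'
#' Excludes every pixel whose Euclidean distance from the centre exceeds
#' `diameter_px / 2`; used to restrict per-cluster pixel counts to a
#' fixed-area disc (e.g. the 5 mm wound region).
#'
#' @param spatial_shape integer c(rows, cols).
#' @param center numeric c(row, col) of the disc centre (1-based pixel
#'   coordinates; defaults to the image centre).
#' @param diameter_px disc diameter in pixels.
#' @return a [pixel_mask()] with reason `"roi"` outside the disc.
#' @export
circular_roi_mask <- function(spatial_shape, diameter_px,
                              center = (spatial_shape + 1) / 2) {
  stopifnot(diameter_px > 0, length(spatial_shape) == 2L)
  r <- matrix(seq_len(spatial_shape[1L]), spatial_shape[1L], spatial_shape[2L])
  cc <- matrix(seq_len(spatial_shape[2L]), spatial_shape[1L], spatial_shape[2L],
               byrow = TRUE)
  dist <- sqrt((r - center[1L])^2 + (cc - center[2L])^2)
  pixel_mask(dist > diameter_px / 2, "roi")
}
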