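#' Default wavelength grid of the synthetic scenes
#'
#' 450-790 nm sampled at 2.73 nm (125 bands), the analysis range and
#' spectral resolution of a visible/NIR push-broom acquisition.
#'
#' @return numeric vector of band centres in nm.
#' @export
default_wavelengths <- function() seq(450, by = 2.73, length.out = 125L)

#' Generate smooth, well-separated endmember spectra
#'
#' Each endmember is a small positive baseline plus 2-4 Gaussian bumps
#' over the wavelength axis, rescaled to a peak at most 0.9 reflectance.
#' Candidates are redrawn (bounded retries) until every spectrum is
#' smooth (max band-to-band change <= 0.045), has mean reflectance at
#' least 0.15 (so tissue is clearly brighter than the dark dish), and is
#' at least `separation_floor` away (Euclidean) from every other
#' endmember.
#'
#' @param g number of endmembers.
#' @param wavelengths wavelength grid in nm.
#' @param seed integer seed, or `NULL` to draw from the current RNG
#'   stream.
#' @param separation_floor minimum pairwise Euclidean distance
#'   (default 1).
#' @param max_retry retry budget per endmember (default 200).
#' @return `m x g` matrix of endmember spectra (columns).
#' @export
make_endmembers <- function(g, wavelengths = default_wavelengths(), seed = 0L,
                            separation_floor = 1.0, max_retry = 200L) {
  stopifnot(g >= 1L)
  gen <- function() {
    m <- length(wavelengths)
    out <- matrix(NA_real_, m, g)
    rng <- range(wavelengths)
    for (j in seq_len(g)) {
      ok <- FALSE
      for (try in seq_len(max_retry)) {
        nb <- sample(2:4, 1L)
        centers <- stats::runif(nb, rng[1L], rng[2L])
        sds <- stats::runif(nb, 35, 90)
        amps <- stats::runif(nb, 0.3, 1)
        sp <- rep(0.05, m)
        for (b in seq_len(nb))
          sp <- sp + amps[b] * exp(-0.5 * ((wavelengths - centers[b]) / sds[b])^2)
        sp <- sp * stats::runif(1L, 0.4, 0.9) / max(sp)
        if (max(abs(diff(sp))) > 0.045) next
        if (mean(sp) < 0.15) next
        if (j > 1L) {
          seps <- apply(out[, seq_len(j - 1L), drop = FALSE], 2L,
                        function(e) euclidean_dist(e, sp))
          if (any(seps < separation_floor)) next
        }
        out[, j] <- sp
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not generate ", g, " endmembers with separation >= ",
             separation_floor, " within the retry budget")
    }
    out
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Synthetic wound-scene specification
#'
#' Describes a piecewise-constant disc scene emulating a wounded tissue
#' disc imaged on a dark dish: an outer tissue-periphery disc, a
#' wound-margin annulus, and a central wound-bed disc, each carrying one
#' endmember spectrum, over a dark background, with a few overexposed
#' "fluid" pixels whose reflectance exceeds 1.
#'
#' @param spatial_shape integer c(rows, cols) (default 64 x 64).
#' @param wavelengths band centres in nm (default [default_wavelengths()]).
#' @param endmembers optional `m x 3` endmember matrix (columns:
#'   periphery, margin, wound bed); generated from the seed if `NULL`.
#' @param outer_radius,margin_radius,bed_radius region radii in pixels
#'   (defaults 28, 16, 8); regions are concentric around the image
#'   centre: wound bed inside `bed_radius`, margin annulus from
#'   `bed_radius` to `margin_radius`, periphery out to `outer_radius`.
#' @param noise_sd additive iid Gaussian noise per band (default 0.01).
#' @param n_overexposed number of overexposed fluid pixels scattered
#'   over the tissue (default 30; per-band values drawn in 1.05-1.5).
#' @param background_level dark-dish reflectance (default 0.01).
#' @param separation_floor minimum endmember separation (default 1).
#' @param seed integer seed (default 0).
#' @return an object of class `scene_spec` (named list).
#' @export
scene_spec <- function(spatial_shape = c(64L, 64L),
                       wavelengths = default_wavelengths(),
                       endmembers = NULL,
                       outer_radius = 28, margin_radius = 16, bed_radius = 8,
                       noise_sd = 0.01, n_overexposed = 30L,
                       background_level = 0.01, separation_floor = 1.0,
                       seed = 0L) {
  if (outer_radius > min(spatial_shape) / 2)
    stop("outer_radius exceeds the image bounds")
  if (!(bed_radius < margin_radius && margin_radius < outer_radius))
    stop("radii must satisfy bed < margin < outer")
  structure(list(spatial_shape = as.integer(spatial_shape),
                 wavelengths = wavelengths, endmembers = endmembers,
                 outer_radius = outer_radius, margin_radius = margin_radius,
                 bed_radius = bed_radius, noise_sd = noise_sd,
                 n_overexposed = as.integer(n_overexposed),
                 background_level = background_level,
                 separation_floor = separation_floor,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a ground-truthed synthetic wound cube
#'
#' Renders the scene described by a [scene_spec()]: each pixel's
#' spectrum is its region endmember (or the background level) plus iid
#' Gaussian noise, clipped at 0; overexposed fluid pixels get per-band
#' values in 1.05-1.5. The ground truth labels every pixel as background
#' (0), tissue region (1 = periphery, 2 = margin, 3 = wound bed) or
#' overexposed (-1), and records the true endmember spectra, so cluster
#' recovery and masking can be scored exactly.
#'
#' @param spec a [scene_spec()].
#' @return list with `cube` (a reflectance [spectral_cube()]) and
#'   `truth` (list: `labels` integer grid, `background` / `overexposed`
#'   logical grids, `endmembers`).
#' @export
make_wound_cube <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    d <- c(spec$spatial_shape, length(spec$wavelengths))
    E <- spec$endmembers
    if (is.null(E))
      E <- make_endmembers(3L, spec$wavelengths, seed = NULL,
                           separation_floor = spec$separation_floor)
    stopifnot(nrow(E) == d[3L], ncol(E) >= 3L)
    ctr <- (spec$spatial_shape + 1) / 2
    r <- matrix(seq_len(d[1L]), d[1L], d[2L])
    cc <- matrix(seq_len(d[2L]), d[1L], d[2L], byrow = TRUE)
    dist <- sqrt((r - ctr[1L])^2 + (cc - ctr[2L])^2)
    region <- matrix(0L, d[1L], d[2L])
    region[dist <= spec$outer_radius] <- 1L
    region[dist <= spec$margin_radius] <- 2L
    region[dist <= spec$bed_radius] <- 3L

    vals <- array(spec$background_level, d)
    npix <- d[1L] * d[2L]
    flat <- matrix(vals, npix, d[3L])
    for (g in 1:3) {
      pix <- which(region == g)
      if (length(pix))
        flat[pix, ] <- matrix(E[, g], length(pix), d[3L], byrow = TRUE)
    }
    if (spec$noise_sd > 0)
      flat <- flat + matrix(stats::rnorm(npix * d[3L], sd = spec$noise_sd),
                            npix, d[3L])
    flat <- pmax(flat, 0)

    over <- matrix(FALSE, d[1L], d[2L])
    tissue <- which(region > 0L)
    n_over <- min(spec$n_overexposed, length(tissue))
    if (n_over > 0L) {
      fluid <- sample(tissue, n_over)
      over[fluid] <- TRUE
      flat[fluid, ] <- matrix(stats::runif(n_over * d[3L], 1.05, 1.5),
                              n_over, d[3L])
    }
    labels <- region
    labels[over] <- -1L
    cube <- spectral_cube(array(flat, d), spec$wavelengths,
                          meta = list(kind = "synthetic_wound_scene",
                                      seed = spec$seed, calibrated = TRUE))
    list(cube = cube,
         truth = list(labels = labels, background = region == 0L & !over,
                      overexposed = over, endmembers = E[, 1:3, drop = FALSE]))
  })
}

#' Generate a synthetic wound-healing timecourse
#'
#' A deterministic series of scenes over "days" and conditions sharing
#' one endmember set: under the control condition the wound-bed disc
#' shrinks with time (the wound closes), under a treated condition it
#' persists (impaired closure). Exercises model training on early days
#' and per-cluster quantification across the series.
#'
#' @param days numeric vector of day labels (default c(0, 5, 10)).
#' @param conditions character vector (default c("control", "treated")).
#' @param base a [scene_spec()] providing geometry, noise and seed; the
#'   wound-bed radius of day `d` is `bed_radius * (1 - 0.08 d)` for
#'   control and constant for treated conditions.
#' @return list of entries, each `list(day, condition, cube, truth)`,
#'   in `expand.grid(days, conditions)` order; identical for identical
#'   seeds.
#' @export
make_timecourse <- function(days = c(0, 5, 10),
                            conditions = c("control", "treated"),
                            base = scene_spec()) {
  E <- base$endmembers
  if (is.null(E))
    E <- make_endmembers(3L, base$wavelengths, seed = base$seed,
                         separation_floor = base$separation_floor)
  grid <- expand.grid(day = days, condition = conditions,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    day <- grid$day[i]; cond <- grid$condition[i]
    bed <- if (cond == "control")
      max(base$bed_radius * (1 - 0.08 * day), 1) else base$bed_radius
    sp <- base
    sp$endmembers <- E
    sp$bed_radius <- bed
    sp$seed <- derive_seed(base$seed, i + 1L)
    out[[i]] <- c(list(day = day, condition = cond), make_wound_cube(sp))
  }
  out
}
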