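#' Euclidean distance between two spectra
#'
#' `sqrt(sum((a - b)^2))`, the distance underlying pivot selection,
#' projection and nearest-representative assignment.
#'
#' @param a,b numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
euclidean_dist <- function(a, b) {
  if (length(a) != length(b))
    stop("spectra have different lengths (", length(a), " vs ", length(b), ")")
  sqrt(sum((a - b)^2))
}

# distances from one spectrum to every column of X, vectorised
dist_to_cols <- function(X, v) {
  sqrt(pmax(colSums((X - v)^2), 0))
}

# evaluate `code` under a seeded, self-contained RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Choose pivot signatures by the farthest-point heuristic
#'
#' Three steps: pick a start column uniformly at random (seeded), let
#' `b` be the column farthest from the start, then let `a` be the column
#' farthest from `b`. The two pivots approximate the most extreme
#' (archetypal) points of the set, so the projection axis through them
#' follows the data's widest spread. Ties in the farthest-point searches
#' go to the lowest column index.
#'
#' @param X numeric matrix, spectra in columns (at least 2 columns).
#' @param seed integer seed for the start-point draw, or `NULL` to use
#'   the current RNG stream (as inside a seeded tree build).
#' @return list `(a, b, start)` of column indices with `Dist(a, b) > 0`,
#'   or `NULL` if all columns are identical (degenerate node).
#' @export
choose_pivots <- function(X, seed = NULL) {
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 points to choose pivots")
  pick <- function() {
    start <- sample.int(n, 1L)
    db <- dist_to_cols(X, X[, start])
    b <- which.max(db)
    if (db[b] == 0) return(NULL)  # all points identical
    da <- dist_to_cols(X, X[, b])
    a <- which.max(da)
    list(a = a, b = b, start = start)
  }
  if (is.null(seed)) pick() else with_seed(seed, pick())
}

#' FastMap 1-D projection onto the pivot axis
#'
#' Projects every column of `X` onto the line through the pivots using
#' only pairwise distances. Two formula variants are provided:
#' `"as_printed"` uses unsquared distances,
#' `Proj(x) = (Dist(a,x) + Dist(a,b) - Dist(b,x)) / (2 Dist(a,b))`,
#' which maps `a` to 0, `b` to 1, and (by the triangle inequality) every
#' point into \[0, 1\]; `"law_of_cosines"` is the classical FastMap form
#' with squared distances,
#' `Proj(x) = (Dist(a,x)^2 + Dist(a,b)^2 - Dist(b,x)^2) / (2 Dist(a,b))`,
#' mapping `a` to 0 and `b` to `Dist(a,b)`. Both give a valid 1-D
#' ordering; the default is `"as_printed"`.
#'
#' @param X numeric matrix, spectra in columns.
#' @param a,b pivot spectra (numeric vectors) or column indices into `X`.
#' @param variant `"as_printed"` (default) or `"law_of_cosines"`.
#' @return numeric vector of projection values, one per column.
#' @export
fastmap_project <- function(X, a, b, variant = c("as_printed", "law_of_cosines")) {
  variant <- match.arg(variant)
  if (length(a) == 1L) a <- X[, a]
  if (length(b) == 1L) b <- X[, b]
  dab <- euclidean_dist(a, b)
  if (dab == 0) stop("coincident pivots: Dist(a, b) = 0")
  dax <- dist_to_cols(X, a)
  dbx <- dist_to_cols(X, b)
  if (variant == "as_printed")
    (dax + dab - dbx) / (2 * dab)
  else
    (dax^2 + dab^2 - dbx^2) / (2 * dab)
}

#' Best variance-minimising split of a projection list
#'
#' Sorts the projections `s_1 <= ... <= s_n` and finds the split index
#' `i` (1..n-1) minimising the sum of the two within-side mean squared
#' deviations,
#' `c_i = (1/i) sum_{j<=i} (s_j - mu1)^2 + (1/(n-i)) sum_{j>i} (s_j - mu2)^2`,
#' with `mu1`, `mu2` the side means. Ties go to the smallest `i`. The
#' split threshold is the midpoint `theta = (s_i + s_{i+1}) / 2`, and the
#' node rule is `Proj(x) <= theta`.
#'
#' @param s numeric vector of projection values (length >= 2).
#' @return list `(i, theta, cost)`, or `NULL` when all values are equal
#'   (degenerate split; the caller should make the node a leaf).
#' @export
best_split <- function(s) {
  n <- length(s)
  if (n < 2L) stop("need at least 2 projection values to split")
  s <- sort(s)
  if (s[n] == s[1L]) return(NULL)
  i <- seq_len(n - 1L)
  cs <- cumsum(s); css <- cumsum(s^2)
  left_ss <- css[i] - cs[i]^2 / i                       # sum (s_j - mu1)^2
  right_ss <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i)
  cost <- left_ss / i + right_ss / (n - i)
  best <- which.min(cost)  # smallest index on ties
  list(i = best, theta = (s[best] + s[best + 1L]) / 2, cost = cost[best])
}
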