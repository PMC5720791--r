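# squared distances from every column of X to every column of C: n x k
dist2_table <- function(X, C) {
  vapply(seq_len(ncol(C)), function(j) colSums((X - C[, j])^2),
         numeric(ncol(X)))
}

# nearest column of C for every column of X; exact ties -> lowest index
nearest_label <- function(X, C) {
  D2 <- dist2_table(X, C)
  if (is.null(dim(D2))) D2 <- matrix(D2, nrow = ncol(X))
  max.col(-D2, ties.method = "first")
}

# canonical column order: by mean value, then lexicographically by band
canonical_order <- function(M) {
  keys <- c(list(colMeans(M)), lapply(seq_len(nrow(M)), function(i) M[i, ]))
  do.call(order, keys)
}

# farthest-point (maximin) seeding: seeded uniform first centre, then
# repeatedly the point farthest from the chosen set; ties -> lowest index
maximin_init <- function(X, k) {
  n <- ncol(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- colSums((X - X[, centers[1L]])^2)
  if (k > 1L) for (j in 2:k) {
    nxt <- which.max(d2)
    if (d2[nxt] == 0)
      stop("fewer than ", k, " distinct points; cannot place ", k, " centres")
    centers[j] <- nxt
    d2 <- pmin(d2, colSums((X - X[, nxt])^2))
  }
  centers
}

#' Lloyd k-means on spectra (columns)
#'
#' Standard Lloyd iterations from a seeded farthest-point (maximin)
#' initialisation: assign every point to its nearest centroid, recompute
#' centroids as cluster means, and stop when the assignment no longer
#' changes or after `max_iters` iterations (default 1000). A centroid
#' left without members is re-seeded on the point currently farthest
#' from its own centroid, keeping k clusters alive. Used both as the
#' post-pruning step on leaf means and as the flat baseline the tree
#' decomposition is compared against.
#'
#' @param X numeric matrix or `spectral_matrix`, points in columns.
#' @param k number of clusters.
#' @param seed integer seed for the initialisation (default 0).
#' @param max_iters iteration cap (default 1000).
#' @return list with `labels` (per column), `centers` (`m x k`),
#'   `iterations`, `converged`, and `wss` (total within-cluster sum of
#'   squares after each assignment step).
#' @export
kmeans_lloyd <- function(X, k, seed = 0L, max_iters = 1000L) {
  if (inherits(X, "spectral_matrix")) X <- X$X
  X <- as.matrix(X)
  n <- ncol(X)
  if (n < k) stop("fewer points (", n, ") than clusters (", k, ")")
  C <- with_seed(seed, X[, maximin_init(X, k), drop = FALSE])
  labels <- integer(n)
  wss_hist <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iters) {
    iter <- iter + 1L
    D2 <- dist2_table(X, C)
    if (is.null(dim(D2))) D2 <- matrix(D2, nrow = n)
    new_labels <- max.col(-D2, ties.method = "first")
    wss_hist <- c(wss_hist, sum(D2[cbind(seq_len(n), new_labels)]))
    if (iter > 1L && identical(new_labels, labels)) {
      converged <- TRUE
      labels <- new_labels
      break
    }
    labels <- new_labels
    d2own <- D2[cbind(seq_len(n), labels)]
    for (j in seq_len(k)) {
      mem <- labels == j
      if (any(mem)) C[, j] <- rowMeans(X[, mem, drop = FALSE])
      else {
        # re-seed an emptied centroid on the worst-fitted point
        far <- which.max(d2own)
        d2own[far] <- -Inf
        C[, j] <- X[, far]
      }
    }
  }
  list(labels = labels, centers = C, iterations = iter,
       converged = converged, wss = wss_hist)
}

#' Flat k-means baseline on a signature matrix
#'
#' Runs [kmeans_lloyd()] directly on all signatures (the conventional
#' approach XHC is compared against) and canonicalises the cluster ids
#' (centroids sorted by mean reflectance, then lexicographically) so
#' labels are stable across runs.
#'
#' @inheritParams kmeans_lloyd
#' @return list with `labels` and `centers` (canonically ordered),
#'   plus `iterations` and `converged`.
#' @export
kmeans_baseline <- function(X, k, seed = 0L, max_iters = 1000L) {
  km <- kmeans_lloyd(X, k, seed, max_iters)
  ord <- canonical_order(km$centers)
  relabel <- match(seq_len(k), ord)
  list(labels = relabel[km$labels], centers = km$centers[, ord, drop = FALSE],
       iterations = km$iterations, converged = km$converged)
}

#' Prune tree leaves to k representative spectra
#'
#' The post-pruning step: Lloyd k-means on the leaf-mean spectra of one
#' or more decomposition trees reduces the (many) leaves to `k` final
#' representatives — the cluster centroids. Leaf means are first put in
#' a canonical order (sorted by mean reflectance, then lexicographically),
#' so the result does not depend on tree or subset order; the returned
#' representatives are canonicalised the same way, giving stable cluster
#' ids across runs.
#'
#' @param Y `m x l` matrix of leaf means (see [leaf_means()]), or an
#'   `xhc_tree`, or a list of trees.
#' @param k number of final clusters (default 7).
#' @param seed integer seed for the k-means initialisation (default 0).
#' @param max_iters k-means iteration cap (default 1000).
#' @param wavelengths optional wavelength axis recorded on the model.
#' @return an object of class `xhc_model`: list with `representatives`
#'   (`m x k`), `k`, `wavelengths`, `params`.
#' @export
prune_to_k <- function(Y, k = 7L, seed = 0L, max_iters = 1000L,
                       wavelengths = NULL) {
  if (inherits(Y, "xhc_tree") || (is.list(Y) && !is.matrix(Y) &&
                                  all(vapply(Y, inherits, TRUE, "xhc_tree")))) {
    if (is.null(wavelengths))
      wavelengths <- (if (inherits(Y, "xhc_tree")) Y else Y[[1L]])$wavelengths
    Y <- leaf_means(Y)
  }
  Y <- as.matrix(Y)
  l <- ncol(Y)
  if (l < k)
    stop("only ", l, " leaf means but k = ", k,
         ": deepen the tree (larger max_depth / smaller min_leaf) or lower k")
  Y <- Y[, canonical_order(Y), drop = FALSE]
  km <- kmeans_lloyd(Y, k, seed, max_iters)
  reps <- km$centers[, canonical_order(km$centers), drop = FALSE]
  structure(list(representatives = reps, k = as.integer(k),
                 wavelengths = wavelengths,
                 params = list(seed = as.integer(seed),
                               max_iters = as.integer(max_iters),
                               n_leaves = l)),
            class = "xhc_model")
}

#' @export
print.xhc_model <- function(x, ...) {
  cat(sprintf("xhc_model: k = %d representatives over %d bands (from %d leaves)\n",
              x$k, nrow(x$representatives), x$params$n_leaves))
  invisible(x)
}

#' Assign signatures to their nearest representative
#'
#' Labels every column of `X` with the index (1..k) of the closest
#' representative spectrum by Euclidean distance; exact ties go to the
#' lowest representative index.
#'
#' @param X `spectral_matrix` or numeric matrix, spectra in columns.
#' @param model an `xhc_model`.
#' @return integer vector of labels, one per column.
#' @export
assign_clusters <- function(X, model) {
  if (inherits(X, "spectral_matrix")) X <- X$X
  X <- as.matrix(X)
  if (nrow(X) != nrow(model$representatives))
    stop("signature length (", nrow(X), ") does not match the model (",
         nrow(model$representatives), " bands)")
  nearest_label(X, model$representatives)
}

#' Fit an XHC cluster model (serial)
#'
#' Convenience wrapper: [grow_tree()] then [prune_to_k()] on the leaf
#' means.
#'
#' @param X `spectral_matrix` or numeric matrix, spectra in columns.
#' @param k number of final clusters (default 7).
#' @param max_depth,min_leaf,seed,variant see [grow_tree()].
#' @param max_iters pruning k-means iteration cap (default 1000).
#' @return an `xhc_model`.
#' @export
xhc_fit <- function(X, k = 7L, max_depth = 10L, min_leaf = 100L, seed = 0L,
                    variant = c("as_printed", "law_of_cosines"),
                    max_iters = 1000L) {
  variant <- match.arg(variant)
  tree <- grow_tree(X, max_depth, min_leaf, seed, variant)
  prune_to_k(leaf_means(tree), k, seed, max_iters,
             wavelengths = tree$wavelengths)
}

# derive an independent 31-bit sub-seed for subset i from the master seed
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + (i - 1) * 1000003) %% 2147483647)
}

#' Fit an XHC model on data subsets (parallel merge)
#'
#' Grows one decomposition tree per subset (every subset build is seeded
#' with the master seed, so a subset's tree does not depend on its
#' position in the list), collects all leaf means into one matrix `Y`,
#' and prunes `Y` to `k` representatives. Because [prune_to_k()]
#' canonicalises the leaf means, the model is a pure function of the
#' set of inputs and the master seed, regardless of subset order or
#' execution order; with a single subset it equals the serial
#' [xhc_fit()] exactly.
#'
#' @param matrices list of `spectral_matrix` (or plain matrices) sharing
#'   the wavelength axis.
#' @param k,max_depth,min_leaf,seed,variant,max_iters as in [xhc_fit()].
#' @return an `xhc_model`.
#' @export
xhc_parallel <- function(matrices, k = 7L, max_depth = 10L, min_leaf = 100L,
                         seed = 0L, variant = c("as_printed", "law_of_cosines"),
                         max_iters = 1000L) {
  variant <- match.arg(variant)
  stopifnot(length(matrices) >= 1L)
  ms <- vapply(matrices, function(x)
    if (inherits(x, "spectral_matrix")) nrow(x$X) else nrow(x), integer(1))
  if (length(unique(ms)) != 1L)
    stop("subsets disagree on the number of bands: ",
         paste(unique(ms), collapse = ", "))
  wl <- if (inherits(matrices[[1L]], "spectral_matrix"))
    matrices[[1L]]$wavelengths else NULL
  trees <- lapply(matrices, grow_tree, max_depth = max_depth,
                  min_leaf = min_leaf, seed = seed, variant = variant)
  prune_to_k(leaf_means(trees), k, seed, max_iters, wavelengths = wl)
}

#' Per-cluster pixel counts inside a region of interest
#'
#' Counts the labelled pixels of each cluster inside the (optional) ROI,
#' the quantity tracked over days and treatments to follow wound
#' closure.
#'
#' @param map a `cluster_map`.
#' @param roi optional `pixel_mask` (e.g. [circular_roi_mask()]); only
#'   pixels *not* excluded by it are counted.
#' @return data.frame with columns `cluster` (1..k) and `pixels`;
#'   attribute `total_labelled` holds the number of labelled in-ROI
#'   pixels (`sum(pixels)`).
#' @export
quantify_clusters <- function(map, roi = NULL) {
  stopifnot(inherits(map, "cluster_map"))
  lab <- map$labels
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "pixel_mask"))
    if (!identical(dim(roi$excluded), dim(lab)))
      stop("ROI dimensions do not match the cluster map")
    lab[roi$excluded] <- NA_integer_
  }
  counts <- tabulate(lab[!is.na(lab)], nbins = map$k)
  out <- data.frame(cluster = seq_len(map$k), pixels = counts)
  attr(out, "total_labelled") <- sum(counts)
  out
}

#' Serialise an XHC model to JSON
#'
#' @param model an `xhc_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_model <- function(model, path) {
  obj <- list(kind = "xhc_model", k = model$k,
              wavelengths = model$wavelengths,
              representatives = unname(as.matrix(model$representatives)),
              params = model$params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read an XHC model written by [write_model()]
#'
#' @param path JSON path.
#' @return an `xhc_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$kind) || obj$kind != "xhc_model")
    stop("not an xhc_model file: ", path)
  structure(list(representatives = as.matrix(obj$representatives),
                 k = as.integer(obj$k),
                 wavelengths = obj$wavelengths,
                 params = as.list(obj$params)),
            class = "xhc_model")
}
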