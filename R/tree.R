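#' Grow an XHC decomposition tree
#'
#' Recursively decomposes the signature matrix: at each node two pivot
#' signatures are found by the farthest-point heuristic
#' ([choose_pivots()]), every member is projected onto the pivot axis
#' ([fastmap_project()]), the projection list is split at the
#' variance-minimising threshold ([best_split()]), and the members are
#' sorted into the "success" child (`Proj(x) <= theta`) and the
#' "failure" child. Splitting stops when a node holds fewer than
#' `2 * min_leaf` members, when `max_depth` is reached, or when the node
#' is degenerate (identical members or constant projections). Each leaf
#' stores its member column indices and mean spectrum; the leaf means
#' feed the pruning step ([prune_to_k()]).
#'
#' @param X a `spectral_matrix` or plain numeric matrix (spectra in
#'   columns).
#' @param max_depth maximum tree depth; the root is depth 0 (default 10).
#' @param min_leaf minimum leaf size in signatures; a node splits only
#'   if it holds at least `2 * min_leaf` members (default 100).
#' @param seed integer seed for the per-node start-point draws
#'   (default 0); the whole build is reproducible from it.
#' @param variant projection variant, see [fastmap_project()].
#' @return an object of class `xhc_tree`: list with `root` (nested node
#'   list), `n`, `m`, `wavelengths` (may be `NULL`), and `params`.
#' @export
grow_tree <- function(X, max_depth = 10L, min_leaf = 100L, seed = 0L,
                      variant = c("as_printed", "law_of_cosines")) {
  variant <- match.arg(variant)
  wavelengths <- NULL
  if (inherits(X, "spectral_matrix")) {
    wavelengths <- X$wavelengths
    X <- X$X
  }
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("cannot grow a tree on an empty matrix")
  stopifnot(max_depth >= 0L, min_leaf >= 1L)

  make_leaf <- function(members, depth) {
    list(type = "leaf", members = members, depth = depth,
         mean = rowMeans(X[, members, drop = FALSE]))
  }
  grow <- function(members, depth) {
    n_node <- length(members)
    if (n_node < 2L * min_leaf || depth >= max_depth)
      return(make_leaf(members, depth))
    Xs <- X[, members, drop = FALSE]
    piv <- choose_pivots(Xs)          # uses the enclosing seeded stream
    if (is.null(piv)) return(make_leaf(members, depth))
    s <- fastmap_project(Xs, piv$a, piv$b, variant)
    sp <- best_split(s)
    if (is.null(sp)) return(make_leaf(members, depth))
    left <- s <= sp$theta
    if (all(left) || !any(left)) return(make_leaf(members, depth))
    rule <- list(pivot_a = Xs[, piv$a], pivot_b = Xs[, piv$b],
                 theta = sp$theta, cost = sp$cost, variant = variant)
    list(type = "internal", rule = rule, size = n_node, depth = depth,
         left = grow(members[left], depth + 1L),
         right = grow(members[!left], depth + 1L))
  }
  root <- with_seed(seed, grow(seq_len(ncol(X)), 0L))
  structure(list(root = root, n = ncol(X), m = nrow(X),
                 wavelengths = wavelengths,
                 params = list(max_depth = as.integer(max_depth),
                               min_leaf = as.integer(min_leaf),
                               seed = as.integer(seed), variant = variant)),
            class = "xhc_tree")
}

walk_leaves <- function(node, fn) {
  if (node$type == "leaf") fn(node)
  else {
    walk_leaves(node$left, fn)
    walk_leaves(node$right, fn)
  }
  invisible(NULL)
}

#' Leaves of a decomposition tree
#'
#' @param tree an `xhc_tree`.
#' @return list of leaf nodes in left-to-right order, each with
#'   `members`, `depth`, `mean`.
#' @export
tree_leaves <- function(tree) {
  out <- list()
  walk_leaves(tree$root, function(l) out[[length(out) + 1L]] <<- l)
  out
}

#' Leaf-mean matrix of one or more trees
#'
#' Collects the mean spectrum of every leaf into the `m x l` matrix on
#' which the pruning k-means runs.
#'
#' @param trees an `xhc_tree` or list of them (subset trees of a
#'   parallel run).
#' @return numeric matrix, one column per leaf, trees in order.
#' @export
leaf_means <- function(trees) {
  if (inherits(trees, "xhc_tree")) trees <- list(trees)
  cols <- lapply(trees, function(tr)
    vapply(tree_leaves(tr), `[[`, numeric(tr$m), "mean"))
  do.call(cbind, cols)
}

#' @export
print.xhc_tree <- function(x, ...) {
  nl <- length(tree_leaves(x))
  dmax <- 0L
  walk_leaves(x$root, function(l) dmax <<- max(dmax, l$depth))
  cat(sprintf(paste0("xhc_tree: %d signatures, %d leaves, depth %d ",
                     "(max_depth %d, min_leaf %d, seed %d, %s)\n"),
              x$n, nl, dmax, x$params$max_depth, x$params$min_leaf,
              x$params$seed, x$params$variant))
  invisible(x)
}
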