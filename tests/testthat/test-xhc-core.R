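test_that("euclidean_dist matches hand values and a loop-based oracle", {
  expect_equal(euclidean_dist(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_dist(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(euclidean_dist(1:3, 1:4), "length")
  withr::local_seed(1)
  for (rep in 1:20) {
    a <- runif(50); b <- runif(50)
    acc <- 0
    for (i in 1:50) acc <- acc + (a[i] - b[i])^2
    expect_equal(euclidean_dist(a, b), sqrt(acc), tolerance = 1e-12)
  }
})

test_that("choose_pivots finds the extreme pair of 1-D points {0, 1, 10}", {
  X <- matrix(c(0, 1, 10), 1)
  # whatever the seeded start, the farthest-point steps must end on the
  # extreme pair: b farthest from start, a farthest from b
  for (seed in 1:12) {
    p <- choose_pivots(X, seed = seed)
    if (p$start == 2L) {          # the spec'd walk-through: 1 -> 10 -> 0
      expect_equal(p$b, 3L)
      expect_equal(p$a, 1L)
    }
    expect_setequal(c(p$a, p$b), c(1L, 3L))
  }
})

test_that("two distinct points are their own pivots for any start", {
  X <- matrix(c(0, 0, 1, 1), 2)
  for (seed in 1:6) {
    p <- choose_pivots(X, seed = seed)
    expect_setequal(c(p$a, p$b), c(1L, 2L))
  }
})

test_that("pivot distance dominates all distances from start and from b", {
  withr::local_seed(5)
  for (rep in 1:25) {
    n <- sample(3:50, 1)
    X <- matrix(runif(8 * n), 8, n)
    p <- choose_pivots(X, seed = rep)
    D <- as.matrix(dist(t(X)))
    dab <- D[p$a, p$b]
    expect_gte(dab, max(D[p$start, ]) - 1e-12)
    expect_gte(dab, max(D[p$b, ]) - 1e-12)
  }
})

test_that("identical points yield a degenerate-pivot signal", {
  X <- matrix(1, 4, 10)
  expect_null(choose_pivots(X, seed = 1))
})

test_that("fastmap projections match hand-evaluated values", {
  a <- c(0, 0); b <- c(4, 0)
  X <- cbind(a, b, c(2, 0))
  as_printed <- fastmap_project(X, a, b, "as_printed")
  law <- fastmap_project(X, a, b, "law_of_cosines")
  expect_equal(as_printed, c(0, 1, 0.5), ignore_attr = TRUE)
  expect_equal(law, c(0, 4, 2), ignore_attr = TRUE)
  expect_error(fastmap_project(X, a, a), "coincident")
})

test_that("as_printed projections stay in [0, 1] on random node subsets", {
  withr::local_seed(11)
  for (rep in 1:30) {
    n <- sample(5:80, 1)
    X <- matrix(rnorm(12 * n), 12, n)
    p <- choose_pivots(X, seed = rep)
    s <- fastmap_project(X, p$a, p$b)
    expect_equal(s[p$a], 0)
    expect_equal(s[p$b], 1)
    expect_true(all(s >= -1e-9 & s <= 1 + 1e-9))
  }
})

test_that("best_split reproduces hand-worked examples and tie rules", {
  sp <- best_split(c(0, 0, 10, 10))
  expect_equal(sp, list(i = 2L, theta = 5, cost = 0))
  sp2 <- best_split(c(1, 0))           # sorting is internal
  expect_equal(sp2, list(i = 1L, theta = 0.5, cost = 0))
  expect_null(best_split(rep(3, 7)))   # constant projections: degenerate
  # symmetric input with two equally good splits: smallest i wins
  sp3 <- best_split(c(0, 0, 1, 1))
  expect_equal(sp3$i, 2L)
})

test_that("best_split agrees with the exhaustive direct-summation oracle", {
  withr::local_seed(99)
  for (rep in 1:200) {
    n <- sample(2:120, 1)
    s <- switch(sample(3, 1),
                runif(n, -5, 5),
                rnorm(n),
                sample(0:5, n, replace = TRUE) + 0)
    if (length(unique(s)) == 1L) next
    got <- best_split(s)
    exp <- split_oracle(s)
    expect_equal(got$i, exp$i)
    expect_equal(got$theta, exp$theta)
    expect_equal(got$cost, exp$cost, tolerance = 1e-9)
  }
})

test_that("small or degenerate nodes become single-leaf trees", {
  withr::local_seed(2)
  X <- matrix(runif(10 * 30), 10, 30)
  tr <- grow_tree(X, min_leaf = 20)    # 30 < 2 * 20
  expect_equal(tr$root$type, "leaf")
  expect_equal(tr$root$members, 1:30)
  expect_equal(tr$root$mean, rowMeans(X))
  same <- matrix(5, 4, 500)            # identical columns, any size
  tr2 <- grow_tree(same, min_leaf = 10)
  expect_equal(tr2$root$type, "leaf")
  expect_error(grow_tree(matrix(numeric(0), 3, 0)), "empty")
})

test_that("tree leaves partition the columns and respect the guards", {
  bl <- blob_matrix(g = 3, n_per = 80, seed = 3)
  tr <- grow_tree(bl$X, max_depth = 6, min_leaf = 10, seed = 1)
  leaves <- tree_leaves(tr)
  members <- sort(unlist(lapply(leaves, `[[`, "members")))
  expect_equal(members, seq_len(ncol(bl$X)))          # disjoint + exhaustive
  expect_true(all(vapply(leaves, `[[`, 0L, "depth") <= 6))
  # every internal node that split held at least 2 * min_leaf members
  check_sizes <- function(node) {
    if (node$type == "internal") {
      expect_gte(node$size, 2 * 10)
      check_sizes(node$left); check_sizes(node$right)
    }
  }
  check_sizes(tr$root)
  # left/right sizes always sum to the parent size
  check_sum <- function(node) {
    if (node$type == "internal") {
      ls <- if (node$left$type == "leaf") length(node$left$members) else node$left$size
      rs <- if (node$right$type == "leaf") length(node$right$members) else node$right$size
      expect_equal(ls + rs, node$size)
      check_sum(node$left); check_sum(node$right)
    }
  }
  check_sum(tr$root)
})

test_that("well-separated groups give pure leaves at shallow depth", {
  bl <- blob_matrix(g = 3, n_per = 100, sep = 8, noise = 0.02, seed = 4)
  tr <- grow_tree(bl$X, max_depth = 4, min_leaf = 5, seed = 0)
  for (leaf in tree_leaves(tr)) {
    tab <- table(bl$labels[leaf$members])
    expect_gte(max(tab) / sum(tab), 0.99)
  }
})

test_that("tree growth is deterministic and refines with depth", {
  bl <- blob_matrix(seed = 6)
  t1 <- grow_tree(bl$X, max_depth = 5, min_leaf = 8, seed = 3)
  t2 <- grow_tree(bl$X, max_depth = 5, min_leaf = 8, seed = 3)
  expect_identical(t1, t2)
  n_leaves <- vapply(c(0, 1, 2, 4, 6), function(d)
    length(tree_leaves(grow_tree(bl$X, max_depth = d, min_leaf = 8, seed = 3))),
    integer(1))
  expect_true(all(diff(n_leaves) >= 0))
})

test_that("prune_to_k keeps distinct leaf means when l == k, averages when k == 1", {
  withr::local_seed(12)
  Y <- matrix(runif(20 * 5), 20, 5)
  mod <- prune_to_k(Y, k = 5, seed = 1)
  # each representative is one of the leaf means, all recovered
  got <- apply(mod$representatives, 2, function(r)
    min(apply(Y, 2, function(y) euclidean_dist(y, r))))
  expect_equal(max(got), 0)
  expect_equal(nrow(unique(t(mod$representatives))), 5)
  one <- prune_to_k(Y, k = 1, seed = 1)
  expect_equal(drop(one$representatives), rowMeans(Y))
  expect_error(prune_to_k(Y, k = 6), "deepen the tree")
})

test_that("pruning k-means recovers tight blob centres", {
  bl <- blob_matrix(g = 4, n_per = 12, sep = 10, noise = 0.01, seed = 8)
  mod <- prune_to_k(bl$X, k = 4, seed = 2)
  for (g in 1:4) {
    d <- min(apply(mod$representatives, 2, function(r)
      euclidean_dist(r, bl$centers[, g])))
    expect_lt(d, 0.05)   # within noise scale of the true centre
  }
})

test_that("assignment picks the nearest representative with low-index ties", {
  withr::local_seed(13)
  R <- matrix(runif(10 * 4), 10, 4)
  model <- structure(list(representatives = R, k = 4L, wavelengths = NULL,
                          params = list()), class = "xhc_model")
  expect_equal(assign_clusters(R, model), 1:4)
  # a point exactly between representatives 2 and 3 gets the lower id
  mid <- (R[, 2] + R[, 3]) / 2
  expect_equal(assign_clusters(matrix(mid), model), 2L)
  # exhaustive distance-table oracle on random columns
  X <- matrix(runif(10 * 60), 10, 60)
  lab <- assign_clusters(X, model)
  for (j in 1:60) {
    d <- apply(R, 2, function(r) euclidean_dist(X[, j], r))
    expect_equal(lab[j], which.min(d))
  }
  expect_error(assign_clusters(matrix(1, 3, 2), model), "does not match")
})

test_that("Lloyd k-means satisfies its basic contracts", {
  withr::local_seed(14)
  X <- matrix(runif(6 * 40), 6, 40)
  one <- kmeans_lloyd(X, k = 1, seed = 0)
  expect_equal(drop(one$centers), rowMeans(X))
  # duplicated blob points converge immediately to blob means
  P <- matrix(runif(6 * 3), 6, 3) * 5
  Xb <- P[, rep(1:3, each = 7)]
  km <- kmeans_lloyd(Xb, k = 3, seed = 1)
  expect_true(km$converged)
  expect_lte(km$iterations, 3)
  expect_equal(sort(apply(km$centers, 2, min)), sort(apply(P, 2, min)))
  expect_error(kmeans_lloyd(matrix(1, 2, 5), k = 2), "distinct")
  expect_error(kmeans_lloyd(X[, 1:3], k = 4), "fewer points")
})

test_that("within-cluster sum of squares never increases across iterations", {
  for (seed in 1:5) {
    X <- withr::with_seed(seed, matrix(rnorm(8 * 150), 8, 150))
    km <- kmeans_lloyd(X, k = 4, seed = seed)
    expect_true(all(diff(km$wss) <= 1e-9))
  }
})

test_that("our Lloyd solution matches stats::kmeans run from the same start", {
  bl <- blob_matrix(g = 3, n_per = 40, sep = 6, noise = 0.05, seed = 9)
  km <- kmeans_lloyd(bl$X, k = 3, seed = 0)
  ref <- stats::kmeans(t(bl$X), centers = t(km$centers),
                       algorithm = "Lloyd", iter.max = 1000)
  expect_equal(unname(t(ref$centers)), km$centers, tolerance = 1e-9)
  expect_equal(unname(ref$cluster), km$labels)
})

test_that("parallel merge with one subset equals the serial fit bit-for-bit", {
  sc <- std_scene(seed = 2)
  sm <- scene_matrix(sc)
  serial <- xhc_fit(sm$X, k = 3, min_leaf = 50, seed = 5)
  par1 <- xhc_parallel(list(sm$X), k = 3, min_leaf = 50, seed = 5)
  expect_identical(serial$representatives, par1$representatives)
})

test_that("splitting the data in two subsets preserves the clustering", {
  sc <- std_scene(seed = 3)
  sm <- scene_matrix(sc)
  n <- ncol(sm$X$X)
  half <- seq_len(n %/% 2)
  a <- spectral_matrix(sm$X$X[, half], sm$X$wavelengths)
  b <- spectral_matrix(sm$X$X[, -half], sm$X$wavelengths)
  serial <- xhc_fit(sm$X, k = 3, min_leaf = 50, seed = 1)
  par2 <- xhc_parallel(list(a, b), k = 3, min_leaf = 25, seed = 1)
  expect_gte(ari(assign_clusters(sm$X, serial), assign_clusters(sm$X, par2)),
             0.95)
  # subset order must not matter: Y is the same set of leaf means, and
  # the canonicalised representatives are bit-identical
  par2r <- xhc_parallel(list(b, a), k = 3, min_leaf = 25, seed = 1)
  expect_identical(par2$representatives, par2r$representatives)
})

test_that("quantify_clusters counts labelled in-ROI pixels and conserves totals", {
  lab <- matrix(NA_integer_, 6, 6)
  lab[1:2, 1:5] <- 3L
  lab[4, 1:4] <- 1L
  map <- structure(list(labels = lab, k = 3L, image = "t"),
                   class = "cluster_map")
  q <- quantify_clusters(map)
  expect_equal(q$pixels[3], 10)
  expect_equal(q$pixels[1], 4)
  expect_equal(q$pixels[2], 0)
  expect_equal(attr(q, "total_labelled"), sum(!is.na(lab)))
  # an ROI that excludes all label-3 pixels
  roi <- pixel_mask(matrix(c(TRUE, TRUE, rep(FALSE, 4)), 6, 6), "roi")
  q2 <- quantify_clusters(map, roi)
  expect_equal(q2$pixels[3], 0)
  expect_equal(sum(q2$pixels), attr(q2, "total_labelled"))
})

test_that("models survive a JSON round trip", {
  sc <- std_scene(seed = 1)
  sm <- scene_matrix(sc)
  mod <- xhc_fit(sm$X, k = 3, min_leaf = 50, seed = 0)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(mod, f)
  back <- read_model(f)
  expect_equal(back$representatives, mod$representatives, ignore_attr = TRUE)
  expect_equal(back$k, mod$k)
  expect_equal(assign_clusters(sm$X, back), assign_clusters(sm$X, mod))
})
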