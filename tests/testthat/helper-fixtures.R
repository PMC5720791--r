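# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so the suite is deterministic.

# small random cube with float32-representable values (exact ENVI round trips)
random_cube <- function(rows = 4, cols = 5, bands = 3, seed = 1) {
  withr::with_seed(seed, {
    vals <- array(sample.int(4096L, rows * cols * bands, replace = TRUE) / 1024,
                  c(rows, cols, bands))
    spectral_cube(vals, seq(450, by = 10, length.out = bands))
  })
}

# n points drawn from g well-separated spectral blobs; returns matrix + labels
blob_matrix <- function(g = 3, n_per = 60, m = 40, sep = 5, noise = 0.05,
                        seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(stats::runif(m * g), m, g) * sep
    lab <- rep(seq_len(g), each = n_per)
    X <- centers[, lab] + matrix(stats::rnorm(m * g * n_per, sd = noise),
                                 m, g * n_per)
    list(X = X, labels = lab, centers = centers)
  })
}

# exhaustive evaluator of the split cost at every index, by direct summation
split_oracle <- function(s) {
  s <- sort(s)
  n <- length(s)
  cost <- vapply(seq_len(n - 1L), function(i) {
    left <- s[seq_len(i)]; right <- s[(i + 1L):n]
    sum((left - mean(left))^2) / i + sum((right - mean(right))^2) / (n - i)
  }, numeric(1))
  i <- which.min(cost)
  list(i = i, theta = (s[i] + s[i + 1L]) / 2, cost = cost[i])
}

# ground-truth tissue labels aligned to the columns of a signature matrix
truth_for_matrix <- function(X, truth) {
  truth$labels[cbind(X$pixel_index$row, X$pixel_index$col)]
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# fast standard synthetic scene used across clustering tests
std_scene <- function(seed = 1, ...) {
  make_wound_cube(scene_spec(seed = seed, ...))
}

# preprocess a synthetic reflectance cube and return the signature matrix
scene_matrix <- function(scene) {
  pp <- preprocess_cube(scene$cube)
  X <- cube_to_matrix(pp$cube, pp$mask)
  list(X = X, mask = pp$mask, cube = pp$cube,
       truth_labels = truth_for_matrix(X, scene$truth))
}
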