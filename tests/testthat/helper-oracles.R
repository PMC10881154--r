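# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# KS statistic by explicit scan of both ECDFs over every breakpoint
ks_D_scan <- function(x, y) {
  br <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x); Fy <- stats::ecdf(y)
  max(abs(Fx(br) - Fy(br)))
}

# straight-loop randomization score using stats::ks.test and plain
# sequential seeding (a different generator stream from the package's
# hashed substreams)
rand_score_straight_loop <- function(angles, n_reps, alpha, seed, null_size = length(angles)) {
  p <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(seed * 1000003L + i)
    y <- runif(null_size, 0, 90)
    p[i] <- suppressWarnings(stats::ks.test(angles, y)$p.value)
  }
  100 * sum(p > alpha) / n_reps
}

# numeric arc length of y = f(x) on [0, span]
arc_length_numeric <- function(f, span, eps = 1e-4) {
  g <- function(x) sqrt(1 + ((f(x + eps) - f(x - eps)) / (2 * eps))^2)
  stats::integrate(g, 0, span, subdivisions = 2000L)$value
}

# random rigid motion applied to a set of 2-D points (rows)
apply_rigid <- function(pts, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(pts %*% t(R), 2, -shift)
}

rotate_vec <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

# fresh scratch directory for io round-trip tests
withr_like_tempdir <- function() {
  d <- tempfile("epispindle-test-")
  dir.create(d)
  d
}
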