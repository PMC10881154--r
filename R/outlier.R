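#' Gaussian-simulation outlier test for rare-event frequencies
#'
#' Estimates the probability that a group of `k_draws` animals drawn from a
#' reference Gaussian (mean and SD of a comparison genotype's per-animal
#' frequencies) would contain at least one value above `threshold`. The
#' estimate is the fraction of `n_sim` simulated groups with a value above
#' the threshold; the closed form `1 - pnorm(threshold, mean, sd)^k` is
#' reported alongside as an analytic companion.
#'
#' @param ref_mean,ref_sd mean and standard deviation of the reference
#'   frequencies (events/µm); `ref_sd` must be non-negative.
#' @param threshold frequency threshold in events/µm. The threshold is a
#'   mandatory explicit parameter of the test.
#' @param k_draws number of values per simulated group (default 6).
#' @param n_sim number of simulated groups (default 10000).
#' @param seed integer seed.
#' @return `outlier_test_result` with `probability` (Monte-Carlo),
#'   `probability_analytic`, `mc_se`, and the parameters used.
#' @export
gaussian_outlier_probability <- function(ref_mean, ref_sd, threshold,
                                         k_draws = 6, n_sim = 10000, seed = 1) {
  stopifnot_scalar_number(ref_mean, "ref_mean")
  stopifnot_scalar_number(ref_sd, "ref_sd")
  stopifnot_scalar_number(threshold, "threshold")
  if (ref_sd < 0) stop("ref_sd must be >= 0", call. = FALSE)
  if (k_draws < 1 || n_sim < 1) stop("k_draws and n_sim must be >= 1", call. = FALSE)
  if (ref_sd == 0) {
    analytic <- as.numeric(ref_mean > threshold)
    prob <- analytic
  } else {
    analytic <- 1 - stats::pnorm(threshold, ref_mean, ref_sd)^k_draws
    set.seed(substream_seed(seed, 0))
    draws <- matrix(stats::rnorm(n_sim * k_draws, ref_mean, ref_sd), nrow = n_sim)
    prob <- mean(apply(draws, 1, max) > threshold)
  }
  structure(list(probability = prob,
                 probability_analytic = analytic,
                 mc_se = sqrt(analytic * (1 - analytic) / n_sim),
                 k_draws = as.integer(k_draws), n_sim = as.integer(n_sim),
                 threshold = threshold, ref_mean = ref_mean, ref_sd = ref_sd,
                 seed = as.integer(seed)),
            class = "outlier_test_result")
}

#' @export
print.outlier_test_result <- function(x, ...) {
  cat(sprintf("outlier test: P(any of %d draws from N(%.4g, %.4g) > %.4g)\n",
              x$k_draws, x$ref_mean, x$ref_sd, x$threshold))
  cat(sprintf("  Monte-Carlo %.4f (n_sim = %d), analytic %.4f\n",
              x$probability, x$n_sim, x$probability_analytic))
  invisible(x)
}

#' Flag animals whose rare-event frequency exceeds a threshold
#'
#' Fits the reference Gaussian from the comparison genotype's per-animal
#' frequencies, runs [gaussian_outlier_probability()] with `k_draws` equal to
#' the size of the tested group, and flags the tested animals above the
#' threshold.
#'
#' @param frequencies per-animal event frequencies of the tested group.
#' @param reference per-animal frequencies of the comparison genotype; at
#'   least two animals so the SD is defined.
#' @param threshold frequency threshold (events/µm), explicit.
#' @param n_sim,seed forwarded to [gaussian_outlier_probability()].
#' @return list with `flags` (logical, per tested animal), `n_flagged` and
#'   `test` (the `outlier_test_result`).
#' @export
flag_outlier_animals <- function(frequencies, reference, threshold,
                                 n_sim = 10000, seed = 1) {
  if (length(reference) < 2L)
    stop("reference group must contain >= 2 animals for the SD to be defined", call. = FALSE)
  if (length(frequencies) < 1L) stop("no tested animals", call. = FALSE)
  test <- gaussian_outlier_probability(mean(reference), stats::sd(reference),
                                       threshold, k_draws = length(frequencies),
                                       n_sim = n_sim, seed = seed)
  flags <- frequencies > threshold
  list(flags = flags, n_flagged = sum(flags), test = test)
}
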