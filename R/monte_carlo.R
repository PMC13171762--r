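#' Monte Carlo settings
#'
#' @param n_draws Number of random draws of the brood-set statistic
#'   (default 500000).
#' @param ci_level Confidence-interval coverage in (0, 1) (default 0.95).
#' @param seed Integer seed; every call with the same seed reproduces the
#'   same result exactly.
#' @param statistic `"mean_of_proportions"` (default; unweighted mean of
#'   per-brood undeveloped proportions) or `"pooled"` (total undeveloped
#'   over total eggs).
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n_draws = 500000L, ci_level = 0.95, seed = 1L,
                      statistic = c("mean_of_proportions", "pooled")) {
  stopifnot(n_draws >= 1, ci_level > 0, ci_level < 1)
  structure(list(n_draws = as.integer(n_draws), ci_level = ci_level,
                 seed = as.integer(seed), statistic = match.arg(statistic)),
            class = "mc_config")
}

#' Monte Carlo distribution of the undeveloped-egg proportion
#'
#' Simulates the sampling distribution of the mean undeveloped-egg
#' proportion for a set of broods with fixed egg counts. In every draw each
#' brood's maternal karyotype is sampled afresh (X0 with probability
#' `q_x0`), its undeveloped count is binomial with per-egg failure
#' `0.25 + 0.75*b` (X0) or `b` (XX), and the statistic is computed across
#' broods. Redrawing karyotypes each draw propagates karyotype uncertainty
#' into the interval. The CI is the pair of empirical `(1-level)/2` and
#' `1-(1-level)/2` quantiles (type 7, linear interpolation between order
#' statistics).
#'
#' @param egg_counts Integer vector of per-brood egg totals, all >= 1.
#' @param q_x0 Probability a brood's mother is feminized X0.
#' @param b Background per-egg failure probability.
#' @param config An [mc_config()].
#' @return A list of class `mc_result` with `samples`, `mean`, `ci_lo`,
#'   `ci_hi`, and the inputs used.
#' @export
simulate_undeveloped_distribution <- function(egg_counts, q_x0, b, config) {
  stopifnot(inherits(config, "mc_config"))
  if (length(egg_counts) == 0L) stop("egg_counts must contain at least one brood")
  stopifnot(all(egg_counts >= 1))
  stopifnot(q_x0 >= 0, q_x0 <= 1, b >= 0, b <= 1)

  mm <- mortality_model(min(b, 1 - 1e-12))
  n_b <- length(egg_counts)
  n_draws <- config$n_draws
  pooled <- config$statistic == "pooled"
  total_eggs <- sum(egg_counts)

  set.seed(config$seed)
  samples <- numeric(n_draws)
  chunk <- max(1L, min(n_draws, as.integer(2e6 / n_b)))
  done <- 0L
  while (done < n_draws) {
    k <- min(chunk, n_draws - done)
    m <- k * n_b
    is_x0 <- stats::runif(m) < q_x0
    p_fail <- ifelse(is_x0, mm$e_x0, mm$e_xx)
    undev <- stats::rbinom(m, size = rep(egg_counts, k), prob = p_fail)
    if (pooled) {
      stat <- colSums(matrix(undev, nrow = n_b)) / total_eggs
    } else {
      stat <- colMeans(matrix(undev / rep(egg_counts, k), nrow = n_b))
    }
    samples[(done + 1L):(done + k)] <- stat
    done <- done + k
  }

  alpha <- (1 - config$ci_level) / 2
  qs <- stats::quantile(samples, probs = c(alpha, 1 - alpha),
                        names = FALSE, type = 7)
  structure(list(samples = samples, mean = mean(samples),
                 ci_lo = qs[1L], ci_hi = qs[2L],
                 n_draws = n_draws, ci_level = config$ci_level,
                 q_x0 = q_x0, b = b, egg_counts = egg_counts,
                 statistic = config$statistic, seed = config$seed),
            class = "mc_result")
}

#' Does an observed mean fall inside the Monte Carlo interval?
#'
#' @param observed_mean Observed mean proportion of undeveloped eggs.
#' @param result An `mc_result` from [simulate_undeveloped_distribution()].
#' @return `TRUE` iff `ci_lo <= observed_mean <= ci_hi`.
#' @export
observed_within_ci <- function(observed_mean, result) {
  stopifnot(inherits(result, "mc_result"))
  observed_mean >= result$ci_lo && observed_mean <= result$ci_hi
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo undeveloped-egg proportion (%d draws, %d broods)\n",
    x$n_draws, length(x$egg_counts)))
  cat(sprintf("  mean = %.4f, %g%% CI [%.4f, %.4f]\n",
              x$mean, 100 * x$ci_level, x$ci_lo, x$ci_hi))
  invisible(x)
}
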