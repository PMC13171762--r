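#' Per-egg mortality model
#'
#' Background (non-feminization) egg failure occurs with probability `b`
#' for every egg. X0 mothers additionally lose the OO quarter of their
#' eggs, and the two sources compose multiplicatively, so
#' `e_x0 = 1 - 0.75 * (1 - b) = 0.25 + 0.75 * b` while `e_xx = b`.
#'
#' @param b Background per-egg failure probability in \[0, 1).
#' @return A list of class `mortality_model` with `b`, `e_xx`, `e_x0`.
#' @export
mortality_model <- function(b) {
  stopifnot(is.numeric(b), length(b) == 1L, b >= 0, b < 1)
  structure(list(b = b, e_xx = b, e_x0 = 0.25 + 0.75 * b),
            class = "mortality_model")
}

#' Pooled baseline egg mortality from non-feminized broods
#'
#' Estimates the background per-egg failure probability as total
#' undeveloped eggs over total eggs across the supplied broods (a pooled
#' per-egg rate, which is what the multiplicative composition in
#' [expected_undeveloped()] requires). Set `method = "mean"` for the
#' mean-of-per-brood-proportions variant (sensitivity analysis only).
#'
#' @param broods Data frame with columns `eggs_laid` and `eggs_undeveloped`,
#'   restricted to non-feminized symbiotypes and already filtered by
#'   [apply_exclusions()].
#' @param method `"pooled"` (default) or `"mean"`.
#' @return Estimated baseline probability in \[0, 1\].
#' @export
baseline_mortality <- function(broods, method = c("pooled", "mean")) {
  method <- match.arg(method)
  if (is.null(broods) || nrow(broods) == 0L) {
    stop("no broods supplied for baseline mortality")
  }
  stopifnot(all(c("eggs_laid", "eggs_undeveloped") %in% names(broods)))
  total <- sum(broods$eggs_laid)
  if (total <= 0) stop("zero total eggs; cannot estimate baseline mortality")
  if (method == "pooled") {
    sum(broods$eggs_undeveloped) / total
  } else {
    keep <- broods$eggs_laid > 0
    mean(broods$eggs_undeveloped[keep] / broods$eggs_laid[keep])
  }
}

#' Expected proportion of undeveloped eggs
#'
#' Mixture of X0 mothers (fraction `q_x0`, per-egg failure `0.25 + 0.75*b`)
#' and XX mothers (failure `b`):
#' \deqn{E = 1 - (1 - 0.25\,q_{X0})(1 - b)}
#' identical to `q_x0 * e_x0 + (1 - q_x0) * e_xx`.
#'
#' @param q_x0 Equilibrium fraction of feminized X0 mothers, in \[0, 1\].
#' @param b Background per-egg failure probability, in \[0, 1\].
#' @return Expected undeveloped proportion, bounded in `[b, 0.25 + 0.75*b]`.
#' @export
expected_undeveloped <- function(q_x0, b) {
  stopifnot(is.numeric(q_x0), all(q_x0 >= 0 & q_x0 <= 1))
  stopifnot(is.numeric(b), all(b >= 0 & b <= 1))
  1 - (1 - 0.25 * q_x0) * (1 - b)
}

#' Expected undeveloped proportions per feminizing symbiotype
#'
#' Chains [solve_equilibrium()] and [expected_undeveloped()] for each
#' symbiotype's feminization success rate.
#'
#' @param phi_per_symbiotype Named numeric vector of `phi` values, one per
#'   feminizing symbiotype; each in (0, 1\].
#' @param b Background per-egg failure probability.
#' @param rho Relative fecundity of X0 versus XX mothers.
#' @return Data frame with columns `symbiotype`, `phi`, `q_x0`,
#'   `expected_undeveloped`.
#' @export
expectations_for_symbiotypes <- function(phi_per_symbiotype, b, rho = 1) {
  stopifnot(length(phi_per_symbiotype) >= 1L,
            !is.null(names(phi_per_symbiotype)))
  rows <- lapply(names(phi_per_symbiotype), function(s) {
    phi <- phi_per_symbiotype[[s]]
    eq <- solve_equilibrium(feminization_params(phi = phi, rho = rho))
    data.frame(symbiotype = s, phi = phi, q_x0 = eq$q_x0,
               expected_undeveloped = expected_undeveloped(eq$q_x0, b))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
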