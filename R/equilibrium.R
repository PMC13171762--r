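#' One generation of the infected-female karyotype recursion
#'
#' Among infected females, let `x` be the fraction that are genetic XX.
#' XX mothers produce XX daughters at rate 1/2 per egg and feminized X0
#' daughters at rate `phi/2`; infected X0 mothers produce XX daughters at
#' rate 1/4, feminized X0 daughters at rate `phi/2`, and 1/4 inviable OO
#' zygotes. X0 mothers lay `rho` times as many eggs as XX mothers. The
#' next-generation XX fraction is XX-daughter production over total
#' daughter production:
#' \deqn{x' = \frac{x/2 + \rho(1-x)/4}{x(1/2+\phi/2) + \rho(1-x)(1/4+\phi/2)}}
#'
#' @param x_xx Current fraction of infected adult females that are XX.
#' @param params A [feminization_params()].
#' @return Next-generation XX fraction, in \[0,1\].
#' @export
recursion_step <- function(x_xx, params) {
  stopifnot(inherits(params, "feminization_params"))
  stopifnot(is.numeric(x_xx), x_xx >= 0, x_xx <= 1)
  phi <- params$phi
  rho <- params$rho
  if (phi == 0 && x_xx == 0) {
    # with zero feminization no X0 individual is female, so an all-X0
    # infected-female population cannot exist
    stop("degenerate input: no infected females produced (phi = 0 and x_xx = 0)")
  }
  num <- x_xx / 2 + rho * (1 - x_xx) / 4
  den <- x_xx * (1 / 2 + phi / 2) + rho * (1 - x_xx) * (1 / 4 + phi / 2)
  if (den <= .Machine$double.eps) {
    stop("degenerate input: no daughter production")
  }
  num / den
}

#' Equilibrium XX/X0 composition of infected females
#'
#' Solves the fixed point of [recursion_step()]. The fixed-point condition
#' is a quadratic in `x`; for `rho = 1` it reduces to
#' `x^2 + 2*phi*x - 1 = 0` with admissible root
#' `x* = -phi + sqrt(phi^2 + 1)`. The closed-form root is cross-checked
#' against fixed-point iteration started from `x = 0.5`.
#'
#' @param params A [feminization_params()] with `phi` in (0, 1\].
#' @param tol Convergence tolerance for the fixed-point residual.
#' @return A list of class `equilibrium_state` with `x_xx` (equilibrium XX
#'   fraction) and `q_x0 = 1 - x_xx` (feminized X0 fraction).
#' @export
solve_equilibrium <- function(params, tol = 1e-10) {
  stopifnot(inherits(params, "feminization_params"))
  stopifnot(tol > 0)
  phi <- params$phi
  rho <- params$rho
  if (phi <= 0) stop("phi must be in (0, 1] for an equilibrium with infected females")

  # x * D(x) - N(x) = a x^2 + b x + c = 0
  a <- (1 + phi) / 2 - rho * (1 / 4 + phi / 2)
  b <- rho * (1 / 4 + phi / 2) - 1 / 2 + rho / 4
  cc <- -rho / 4
  if (abs(a) < 1e-14) {
    roots <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("no real fixed point for the supplied parameters")
    roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
  }
  adm <- roots[roots >= -tol & roots <= 1 + tol]
  if (length(adm) == 0L) stop("no fixed point in [0, 1] for the supplied parameters")
  x_star <- min(max(adm[1L], 0), 1)

  if (abs(recursion_step(x_star, params) - x_star) >= max(tol, 1e-12)) {
    stop("closed-form root failed the fixed-point residual check")
  }
  structure(list(x_xx = x_star, q_x0 = 1 - x_star), class = "equilibrium_state")
}

#' Fixed-point iteration of the karyotype recursion
#'
#' Verification path for [solve_equilibrium()]: iterates
#' [recursion_step()] from a starting value until successive iterates
#' differ by less than `tol` or `max_iter` is reached.
#'
#' @param params A [feminization_params()].
#' @param x0 Starting XX fraction.
#' @param tol Convergence tolerance on successive iterates.
#' @param max_iter Iteration cap.
#' @return The converged XX fraction.
#' @export
iterate_equilibrium <- function(params, x0 = 0.5, tol = 1e-12, max_iter = 10000L) {
  x <- x0
  for (i in seq_len(max_iter)) {
    x_new <- recursion_step(x, params)
    if (abs(x_new - x) < tol) return(x_new)
    x <- x_new
  }
  x
}

#' Expected male fraction among viable offspring of infected mothers
#'
#' Feminization failure turns X0 offspring of infected mothers into males:
#' each mother's eggs yield X0 offspring with probability 1/2, male with
#' probability `1 - phi`. Viable output per egg is 1 for XX mothers and 3/4
#' for X0 mothers (the OO quarter is inviable).
#'
#' @param state An `equilibrium_state` from [solve_equilibrium()].
#' @param params A [feminization_params()].
#' @return Proportion of viable adult offspring that are male; 0 when
#'   `phi = 1`, at most 0.5 for `rho = 1`.
#' @export
expected_male_fraction <- function(state, params) {
  stopifnot(inherits(state, "equilibrium_state"))
  stopifnot(inherits(params, "feminization_params"))
  x <- state$x_xx
  phi <- params$phi
  rho <- params$rho
  num <- x * (1 - phi) / 2 + rho * (1 - x) * (1 - phi) / 2
  den <- x + rho * (1 - x) * (3 / 4)
  num / den
}

#' Estimate feminization success from an observed brood sex ratio
#'
#' Inverts the composition [expected_male_fraction()] after
#' [solve_equilibrium()]: the equilibrium male fraction is continuous and
#' strictly decreasing in `phi` (0.5 as `phi -> 0`, 0 at `phi = 1`), so the
#' observed adult male fraction identifies `phi` by bisection on \[0, 1\].
#'
#' @param observed_male_fraction Observed proportion of males among viable
#'   adult offspring of infected mothers; must be in \[0, 0.5).
#' @param rho Relative fecundity of X0 versus XX mothers.
#' @param tol Bisection tolerance on `phi`.
#' @return A [feminization_params()] with the estimated `phi`.
#' @export
estimate_phi_from_sex_ratio <- function(observed_male_fraction, rho = 1,
                                        tol = 1e-8) {
  m <- observed_male_fraction
  stopifnot(is.numeric(m), length(m) == 1L)
  if (m < 0 || m >= 0.5) {
    stop("observed male fraction must be in [0, 0.5) for a feminizer at equilibrium")
  }
  if (m == 0) return(feminization_params(phi = 1, rho = rho))

  g <- function(phi) {
    p <- feminization_params(phi = phi, rho = rho)
    expected_male_fraction(solve_equilibrium(p), p) - m
  }
  lo <- 1e-9
  hi <- 1
  g_lo <- g(lo)
  g_hi <- g(hi)
  if (g_lo < 0 || g_hi > 0) {
    stop("male fraction not monotone on [0,1] for these parameters; cannot bisect")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  feminization_params(phi = (lo + hi) / 2, rho = rho)
}
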