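test_that("recursion step matches direct enumeration via offspring classes", {
  # all-XX mothers with perfect feminization: daughters 1/2 XX + 1/2 X0
  p <- feminization_params(phi = 1)
  expect_equal(recursion_step(1, p), 0.5)

  # general check against offspring_distribution-derived daughter rates
  for (phi in c(0.3, 0.7, 0.95)) {
    p <- feminization_params(phi = phi)
    dxx <- offspring_distribution("XX", TRUE, p)
    dx0 <- offspring_distribution("X0", TRUE, p)
    rate <- function(d, k) sum(d$prob[d$karyotype == k & d$fate == "female"])
    for (x in c(0.1, 0.5, 0.9)) {
      num <- x * rate(dxx, "XX") + (1 - x) * rate(dx0, "XX")
      den <- x * (rate(dxx, "XX") + rate(dxx, "X0")) +
        (1 - x) * (rate(dx0, "XX") + rate(dx0, "X0"))
      expect_equal(recursion_step(x, p), num / den, tolerance = 1e-12)
    }
  }
})

test_that("recursion maps [0,1] into [0,1] and handles degenerate input", {
  for (phi in seq(0.05, 1, by = 0.05)) {
    for (rho in c(0.1, 1, 5, 10)) {
      p <- feminization_params(phi = phi, rho = rho)
      for (x in seq(0, 1, by = 0.1)) {
        r <- recursion_step(x, p)
        expect_gte(r, 0)
        expect_lte(r, 1)
      }
    }
  }
  expect_equal(recursion_step(0.3, feminization_params(phi = 0)), 1)
  expect_error(recursion_step(0, feminization_params(phi = 0)), "degenerate")
})

test_that("equilibrium matches the quadratic root and fixed-point iteration", {
  # phi = 1: positive root of x^2 + 2x - 1 = 0
  eq <- solve_equilibrium(feminization_params(phi = 1))
  expect_equal(eq$x_xx, sqrt(2) - 1, tolerance = 1e-10)
  expect_equal(eq$x_xx + eq$q_x0, 1)

  # phi = 0.9: positive root of x^2 + 1.8x - 1 = 0
  eq9 <- solve_equilibrium(feminization_params(phi = 0.9))
  expect_equal(eq9$x_xx, -0.9 + sqrt(0.9^2 + 1), tolerance = 1e-10)
  expect_equal(eq9$x_xx, 0.44536, tolerance = 1e-4)

  # closed form vs 10,000-step independent iteration, across phi and rho
  for (phi in c(0.2, 0.6, 0.85, 1)) {
    for (rho in c(0.8, 1, 1.5)) {
      p <- feminization_params(phi = phi, rho = rho)
      x <- 0.5
      for (i in 1:10000) x <- recursion_step(x, p)
      expect_equal(solve_equilibrium(p)$x_xx, x, tolerance = 1e-8)
    }
  }

  # phi -> 0+: no feminized females persist
  expect_gt(solve_equilibrium(feminization_params(phi = 1e-4))$x_xx, 0.99)
})

test_that("equilibrium X0 fraction increases strictly with phi", {
  phis <- seq(0.05, 1, by = 0.05)
  q <- vapply(phis, function(phi)
    solve_equilibrium(feminization_params(phi = phi))$q_x0, numeric(1))
  expect_true(all(diff(q) > 0))
})

test_that("equilibrium agrees with an individual-based forward simulation", {
  set.seed(401)
  for (phi in c(0.85, 1)) {
    x_sim <- simulate_karyotype_generations(phi, n_mothers = 1e5,
                                            generations = 50)
    x_star <- solve_equilibrium(feminization_params(phi = phi))$x_xx
    expect_equal(x_sim, x_star, tolerance = 0.01)
  }
})

test_that("expected male fraction is zero at perfect feminization", {
  p <- feminization_params(phi = 1)
  expect_equal(expected_male_fraction(solve_equilibrium(p), p), 0)

  # phi = 0, x = 1 corresponds to an even, uninfected-like sex ratio
  st <- structure(list(x_xx = 1, q_x0 = 0), class = "equilibrium_state")
  expect_equal(expected_male_fraction(st, feminization_params(phi = 0)), 0.5)

  # plug-in at phi = 0.9: (1-phi)/2 over (x + (1-x)*3/4)
  p9 <- feminization_params(phi = 0.9)
  eq9 <- solve_equilibrium(p9)
  expect_equal(expected_male_fraction(eq9, p9),
               0.05 / (eq9$x_xx + (1 - eq9$x_xx) * 0.75), tolerance = 1e-12)
})

test_that("male fraction at equilibrium matches a large offspring simulation", {
  set.seed(402)
  p9 <- feminization_params(phi = 0.9)
  eq9 <- solve_equilibrium(p9)
  n <- 1e6
  is_x0 <- runif(n) < eq9$q_x0
  # one egg per draw, mother karyotype sampled at equilibrium; classify the
  # egg by the offspring class probabilities of that mother type
  u2 <- runif(n)
  cls <- character(n)
  cls[!is_x0] <- ifelse(u2[!is_x0] < 0.5, "XXf",
                        ifelse(u2[!is_x0] < 0.5 + 0.5 * p9$phi, "X0f", "X0m"))
  cls[is_x0] <- ifelse(u2[is_x0] < 0.25, "XXf",
                       ifelse(u2[is_x0] < 0.25 + 0.5 * p9$phi, "X0f",
                              ifelse(u2[is_x0] < 0.75, "X0m", "OO")))
  m_sim <- sum(cls == "X0m") / sum(cls != "OO")
  expect_lt(abs(m_sim - expected_male_fraction(eq9, p9)), 0.0015)
})

test_that("feminization success is recoverable from the brood sex ratio", {
  expect_equal(estimate_phi_from_sex_ratio(0)$phi, 1)
  expect_error(estimate_phi_from_sex_ratio(0.5), "0.5")

  # round-trip identity on a phi grid
  for (phi in c(0.5, 0.85, 0.95)) {
    p <- feminization_params(phi = phi)
    m <- expected_male_fraction(solve_equilibrium(p), p)
    expect_equal(estimate_phi_from_sex_ratio(m)$phi, phi, tolerance = 1e-6)
  }

  # finite-brood recovery: simulated sex ratio at phi = 0.9
  set.seed(403)
  p9 <- feminization_params(phi = 0.9)
  eq9 <- solve_equilibrium(p9)
  m_true <- expected_male_fraction(eq9, p9)
  n <- 5000
  males <- rbinom(1, n, m_true)
  est <- estimate_phi_from_sex_ratio(males / n)$phi
  se_m <- sqrt(m_true * (1 - m_true) / n)
  # phi moves ~2x faster than m near 0.9 (|dphi/dm| ~ 1.9)
  expect_lt(abs(est - 0.9), 3 * se_m * 2.5)
})
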