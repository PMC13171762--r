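test_that("saturated two-group logistic fit matches closed-form log-odds", {
  d <- data.frame(trials = c(100, 100), failures = c(20, 4),
                  group = c("fem", "ctrl"))
  fit <- fit_logistic(d, ~ group)
  # one observation per group: saturated, deviance 0
  expect_lt(fit$deviance, 1e-10)
  X <- model.matrix(~ group, d)
  eta <- unname(drop(X %*% fit$coefficients))
  expect_equal(sort(eta), sort(c(log(0.25), log(0.04 / 0.96))),
               tolerance = 1e-10)
  # odds ratio between the groups is 6
  expect_equal(unname(exp(abs(diff(eta)))), 6, tolerance = 1e-8)
})

test_that("logistic coefficients are recovered from simulated data", {
  set.seed(501)
  n <- 200
  covered <- replicate(200, {
    g <- rep(c("a", "b"), each = n / 2)
    eta <- ifelse(g == "a", -2.2, -1.0)
    trials <- sample(10:25, n, replace = TRUE)
    d <- data.frame(trials = trials,
                    failures = rbinom(n, trials, plogis(eta)),
                    group = g)
    fit <- fit_logistic(d, ~ group)
    se <- sqrt(diag(fit$vcov))
    all(abs(fit$coefficients - c(-2.2, 1.2)) <= 2 * se)
  })
  # joint 2-SE coverage of two coefficients; each ~95%, jointly >= 90%
  expect_gt(mean(covered), 0.85)
})

test_that("separation is flagged and coefficients capped", {
  d <- data.frame(trials = c(20, 20, 20, 20),
                  failures = c(0, 0, 5, 4),
                  group = rep(c("a", "b"), each = 2))
  expect_warning(fit <- fit_logistic(d, ~ group), "separation")
  expect_true(all(abs(fit$coefficients) <= 30))
})

test_that("Williams weights reduce to one at delta zero and identify nothing at trials 1", {
  d <- data.frame(trials = rep(1L, 10), failures = rbinom(10, 1, 0.3),
                  group = rep(c("a", "b"), each = 5))
  fit <- fit_logistic(d, ~ group)
  expect_warning(w <- williams_correction(fit), "unidentifiable")
  expect_equal(w$delta, 0)
  expect_equal(w$weights, rep(1, 10))
})

test_that("Williams delta recovers beta-binomial heterogeneity", {
  set.seed(502)
  icc <- 0.1
  n <- 500
  trials <- sample(10:25, n, replace = TRUE)
  d <- data.frame(trials = trials,
                  failures = rbb(n, trials, 0.15, icc),
                  group = rep(c("a", "b"), each = n / 2))
  w <- williams_correction(fit_logistic(d, ~ group))
  expect_gt(w$delta, icc * 0.5)
  expect_lt(w$delta, icc * 1.5)
  expect_true(all(w$weights > 0 & w$weights <= 1))
})

test_that("corrected fit with delta 0 equals the uncorrected fit exactly", {
  set.seed(503)
  d <- data.frame(trials = rep(20, 40), failures = rbinom(40, 20, 0.1),
                  group = rep(c("a", "b"), each = 20))
  fit <- fit_logistic(d, ~ group)
  refit <- fit_logistic(d, ~ group, weights = rep(1, 40))
  expect_identical(fit$coefficients, refit$coefficients)
  expect_identical(fit$deviance, refit$deviance)
})

test_that("deviance test basics: nesting, null data, identical models", {
  set.seed(504)
  d <- data.frame(trials = rep(20, 30), failures = rbinom(30, 20, 0.1),
                  group = rep(c("a", "b"), each = 15))
  full <- fit_logistic(d, ~ group)
  same <- deviance_test(full, full)
  expect_equal(same$delta_deviance, 0)
  expect_equal(same$df, 0)
  expect_equal(same$p_value, 1)

  reduced <- fit_logistic(d, ~ 1)
  dt <- deviance_test(full, reduced)
  expect_gte(dt$delta_deviance, 0)
  expect_equal(dt$df, 1)

  # two groups with identical proportions: delta deviance ~ 0, p ~ 1
  d2 <- data.frame(trials = c(50, 50), failures = c(5, 5),
                   group = c("a", "b"))
  dt2 <- deviance_test(fit_logistic(d2, ~ group), fit_logistic(d2, ~ 1))
  expect_lt(dt2$delta_deviance, 1e-8)
  expect_gt(dt2$p_value, 0.999)

  # mismatched weights are rejected
  wfit <- fit_logistic(d, ~ group, weights = rep(0.5, 30))
  expect_error(deviance_test(wfit, reduced), "weights")
})

test_that("deviance of nested models is monotone across simulations", {
  set.seed(505)
  for (i in 1:20) {
    n <- 40
    trials <- sample(5:30, n, replace = TRUE)
    d <- data.frame(trials = trials,
                    failures = rbinom(n, trials, runif(1, 0.05, 0.3)),
                    group = sample(c("a", "b", "c"), n, replace = TRUE))
    full <- fit_logistic(d, ~ group)
    reduced <- fit_logistic(d, ~ 1)
    expect_gte(reduced$deviance - full$deviance, -1e-8)
  }
})

test_that("group encoding does not change the deviance test", {
  set.seed(506)
  d <- data.frame(trials = rep(20, 60),
                  failures = rbinom(60, 20, rep(c(0.05, 0.1, 0.2), each = 20)),
                  group = rep(c("U", "R", "RTW1"), each = 20))
  d2 <- d
  d2$group <- factor(d2$group, levels = c("RTW1", "U", "R"))
  r1 <- williams_deviance_test(d, ~ group)
  r2 <- williams_deviance_test(d2, ~ group)
  expect_equal(r1$delta_deviance, r2$delta_deviance, tolerance = 1e-8)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-8)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  # SSB = 3*(2-3.5)^2 + 3*(5-3.5)^2 = 13.5 on 1 df; SSE = 4 on 4 df,
  # MSE = 1, hence F = 13.5
  fit <- fit_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(fit$F, 13.5)
  expect_equal(fit$df1, 1L)
  expect_equal(fit$df2, 4L)
  expect_equal(fit$mse, 1)

  # all equal -> F = 0 requires nonzero residual variance; degenerate errors
  expect_error(suppressWarnings(fit_anova(rep(5, 6), rep(c("a", "b"), each = 3))),
               "zero residual variance")
  set.seed(507)
  y <- rnorm(20)
  f0 <- fit_anova(c(y, y), rep(c("a", "b"), each = 20))
  expect_equal(f0$F, 0, tolerance = 1e-12)
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(508)
  p <- replicate(1000, fit_anova(rnorm(30), rep(c("a", "b", "c"), 10))$p_value)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planned contrast is antisymmetric and zero for equal means", {
  set.seed(509)
  y <- rnorm(40)
  fit <- fit_anova(c(y, y + 0), rep(c("a", "b"), each = 40))
  ct <- planned_contrast(fit, "a", "b")
  expect_equal(ct$t, 0, tolerance = 1e-10)

  y2 <- c(rnorm(20, 0), rnorm(20, 1), rnorm(20, 2), rnorm(20, 3))
  g <- rep(c("a", "b", "c", "d"), each = 20)
  fit2 <- fit_anova(y2, g)
  f <- planned_contrast(fit2, c("a", "b"), c("c", "d"))
  r <- planned_contrast(fit2, c("c", "d"), c("a", "b"))
  expect_equal(f$t, -r$t)
  expect_equal(f$df, 76)
  expect_lt(f$p_value, 0.001)
})

test_that("Tukey HSD separates far groups and pools identical ones", {
  set.seed(510)
  y <- c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 0))
  fit <- fit_anova(y, rep(c("a", "b", "c"), each = 10))
  tk <- tukey_hsd(fit)
  expect_equal(unname(tk$letters), rep("A", 3))

  y2 <- c(rnorm(10, 0), rnorm(10, 100))
  fit2 <- fit_anova(y2, rep(c("a", "b"), each = 10))
  tk2 <- tukey_hsd(fit2)
  expect_setequal(unname(tk2$letters), c("A", "B"))
})

test_that("Tukey-Kramer p-values match TukeyHSD on unbalanced data", {
  set.seed(511)
  g <- rep(c("a", "b", "c"), times = c(8, 12, 15))
  y <- rnorm(35, mean = c(a = 0, b = 0.8, c = 1.6)[g])
  fit <- fit_anova(y, g)
  ours <- tukey_hsd(fit)$pairs
  ref <- TukeyHSD(aov(y ~ factor(g)))$`factor(g)`
  key <- paste(ours$group2, ours$group1, sep = "-")
  expect_equal(unname(ours$p_value[match(rownames(ref), key)]),
               unname(ref[, "p adj"]), tolerance = 1e-6)
})

test_that("letter display matches the brute-force clique-cover oracle", {
  set.seed(512)
  for (rep in 1:30) {
    k <- sample(3:6, 1)
    groups <- LETTERS[1:k]
    means <- setNames(sort(runif(k), decreasing = TRUE), groups)
    sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      s <- runif(1) < 0.4
      sig[i, j] <- s; sig[j, i] <- s
    }
    letters_pkg <- compact_letter_display(sig, means)
    share_pkg <- letters_sharing(letters_pkg)
    share_oracle <- clique_cover_sharing(sig)
    expect_identical(share_pkg, share_oracle)
    # defining invariant: share a letter iff not significantly different
    diag(sig) <- FALSE
    expect_identical(unname(share_pkg), unname(!sig | diag(k) > 0))
  }
})
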