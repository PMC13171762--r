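#' Grouped binomial logistic regression
#'
#' Fits a binomial logistic model to brood-level counts (eggs laid,
#' eggs undeveloped) by maximum likelihood via iteratively reweighted
#' least squares, with optional per-observation prior weights (used by
#' [williams_correction()]). The modelled probability is that an egg is
#' undeveloped.
#'
#' @param data Data frame with columns `trials` (eggs laid), `failures`
#'   (undeveloped eggs), and any grouping columns named in `design`.
#' @param design One-sided formula over columns of `data`
#'   (default `~ group`); use `~ 1` for the intercept-only reduced model.
#' @param weights Optional per-observation weights in (0, 1\]; default all 1.
#' @param coef_cap Absolute cap applied to coefficients under complete
#'   separation (a group with all-0 or all-1 outcomes), with a warning.
#' @return A list of class `glm_fit` with logit-scale `coefficients`,
#'   `deviance`, `df_residual`, `rank`, `pearson` (Pearson chi-square),
#'   `delta` (Williams heterogeneity, 0 here), `weights`, `fitted`, and the
#'   data and design used.
#' @export
fit_logistic <- function(data, design = ~ group, weights = NULL,
                         coef_cap = 30) {
  stopifnot(all(c("trials", "failures") %in% names(data)))
  stopifnot(all(data$trials >= 1), all(data$failures >= 0),
            all(data$failures <= data$trials))
  n <- nrow(data)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0), all(weights <= 1 + 1e-12))

  df_fit <- data
  df_fit$.y <- df_fit$failures / df_fit$trials
  df_fit$.w <- weights * df_fit$trials
  form <- stats::as.formula(paste(".y", paste(deparse(design), collapse = "")))
  # quasibinomial: identical IRLS and deviance to binomial, but accepts the
  # fractional prior weights that Williams' correction introduces
  gfit <- stats::glm(form, family = stats::quasibinomial("logit"),
                     data = df_fit, weights = .w)
  if (!gfit$converged) {
    stop("IRLS failed to converge after ", gfit$iter, " iterations")
  }

  coefs <- stats::coef(gfit)
  mu <- stats::fitted(gfit)
  if (any(mu < 1e-8 | mu > 1 - 1e-8) || any(abs(coefs) > coef_cap)) {
    warning("possible complete separation (a fitted proportion at 0 or 1): ",
            "coefficients reported capped at +/-", coef_cap)
    coefs <- pmin(pmax(coefs, -coef_cap), coef_cap)
  }
  pearson <- sum(df_fit$.w * (df_fit$.y - mu)^2 / (mu * (1 - mu)))

  structure(list(coefficients = coefs,
                 deviance = stats::deviance(gfit),
                 df_residual = gfit$df.residual,
                 rank = gfit$rank,
                 pearson = pearson,
                 delta = 0,
                 weights = weights,
                 fitted = mu,
                 vcov = summary(gfit)$cov.unscaled,
                 data = data,
                 design = design),
            class = "glm_fit")
}

pearson_at_delta <- function(delta, fit) {
  w <- 1 / (1 + delta * (fit$data$trials - 1))
  refit <- fit_logistic(fit$data, design = fit$design, weights = w)
  refit$pearson - refit$df_residual
}

#' Williams' correction for overdispersed grouped binomial data
#'
#' Moment-based estimation of a heterogeneity parameter `delta`: the model
#' is refit with per-brood weights `w_i = 1 / (1 + delta * (n_i - 1))`, and
#' `delta` is chosen so the Pearson chi-square of the weighted fit equals
#' its residual degrees of freedom. `delta` is floored at 0 (no
#' underdispersion correction); when every brood has a single egg the
#' weights cannot identify `delta` and the uncorrected fit is returned with
#' a warning.
#'
#' @param fit A `glm_fit` from [fit_logistic()] (unweighted).
#' @param max_iter Iteration cap for the root search on `delta`.
#' @param tol Convergence tolerance on `delta`.
#' @return The refitted `glm_fit` with `delta` and Williams weights
#'   recorded.
#' @export
williams_correction <- function(fit, max_iter = 50L, tol = 1e-8) {
  stopifnot(inherits(fit, "glm_fit"))
  if (fit$df_residual < 1) stop("Williams' correction needs residual df >= 1")
  trials <- fit$data$trials
  if (all(trials == 1)) {
    warning("all broods have a single egg: delta is unidentifiable, returning 0")
    fit$delta <- 0
    return(fit)
  }

  if (pearson_at_delta(0, fit) <= 0) {    # no overdispersion signal
    fit$delta <- 0
    return(fit)
  }
  hi <- 0.05
  it <- 0L
  while (pearson_at_delta(hi, fit) > 0) {
    hi <- hi * 2
    it <- it + 1L
    if (it > max_iter) {
      stop("delta search diverged; last delta tried = ", hi)
    }
  }
  root <- stats::uniroot(pearson_at_delta, fit = fit, interval = c(0, hi),
                         tol = tol, maxiter = max_iter)
  delta <- max(root$root, 0)
  w <- 1 / (1 + delta * (trials - 1))
  out <- fit_logistic(fit$data, design = fit$design, weights = w)
  out$delta <- delta
  out
}

#' Deviance-difference test for nested grouped binomial models
#'
#' Compares a reduced model nested in a full model fitted on identical
#' data and identical (Williams) weights; the deviance difference is
#' referred to a chi-square with df equal to the parameter-count
#' difference.
#'
#' @param full,reduced `glm_fit` objects, reduced nested in full.
#' @return A list with `delta_deviance`, `df`, `p_value`.
#' @export
deviance_test <- function(full, reduced) {
  stopifnot(inherits(full, "glm_fit"), inherits(reduced, "glm_fit"))
  if (nrow(full$data) != nrow(reduced$data)) {
    stop("full and reduced models must be fitted on identical data")
  }
  if (!isTRUE(all.equal(full$weights, reduced$weights, tolerance = 1e-10))) {
    stop("full and reduced models must share identical weights")
  }
  df <- full$rank - reduced$rank
  if (df < 0) stop("reduced model has more parameters than the full model")
  dd <- reduced$deviance - full$deviance
  if (dd < -1e-8) stop("negative deviance difference: fit failure")
  dd <- max(dd, 0)
  p <- if (df == 0) 1 else stats::pchisq(dd, df = df, lower.tail = FALSE)
  list(delta_deviance = dd, df = df, p_value = p)
}

#' Williams-corrected nested comparison in one call
#'
#' Fits the full model, estimates Williams' `delta` on it, refits both the
#' full and the reduced model with the full model's weights held fixed (so
#' the nested deviances are comparable), and runs [deviance_test()].
#'
#' @param data As in [fit_logistic()].
#' @param full_design,reduced_design One-sided formulas, reduced nested in
#'   full.
#' @param correct Apply Williams' correction (default `TRUE`).
#' @return The [deviance_test()] result plus `delta` and both fits.
#' @export
williams_deviance_test <- function(data, full_design, reduced_design = ~ 1,
                                   correct = TRUE) {
  full0 <- fit_logistic(data, design = full_design)
  full <- if (correct) williams_correction(full0) else full0
  reduced <- fit_logistic(data, design = reduced_design,
                          weights = full$weights)
  out <- deviance_test(full, reduced)
  out$delta <- full$delta
  out$full <- full
  out$reduced <- reduced
  out
}

#' One-way fixed-effects linear model on total eggs
#'
#' @param total_eggs Numeric vector of per-brood egg totals.
#' @param group Factor or character vector of symbiotype labels.
#' @return A list of class `anova_fit` with `group_means`, `group_n`, `F`,
#'   `df1`, `df2`, `mse`, `p_value`, and the data used.
#' @export
fit_anova <- function(total_eggs, group) {
  group <- factor(group)
  stopifnot(length(total_eggs) == length(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (length(total_eggs) < nlevels(group) + 1L) {
    stop("need residual degrees of freedom (more observations than groups)")
  }
  lfit <- stats::lm(total_eggs ~ group)
  an <- stats::anova(lfit)
  mse <- an["Residuals", "Mean Sq"]
  if (mse <= .Machine$double.eps) stop("zero residual variance")
  gm <- tapply(total_eggs, group, mean)
  structure(list(group_means = stats::setNames(as.numeric(gm), names(gm)),
                 group_n = as.integer(table(group)),
                 F = an[1L, "F value"],
                 df1 = an[1L, "Df"],
                 df2 = an["Residuals", "Df"],
                 mse = mse,
                 p_value = an[1L, "Pr(>F)"],
                 lm = lfit,
                 group = group,
                 y = total_eggs),
            class = "anova_fit")
}

#' Planned contrast between two sets of group means
#'
#' Tests `mean of set1 group means - mean of set2 group means` with the
#' pooled residual mean square of the one-way model; df = residual df.
#'
#' @param fit An `anova_fit` from [fit_anova()].
#' @param set1,set2 Character vectors naming a partition of the groups into
#'   two non-empty sets.
#' @return A list with `estimate`, `t`, `df`, `p_value`.
#' @export
planned_contrast <- function(fit, set1, set2) {
  stopifnot(inherits(fit, "anova_fit"))
  lev <- names(fit$group_means)
  stopifnot(length(set1) >= 1L, length(set2) >= 1L,
            all(set1 %in% lev), all(set2 %in% lev),
            length(intersect(set1, set2)) == 0L)
  cvec <- stats::setNames(rep(0, length(lev)), lev)
  cvec[set1] <- 1 / length(set1)
  cvec[set2] <- -1 / length(set2)
  n <- stats::setNames(fit$group_n, lev)
  est <- sum(cvec * fit$group_means)
  se <- sqrt(fit$mse * sum(cvec^2 / n))
  t <- est / se
  list(estimate = est, t = t, df = fit$df2,
       p_value = 2 * stats::pt(abs(t), df = fit$df2, lower.tail = FALSE))
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' All pairwise group-mean differences tested against the studentized
#' range; unbalanced designs use the Tukey-Kramer standard error
#' `sqrt(MSE/2 * (1/n_i + 1/n_j))`. Letters are assigned by the
#' insert-and-absorb algorithm over groups sorted by mean, so that two
#' groups share a letter iff they are not significantly different.
#'
#' @param fit An `anova_fit` from [fit_anova()].
#' @param alpha Familywise significance level (default 0.05).
#' @return A list of class `tukey_result` with `pairs` (data frame:
#'   `group1`, `group2`, `diff`, `q`, `p_value`, `significant`) and
#'   `letters` (named character vector of letter codes per group).
#' @export
tukey_hsd <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "anova_fit"))
  means <- fit$group_means
  n <- stats::setNames(fit$group_n, names(means))
  k <- length(means)
  df <- fit$df2
  combs <- utils::combn(names(means), 2)
  pairs <- data.frame(group1 = combs[1, ], group2 = combs[2, ])
  pairs$diff <- means[pairs$group1] - means[pairs$group2]
  se <- sqrt(fit$mse / 2 * (1 / n[pairs$group1] + 1 / n[pairs$group2]))
  pairs$q <- abs(pairs$diff) / se
  pairs$p_value <- stats::ptukey(pairs$q, nmeans = k, df = df,
                                 lower.tail = FALSE)
  pairs$significant <- pairs$p_value < alpha
  rownames(pairs) <- NULL

  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(nrow(pairs))) {
    sig[pairs$group1[i], pairs$group2[i]] <- pairs$significant[i]
    sig[pairs$group2[i], pairs$group1[i]] <- pairs$significant[i]
  }
  letters_out <- compact_letter_display(sig, means)
  structure(list(pairs = pairs, letters = letters_out, alpha = alpha),
            class = "tukey_result")
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb: start with a single letter covering every group; for
#' each significant pair, split any letter set containing both into two
#' sets, one without each member; drop sets that are subsets of others;
#' order letters by descending group mean.
#'
#' @param sig_matrix Logical symmetric matrix; `TRUE` where the pair
#'   differs significantly. Row/column names are the group labels.
#' @param means Named numeric vector of group means (for letter ordering).
#' @return Named character vector mapping group to its letter string.
#' @export
compact_letter_display <- function(sig_matrix, means) {
  groups <- rownames(sig_matrix)
  stopifnot(!is.null(groups), identical(groups, colnames(sig_matrix)))
  sets <- list(groups)
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i || !sig_matrix[i, j]) next
      gi <- groups[i]; gj <- groups[j]
      new_sets <- list()
      for (s in sets) {
        if (gi %in% s && gj %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, gi)), list(setdiff(s, gj)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_sets))
      for (a in seq_along(new_sets)) {
        for (b in seq_along(new_sets)) {
          if (a == b || !keep[a]) next
          if (all(new_sets[[a]] %in% new_sets[[b]]) &&
              (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      sets <- unique(new_sets[keep])
    }
  }
  sets <- sets[order(-vapply(sets, function(s) max(means[s]), numeric(1)))]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (idx in seq_along(sets)) {
    for (g in sets[[idx]]) out[g] <- paste0(out[g], LETTERS[idx])
  }
  out
}
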