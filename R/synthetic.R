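#' Study design for the six-symbiotype brood experiment
#'
#' The default roster mirrors the spider experiment the package models:
#' six maternally inherited symbiont combinations (U = uninfected,
#' R = Rickettsiella only, RT adds Tisiphia, and RTW1/RTW12/RTW123 add one
#' to three Wolbachia strains), of which any symbiotype carrying
#' Wolbachia 1 is feminizing; 30 females per symbiotype, each laying one
#' eggmass sired by an uninfected X0 male.
#'
#' @param symbiotypes Ordered character vector of unique labels.
#' @param females_per_symbiotype Females per symbiotype (default 30).
#' @param feminizing Logical vector flagging feminizing symbiotypes;
#'   defaults to labels containing "W" (Wolbachia 1 bearers).
#' @return A list of class `study_design`.
#' @export
study_design <- function(symbiotypes = c("U", "R", "RT", "RTW1", "RTW12", "RTW123"),
                         females_per_symbiotype = 30L,
                         feminizing = grepl("W", symbiotypes)) {
  stopifnot(!anyDuplicated(symbiotypes), females_per_symbiotype >= 1,
            length(feminizing) == length(symbiotypes))
  structure(list(symbiotypes = symbiotypes,
                 females_per_symbiotype = as.integer(females_per_symbiotype),
                 feminizing = stats::setNames(feminizing, symbiotypes)),
            class = "study_design")
}

#' Generator parameters for synthetic brood data
#'
#' Defaults are calibrated to the experiment the package emulates: per-
#' symbiotype feminization success rates that, with the 4% background
#' failure, put the expected undeveloped proportions near 0.170-0.176; a
#' ~16% egg-count reduction in feminized symbiotypes (means 15.75 vs
#' 18.75); a 6.1% mating-failure rate; and a 0.6% symbiotype-mismatch rate.
#' Egg counts are negative-binomial by default (size = dispersion; larger
#' is closer to Poisson), with a pure-Poisson option.
#'
#' @param phi Named vector of feminization success rates for the
#'   feminizing symbiotypes.
#' @param b Background per-egg failure probability.
#' @param mean_eggs_nonfem,mean_eggs_fem Mean eggs per eggmass.
#' @param egg_dispersion Negative-binomial size parameter; `Inf` gives
#'   Poisson counts.
#' @param count_model `"nbinom"` (default) or `"poisson"`.
#' @param mating_failure_prob Probability a female fails to mate (lays no
#'   eggmass).
#' @param mismatch_prob Probability a female's diagnostic symbiotype does
#'   not match its expected line.
#' @param rho Relative fecundity of X0 vs XX mothers inside the
#'   equilibrium recursion.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(phi = c(RTW1 = 0.86, RTW12 = 0.87, RTW123 = 0.94),
                             b = 0.04,
                             mean_eggs_nonfem = 18.75,
                             mean_eggs_fem = 15.75,
                             egg_dispersion = 20,
                             count_model = c("nbinom", "poisson"),
                             mating_failure_prob = 0.061,
                             mismatch_prob = 0.006,
                             rho = 1) {
  stopifnot(all(phi > 0 & phi <= 1), b >= 0, b < 1,
            mean_eggs_nonfem > 0, mean_eggs_fem > 0, egg_dispersion > 0,
            mating_failure_prob >= 0, mating_failure_prob <= 1,
            mismatch_prob >= 0, mismatch_prob <= 1)
  structure(list(phi = phi, b = b,
                 mean_eggs_nonfem = mean_eggs_nonfem,
                 mean_eggs_fem = mean_eggs_fem,
                 egg_dispersion = egg_dispersion,
                 count_model = match.arg(count_model),
                 mating_failure_prob = mating_failure_prob,
                 mismatch_prob = mismatch_prob,
                 rho = rho),
            class = "generator_params")
}

draw_egg_counts <- function(n, mean_eggs, params) {
  draw <- function(m) {
    if (params$count_model == "poisson" || is.infinite(params$egg_dispersion)) {
      stats::rpois(m, lambda = mean_eggs)
    } else {
      stats::rnbinom(m, size = params$egg_dispersion, mu = mean_eggs)
    }
  }
  x <- draw(n)
  while (any(x == 0)) {        # mated females lay at least one egg
    z <- x == 0
    x[z] <- draw(sum(z))
  }
  x
}

#' Generate a synthetic brood-level dataset
#'
#' Per female: a mating Bernoulli; for feminizing symbiotypes a latent
#' maternal karyotype drawn X0 with the equilibrium probability `q_x0`
#' implied by that symbiotype's `phi`; an egg count from the configured
#' count distribution (mated females only); independent per-egg failure at
#' `0.25 + 0.75*b` (X0 mothers) or `b` (XX mothers); and a rare
#' symbiotype-mismatch flag. Deterministic given `seed`.
#'
#' @param design A [study_design()].
#' @param params A [generator_params()]; every feminizing symbiotype in
#'   `design` must have a `phi` entry.
#' @param seed Integer master seed.
#' @param reveal_latent Emit the latent `karyotype` column (default
#'   `FALSE`, mimicking what an experimenter can observe).
#' @return Data frame with columns `female_id`, `symbiotype`, `mated`,
#'   `eggs_laid`, `eggs_developed`, `eggs_undeveloped`, `excluded_reason`
#'   (+ `karyotype` when revealed).
#' @export
generate_study <- function(design = study_design(),
                           params = generator_params(),
                           seed = 1L, reveal_latent = FALSE) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "generator_params"))
  fem <- design$symbiotypes[design$feminizing]
  missing_phi <- setdiff(fem, names(params$phi))
  if (length(missing_phi)) {
    stop("no phi supplied for feminizing symbiotype(s): ",
         paste(missing_phi, collapse = ", "))
  }
  mm <- mortality_model(params$b)
  q_map <- vapply(fem, function(s) {
    solve_equilibrium(feminization_params(params$phi[[s]], rho = params$rho))$q_x0
  }, numeric(1))

  set.seed(as.integer(seed))
  out <- lapply(design$symbiotypes, function(s) {
    n <- design$females_per_symbiotype
    is_fem <- design$feminizing[[s]]
    mated <- stats::runif(n) >= params$mating_failure_prob
    kary <- rep("XX", n)
    if (is_fem) kary[stats::runif(n) < q_map[[s]]] <- "X0"
    mu <- if (is_fem) params$mean_eggs_fem else params$mean_eggs_nonfem
    eggs <- integer(n)
    eggs[mated] <- draw_egg_counts(sum(mated), mu, params)
    p_fail <- ifelse(kary == "X0", mm$e_x0, mm$e_xx)
    undev <- integer(n)
    undev[mated] <- stats::rbinom(sum(mated), size = eggs[mated],
                                  prob = p_fail[mated])
    mismatch <- stats::runif(n) < params$mismatch_prob
    dev <- eggs - undev
    reason <- rep("none", n)
    reason[mismatch] <- "symbiotype_mismatch"
    reason[eggs >= 1 & dev == 0] <- "zero_development"
    reason[!mated] <- "unmated"
    data.frame(female_id = sprintf("%s_%02d", s, seq_len(n)),
               symbiotype = s, mated = mated,
               karyotype = kary,
               eggs_laid = eggs, eggs_developed = dev,
               eggs_undeveloped = undev,
               excluded_reason = reason)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!reveal_latent) out$karyotype <- NULL
  out
}

#' Apply the experiment's exclusion filters
#'
#' Removes females that did not mate, broods with at least one egg but 0%
#' development, and symbiotype mismatches. Idempotent.
#'
#' @param table Brood table with columns `mated`, `eggs_laid`,
#'   `eggs_developed`; `excluded_reason` is honoured for mismatches when
#'   present.
#' @return A list with `broods` (the filtered table) and `tally` (named
#'   counts per exclusion reason).
#' @export
apply_exclusions <- function(table) {
  req <- c("symbiotype", "mated", "eggs_laid", "eggs_developed")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    stop("brood table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  reason <- rep("none", nrow(table))
  if ("excluded_reason" %in% names(table)) {
    reason[table$excluded_reason == "symbiotype_mismatch"] <- "symbiotype_mismatch"
  }
  reason[table$eggs_laid >= 1 & table$eggs_developed == 0] <- "zero_development"
  reason[!table$mated] <- "unmated"
  tally <- table(factor(reason[reason != "none"],
                        levels = c("unmated", "zero_development",
                                   "symbiotype_mismatch")))
  list(broods = table[reason == "none", , drop = FALSE],
       tally = stats::setNames(as.integer(tally), names(tally)))
}

#' Per-symbiotype brood summaries
#'
#' Means and standard errors of eggs per eggmass and of the per-brood
#' undeveloped proportion (proportions computed per brood, then averaged).
#'
#' @param table Filtered brood table (see [apply_exclusions()]).
#' @param symbiotypes Optional level order; defaults to order of
#'   appearance.
#' @return Data frame with one row per symbiotype: `n`, `mean_eggs`,
#'   `se_eggs`, `mean_prop_undeveloped`, `se_prop_undeveloped`.
#' @export
summarize_study <- function(table, symbiotypes = unique(table$symbiotype)) {
  if (nrow(table) == 0L) stop("empty brood table")
  rows <- lapply(symbiotypes, function(s) {
    sub <- table[table$symbiotype == s, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0L) {
      return(data.frame(symbiotype = s, n = 0L, mean_eggs = NA_real_,
                        se_eggs = NA_real_, mean_prop_undeveloped = NA_real_,
                        se_prop_undeveloped = NA_real_))
    }
    prop <- sub$eggs_undeveloped / sub$eggs_laid
    se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
    data.frame(symbiotype = s, n = n,
               mean_eggs = mean(sub$eggs_laid), se_eggs = se(sub$eggs_laid),
               mean_prop_undeveloped = mean(prop),
               se_prop_undeveloped = se(prop))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
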