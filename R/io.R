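#' Read a brood table from delimited text
#'
#' Accepts comma- or tab-delimited files (dialect chosen by extension,
#' `.tsv`/`.tab` for tabs, otherwise comma) with the documented header:
#' `female_id, symbiotype, mated, eggs_laid, eggs_developed,
#' eggs_undeveloped, excluded_reason` (optional `karyotype`). Validates the
#' schema and the per-row conservation constraint
#' `eggs_developed + eggs_undeveloped == eggs_laid`, reporting offending
#' rows by line number.
#'
#' @param path Path to the file.
#' @return Validated brood data frame.
#' @export
read_brood_table <- function(path) {
  if (!file.exists(path)) stop("brood table not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  req <- c("female_id", "symbiotype", "mated", "eggs_laid",
           "eggs_developed", "eggs_undeveloped")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols)) {
    stop("brood table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    warning("brood table has a header but no rows: ", path)
    return(tab)
  }
  tab$mated <- as.logical(tab$mated)
  num_cols <- c("eggs_laid", "eggs_developed", "eggs_undeveloped")
  for (cn in num_cols) {
    tab[[cn]] <- as.integer(tab[[cn]])
    if (anyNA(tab[[cn]])) {
      stop("non-numeric values in column ", cn, " (rows ",
           paste(which(is.na(tab[[cn]])) + 1L, collapse = ", "), ")")
    }
  }
  bad <- which(tab$eggs_developed + tab$eggs_undeveloped != tab$eggs_laid)
  if (length(bad)) {
    stop("eggs_developed + eggs_undeveloped != eggs_laid at file row(s) ",
         paste(bad + 1L, collapse = ", "))   # +1 for the header line
  }
  if (!"excluded_reason" %in% names(tab)) tab$excluded_reason <- "none"
  tab
}

#' Write a brood table
#'
#' @param table Brood data frame.
#' @param path Destination; `.tsv`/`.tab` extension writes tabs, otherwise
#'   commas.
#' @export
write_brood_table <- function(table, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param phi Named vector of feminization success rates per feminizing
#'   symbiotype.
#' @param rho Relative X0/XX fecundity.
#' @param b_override Optional fixed baseline mortality; by default the
#'   baseline is estimated from the non-feminized broods.
#' @param n_draws,ci_level Monte Carlo settings.
#' @param alpha Significance level for Tukey HSD.
#' @param seed Master seed; per-symbiotype Monte Carlo streams are derived
#'   from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(phi = c(RTW1 = 0.86, RTW12 = 0.87, RTW123 = 0.94),
                            rho = 1, b_override = NULL,
                            n_draws = 500000L, ci_level = 0.95,
                            alpha = 0.05, seed = 1L) {
  stopifnot(all(phi > 0 & phi <= 1), rho > 0,
            is.null(b_override) || (b_override >= 0 && b_override < 1),
            alpha > 0, alpha < 1)
  structure(list(phi = phi, rho = rho, b_override = b_override,
                 n_draws = as.integer(n_draws), ci_level = ci_level,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a brood table
#'
#' Orchestrates the analysis in experiment order: exclusion filters,
#' baseline mortality from the non-feminized symbiotypes, equilibrium
#' XX/X0 composition and expected undeveloped proportion per feminizing
#' symbiotype, Monte Carlo confidence intervals conditioned on the
#' observed egg counts with within-CI flags for the observed means, and
#' the inferential statistics (Williams-corrected deviance tests, one-way
#' ANOVA on total eggs, planned feminized-vs-not contrast, Tukey letters).
#'
#' @param broods Brood data frame (e.g. from [read_brood_table()] or
#'   [generate_study()]).
#' @param config A [pipeline_config()].
#' @param design A [study_design()] describing which symbiotypes feminize.
#' @return A nested list (results document) embedding the resolved
#'   configuration; serialize with [write_results()].
#' @export
run_pipeline <- function(broods, config = pipeline_config(),
                         design = study_design()) {
  stopifnot(inherits(config, "pipeline_config"))
  filt <- apply_exclusions(broods)
  dat <- filt$broods
  if (nrow(dat) == 0L) stop("stage exclusions: no broods left after filtering")

  fem <- intersect(names(config$phi), unique(dat$symbiotype))
  nonfem <- setdiff(unique(dat$symbiotype), names(config$phi))
  if (length(fem) == 0L) stop("stage baseline: no feminizing symbiotypes present")
  if (is.null(config$b_override) && length(nonfem) == 0L) {
    stop("stage baseline: no non-feminized broods and no b_override")
  }
  b <- if (!is.null(config$b_override)) config$b_override else
    baseline_mortality(dat[dat$symbiotype %in% nonfem, , drop = FALSE])

  expect <- expectations_for_symbiotypes(config$phi[fem], b = b,
                                         rho = config$rho)

  mc <- lapply(seq_along(fem), function(i) {
    s <- fem[i]
    sub <- dat[dat$symbiotype == s, , drop = FALSE]
    cfg <- mc_config(n_draws = config$n_draws, ci_level = config$ci_level,
                     seed = (config$seed * 1000L + i) %% .Machine$integer.max)
    res <- simulate_undeveloped_distribution(
      sub$eggs_laid, q_x0 = expect$q_x0[expect$symbiotype == s], b = b, cfg)
    obs <- mean(sub$eggs_undeveloped / sub$eggs_laid)
    list(symbiotype = s, mean = res$mean, ci_lo = res$ci_lo,
         ci_hi = res$ci_hi, observed_mean = obs,
         within_ci = observed_within_ci(obs, res))
  })
  names(mc) <- fem

  gdat <- data.frame(trials = dat$eggs_laid, failures = dat$eggs_undeveloped,
                     group = factor(dat$symbiotype,
                                    levels = unique(dat$symbiotype)),
                     feminized = dat$symbiotype %in% fem)
  overall <- williams_deviance_test(gdat, ~ group)
  fem_vs_not <- williams_deviance_test(gdat, ~ feminized)
  w1_pair <- intersect(c("RTW1", "RT"), unique(dat$symbiotype))
  w1_test <- NULL
  if (length(w1_pair) == 2L) {
    sub <- gdat[as.character(gdat$group) %in% w1_pair, , drop = FALSE]
    sub$group <- droplevels(sub$group)
    w1_test <- williams_deviance_test(sub, ~ group)
  }

  afit <- fit_anova(dat$eggs_laid, dat$symbiotype)
  contrast <- planned_contrast(afit, set1 = fem, set2 = nonfem)
  tukey <- tukey_hsd(afit, alpha = config$alpha)

  strip <- function(x) x[c("delta_deviance", "df", "p_value", "delta")]
  list(
    config = unclass(config),
    exclusions = as.list(filt$tally),
    n_broods = nrow(dat),
    baseline_b = b,
    expectations = expect,
    monte_carlo = mc,
    stats = list(
      overall = strip(overall),
      feminized_vs_not = strip(fem_vs_not),
      rtw1_vs_rt = if (!is.null(w1_test)) strip(w1_test),
      anova = list(F = afit$F, df1 = afit$df1, df2 = afit$df2,
                   p_value = afit$p_value),
      contrast = contrast,
      tukey_letters = as.list(tukey$letters)
    ),
    summary = summarize_study(dat)
  )
}

#' Serialize a results document to JSON
#'
#' @param results A results document from [run_pipeline()].
#' @param path Destination path.
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
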