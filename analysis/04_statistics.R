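#!/usr/bin/env Rscript
# Stage 4: inferential statistics — Williams-corrected deviance tests on egg
# viability, one-way ANOVA on total eggs with the feminized-vs-not planned
# contrast, and Tukey-Kramer letters.

library(femcost)
broods <- read_brood_table("results/broods_filtered.csv")

g <- data.frame(trials = broods$eggs_laid, failures = broods$eggs_undeveloped,
                group = factor(broods$symbiotype),
                feminized = grepl("W", broods$symbiotype))

overall <- williams_deviance_test(g, ~ group)
femtest <- williams_deviance_test(g, ~ feminized)
pair <- droplevels(g[as.character(g$group) %in% c("RTW1", "RT"), ])
w1 <- williams_deviance_test(pair, ~ group)

cat(sprintf("Viability varies among symbiotypes: dDev = %.2f, df = %d, p = %.2g (delta = %.3f)\n",
            overall$delta_deviance, overall$df, overall$p_value, overall$delta))
cat(sprintf("Feminized vs not:                    dDev = %.2f, df = %d, p = %.2g\n",
            femtest$delta_deviance, femtest$df, femtest$p_value))
cat(sprintf("RTW1 vs RT (Wolbachia 1 alone):      dDev = %.2f, df = %d, p = %.2g\n",
            w1$delta_deviance, w1$df, w1$p_value))

afit <- fit_anova(broods$eggs_laid, broods$symbiotype)
fem <- unique(broods$symbiotype[grepl("W", broods$symbiotype)])
non <- unique(broods$symbiotype[!grepl("W", broods$symbiotype)])
ct <- planned_contrast(afit, fem, non)
tk <- tukey_hsd(afit)
cat(sprintf("Total eggs: F(%d,%d) = %.3f, p = %.2g; feminized contrast t = %.3f (df %d)\n",
            afit$df1, afit$df2, afit$F, afit$p_value, ct$t, ct$df))
cat("Tukey letters:", paste(names(tk$letters), tk$letters, sep = "=",
                            collapse = " "), "\n")

out <- list(overall = overall[c("delta_deviance", "df", "p_value", "delta")],
            feminized_vs_not = femtest[c("delta_deviance", "df", "p_value", "delta")],
            rtw1_vs_rt = w1[c("delta_deviance", "df", "p_value", "delta")],
            anova = list(F = afit$F, df1 = afit$df1, df2 = afit$df2,
                         p_value = afit$p_value),
            contrast = ct, tukey_letters = as.list(tk$letters))
jsonlite::write_json(out, "results/statistics.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("Wrote results/statistics.json\n")
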