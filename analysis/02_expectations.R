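#!/usr/bin/env Rscript
# Stage 2: equilibrium XX/X0 composition and expected undeveloped-egg
# proportions, using the baseline mortality estimated from the simulated
# non-feminized broods.

library(femcost)
broods <- read_brood_table("results/broods_filtered.csv")

nonfem <- broods[!grepl("W", broods$symbiotype), ]
b <- baseline_mortality(nonfem)
cat("Pooled baseline per-egg failure (U, R, RT):", round(b, 4), "\n")

phi <- c(RTW1 = 0.86, RTW12 = 0.87, RTW123 = 0.94)
expect <- expectations_for_symbiotypes(phi, b = b)
write.csv(expect, "results/expectations.csv", row.names = FALSE)
print(expect, digits = 4)
cat("A quarter of each X0 mother's eggs are OO and inviable; at equilibrium\n",
    "just over half of infected females are X0, so the expected undeveloped\n",
    "proportion lands near 0.17 for every feminizing symbiotype.\n")
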