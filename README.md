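# femcost

Fitness costs of symbiont-mediated feminization in XX/X0 hosts.

Maternally inherited bacterial endosymbionts such as *Wolbachia* can
feminize genetic males into functional females, biasing host broods toward
infected, transmitting daughters. In a host with XX-female / X0-male sex
determination (including composite systems such as the spider
X1X1X2X2 / X1X2 karyotype, treated here as one linked XX/X0 unit), a
feminized X0 mother can provision an X chromosome to only half of her
eggs. Crossed to an X0 male — whose sperm carry an X half the time — her
zygotes are 1/4 XX, 1/2 X0, and 1/4 OO, and OO zygotes are presumed
inviable: a built-in 25% viability cost that the symbiont cannot
manipulate away.

`femcost` is for researchers studying reproductive manipulation who want
to ask: *given a population at transmission equilibrium, what proportion
of undeveloped eggs should a feminizing infection produce, and do observed
broods match that expectation?* It provides:

- **Karyotype transmission model.** Among infected females, let `x` be
  the fraction that are genetic XX and `φ` the probability that an
  infected X0 individual develops as a functional female (so `1 − φ` is
  feminization failure). With perfect maternal transmission the
  generation recursion is

      x' = [x/2 + ρ(1−x)/4] / [x(1/2 + φ/2) + ρ(1−x)(1/4 + φ/2)]

  (`ρ` = relative X0/XX fecundity, default 1). For `ρ = 1` the fixed
  point is the root of `x² + 2φx − 1 = 0`, i.e. `x* = −φ + √(φ²+1)`;
  at `φ = 1`, `x* = √2 − 1 ≈ 0.414`, so ~59% of infected females are
  feminized X0. `φ` is estimable from observed brood sex ratios by
  inverting the equilibrium male fraction.
- **Expected undeveloped-egg proportion.** X0 mothers lose the OO
  quarter; background per-egg mortality `b` (estimated by pooling the
  non-feminizing broods) composes multiplicatively:
  `E = 1 − (1 − 0.25 q)(1 − b)` where `q = 1 − x*`.
- **Monte Carlo confidence intervals.** 500,000 seeded draws of the
  brood-mean undeveloped proportion, conditioned on the observed eggs per
  eggmass, with each brood's maternal karyotype redrawn every draw.
- **Overdispersion-corrected statistics.** Grouped binomial logistic
  regression with Williams' correction (weights `1/(1 + δ(n−1))`, `δ`
  solved so Pearson χ² equals its residual df), deviance-difference
  tests, one-way ANOVA on total eggs with a planned contrast, and
  Tukey–Kramer pairwise tests with a compact letter display.
- **Synthetic data generator.** Brood-level datasets with the structure
  of a six-symbiotype spider experiment (U, R, RT, RTW1, RTW12, RTW123;
  30 females each; latent XX/X0 karyotypes; mating failures; exclusion
  filters), so the whole pipeline is testable without any downloads.

## Worked example

The analysis lives in numbered scripts under `analysis/`
(`01_simulate.R` → `04_statistics.R`), each a thin driver over the
package functions, writing its tables to `results/`. Running them in
order prints, for one simulated experiment:

```
Pooled baseline per-egg failure (U, R, RT): 0.0465
  symbiotype  phi   q_x0 expected_undeveloped
1       RTW1 0.86 0.5411               0.1755
2      RTW12 0.87 0.5445               0.1763
3     RTW123 0.94 0.5676               0.1818

  symbiotype expected ci_lo ci_hi observed within_ci
1       RTW1    0.176 0.121 0.234    0.128      TRUE
2      RTW12    0.176 0.120 0.236    0.188      TRUE
3     RTW123    0.182 0.128 0.239    0.164      TRUE

Viability varies among symbiotypes: dDev = 65.26, df = 5, p = 9.9e-13 (delta = 0.039)
Feminized vs not:                    dDev = 61.36, df = 1, p = 4.7e-15
Total eggs: F(5,163) = 3.499, p = 0.005; feminized contrast t = -3.797 (df 163)
```

Reading this: about 4.7% of eggs fail in the non-feminizing symbiotypes
(background mortality). At equilibrium ~54–57% of infected mothers are
X0, so the model expects ~17–18% of feminized-symbiotype eggs to be
undeveloped — and each symbiotype's observed brood mean falls inside its
Monte Carlo 95% interval, while the deviance tests confirm that the extra
egg failure and the egg-count reduction track the feminizing symbiont.

Equivalent single calls: `generate_study()`, then
`run_pipeline(broods, pipeline_config())` returns the whole results
document at once.

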