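---
title: "Modelling the fitness cost of symbiont feminization in XX/X0 hosts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the fitness cost of symbiont feminization in XX/X0 hosts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femcost)
```

## The model

A feminizing, maternally transmitted endosymbiont turns genetic X0 males
into functional females. Because an X0 mother segregates her single
(composite) X fairly, half her eggs carry no sex chromosome; sired by an
X0 male, her zygotes are 1/4 XX, 1/2 X0 and 1/4 OO, and OO zygotes are
taken to be inviable. The host's two distinct X chromosomes are modelled
as one co-segregating linked unit — the expectation is unchanged in
composite XX/X0 systems — and independent segregation of the two X's is
deliberately not modelled.

Three assumptions define the transmission model:

1. **Perfect maternal transmission**: every offspring of an infected
   mother is infected.
2. **Imperfect feminization**: an infected X0 individual develops as a
   functional female with probability $\varphi$; otherwise it is male.
3. **All sires are X0 males**, and sire infection is irrelevant to
   karyotype outcomes (cytoplasmic incompatibility is outside the model's
   scope, which is why crosses use uninfected males).

Among infected adult females, with $x$ the genetic-XX fraction and $\rho$
the relative egg number of X0 mothers, next generation's XX fraction is
XX-daughter production over total daughter production:

$$x' = \frac{x/2 + \rho(1-x)/4}
            {x\,(1/2+\varphi/2) + \rho(1-x)\,(1/4+\varphi/2)}.$$

For $\rho = 1$ this simplifies to $x' = (1+x)/(1+x+2\varphi)$, whose
fixed point is the admissible root of $x^2 + 2\varphi x - 1 = 0$,
$x^* = -\varphi + \sqrt{\varphi^2+1}$. `solve_equilibrium()` uses the
closed form and verifies the fixed-point residual; `iterate_equilibrium()`
provides the iterative cross-check. At $\varphi = 1$,
$x^* = \sqrt2 - 1 \approx 0.414$: a majority ($q = 1-x^* \approx 0.586$)
of infected females are feminized X0.

Feminization failure sends X0 offspring into the male pool, so the
equilibrium male fraction among viable offspring,
$[(1-\varphi)/2] \,/\, [x + \rho(1-x)\tfrac34]$, is strictly decreasing
in $\varphi$; `estimate_phi_from_sex_ratio()` inverts it by bisection on
$[0,1]$ (tolerance $10^{-8}$), which is how $\varphi$ is estimated from
the observed adult sex ratios of the broods that produce the experimental
mothers.

## Expected undeveloped eggs

X0 mothers lose the OO quarter of their eggs; background per-egg
mortality $b$ affects every egg and composes multiplicatively, giving
per-egg failure $b$ for XX mothers and $0.25 + 0.75\,b$ for X0 mothers.
Averaging over the equilibrium mix,

$$E = 1 - (1 - 0.25\,q)(1 - b)
    = q\,(0.25 + 0.75\,b) + (1-q)\,b .$$

$b$ is estimated from the non-feminizing symbiotypes as total undeveloped
eggs over total eggs (**pooled**, not a mean of per-brood proportions): a
per-egg probability is what the multiplicative composition requires. The
mean-of-proportions variant is available via
`baseline_mortality(..., method = "mean")` for sensitivity analysis; on
balanced brood sizes the two nearly coincide. Exclusion filters are
applied before estimating $b$.

With $b = 0.04$ and $\varphi$ between 0.85 and 0.95, $E$ falls between
0.165 and 0.180 — the window in which feminizing symbiotypes are expected
to land, roughly four times the background failure rate.

## Monte Carlo confidence intervals

`simulate_undeveloped_distribution()` simulates the sampling distribution
of the **unweighted mean of per-brood undeveloped proportions** (the
statistic used for the observed data; a pooled variant is available via
`mc_config(statistic = "pooled")`), holding each brood's egg count fixed
at its observed value. Each of the 500,000 draws resamples every brood's
maternal karyotype (X0 with probability $q$) and then its undeveloped
count binomially. Redrawing karyotypes every draw is a deliberate choice:
the experimenter cannot condition on karyotype (XX and X0 females are
morphologically indistinguishable), so karyotype uncertainty belongs in
the interval, and it is what makes the intervals as wide as ~0.12 at 30
broods of ~16 eggs — the karyotype lottery contributes far more variance
than the binomial layer. The 95% interval is the pair of empirical 2.5%
and 97.5% quantiles (type-7 linear interpolation). A single integer seed
makes the result exactly reproducible; pipeline runs derive independent
per-symbiotype streams from the master seed.

## Overdispersion-corrected statistics

Brood-level proportions are typically more variable than binomial
sampling allows. The grouped binomial logistic fits (`fit_logistic()`,
IRLS via the standard quasi-binomial machinery) are therefore corrected
with Williams' moment method: per-brood weights
$w_i = 1/(1+\delta(n_i-1))$ with the heterogeneity $\delta$ chosen so the
weighted fit's Pearson $\chi^2$ equals its residual degrees of freedom.
$\delta$ is found as a root of that moment condition (bracketed search,
at most 50 iterations, tolerance $10^{-8}$) and floored at 0 —
underdispersion is not corrected, and when every brood has a single egg
$\delta$ is unidentifiable and reported as 0 with a warning. Nested
models are always refit with the **full model's weights held fixed**, so
the deviance difference has its usual $\chi^2$ reference; in simulations
this restores near-nominal size under beta-binomial heterogeneity, where
the uncorrected test rejects a true null several times too often.

Total egg counts are compared with a one-way fixed-effects model; the
feminized-vs-not comparison is a planned contrast of the two sets of
group means using the pooled residual mean square (computed within the
six-group model, so its df is the model's residual df). All pairwise mean
comparisons use the studentized range with the Tukey–Kramer standard
error for unbalanced groups (exclusions make groups unequal); the compact
letter display is built by insert-and-absorb over the significance
matrix, which the test suite checks against a brute-force clique-cover
oracle. Group dummy coding is reference-level and the tests verify the
results are invariant to the reference choice.

## The synthetic-data generator

`generate_study()` emulates the design of the motivating spider
experiment: six symbiotypes (U, R, RT, RTW1, RTW12, RTW123; any carrying
Wolbachia 1 feminizes), 30 females each, one eggmass per female sired by
an uninfected male. Per female it draws a mating Bernoulli, a latent
karyotype (X0 with the equilibrium probability implied by that
symbiotype's $\varphi$), a negative-binomial egg count, independent
per-egg failures, and a rare symbiotype-mismatch flag.
`apply_exclusions()` then removes unmated females, zero-development
broods and mismatches, as the experimental dataset construction does.

Default calibration, chosen once:

| parameter | default | rationale |
|---|---|---|
| $\varphi$ (RTW1, RTW12, RTW123) | 0.86, 0.87, 0.94 | back-calculated so that with $b=0.04$ the model expectations reproduce the reported 0.170 / 0.171 / 0.176; the study's own per-symbiotype feminization-failure estimates live in its supplement and are not public in the main text, so these are calibration defaults, not ground truth |
| $b$ | 0.04 | the reported non-feminized undeveloped proportion |
| mean eggs/eggmass | 18.75 (non-fem), 15.75 (fem) | back-calculated from ~3.19 undeveloped eggs at proportion ~0.20 and the reported ~16% egg reduction |
| egg-count dispersion | NB size 20 | means are all that is reported; moderate count overdispersion is biologically typical and exercises the Williams machinery; a Poisson option exists |
| mating failure | 0.061 | the reported initial non-mating rate |
| symbiotype mismatch | 0.006 | the reported diagnostic mismatch rate |

What the generator does **not** emulate: real between-female
heterogeneity in per-egg mortality beyond the karyotype mixture (eggs
fail independently given karyotype), maternal age or condition effects,
multi-generation pedigrees, lifetime fecundity beyond the first eggmass,
and any mechanism producing whole-brood failure (zero-development broods
arise only as rare binomial accidents, not at the few-percent rate real
infertility produces). Passing tests therefore show the pipeline is
correct under the stated model, not that real broods obey it.

Zero-egg females are recorded as unmated (the design distinguishes "did
not mate" from "0% development"); mated females always lay at least one
egg (zero-truncated counts). The latent karyotype column is emitted only
with `reveal_latent = TRUE`, so tests can condition on truth while the
default output mimics what an experimenter can observe.

## Numerical choices and degenerate inputs

- Equilibrium: closed-form quadratic root, residual-checked at
  $10^{-10}$ by default, cross-checked against 10,000 fixed-point
  iterations in the tests; no admissible root in $[0,1]$ is an error.
- `recursion_step(0, phi = 0)` is rejected as degenerate: with no
  feminization an all-X0 infected-female population cannot exist (the
  formula itself does not underflow there, so the guard is explicit).
- Offspring distributions must sum to 1 within $10^{-12}$ (asserted at
  construction).
- Complete separation in the logistic fit (a group with all-0 or all-1
  outcomes) is flagged and coefficients are capped at $\pm 30$.
- Monte Carlo sampling is chunked (~2M deviates per block) to bound
  memory at 500,000 draws.

## Problem sizes used in the checks

The shipped test-suite simulations use: 500,000 draws for the single-run
Monte Carlo checks with 500-replicate coverage; 200 replicates for the
null behaviour of $\delta$; 1,000 replicates for type-I error under
beta-binomial heterogeneity; 500 replicates for end-to-end power at the
default 30-females-per-symbiotype design; and $10^5$ mothers over 50
generations for the individual-based equilibrium check. These sizes give
Monte Carlo standard errors comfortably below the tolerances asserted.

## Known limitations

- The per-symbiotype $\varphi$ defaults are calibrated, not estimated
  from public data; analyses of real broods should supply their own via
  `generator_params()` / `pipeline_config()`.
- $q$ cannot be estimated from offspring genotypes here (no X-linked
  markers distinguish X0 from XX females); everything flows through the
  equilibrium assumption.
- The Williams-corrected deviance test is approximate: the $\chi^2$
  reference holds the weights fixed, and small numerical differences from
  other implementations' weight-initialization choices are expected.
- The recursion weights mothers by viable-offspring output when composing
  the next generation; weighting by total eggs laid would change the
  equilibrium slightly. The viable-output weighting is the biologically
  coherent choice (inviable OO eggs cannot be counted as daughters).
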