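---
title: "Methods: choice-experiment design, simulation and estimation in capdce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: choice-experiment design, simulation and estimation in capdce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

capdce implements the quantitative pipeline of a stated-preference pilot for
capitation contracts. Random Utility Theory supplies the model: respondent
$n$ facing task $s$ assigns alternative $j$ the utility
$U_{nsj} = x_{sj}'\beta + \varepsilon_{nsj}$, chooses the maximum, and with
i.i.d. type-I extreme value errors the first choice follows the multinomial
logit (MNL)

$$P_{sj}(\beta) = \frac{\exp(x_{sj}'\beta)}{\sum_m \exp(x_{sm}'\beta)}.$$

The opt-out ("none") alternative is an all-zero attribute row plus an
estimated alternative-specific constant (ASC), so a single coefficient
captures the average disutility of choosing nothing.

### Attribute coding

Every attribute enters the utility **linearly through its numeric level
code** — months for the payment schedule (1, 3, 6, 12), shillings for the
capitation rate (1200–4800), 0/1 indicators for timeliness and performance,
and an ordered 0–3 service-package count. This matches the pilot's
published analysis, which reports one coefficient per attribute and builds
"maximum effects" as $|\beta_k|$ times the code range (11, 1, 3600, 3, 1).
Dummy (indicator) coding is available as an option (`coding: indicator` in
the config) for genuinely categorical attributes, but it is not the default
scheme. For the final four-attribute set the 3-level timeliness and 4-level
services attributes are plausibly categorical; the shipped fixture defaults
them to linear codes 0,1,2(,3) and a user who disagrees flips one field.

## Design generation

The D-error of a design at point priors $\beta_0$ is
$\det(I(\beta_0)^{-1})^{1/K}$ with the MNL Fisher information
$I = \sum_s X_s'(\mathrm{diag}(p_s) - p_s p_s')X_s$. `optimize_design`
minimizes it by multi-start **coordinate exchange**: sweep every (task,
alternative, attribute) position, try each level, accept only strict
improvements (first improving level wins; ties never move — determinism),
stop after a pass without change. The opt-out row is fixed and never
exchanged; exchanges that would duplicate an alternative within its task
are skipped, and random starts redraw distinct profiles per task. A
singular information matrix yields `d_error = Inf` (a flag, not an error),
which the optimizer escapes on the first identifying exchange.

The true pilot priors were "educated best guesses" and were never
published. The fixture configs therefore carry **sign-consistent stand-ins**
scaled so each attribute's prior utility span $|\beta_{0k}| \times
\mathrm{range}_k$ is roughly 0.5 (schedule −0.045, timeliness 0.5, rate
0.00014, services −0.17, performance −0.5, ASC −0.2). These are package
defaults chosen once, documented as non-published values; the generated
8-task design is shape-compatible with the pilot's, not byte-identical,
because the original tasks were not published either.

## Synthetic data

`simulate_choices` is the package's stated world for the pilot: 31
respondents × 8 tasks × (2 capitation alternatives + opt-out), utilities
linear in the codes plus independent Gumbel noise drawn as
$-\log(-\log u)$, full rankings from best (1) to worst (3) by descending
utility — hence 248 first-choice observations over 744 rows. The pure MNL
process draws fresh noise per task with no respondent effect; an optional
normal random-coefficient layer (`random_sds`) makes panel mixed-logit data
for recovery tests. What the generator does **not** emulate: attribute
non-attendance, learning or fatigue across the eight tasks, or any
real-respondent deviation from utility maximization. A green recovery test
therefore establishes correctness of the estimator under the model, not
behavioural realism of the pilot sample, whose microdata were never
released.

## Estimation

`fit_mnl` maximizes the MNL log-likelihood by Newton–Raphson with the
analytic score and Fisher information $X'(\mathrm{diag}(p)-pp')X$ (for the
MNL the observed and expected information coincide and do not involve the
outcome). The log-likelihood is globally concave, so the optimum is unique
and start-point invariant; convergence is declared at score norm
$\le 10^{-8}$ with a 500-iteration cap and step-halving as a safeguard.
Non-identified fits (for example an attribute with no within-task contrast
anywhere) are flagged `converged = FALSE` with a note, never silently
returned.

Two covariances are reported: classical $I^{-1}$ and the sandwich
$I^{-1} B I^{-1}$ with scores summed within respondent before the outer
product (**cluster-robust**, 8 tasks per cluster). Clustering on the
respondent is the defensible panel choice when only "robust" is specified;
it is switchable (`cluster = FALSE`), and no small-sample degrees-of-freedom
correction is applied — the convention is fixed for reproducibility. With
one task per respondent the clustered and per-observation sandwiches
coincide exactly, which the tests assert.

**Numerical conditioning.** The shillings column spans 1200–4800 while the
indicator columns span 0–1, putting the raw information matrix's condition
number past $10^8$ and stalling Newton from extreme starts. Estimation
therefore max-abs-scales each encoded column internally and transforms
coefficients and covariances back to original units afterwards; the
reported estimates are unchanged (the same device, fixed at per-1,000
shillings, conditions the design module's information matrix).

**Forced choice.** `include_optout = FALSE` drops opt-out rows, discards
tasks where the opt-out was chosen (the count is reported, never silent),
and removes the ASC — the secondary analysis in which a counter-intuitive
performance-requirements sign reversed.

**Fit statistics.** `fit_stats` computes $AIC = 2K - 2\ell$,
$BIC = K\ln n - 2\ell$ and adjusted
$\rho^2 = 1 - (\ell - K)/\ell_0$. The published baseline
$\ell_0 = -250.6159$ is *not* the equal-shares null
($248\ln\frac13 = -272.456$); conventions differ across estimation
software, so the baseline is an explicit parameter defaulting to the
equal-shares null, and both conventions are documented here. Estimation
uses first choices only; rank-ordered (exploded) logit is out of scope, the
generator emitting full ranks so either analysis remains possible.

**Mixed logit.** `fit_mmnl` maximizes the simulated log-likelihood of the
panel mixed MNL: per respondent, the log of the average over draws of the
product over tasks of MNL probabilities at normally distributed
coefficients. Defaults follow the secondary analysis's spirit: all five
attribute coefficients random, ASC fixed, 500 Halton draws (the published
supplement holding the exact specification is not in the main text). The
Halton generator allocates **contiguous blocks** of the sequence to each
respondent — interleaving would give every respondent a strided, badly
clustered subsequence and biases the variance estimates (caught by the
recovery test during development). With all standard deviations at zero
every draw coincides and the simulated likelihood equals the MNL
log-likelihood up to floating-point reordering ($<10^{-12}$); standard
errors come from the numerical Hessian.

## Post-estimation

Willingness to accept for attribute $k$ is $-\beta_k/\beta_{cost}$,
shillings per individual per year of compensation per unit of the
attribute's code; its standard error is the delta method with gradient
$(-1/\beta_c,\ \beta_k/\beta_c^2)$ on the corresponding 2×2 block of the
robust covariance. The ratio is refused when $|\beta_{cost}| < 10^{-12}$.
Relative importance is $|\beta_k| \cdot \mathrm{range}_k$ normalized to
shares. The ASC is excluded from both by default — it is not an attribute —
though the published table does print an opt-out WTA, so
`include_optout = TRUE` reproduces it. Feeding the published rounded
coefficients through these formulas reproduces the published importance
table exactly at 4 decimals and the WTA column within 2% (the published
ratios were formed from unrounded internals).

## Tolerances and degenerate inputs

- D-error: `Inf` on `rcond` below $10^{-12}$ or non-positive determinant.
- Coordinate exchange accepts improvements larger than $10^{-12}$ only.
- One-respondent datasets estimate but flag non-convergence or huge SEs;
  empty files, duplicate keys and multi-chosen tasks are parse errors that
  name the offending task.
- All randomness is seeded; identical configs give bit-identical datasets,
  designs and output manifests (md5-hashed in `manifest.json`).

## Known limitations

Bayesian D-error over prior distributions, blocked designs, interactions,
rank-ordered estimation, latent-class and WTP-space models, and
Krinsky–Robb WTA intervals are deliberately out of scope. The
minimum-information group-inference (acceptable/unacceptable) responses
collected in the pilot have no published quantitative analysis and are not
modelled.
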