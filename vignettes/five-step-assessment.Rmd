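---
title: "Assessing statistical and clinical significance of a randomised trial in five steps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing statistical and clinical significance of a randomised trial in five steps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fivestep)
```

## The problem

A randomised clinical superiority trial is conventionally declared positive
when the primary outcome's two-sided P-value falls below 0.05.  Three things
make that declaration fragile.  First, the P-value measures compatibility
with the null hypothesis only; a result can be incompatible with the null
and *also* incompatible with the effect the trial was powered to detect.
Second, apparent significance may be manufactured by multiplicity — many
outcomes, many time points, or repeated looks at accumulating data.  Third,
a statistically significant effect can be clinically trivial.  `fivestep`
operationalises a five-step assessment that addresses each of these in
turn, for trials whose results are available as published summary
statistics (an estimate with a confidence interval, standard error or
P-value, or a 2×2 table of events).

## The model

All ratio measures (odds, risk and hazard ratios) are analysed on the
natural-log scale; mean differences on the identity scale.  A trial result
is reduced to the triplet \((\hat\theta, SE, P)\), where
\(P = 2(1 - \Phi(|\hat\theta|/SE))\) is the two-sided Wald P-value.  When a
result supplies several precision sources the confidence interval is
authoritative; the standard error implied by the P-value is recomputed and
a warning raised if the two disagree by more than 10% in relative terms
(published inputs are rounded, so small disagreement is expected).
Published hazard- and risk-ratio results are log-transformed and then
treated exactly like log odds ratios downstream; risk-ratio design effects
are first converted through the control-group risk,
\(OR = \frac{RR\,p_0/(1-RR\,p_0)}{p_0/(1-p_0)}\).

### Step 2: the Bayes factor

The alternative hypothesis \(\theta_A\) is the intervention effect assumed
in the sample-size calculation, on the analysis scale.  The Bayes factor is
the deliberately simple two-point Gaussian likelihood ratio

\[
BF \;=\; \frac{\exp\!\left(-\hat\theta^2/2SE^2\right)}
             {\exp\!\left(-(\hat\theta-\theta_A)^2/2SE^2\right)},
\qquad
\log BF = \frac{\theta_A^2 - 2\hat\theta\theta_A}{2SE^2}.
\]

No priors and no integration are involved: the ratio compares the data's
likelihood under exactly two point hypotheses.  \(BF = 1\) when
\(\hat\theta = \theta_A/2\); \(BF < 0.1\) (the default, configurable
threshold) is read as ten-fold support for the anticipated effect, and
\(BF > 10\) as the mirror-image support for the null.  Direction matters:
an observed harm against an anticipated benefit produces an enormous BF.
When the anticipated effect was not taken from a systematic review, a
*sceptical* BF is added, whose alternative is the ratio halfway between 1.0
and the hypothesised ratio — the midpoint is taken on the ratio scale
(so RR 0.80 becomes 0.90), with a log-scale option available in
`sceptical_alternative()`.

```{r}
bayes_factor(-0.12, 0.04, -0.11)
```

A caveat established analytically in the test suite: at a design with 80%
power, the probability of attaining \(BF < 0.1\) when the true effect
equals \(\theta_A\) is about 0.71, not 0.80 — the BF threshold is a
strictly harder bar than \(P < 0.05\).  The package makes no claim that the
two coincide.

### Step 3: early stopping and interim analyses

The information fraction is \(t = \min(1, n/N)\) for \(n\) randomised of
\(N\) planned.  Thresholds are adjusted with O'Brien–Fleming-type
boundaries in two forms:

* `obf_classic`: constant score-scale critical value, \(z_k = c/\sqrt{t_k}\),
  with \(c\) solved so the total two-sided crossing probability equals
  \(\alpha\);
* `obf_spending` (default): the Lan–DeMets O'Brien–Fleming-type spending
  function \(\alpha^*(t) = 2(1 - \Phi(z_{1-\alpha/2}/\sqrt t))\), which
  permits arbitrary, unplanned stopping fractions.

Crossing probabilities for the correlated statistic sequence are computed
by recursive numerical integration of the score process: the continuation
density is propagated between looks by convolution with the independent
Gaussian increment, using composite Simpson quadrature on an adaptive grid
(at least 801 nodes, refined whenever the increment kernel is narrow, so
that single-look results agree with \(\Phi\) to better than 1e-8 and
cumulative alpha is conserved to 1e-6).  Critical values are found by
`uniroot` to 1e-9.  The two forms are close but not identical — the
spending function is a deliberate approximation of the classic boundary;
measured differences at equally spaced looks reach ~0.18 on the z scale at
the first of five looks, shrinking to <0.03 at the final look.  A trial
stopped at half information faces a threshold of about 0.0056 rather than
0.05:

```{r}
gs_boundaries(c(0.5, 1), method = "obf_classic")
apply_sequential_adjustment(0.04, 0.5)$required_threshold
```

Confidence intervals at an adjusted look are widened to the complementary
level \(1 - p_{\text{nominal}}\) (repeated-confidence-interval style); the
field offers no single canonical answer here, and the report flags the
convention used.  For a trial with planned interim looks the threshold
comes from the full boundary set; for a single unplanned early stop it
comes from the spending function at the achieved fraction.  A trial that
reaches (or exceeds) its planned size with no interim analyses keeps its
design alpha unchanged.

### Step 4: multiplicity

When several non-exploratory outcome comparisons can each declare the
trial positive, familywise error is controlled strongly (under every
configuration of true and false nulls).  Bonferroni and Hommel adjusted
P-values are delegated to `stats::p.adjust`; the fixed-sequence procedure
(test in pre-specified order at full alpha, stop at the first failure) and
the fallback procedure (weighted alpha that accumulates along the
hierarchy and never stops) are implemented directly.  An independent
closed-testing oracle (`closed_testing_adjust`) enumerates all \(2^m-1\)
intersection hypotheses with Simes or Bonferroni local tests; with Simes
tests it reproduces Hommel exactly and is used to verify it.  Hommel is the
default when several comparisons exist and no procedure was pre-specified,
because Bonferroni is needlessly conservative for positively correlated
outcomes.  Exploratory outcomes are excluded from the family and flagged
for conservative interpretation.  No standard simultaneous confidence
interval exists for Hommel; the report provides adjusted intervals only
where a per-comparison local alpha is defined.

### Step 5: clinical significance

Clinical significance is assessed only when steps 1–4 all passed and
\(BF\) is strictly below its threshold; the gate is monotone (failing any
step can never switch it on).  For binary outcomes the package reports the
risk difference and \(NNT = \lceil 1/|\Delta| \rceil\) (ceiling, the
conservative convention: a risk difference of 0.08 prints NNH 13, not
12.5), labelled NNT or NNH according to the declared direction of benefit.
When arm risks are available but the gate failed, the NNT/NNH is still
shown, explicitly marked descriptive.  If a minimal clinically relevant
difference (MCID) is supplied on the analysis scale, the estimate is
compared inclusively against it, and a second flag records whether the
entire confidence interval clears it.  The balance of benefit against harm
is surfaced as a checklist flag, not computed: no harms model is part of
the procedure.

## The orchestrator

`assess_trial()` consumes a JSON (or YAML) trial specification, runs the
five steps and returns a deterministic, classed report; two identical
specifications yield byte-identical JSON renderings (reports carry no
timestamps for this reason).  Validation is schema-wide: all violations
are reported with their paths, and unknown fields are rejected.  A trial
whose protocol did not pre-specify a primary outcome
(`"primary_predefined": false`) fails step 4 outright, because the later
choice of which comparison to headline is itself a multiplicity.  The
composition order of steps 3 and 4 is: step 3 adjusts the primary
outcome's threshold for information, step 4 governs the family of
comparisons; the report documents this ordering rather than multiplying
the two adjustments.

```{r}
spec <- read_trial_spec(system.file("extdata", "example2.json",
                                    package = "fivestep"))
assess_trial(spec)
```

## The synthetic-trial generator

`simulate_binary_trial()` draws arm event counts binomially — at the count
level, with no normal approximation on the data side — with control risk
`p_control` and experimental risk `rr * p_control`.  Replicate `k` is
seeded as `seed + k`, so any single replicate is reproducible in
isolation; the batch harnesses (`estimate_type1_and_power`,
`bf_operating_characteristics`, `simulate_sequential_rejection`) seed once
and vectorise.  The generator emulates a parallel two-arm superiority
trial with a binary outcome and fixed per-arm size.  It does not emulate
survival time, covariates, missing data, non-compliance or drift over
calendar time, so passing calibration tests demonstrate the *procedural*
operating characteristics (type-I error, power, familywise error, BF
discrimination) under idealised sampling, not robustness to those
real-data complications.  Analyses of simulated tables use the Wald
log-odds statistic with a Haldane–Anscombe 0.5 correction on zero cells —
at very small arm sizes the Wald approximation is visibly anticonservative,
which is an intended, tested warning case rather than a defect.

## Numerical and design choices

* Calculations run at full precision; only report rendering rounds (log
  effects to 2 decimals, count-based SEs to 3).  Published worked values
  are reproduced at display precision; analytic identities are tested at
  1e-9 relative tolerance, values recomputed from rounded published inputs
  at 1%.
* The P↔SE inversion is limited by double precision through the normal
  tail: round trips hold to ~1e-9 at moderate z and degrade beyond z ≈ 6.
* Sample sizes use the unpooled normal-approximation formula without
  continuity correction, rounded up per group — the simplest standard
  form; designs stated as (control risk, RR) are converted to two risks
  before sizing.  An outcome with computed power below 0.80 is classified
  exploratory (0.80 itself is confirmatory).
* Monte-Carlo suite sizes: 10⁴ replicates for FWER/power/inflation checks,
  10⁶ for the two-look boundary oracle, 10³ random families for the
  Hommel/closed-testing identity — chosen so every stochastic assertion is
  a ≥/≤ bound with a 3-standard-error buffer rather than an equality.
* Zero cells in 2×2 tables receive a 0.5 addition to all four cells,
  flagged in the output.
* `information_fraction()` clamps over-recruitment to 1 with a note.

## Known limitations

Binding futility bounds, Pocock/Haybittle–Peto boundaries, stage-wise
adjusted point estimates, correlation-exploiting gatekeeping, adaptive
sample-size re-estimation, survival-time simulation and full Bayesian
posterior analysis are out of scope.  The Bayes factor is a two-point
likelihood ratio by design; it inherits the arbitrariness of the
sample-size calculation's anticipated effect, which is why the sceptical
variant exists and why a pre-registered \(\theta_A\) matters.
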