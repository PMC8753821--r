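---
title: "Methods: the adaptive recall-by-genotype design engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the adaptive recall-by-genotype design engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbgadapt)
```

## The design problem

A recall-by-genotype (RbG) study recruits from a genotyped cohort
conditional on genotype: a control group homozygous for the major allele at
every candidate SNP, and test groups homozygous for minor alleles, compared
on a deeply phenotyped continuous endpoint. Here the endpoint is the heat
pain threshold (HPT) after topical sensitization, with reference
distribution 42 ± 2.5 °C, and effects are expressed as Cohen's
d = (μ_test − μ_control)/σ, so 1 °C ≡ d = 0.4 at the default σ = 2.5 °C.

When the allelic effect size cannot be estimated in advance, a fixed design
gambles its whole budget on one guess. The adaptive alternative implemented
here spends a fixed budget (default `total_n = 100`) across up to
`n_groups = 3` sequential test groups. Each group is recruited alongside the
shared control arm to a single interim of `interim_n = 15` per group, at
which a pre-specified rule decides:

1. **Futility** — plug the observed |d̂| into the exact power function at
   the stage's *final* per-group size and the final two-sided level
   `alpha_final = 0.05`. Predicted power below `power_target = 0.80` stops
   the group; the next group starts.
2. **Efficacy** — otherwise, a two-sided pooled t-test at the stage's
   interim efficacy level; p at or below it stops the group for efficacy.
3. **Continue** — otherwise the stage runs to its final size and ends the
   study with the final analysis.

Predicted power exactly equal to the target counts as adequate (the rule is
"predicts ≥ 80%"). The futility branch is mathematically equivalent to
comparing |d̂| against the stage's minimum detectable effect, and the
package asserts this equivalence in its tests.

## Exact power engine

All design numbers come from the noncentral *t* distribution, never the
normal approximation: for *n* per group the pooled two-sample statistic has
df = 2n − 2 and noncentrality d·√(n/2), and two-sided power is
P(T < −t*) + P(T > t*) with t* the central critical value. Exactness
matters at these sample sizes: it reproduces the published schedule to two
decimals where the normal approximation does not, and it is why the package
reports that seven participants per group give 78.5% power at d = 1.6 — the
claim that seven suffice for "80%" holds only after rounding to the nearest
ten percent, and the smallest exactly-qualifying size is eight
(`required_n(1.6, 0.80, 0.05)`).

`required_n` seeds its search at the normal-approximation size and walks to
the exact boundary, returning the smaller n on ties.
`minimum_detectable_d` root-finds on the exact power curve over (0, 20]
with `uniroot` at tolerance 1e−10. Degenerate inputs error: d = 0 has no
finite sample size; n < 2 has no degrees of freedom; a zero pooled SD has
no effect size.

## The budget rule

Stage k's final per-group size is ⌊(total_n − interim_n·(k−1))/2⌋: each
previously stopped test group consumed `interim_n` participants, and the
remainder is split equally between the control arm and the live test group
(control recruitment slows after each adaptation to preserve parity). With
the defaults this gives 50/42/35 per group and futility cutoffs
d = 0.57/0.62/0.68. The floor (rather than round) is deliberate: it is the
parity-preserving choice, and at stage 2 it yields 42 per group and the
0.62 cutoff. A residual budget that cannot seat two interim-sized groups is
an infeasibility error naming the failing stage.

## Interim efficacy levels: printed constants versus spending

The package ships the three-stage efficacy levels 0.0013/0.0023/0.0055 as
**design constants** (`alpha_provenance = "printed"`), because they are the
published schedule of the design this engine implements. They are *not*
what the Lan–DeMets O'Brien–Fleming spending function produces at the
corresponding information fractions: at t = 15/50 = 0.3 the spend is
≈ 3.5 × 10⁻⁴, roughly a quarter of 0.0013, and no spending-family setting
we can reconstruct yields the printed triple. Rather than guess at the
original software invocation, `plan_design` records the provenance of
whichever levels it used and offers `efficacy_alpha_source = "computed"`
for a from-first-principles schedule, with `of_spending_cumulative` and
`two_look_nominal_alphas`/`crossing_probability` as the exact calculator.
User-supplied levels (`design_params(efficacy_alphas = ...)`) always win
and are tagged `"user"`.

A related published-value discrepancy is surfaced the same way: at the
shipped stage-2 level 0.0023 the exact minimum detectable interim effect at
n = 15 is d ≈ 1.55, while the published schedule prints 1.52 (its rows 1
and 3, 1.63 and 1.42, match our computation to two decimals). The planner
always emits its computed value and attaches the published triple as the
`published_interim_d` attribute; we do not force agreement, since either
the printed alpha or the printed effect size must be inexact and we cannot
know which.

Crossing probabilities for group-sequential schedules use the standard
continuation-density recursion on the Brownian (score) scale — a trapezoid
rule on a 2001-point grid per look, with boundaries capped at |z| = 10
(mass beyond is < 10⁻²³), accurate to ~10⁻⁷ against a closed-form single
look and verified against a 10⁶-draw Monte-Carlo bivariate-normal oracle in
the tests. Schedules with more than four looks fall back to Monte-Carlo
integration with a warning; the package's own designs use two looks.

### Final-analysis level

Whether the final test after a passed interim should use 0.05 unchanged or
a spending-adjusted level is genuinely ambiguous in two-look practice. The
default here tests the final at `alpha_final = 0.05`; with the tiny
O'Brien–Fleming-style interim spends this inflates the stage-wise error
only marginally (to at most ≈ 0.051 at the latest interim fraction, as the
planner tests assert), and it matches the published schedule's footnote
convention. A `strict_spending = TRUE` mode subtracts the interim spend
from the final level for users who want the conservative reading. Exact
error control is available by pairing each interim level with its two-look
partner from `two_look_nominal_alphas`.

## Simulator and its classification convention

`simulate_fixed_effect` draws complete trials (final size per group,
control N(0, 1), test N(d, 1) — "equal to the number of participants" is
read as *per group*, configurable), applies the interim rule to the first
`interim_n` observations per group, runs the final pooled test on the full
data, and classifies: a **halt** is correct iff the completed trial's final
test is non-significant; a **pass** (continue or efficacy stop) is correct
iff it is significant. False-negative halts and false-positive continues
are reported separately. Confidence intervals are percentile bootstrap,
resampling 100 replicate outcomes 1000 times by default, mirroring how the
interim-timing analysis summarises its uncertainty.

One property of this convention is worth flagging: even with
`interim_n = n_final`, the null correct-decision rate is below 100%,
because the futility bar (predicted power ≥ 80% ⟺ |d̂| ≥ 0.57 at n = 50)
is stricter than bare final significance (|d̂| ≥ 0.40), so trials landing
between the two cutoffs are halted yet would have been "significant". That
residual is P(0.40 ≤ |d̂| < 0.57) ≈ 4% under the null — a deliberate
feature of a futility rule that demands adequate power, not mere
significance — and the simulator tests assert its exact central-*t* value.

Both the futility-only and futility-plus-efficacy interim variants are
available (`efficacy_rule`), since either emulation is defensible;
operating characteristics at the design's own effect sizes are essentially
unchanged because an interim p ≤ 0.0013 at n = 15 implies |d̂| ≈ 1.33,
far above every futility cutoff.

`simulate_adaptive_study` chains stages with the budget bookkeeping above;
each replicate's consumption is by construction at most `total_n` (at most
interim_n·(k−1) + 2·⌊(total_n − interim_n·(k−1))/2⌋, checked in tests).
Randomness flows through a single seeded R generator; replicates are drawn
sequentially, so a fixed seed reproduces results bit for bit (there is no
parallel execution to require stream splitting).

## What the synthetic cohort emulates — and what it does not

The generator mimics recall from a birth-cohort-scale genotyped pool
(default `pool_n = 8000` young adults, the order of magnitude a regional
longitudinal cohort offers for recall at this age):

* **Genetics.** Five biallelic SNPs with MAFs 0.40, 0.10, 0.16, 0.15, 0.15
  under Hardy–Weinberg equilibrium; the group-2 pair in LD at r² = 0.51 and
  the group-3 pair at r² = 1, sampled as haplotypes with
  D = sign·√(r²·p_a(1−p_a)·p_b(1−p_b)) and minor alleles positively
  associated by default (the true haplotype phase being unstated,
  `sign = +1` is the natural reading of "high LD" between minor alleles;
  both r² values are feasible for their MAF pairs, and infeasible requests
  error with the Fréchet-bound maximum).
* **Eligibility.** Per-SNP imputation certainties from a mixture (96% of
  calls uniform on (0.99, 1], 4% on (0.90, 0.99]); eligibility requires
  > 0.99 at all five SNPs, retaining ≈ 0.96⁵ ≈ 81% of the pool — a
  realistic well-imputed-cohort yield. Telephone-screening exclusions are
  independent Bernoulli flags with small prevalences (2–5% per criterion,
  plausible for healthy young adults).
* **Recall.** Controls are dosage 0 at all five SNPs; group k members are
  dosage 2 at all of that group's defining SNP(s), with the other loci
  unconstrained (constraining them would shrink already-scarce minor
  homozygote pools, and the analysis compares groups defined only by their
  own SNPs). Shortfalls error with the Hardy–Weinberg expected yield.
* **Phenotypes.** Baseline HPT = 42 + z + e₁ and post-sensitization
  HPT = 42 + shift + Δ + z + e₂, with z a shared participant trait giving
  between-visit correlation 0.7 and both marginal SDs exactly 2.5 °C — so
  the analysis endpoint (post-sensitization HPT by default) has the SD the
  design math assumes. The sensitization shift defaults to −3 °C, a
  moderate heat hyperalgesia after a topical TRPA1 agonist. Secondary QST
  endpoints load on the same trait through a single common factor
  (loading 0.3); the sensitization pain rating is an integer 0–10. No
  thermode safety cap is applied by default (a 50 °C censor flag exists)
  because censoring distorts the normal model.

What passing tests on this cohort show is that the decision engine behaves
exactly as the abstract-scale mathematics predicts when its assumptions
hold. What they cannot show: real QST data have skewed and heteroscedastic
endpoints, log-scale mechanical thresholds, session and experimenter
effects, genotype-correlated attrition, and richer inter-endpoint
covariance than a one-factor model — none of which the generator attempts.
The single-SNP-group effect model also ignores any interaction between
loci.

## Problem sizes and numerical conventions

The test suite runs its Monte-Carlo cross-checks at sizes chosen to give
sub-percent standard errors while keeping the full suite around a minute:
2 × 10⁵ replicate t-tests for the power oracle, 10⁶ draws for the
boundary-crossing oracle, 10⁶ haplotypes (5 × 10⁵ individuals) for MAF and
r² recovery, 10⁴ simulator replicates against the analytic interim power,
and 2000 end-to-end synthetic cohorts for the efficacy-stop rate; all
tolerance bands are three Monte-Carlo standard errors at the size actually
run. Display rounding follows the design's reporting convention — d to two
decimals, °C to one — and lives only in `design_table`; JSON artifacts
carry full precision, and every JSON output embeds the run id of the
manifest that produced it.

## Known limitations

* The information fraction is sample-size-based under equal variance;
  unequal group sizes and variance-based information are out of scope.
* Futility is two-sided (|d̂|), consistent with the two-tailed test; a
  wrong-direction effect large in magnitude counts as "powered".
  A directional variant would need a one-sided redesign.
* The observed d̂ is plugged into the power function without shrinkage;
  interim effect estimates are noisy and upward-biased conditional on
  passing, which is the usual price of simple predicted-power futility.
* Group testing order is taken as given; optimizing it, and designs that
  recruit all groups in parallel, are out of scope.
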