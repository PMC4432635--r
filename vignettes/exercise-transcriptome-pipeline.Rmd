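---
title: "Methods: repeated-measures analysis of exercise time-course transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeated-measures analysis of exercise time-course transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exertome)
```

## Design and data

The pipeline targets subject-paired, multi-group expression time
courses: `G` independent groups (canonically a non-exercise control,
an endurance group and a resistance group), `n` subjects per group,
each measured at a baseline biopsy (Pre) and `T` post-intervention
times (canonically 2.5 h and 5 h, so 3 × 6 × 3 = 54 samples).  Inputs
are log2-scale intensities — the scale RMA-style array summarization
produces — as a transcripts × samples matrix plus a sample sheet
mapping sample → (subject, group, time).  Missing *values* are not
permitted (summarized arrays are complete); missing *samples* (a
subject lacking one post time) are permitted and handled by the model
engine.

## Baseline normalization

The biological quantity of interest is each subject's change from
their own baseline, so every value has the same transcript's Pre value
of the same subject subtracted (`normalize_to_pre()`).  On the log2
scale this is a fold change; Pre columns become identically zero, and
any per-subject additive offset — biological or technical — cancels.
Two consequences shape the rest of the pipeline:

1. After normalization the subject-level variance that remains in the
   ratios is the *shared Pre noise*: `Var(r) = 2σ²`,
   `Cov(r_t, r_t') = σ²` within a subject, which is exactly a subject
   random intercept with `σ²_subject = σ²_resid`.  The mixed model
   below absorbs this automatically; the generator's `sigma_subject`
   cancels entirely, as a paired design should.
2. Pre cannot enter the model as an observed factor level (zero values
   with zero variance); it is the **known** reference level
   `μ_{g,Pre} = 0`.

Before normalization, `baseline_group_test()` screens the Pre samples
alone with a per-transcript one-way ANOVA across groups plus BH-FDR, a
randomization check.  It is a gate that warns — never aborts — because
its role is descriptive; zero-variance transcripts get `F = 0, p = 1`
by convention.

## The per-transcript model

For post-time ratios, per transcript:

$$r_{gts} = \mu_{gt} + b_s + \varepsilon_{gts}, \qquad
  b_s \sim N(0, \sigma^2_{subject}), \;
  \varepsilon \sim N(0, \sigma^2_{resid})$$

a cell-means parameterization over group × post-time with a subject
random intercept, variance components by REML.

**Effects.**  Because baseline is the anchored level, the three
overall tests are the hypotheses a two-way repeated-measures ANOVA
with baseline as a time level would test, expressed on the post-only
model:

* *Time* (numerator df `T`): the group-averaged profile is flat at
  baseline, `mean_g μ_{gt} = 0` for every post time.  A sustained,
  uniform elevation at all post times **is** a Time effect — essential
  for the time-regulated rule below; a post-only profile test would be
  blind to it.
* *Group* (df `G − 1`): post-averaged group means equal — the exact
  classical split-plot F (`MS_group / MS_subject`).
* *Time × Group* (df `(G − 1)T`): all groups share one profile,
  `μ_{gt} = μ_t`.  In the anchored parameterization any
  group-dependent response — including a flat group-specific
  induction — is interaction, which is what the classification rules
  need "interaction" to mean.

**Contrasts.**  `E5h` tests `μ_{Endurance,5} = 0` (equivalent to
"different from Pre"); `SvE2.5h` tests
`μ_{Resistance,2.5} = μ_{Endurance,2.5}`.  Codes are C/E/S for
control/endurance/strength(resistance), configurable for other
designs via `model_spec(group_codes = ...)`.

## Numerical strategy

*Balanced designs* (the common case) are solved in closed form,
vectorized across all transcripts: REML coincides with the ANOVA
method-of-moments estimators
(`σ̂²_resid = MS_err`, `σ̂²_subject = (MS_subj − MS_err)/T`), and the
anchored Wald statistics decompose exactly into independent classical
F ratios from the two error strata, e.g.
`T·F_time = SS_elev/MS_subj + SS_time/MS_err`.  The p-value of such a
mixture is **not** a single F distribution; it is computed exactly as
the tail of a convolution of two independent scaled F variates by
64-point Gauss–Legendre quadrature (with a substitution removing the
integrable singularity), accurate to ~1e-7 — verified against
adaptive quadrature and Monte Carlo.  This keeps effect p-values
exactly uniform under the null, which the rule thresholds (raw
interaction p > 0.1) rely on.

*Unbalanced designs* fall back to a per-transcript profiled REML: the
residual variance is profiled out and the variance ratio
`λ = σ²_subject/σ²_resid` is found by bracketed root-finding on the
analytic REML score (tolerance `min(reml_tol, 1e-10)`, iteration cap
`reml_max_iter`).  Score root-finding, rather than minimizing the flat
profiled criterion, locates λ sharply enough that the Wald F agrees
with the closed form to ~1e-9 on balanced data.  Negative variance
components truncate at zero with a fixed-effects refit (pooled error,
OLS df).  Effect p-values on this path use Satterthwaite denominator
df (an approximation, documented as such); with one random intercept
non-convergence is essentially confined to degenerate inputs, and such
transcripts are flagged, excluded from FDR families (reducing the
family size m) and reported; `fit_all()` aborts only if more than
half the transcripts fail.

*Contrast df.*  Cell-mean contrasts mix the between- and
within-subject strata, so no single stratum df is exact.  The default
is Satterthwaite (pooling `MS_subj` and `MS_err` in the balanced path,
information-based in the general path); under the null its p-values
are uniform to KS distance ~0.001 at the study's size.  Containment
(subject-stratum df) is available via `model_spec(df_method =
"containment")` and is slightly conservative — df 15 versus an
effective ~18–24 under typical variance ratios.

*Degenerate inputs.*  A transcript with zero total variance gets all
`p = 1`, `F = 0`; a contrast with zero SE gets `p = 0` if its estimate
is nonzero (certainty in the zero-noise limit) and `p = 1` otherwise.
Exact zero sums of squares contribute zero evidence even when the
matching mean square is also zero.

## Multiplicity

BH-FDR (`bh_fdr()`, the standard step-up adjustment) is applied
**within one statistical family across transcripts** — one family per
effect and per contrast, never across contrasts — matching how
per-contrast significance flags are reported in this field.  Missing
p-values (non-converged transcripts) are excluded with the family size
reduced.  Significance is FDR q < 0.05 throughout except where a rule
explicitly quotes a raw p threshold.

## Classification rules

All thresholds are arguments with the conventional defaults
(`alpha = 0.05` on q; raw `p_interaction_floor = 0.1`;
raw `p_vs_pre = 0.05`) and are embedded in every export.

* **Changed vs Pre**: q of the cell's vs-Pre contrast < α.
* **Group-specific** (label = one group): at some post time the group
  is changed vs Pre *and* separated from both other groups; and the
  other groups are never changed vs Pre at any time (exclusion clause,
  q ≥ α).  At most one group can qualify.
* **Exercise-general**: both exercise groups changed vs Pre at ≥ 1
  time each; *dependent* of exercise type if the two exercise groups
  differ from each other (q < α) at ≥ 1 time, *independent* otherwise.
  The dependent/independent split is operationalized on the
  endurance-vs-resistance contrast because that is the only
  between-exercise statistic the model produces; it is a documented
  assumption, configurable through the rule arguments.
* **Time-regulated**: no interaction signal (raw p > 0.1), Time effect
  q < 0.05, and — because two thirds of the samples are exercise
  samples, a shared exercise response could masquerade as a time
  effect — all three groups individually changed vs Pre (raw p < 0.05)
  at the same time point.

Specific and general labels are mutually exclusive by construction
(one requires the other exercise group unchanged, the other requires
both changed); this is asserted in the tests on every simulated run.
Non-converged transcripts stay unlabelled (`NA`) in every rule set.

## The simulator

`generate_dataset()` draws
`value = baseline_transcript + subject_intercept + planted_shift +
N(0, sigma_noise)` with a documented RNG order (baselines, subject
intercepts, noise row-major) so identical configs are bit-identical.
Planted classes mirror the classifier's targets: `specific:<group>`
(that group's post cells only), `general_independent` (both exercise
groups equally), `general_dependent` (equal magnitude, opposite
signs), `time_all_groups` (all groups equally), `null`.  Pre cells
never carry shifts.

Defaults are the study's design constants (3 groups × 6 subjects ×
{0, 2.5, 5} h) and field-typical magnitudes: `effect_size = 1` log2
unit (2-fold, a solidly real but not extreme array response),
`sigma_noise = 0.25`, `sigma_subject = 0.5` log2 units (post-RMA
residual and subject scales), baseline `N(8, 1.5)` log2.  These give
high but not trivial power at n = 6.  The simulator emulates the
*structure* the model assumes — homoscedastic Gaussian log-scale
noise, a single shared subject intercept, flat planted shifts.  Real
arrays add heavy-tailed and intensity-dependent noise, correlated
transcripts, probe effects and batch structure; passing tests
therefore validate the statistical machinery and rule logic, not
robustness to those violations.  Per-transcript variance
heterogeneity is the main simplification: the model is fitted per
transcript, so homoscedasticity across transcripts is not assumed by
the pipeline, only by the generator's defaults.

## Problem sizes and runtime

The test-suite simulations are sized to exercise every property at
comfortable statistical resolution on a laptop-class single CPU: KS
uniformity and family-wise q calibration at 5,000 null transcripts
over 20 seeds; planted-effect recovery at 200 transcripts per class
(n = 6 per group); oracle equivalences at 100 transcripts / 1,000
random p-vectors; end-to-end determinism at 1,000 transcripts.  The
balanced closed-form path processes the full 28,869 × 54 study scale
in well under a second; the iterative path costs roughly a
millisecond per transcript.

## Known limitations

* One random intercept only; no moderated/empirical-Bayes variance
  shrinkage, spline time models, or transcript-transcript correlation.
* The exercise-general dependent/independent split rests on the
  between-exercise contrast alone (see above).
* Satterthwaite df on the unbalanced path and for contrasts is an
  approximation (calibration verified by simulation at the default
  design; strongly unbalanced designs should be checked by the user).
* Per-subject constant cancellation in normalization is exact to IEEE
  rounding of the added constant (last-ulp), not bit-for-bit.
* The upstream array processing (background correction, quantile
  normalization, summarization) is out of scope; the pipeline starts
  at the summarized log2 matrix.
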