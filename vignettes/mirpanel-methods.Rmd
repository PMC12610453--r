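---
title: "Methods: qPCR miRNA panel analysis, power and downstream interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qPCR miRNA panel analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpanel)
```

# Scope

`mirpanel` analyzes 96-well qPCR miRNA panels of the kind used in tissue
biomarker studies: 84 target miRNAs, three housekeeping references
(SNORD38B, U6 snRNA, SNORD49A) and vendor control wells. The package
covers within-sample normalization, two-group differential expression,
post hoc power via minimal detectable effect sizes (MDES), validated
miRNA–target convergence with hypergeometric over-representation, and
sign-concordance against an external sequencing-derived DE table. A
synthetic panel generator with the same statistical structure makes the
whole chain testable end to end.

# The inference model and its assumptions

**Normalization.** For sample $i$ and target assay $j$,
$\Delta Ct_{ij} = Ct_{ij} - \overline{Ct}^{HK}_i$, where
$\overline{Ct}^{HK}_i$ is the arithmetic mean of the housekeeping Ct
values detected in sample $i$. Relative expression is $2^{-\Delta Ct}$.
Because Ct is a log2-scale quantity, $\Delta Ct$ is log2 abundance with
inverted sign; all downstream inference operates on this scale.

**Group effects.** For contrast A vs. B,
$\Delta\Delta Ct_j = \overline{\Delta Ct}_{j,A} - \overline{\Delta Ct}_{j,B}$,
fold regulation $= 2^{-\Delta\Delta Ct_j}$, and
$\log_2(\mathrm{FoldReg}) = -\Delta\Delta Ct_j$, so positive values mean
up-regulation in the first-named group. This sign flip is the single
most common implementation error in ΔΔCt pipelines and is pinned by
invariant tests (`log2_fold_reg == -ddct`, `fold_reg * 2^ddct == 1`).

**Testing.** Per assay, Welch's two-sample $t$-test on $\Delta Ct$
(unpaired, unequal variances, Welch–Satterthwaite df), two-sided.
Benjamini–Hochberg step-up adjustment is applied across the *tested*
assays of a contrast: assays with fewer than two non-missing values in
either group are excluded from testing and therefore from the
multiplicity $m$, rather than contributing NA rows. Significance is the
dual filter $|\log_2(\mathrm{FoldReg})| > 1$ and FDR $< 0.05$.

The model assumes additive Gaussian noise on the ΔCt scale,
independence across samples, and no amplification-efficiency or
plate-batch artifacts (those are upstream QC concerns). Degenerate
inputs are resolved by convention: both groups constant and equal gives
$p = 1$; both constant and unequal gives $p = 0$ with infinite $t$.

**Covariate adjustment.** For selected miRNAs, an OLS fit of ΔCt on
group + age + BMI + grade gives a covariate-adjusted group coefficient
(flipped to fold-regulation sign). Grade is coded as unordered
categorical dummies — the weaker assumption, since no ordinal spacing is
known. Rank-deficient designs (e.g. constant grade) are an error naming
the offending columns rather than a silent NA coefficient.

# Post hoc power: MDES, π₀ and α policies

The sensitivity question "what could this comparison detect?" is
answered on the effect-size axis. For a two-sample $t$-test with common
SD $s$, the two-sided power at effect $\delta$ is
$P(|T| > t_{1-\alpha/2,\nu})$ with $T$ noncentral-$t$, noncentrality
$\delta / (s\sqrt{1/n_a + 1/n_b})$. MDES is the root of
power$(\delta) = $ target, solved by `uniroot` on $[10^{-6}, 20s]$ to
$10^{-9}$ log2 units.

Tunable parameters, defaults and rationale:

- **Representative SD** (log2 units / cycles): the median across target
  assays of the per-assay two-group pooled SD. Default: estimated from
  the data; the study-shaped configuration gives ≈ 1.8. A median is used
  so a few noisy assays do not dominate the summary.
- **df convention**: `pooled` ($n_a + n_b - 2$) by default — the
  convention of standard two-group power tools, and the one that
  reproduces the reference MDES values; `welch_equal_variance`
  (Satterthwaite df at equal variances) is available and gives slightly
  larger MDES for unbalanced designs.
- **α policies**: Bonferroni $\alpha = 0.05/m$ with $m$ the number of
  tested assays (84 in the study configuration), and the BH-effective
  level $\alpha_{\mathrm{eff}} = 0.05\,(1 - \pi_0)$, a per-test
  approximation to the average BH rejection threshold.
- **π₀ estimation**: the fixed-λ estimator
  $\#\{p > \lambda\} / (m(1-\lambda))$ with λ = 0.5 by default; a
  smoother variant fits a cubic smoothing spline to the estimate over a
  λ grid and evaluates it at the largest λ. The underlying study did not
  name its estimator, so both standard choices are provided and the one
  used is recorded in the output. Estimates are clamped to
  $[1/m,\, 1]$.
- **Floors**: when $\pi_0 \to 1$, $\alpha_{\mathrm{eff}}$ is floored at
  the Bonferroni level $0.05/m$ rather than collapsing to a zero-width
  rejection region; the MDES then coincides with the Bonferroni MDES,
  which is the conservative limit.

Monotonicity properties (MDES antitone in α and in $n$, increasing in
required power and in $s$; power increasing in δ with power(0) = α
exactly) are asserted over random grids in the test suite, and the power
function is cross-checked against an independent numerical-integration
oracle of the noncentral-$t$ tail.

# The synthetic generator: what it emulates and what it does not

`simulate_panel()` draws target ΔCt values i.i.d. Gaussian per assay
about a per-assay baseline, with dispersion `dct_sd` (default 1.8);
planted effects shift the first-named group's mean ΔCt by
$-\log_2$-effect, so the recovered fold regulation matches the planted
sign and magnitude. POLE-contrast effects apply only within cancer
samples, emulating a subgroup signature (the study-like configuration
plants down-regulation-only POLE signatures). Housekeeping assays are
generated near Ct 20 with SD 0.25; target Ct is reconstructed as
ΔCt + per-sample housekeeping mean, so normalization exactly inverts
the construction. Defaults mirror the study design: 40 cancer / 20
healthy, 7 POLE-mutant, 84 targets, baselines inside a LOD-safe range
(0–8 cycles above housekeeping) giving 0% missingness, as in the study
data.

Choices not fixed by any stated quantity, made once: housekeeping mean
Ct 20 and SD 0.25, baseline ΔCt range 0–8 (arbitrary within LOD-safe
ranges), age ~ N(63, 8) for cancer and N(58, 8) for controls, BMI ~
N(29, 5), grade sampled G1/G2/G3 (0.3/0.4/0.3). Grade is assigned to
*every* synthetic sample, healthy controls included, so the covariate
model is estimable on default panels; real healthy tissue has no tumor
grade, and the metadata reader keeps grade optional for real data. The
`confound_bmi` knob shifts BMI by group and couples it to
effect-bearing assays in the effect's direction, making covariate
adjustment falsifiable (adjusted estimates must attenuate).

What the generator does **not** emulate: amplification curves and
efficiency variation, plate/batch effects, heavy-tailed or correlated
assay noise, LOD censoring dynamics (default panels never censor), and
sequencing counts for the external platform (a fixture DE table with a
configurable agreement rate stands in). A green test therefore
establishes correctness of the statistical pipeline under its own
model assumptions — not robustness to instrument artifacts.

# Targets, enrichment and concordance

**Interactions.** Snapshots of validated miRNA→gene interactions are
deduplicated on (miRNA, gene), concatenating sources, so repeated
database entries never inflate counts. The functional filter keeps
support labels beginning with "Functional MTI"; weakly supported rows
("Functional MTI (Weak)") are excluded by default behind an explicit
flag, recording the policy for an inherently ambiguous label. Gene
symbols are the working key — numeric-id conversion collapses to a join
and is not required.

**Convergence.** Per direction, each gene's count of *distinct*
significant miRNAs targeting it; ranked descending, ties broken
lexicographically so rankings are deterministic. Top-20 by default.

**Over-representation.** Upper-tail hypergeometric test per term, genes
intersected with the universe first; the universe is the union of
validated targets across *all* retained miRNAs (both directions),
mitigating target-retrieval bias and making the two directions
comparable. BH across terms; display order is descending overlap count.

**Concordance.** miRNA names are matched in two stages: exact on
normalized names (lowercase, species prefix stripped), then stem
matching (arm suffix -5p/-3p stripped) for names unmatched at stage 1.
"Stem" matching is name-based: true sequence-level stem matching would
require a sequence catalog, so the conservative name reading is used
and each pair records its match stage. Ambiguous stems (one stem,
several unmatched arms) stay unmatched and are reported. Concordance is
sign agreement of the log2 fold changes, with zero treated as
sign-indeterminate (never concordant); the headline subset is
concordant **and** significant on the panel side only, since the
external table's significance is informative but not conditioned on.

# Numerical and design choices

- All tables are UTF-8 TSV/CSV (delimiter by extension), doubles
  serialized at 17 significant digits so write→read round-trips are
  exact.
- Ct at or above the LOD is retained and flagged, not blanked; exclusion
  decisions belong to the consuming operation.
- BH ties: stable sort, equal p receive equal adjusted values.
- Run configs are JSON (`jsonlite`); no YAML parser is part of the
  supported dependency set.
- Pipeline determinism: one integer seed drives panel simulation and
  every fixture generator (offset seeds per stage); the manifest records
  an MD5 per artifact, and identical config + seed reproduces identical
  hashes.
- The POLE contrast is constructed strictly within cancer samples.

# Known limitations

- Unbalanced-variance power: MDES uses a single representative SD; per-
  assay power curves under heteroscedasticity are out of scope.
- The empirical uniqueness of a single strong planted call is bounded by
  BH itself: with one overwhelming effect among 84 assays, step-up
  rejects at least one of the 83 nulls in ≈ 9–10% of panels (the test
  suite computes this bound with an exact Monte-Carlo oracle over
  uniform p-values and checks the pipeline against it). No
  implementation can exceed that bound without departing from BH.
- Paired designs, >2 groups, and moderated-variance (empirical Bayes)
  tests are out of scope; so are live database queries — interaction
  and term snapshots are local files.
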