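---
title: "Methods: the fraction-upregulated screen and its companions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fraction-upregulated screen and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fupscreen)
```

# The statistical model

## The fraction-upregulated statistic

The screen is built for matched designs: each patient contributes one tumor
and one adjacent-normal sample, so every comparison is within-patient and
patient- and tissue-level baselines cancel. For a marker with paired values
$(x_i, y_i)$ (tumor, normal) over $n$ patients, the statistic is

$$ f_{up} = \frac{k}{n_{eff}}, \qquad
   k = \#\{i : x_i > y_i\}, $$

where $n_{eff}$ counts the *informative* pairs: pairs that tie exactly, or
are missing on either side, enter neither $k$ nor $n_{eff}$. This is the
classical sign-test convention. We chose it (the excluded-ties form) because
it preserves an exact antisymmetry — swapping the tumor and normal matrices
maps $f_{up} \mapsto 1 - f_{up}$ with an identical p-value — which the test
suite verifies on random tied data. Because only the *sign* of each paired
difference is used, $f_{up}$ and its p-value are invariant under any
strictly monotone transform applied to both members of each pair; the
statistic is assumption-light and outlier-robust, at the cost of discarding
magnitude information.

Significance is assessed exactly against $K \sim \mathrm{Binomial}(n_{eff},
1/2)$. The two-sided p-value doubles the smaller tail,
$p = \min\!\big(1,\; 2\min(P(K \le k), P(K \ge k))\big)$, a deterministic
convention common in the sign-test literature (for the symmetric null it
coincides with the minimum-likelihood form). `sign_test_p()` is checked
against literal enumeration of all $2^n$ sign patterns for every $n \le 12$.

## Confidence intervals

Intervals come from a beta distribution with shape parameters set by the
sign-test counts. The default is the uniform-prior posterior
$\mathrm{Beta}(k + 1,\; n_{eff} - k + 1)$ with equal-tailed quantiles; a
Jeffreys option $\mathrm{Beta}(k + \tfrac12, n_{eff} - k + \tfrac12)$ is
exposed (`prior = "jeffreys"`). Both are standard; the default is recorded
in the output's `ci_prior` attribute so a table is never ambiguous about
how it was made. Equal-tailed (not highest-density) quantiles were chosen
because they are deterministic, cheap and symmetric under the
$k \mapsto n-k$ reflection. Calibration is a tested property: over
thousands of simulated markers with true up-probability drawn uniformly,
the 95% interval covers the truth 93–97% of the time.

`fup_screen(..., bonferroni_ci = TRUE)` widens intervals to the
simultaneous level $1 - (1 - \gamma)/m$ over the $m$ testable markers of
the same assay — the convention we attach to "Bonferroni-adjusted
confidence intervals". Both Bonferroni and Benjamini–Hochberg adjusted
p-values are always reported; `adjust_pvalues()` delegates to
`stats::p.adjust()` after input validation.

## Marker filtering and multi-tissue consensus

`filter_detectable()` keeps markers whose paired values differ in at least
half the patients (configurable). Its purpose is to remove
limit-of-detection markers that sit at identical floor values in both
tissues. "Detectable change" is operationalized as strict non-equality of
two non-missing values; an `epsilon` on the absolute difference is
available but defaults to 0. A pair missing on either side counts as "no
detectable change" and is excluded pairwise downstream — every patient
keeps equal weight and nothing is imputed.

For unbalanced multi-platform collections, `consensus_fup()` averages
per-tissue $f_{up}$ values (unweighted, over the tissues where the marker
is testable) and drops markers whose informative pairs sum to fewer than
500 across tissues. It deliberately produces no pooled p-value: the
consensus is a point summary for cross-dataset comparison, not a test.

# Proliferation scoring and detrending

## The meta-PCNA score

Tumor/normal differential signal is dominated by proliferation. The
per-sample proliferation score is the median expression of a
proliferation signature — the meta-PCNA meta-gene of Venet et al. (2011),
a set of 131 genes most correlated with PCNA in non-diseased tissue
compendia. The package does not bundle that gene list (it belongs to the
original publication and its supplement); users supply any signature as a
plain text file, one id per line, and the simulator emits its own
signature so the test-suite needs no external data. No standardization is
applied before taking the median: the inputs are assumed already
normalized to a common log-like scale, and the median is used exactly as
published. Scores are computed per sample — tumor and normal columns
separately — and differenced within patient wherever a "change in
proliferation" is needed.

A marker's proliferation association (`proliferation_association()`) is
the Pearson correlation, across patients, of the tumor−normal change in
the score with the tumor−normal change in the marker, pairwise-complete.

## The detrending model

To isolate tumor-associated signal that is *not* explained by growth rate,
every marker is residualized with ordinary least squares:

$$ \text{marker} \sim \text{metaPCNA} + \text{tissue}
   + \text{metaPCNA{:}tissue} $$

fit over the pooled tumor *and* normal samples of the matched cohort, and
the $f_{up}$ screen is repeated on the residual pairs
(`detrended_fup_screen()`). Two design points matter:

* **Tumor/normal status is deliberately absent from the design.** A
  proliferation-driven marker's tumor shift rides on the score and is
  removed; a proliferation-independent shift is (mostly) orthogonal to the
  design and survives into the residuals. Including status would absorb
  exactly the signal the screen is looking for.
* **One model for both members of each pair.** Residual pairs are only
  comparable if tumor and normal values are residualized under the same
  fit, which is why the fit pools all matched samples.

Tissue enters as full-rank treatment coding with the alphabetically first
tissue as reference; residuals are invariant to the reference choice (a
tested property). Single-tissue cohorts degrade to `~ metaPCNA` with a
message. Rank-deficient designs are resolved by the pivoted QR with a
warning. Numerically, residual pairs whose difference is below $10^{-8}$
of the marker's scale are treated as ties — a perfectly fitted or constant
marker must come out untestable, not as sign noise on $10^{-15}$
residuals.

Detrending attenuates even genuinely proliferation-independent tumor
shifts to the extent that the proliferation score separates tumors from
normals (the score is itself tumor-associated). Under the simulator's
default latent parameters the attenuation factor is
$(\tau_b^2 + \tau_w^2)/(\tau_b^2 + \tau_w^2 + \mu^2/4) \approx 0.75$; the
planted independent class at up-probability 0.9 lands near detrended
$f_{up} \approx 0.83$, still far from 0.5. This is a real property of the
method, not an artifact: perfect preservation is impossible whenever
proliferation and status are correlated.

# Gene-set enrichment

`gene_set_test()` compares the statistic (raw or detrended $f_{up}$)
inside a set against the *exclusive* background — all scored markers not
in the set — with a two-sided Mann–Whitney U test. Exclusive background
keeps the two groups disjoint, as the U test requires. The p-value uses
exact enumeration when both groups have at most 10 members and no ties,
otherwise the normal approximation with tie and continuity correction (the
two agree within 0.02 absolute at group sizes 8–10, a tested property).
Two-sided testing plus an explicit `direction` column was chosen over
one-sided tests so a single screen surfaces both up- and down-enrichments;
`effect` is the difference of medians (in-set minus background).
`min_set_size` defaults to 5 — below that the U test has essentially no
resolution. BH adjustment runs across the full collection.

This is deliberately *not* a running-sum (Subramanian-style) GSEA: the
screen statistic is the rank test itself.

# Co-differential expression

For a target gene, `codiff_profile()` computes Pearson correlations with
every other gene twice: `dx` across the patient-wise differential matrix
(tumor − normal columns) and `dt` across the tumor-only matrix; the
change `cx = dx − dt` flags coordination *specific to the tumor/normal
transition* — gene pairs whose dysregulation co-varies across patients
beyond what tumor co-expression explains. Pearson correlation is used in
both spaces, consistent with its use elsewhere in the package.

Only the target's correlation row is ever materialized, so memory stays at
O(genes × patients) rather than O(genes²); on genome-scale inputs a full
correlation matrix (~18k² entries) would be the binding constraint. The
row-streamed computation is verified against a brute-force implementation
that does materialize both full matrices, to $10^{-10}$.

`pathway_codiff_enrichment()` scores each gene set by its mean `cx`
(target excluded — its own `cx` of 0 would dilute, and in degenerate
one-gene sets dominate, the mean) and can rank the target against every
candidate gene by repeating the profile per candidate; `max_candidates`
caps that loop for desk-scale runs.

# Methylation integration

`classify_genes()` labels genes up/down/neutral from the detrended screen:
`up` if Bonferroni-adjusted $p < \alpha$ and $f_{up} > 0.5$, `down` for
$f_{up} < 0.5$, neutral otherwise (an exact 0.5 is neutral regardless of
p). `methylation_odds_ratio()` then asks whether probes of downregulated
genes are preferentially hypermethylated: the probe statistic (methylation
$f_{up}$, the fraction of patients hypermethylated in tumor) is split at
the **global median over all probes of the chosen region stratum** (TSS or
gene body), and the 2×2 table (above vs not-above median) × (maps to a
down-gene vs other) yields the cross-product odds ratio. The global median
was chosen because the alternative reading — each probe against a median
of its own values — is degenerate. Cell `a` is "above-median probe of a
down-gene", so TSS hypermethylation of silenced genes gives OR > 1 and
gene-body hypomethylation OR < 1. A Haldane–Anscombe +0.5 correction is
applied only when a cell is zero; the CI is the Woolf logit interval and
the p-value Fisher's exact test. The OR point estimate is always the
cross-product ratio, not the conditional-MLE estimate Fisher's test would
report. Unadjusted p-values are reported together with the test count, in
keeping with the small (order-100) test space of this analysis stage.

`gene_probe_view()` reproduces, per gene, the probe-level paired summaries
used for manual inspection of candidate silenced genes, with the same
sign-test machinery as the genome-wide screen.

# The synthetic-data generator

`simulate_cohort()` and friends exist so that every stage has a
recoverable target with known truth. The generative model, with defaults:

* **Cohort**: 3 tissues × 100 matched pairs, 2,000 markers plus 30
  signature genes; Gaussian noise on a log-like scale (`noise_sd` = 1);
  per-marker tissue baselines ~ N(0, 1).
* **Latent proliferation** per sample:
  $p = a_i + \mu\,[\text{tumor}] + w$, with patient baseline
  $a_i \sim N(0, 0.8)$, tumor shift $\mu = 1$, and within-sample noise
  $w \sim N(0, 0.35)$. Normals sit near baseline; tumors proliferate more
  but overlap.
* **Signature genes** load on $p$ with slope 1 and tight noise (sd 0.3),
  so the per-sample median recovers $p$ to about ±0.07.
* **Proliferation-driven markers** (10%) load on $p$ with slope
  `prolif_effect` = 2.34, the solution of
  $\Phi\!\big(\beta\mu / \sqrt{2\beta^2\tau_w^2 + 2\sigma^2}\big) = 0.9$ —
  i.e. calibrated so their *raw* $f_{up}$ is about 0.9.
* **Independent up/down markers** (5% each) receive a tumor-only shift
  $\delta = \sqrt{2}\,\sigma\,\Phi^{-1}(q)$, which makes
  $\Pr(x_i > y_i) = q$ exactly for Gaussian noise ($q$ = 0.9 by default).
* **Patient baselines** (`patient_sd` = 2.5) are added to *both* members
  of each pair on screened markers: they cancel in the matched design —
  the design's whole point — while dominating tumor-only variance the way
  patient-level heterogeneity does in real cohorts. Signature genes are
  modeled as tight proliferation trackers and skip this term.
* **Co-differential module**: 30 null-class genes share a
  patient-specific tumor-only shift $m_i \sim N(0, 2)$ — coordinated
  dysregulation with no net direction. The planted change in correlation
  has the closed form
  $cx = \omega^2/(\omega^2 + 2\sigma^2) - \omega^2/(\omega^2 + \sigma^2 +
  \text{patient\_sd}^2)$ (single tissue), ≈ 0.31 at the defaults — chosen
  via this formula so the module is clearly recoverable at 50-patient
  cohorts, where set-mean noise is a few hundredths.
* **Methylation** is simulated on the logit scale (per-probe baseline
  ~ N(0, 1), sample noise sd 0.5) and inverse-logit transformed, so beta
  values live in (0, 1) and clipping is essentially never active. TSS
  probes of independent-down genes gain a +1.0 logit tumor shift
  (hypermethylation), gene-body probes −0.6 (hypomethylation); all other
  probes are null.
* **Gene sets**: one planted set per non-null class plus the codiff
  module, and 40 random decoy sets of matched sizes.

Everything derives from `seed`; repeat calls are bitwise identical.

What the generator does **not** emulate: platform/batch artifacts, tumor
purity variation, count-based mean–variance structure, correlated null
genes, missing-data patterns, or realistic methylation probe densities.
Passing recovery tests therefore demonstrates that the machinery measures
what it claims under a clean generative model — not that real cohorts are
this well behaved. In particular the sign test's robustness properties
(monotone invariance, outlier insensitivity) are exactly why the method
carries to messier data, but effect-size calibrations observed in
simulation should not be read as predictions for any real cohort.

# Problem sizes and numerical choices

The test suite runs at desk scale, chosen to keep the full suite under
half a minute while leaving Monte Carlo margins interpretable: 5,000 null
markers × 200 pairs for type-I error; 2,000 markers × 100 pairs for CI
calibration; 20 seeds of the default 2,000 × 300 cohort for the
detrending-separation and enrichment checks; 300 genes × 50 patients for
the codiff oracle. Key tolerances: residual-tie snapping at $10^{-8}$ of
marker scale; stream-vs-brute-force agreement at $10^{-10}$; exact
arithmetic (no tolerance) for sign-test p-values against enumeration and
for the odds-ratio cross-product.

Two statistical facts surfaced by the suite are worth stating plainly.
First, the exact size of the two-sided sign test at $n = 200$,
$\alpha = 0.05$ is 0.0400 (rejection at $k \le 85$ or $k \ge 115$):
discreteness makes the test slightly conservative, and empirical rejection
rates hover around 0.040, not 0.050. Second, under the Gaussian null the
paired-t statistic and the sign count correlate at
$\mathbb{E}|d|/\mathrm{sd}(d) = \sqrt{2/\pi} \approx 0.80$; rank agreement
between $|t|$ and $|f_{up} - 0.5|$ across a null-dominated marker panel is
therefore bounded well below that (≈ 0.75 on the default cohort), even
though the two statistics order *true effects* nearly identically. Both
behaviors are properties of the statistics, not implementation artifacts.

# Known limitations

* The detrended screen attenuates independent effects whenever
  proliferation separates tumors from normals (see above); reported
  detrended $f_{up}$ values are conservative.
* `consensus_fup()` treats tissues as exchangeable; a tissue with 30 pairs
  counts as much as one with 300. That matches the unweighted-average
  convention it implements, but a precision-weighted variant would behave
  differently.
* The Woolf CI for odds ratios is asymptotic; with very sparse 2×2 tables
  the Fisher p-value is the more trustworthy of the two outputs.
* The cross-gene codiff ranking is O(candidates × genes × patients); use
  `max_candidates` for genome-scale inputs.
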