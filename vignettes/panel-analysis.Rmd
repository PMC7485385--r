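---
title: "Methods: from Ct values to enriched pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from Ct values to enriched pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelmiR)
```

panelmiR analyses high-density qPCR (OpenArray-style) miRNA panel
experiments: hundreds of assays per sample, a handful of samples per
experimental group, and no sequencing-style count model to lean on. This
vignette describes the statistical procedure each stage implements, the
assumptions behind it, and the design choices made where conventions in
the field are genuinely open.

## The measurement model

A well's cycle threshold Ct is the PCR cycle at which fluorescence
crosses detection; under perfect amplification efficiency each cycle
doubles the template, so Ct is $-\log_2$ of the input quantity up to an
assay-specific offset. The whole pipeline works on this idealization:
**one cycle = one log2 unit**. Amplification-efficiency correction and
standard-curve quantification are out of scope; if efficiencies differ
appreciably from 2 per cycle, fold changes are systematically biased and
this package will not detect it.

## Detection filtering

High Ct values are unreliable: stochastic amplification near the
detection limit makes both the value and its presence noisy. A feature
is therefore **detected** only if its Ct is non-missing and strictly
below a threshold (default 28 cycles) in *every* sample of the analysis
scope — by default all samples of all groups jointly. The strict
inequality means a well at exactly 28.0 fails. A missing
(never-amplified) well and a well at or above threshold are treated
identically as "not detected"; the per-well reason is recorded in the
`detection_report` so the distinction is not lost.

The joint all-samples rule is deliberately conservative: a feature
regulated into undetectability in one group is excluded rather than
imputed. The `scope` argument supports other designs (e.g. detection
within one group) but the default matches the standard panel workflow.

Internal controls (one negative, several endogenous) never enter the
detected set: they are replicated assay controls, not biology.
`check_controls()` is advisory only — a negative control that amplifies
below the detection threshold, or an endogenous control missing in a
sample, yields a warning finding, never data removal.

## Global-mean normalization

With hundreds of assays per sample, the mean Ct of the reliably
detected features is a stable per-sample normalizer (global mean
normalization): $\Delta Ct(f,s) = Ct(f,s) - \overline{Ct}(s)$, the mean
taken over the detected set. Averaging on the Ct scale corresponds to a
geometric mean of linear quantities, the standard choice for qPCR.

Two decisions here were open and are fixed as follows:

* **The mean runs over the jointly detected set, not all wells.**
  Undetected wells carry either a missing value or a noise-dominated
  high Ct; including them would poison the normalizer with exactly the
  values the detection filter exists to exclude.
* SEMs of group-level $\Delta Ct$ summaries use the sample standard
  deviation ($n-1$ denominator); a group of one sample reports `NA`
  rather than a fabricated zero.

Global-mean normalization is shift-invariant: adding a constant to all
Ct values of one sample (a loading or efficiency offset) leaves every
$\Delta Ct$ unchanged, and each sample's $\Delta Ct$ values sum to zero
over the detected set. Both identities are exercised as properties in
the test suite on random matrices.

For small-scale validation assays the classic single-reference form is
provided instead: `reference_normalize()` subtracts a reference gene's
Ct (e.g. U6 snRNA) per sample, and `relative_quantity()` implements
$2^{-\Delta\Delta Ct}$ with
$\Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{reference}$.

## Fold-change classification

Group-level fold change is computed from the difference of group-mean
$\Delta Ct$ values, $FC = 2^{-(\overline{\Delta Ct}_{test} -
\overline{\Delta Ct}_{ref})}$ — a ratio of geometric means. The
alternative (arithmetic mean of per-sample linear ratios) is not
scale-stable and inflates under noise; log-scale averaging is the qPCR
standard. Which convention published tables use is rarely stated; this
package states its.

Classification uses fixed asymmetric thresholds, up if $FC > 1.5$ and
down if $FC < 0.6$, boundaries exclusive. With three pooled samples per
group there is too little replication for FDR-controlled per-feature
testing to have useful power, which is why panel studies of this design
classify by effect size; the optional per-feature pooled t-test on
$\Delta Ct$ values is reported for reference but never drives the
classification. Note the asymmetry: $1/1.5 \approx 0.667 \ne 0.6$, so
swapping test and reference groups does *not* simply swap the up and
down sets — the test suite asserts the exact mapping.

Both baseline schemes used in genotype-by-treatment designs are
expressible by choosing the reference group: every group against the
vehicle-injected wild-type control, or knockout-after-insult directly
against wild-type-after-insult.

## Venn partitioning

Comparing the regulated sets of two comparisons yields eight disjoint
cells: common up, common down, unique up/down on each side, and two
discordant cells (up in one comparison, down in the other). "Unique to
A" excludes features regulated in B in *either* direction; discordant
features live only in their discordant cell. This is the only
definition under which the cells are pairwise disjoint and the marginal
identity $|A_{up}| = |common_{up}| + |unique\,A_{up}| +
|discordant\,A_{up}B_{down}|$ holds exactly. Published marginal counts
assembled by hand occasionally violate these identities by one; the
implementation satisfies the set algebra and makes no attempt to
reproduce internally inconsistent printed totals.

## Target integration

miRNA→gene links come from two kinds of sources: experimentally
validated tables (miRTarBase-, TarBase-style; treated as binary
evidence) and prediction tables carrying a score (TargetScan-,
miRDB-style). Scores are mapped to a common $[0,1]$ confidence scale
per source:

* miRDB-style scores live on $[50, 100]$ by construction (the database
  drops predictions under 50; the maximum is 100), so the linear map to
  $[0.5, 1]$ is uniquely `raw / 100`. Endpoints map exactly:
  $50 \to 0.5$, $100 \to 1.0$.
* TargetScan-style context scores are more negative when stronger and
  have no fixed range, so they are min–max rescaled with the observed
  strongest score mapping to 1. Which of TargetScan's several score
  columns a study used is typically unstated; the orientation is a
  per-source configuration flag (`lower_is_stronger`) rather than a
  hard-coded assumption.
* Validated records carry an implicit rescaled score of 1 and bypass
  score filtering entirely — the removal rule ("rescaled prediction
  score < 0.5") speaks only of predictions.

After rescaling, predicted records below 0.5 are removed (strict; a
record at exactly 0.5 survives), sources are merged to one record per
(miRNA, gene) pair — validated evidence wins, otherwise the maximum
rescaled score — and genes are kept only when targeted by **at least
two** regulated miRNAs of the same direction and condition. The
two-miRNA support rule suppresses single-prediction noise before any
pathway statistics.

## Over-representation analysis

Each gene-set term is tested with the one-sided hypergeometric upper
tail $P(X \ge k)$ for overlap $k$, term size $K$, query size $n$ and
universe size $N$ (equivalently Fisher's exact test), implemented on
stable log-space terms via R's `phyper`. The universe is the set of
genes annotated to at least one term, intersected with any
user-supplied background — the annotation-restricted convention of the
established enrichment packages; query genes without any annotation are
dropped before testing. P-values are Benjamini–Hochberg adjusted across
all tested terms, significance is called at adjusted $p < 0.05$, and
ranking ties are broken by raw p then term id so reports are
deterministic. The collection is format-agnostic (any GMT); no specific
ontology release is bundled or assumed.

## Group statistics

`ttest_from_summary()` reproduces two-group Student's t-tests directly
from printed means, SEMs and group sizes — per-group variances are
recovered as $s_i^2 = SEM_i^2 \, n_i$ and pooled with
$df = n_a + n_b - 2$. Pooled (not Welch) is the default because it is
what the classic desktop statistics packages default to and what
published two-group p-values of this experimental field reproduce
under. `anova_fisher_lsd()` implements one-way ANOVA with Fisher's
protected LSD: pairwise t-tests using the within-group mean square at
its full residual degrees of freedom, with "protection" implemented as
a flag (pairwise p-values are reported but marked unprotected when the
omnibus p fails `alpha`) rather than suppression. Degenerate
all-constant input returns $F = 0$, $p = 1$ explicitly, since the
textbook ratio is 0/0 there. With exactly two groups the omnibus F
equals the squared pooled t — kept accessible as a consistency check.

## The synthetic-data generator

Every pipeline input can be generated with ground truth so the full
chain is testable without any external download.

`generate_ct_dataset()` emulates the panel design: 754 assays plus four
internal controls, four genotype-by-treatment groups of three samples,
each sample pooling two animals. Per feature and group, a latent Ct is
baseline minus the planted log2 effect; per sample, the pool's
animal-level deviations (SD `bio_sd`, default 0.25 cycles) are averaged
and technical noise (SD `noise_sd`, default 0.25 cycles) added; wells
beyond `dropout_ct` (default 35) become missing. Defaults for the
baseline distribution, N(28, 3.5) across features, were chosen so that
roughly 45% of assays pass the joint Ct < 28 filter — the detection
rate scale typical of hippocampal tissue on this panel size. Planted
effects are parameterized per (feature, group); the true log2 fold
change of any comparison is the difference of group effects, which
keeps truth consistent across all comparisons by construction.

Simplifications to be aware of:

* Pooling is modelled as averaging on the log (Ct) scale; physically,
  pooled RNA mixes linear quantities. At the small animal-level SDs
  simulated, the difference is second order.
* Noise is Gaussian and homoscedastic in Ct; real panels show variance
  inflation near the detection limit.
* Dropout is a hard threshold, not a probabilistic hazard.

Consequently, passing recovery tests demonstrates that the pipeline's
arithmetic and thresholds behave as specified under the declared noise
model — not that the thresholds are optimal for any particular real
dataset.

`generate_target_db()` plants "hub" genes with an exact number of
supporting regulated miRNAs as validated records (hub genes receive no
other edges, so their true support is exact), against a background of
random per-source edges with source-appropriate score distributions.
`generate_gene_sets()` plants one enriched term by over-sampling the
query from it. All generators are pure functions of (configuration,
seed): they restore the caller's RNG state and are bit-reproducible.

## Problem sizes used in validation

The packaged tests and the acceptance script validate at the study's
own design scale: the full 754-feature panel with 12 samples for
classification recovery (20 simulation replicates), 60 miRNAs × 200
genes for target integration (10 replicates), and 50 terms over a
1,000-gene universe for enrichment recovery (50 replicates). Oracle
sweeps run exhaustively where enumeration is feasible (hypergeometric
universes up to N = 12) and on large random batches elsewhere.

## Known limitations

* No amplification-efficiency correction and no replicate-well
  collapsing; the input Ct matrix is assumed pre-collapsed to one value
  per assay and sample.
* Classification has no error control beyond the fold-change
  thresholds; with n = 3 that is a deliberate trade-off, not an
  oversight, but it means the false-call rate depends on the true noise
  level.
* Target integration consumes static table exports; reproducing a
  specific study's gene counts requires that study's database releases.
* Enrichment is a gene-membership test only — no topology, no
  ranked-list statistics.
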