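---
title: "Multi-level pathogenicity analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level pathogenicity analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varlevel)
```

This vignette is the package's account of the science it implements: the
classification rules and statistics, the conventions adopted where several
defensible choices existed, what the synthetic cohort does and does not
emulate, and the numerical decisions that affect results at the margins.

## The analysis model

The unit of observation is a non-synonymous SNV: one alternative allele at
a 1-based genomic position, carried with its gene, clinical-significance
terms, HGMD class, optional ancestral-allele call, per-clade conservation
scores, and rank scores from up to twelve pathogenicity predictors. Rank
scores are quantile transforms of each tool's raw output over a common
reference collection, so a single threshold semantics (pathogenic iff
score > cutoff, default 0.5 for every tool, individually overridable)
applies across tools. The strictly-greater-than convention means a score
exactly at the cutoff is a benign call.

**Site groups.** Truth labels come from a four-way classification of
*sites* (not alleles): a site is *pathogenic* when at least one of the
clinical terms attached to its observed alleles maps to pathogenic
evidence and none to benign evidence, *benign* symmetrically, *both* when
evidence of each kind is present, and *other* when neither is. The
term-to-evidence map is a parameter. The default counts "Pathogenic",
"Likely pathogenic" and their combined form as pathogenic evidence, the
benign trio symmetrically, and everything else ("risk factor",
"association", "protective", "Uncertain significance", ...) as no
evidence. Whether the "Likely" grades should count as evidence is a
genuinely open question — clinical practice treats them as actionable, and
the packaged ancestral-reversion table uses both plain and "Likely" labels
in the same role — so the default includes them and the map is
configurable. HGMD evidence is carried separately as a per-site DM flag
(disease-causing mutation), which drives the parallel "DM" analysis arms.
Evaluation restricts truth to pathogenic/benign sites; *both* and *other*
sites are excluded from labels (a configurable sensitivity analysis can
force *both* into either class).

**Evaluation metrics.** With tp/fp/tn/fn the definitive-call cells and
no-calls counted as unclassified:

* sensitivity = tp / (all labeled pathogenic) — a pathogenic variant left
  without a definitive call is a miss. Under the all-agree combination
  rule this makes sensitivity the quantity that collapses as tools are
  added, which is the phenomenon the evaluation is designed to expose.
* specificity = 1 − fp / (all labeled benign) — a benign variant counts
  against specificity only when actively flagged pathogenic. The
  alternative (tn over all labeled benign, penalizing benign no-calls)
  was rejected because it breaks the structural monotonicity of the
  all-agree rule: growing a tool subset can only shrink the set of
  variants called pathogenic, so false alarms can only fall, and
  specificity as defined here is provably non-decreasing along nested
  subset chains — a property the test suite asserts with zero tolerance
  over random chains.
* accuracy = (tp + tn) / (all labeled variants), plus `accuracy_called`
  with the denominator restricted to definitively called variants. The
  first is the conservative headline number; the second is the quantity
  that can peak at small subset sizes (two or three combined tools) before
  the shrinking called set drags it down, and both are reported so the
  reader need not guess which convention a figure uses.

**All-agree combinations.** A subset of tools classifies a variant only
when every member gives the same definitive call; any disagreement or any
missing member score yields a no-call. Variants with missing scores are
kept as no-calls rather than dropped so that denominators are constant
across all 2^k − 1 subsets. The exhaustive scan over the twelve-tool panel
(4095 subsets) takes seconds at a few thousand variants because each
subset reduces to one vectorized row-sum over a 0/1 call matrix.

**Conservation enrichment.** Errors are stratified by vertebrate phastCons
at a 0.5 cutoff, with "high" defined as *score ≥ cutoff*. The boundary
convention matters only for scores exactly at 0.5; the synthetic cohort
draws continuous scores, so flipping the convention there changes nothing,
and real phastCons values at exactly 0.500 are rare enough that the choice
is cosmetic. The test is Pearson's chi-squared on the 2×2 table (error
group vs all-positions background) × (high vs low), *without* Yates
continuity correction: the uncorrected statistic is exactly 0 with p
exactly 1 when the proportions are equal, which keeps the "no enrichment"
case clean, and the correction's conservatism is unnecessary at the group
sizes where the test is read. The background deliberately includes the
error group (it is "all positions of benign variants", mirroring the
dashed reference line of the standard figure). Positions lacking a
conservation score leave both group and background. phyloP-based views are
reported descriptively (sign counts and quartiles per clade and site
group) without hypothesis tests.

**Back mutations.** A variant is a back mutation when its alternative
allele restores the inferred ancestral nucleotide at high confidence (the
1000 Genomes lowercase convention for low-confidence calls is mapped to an
explicit confidence field at parse time; low-confidence calls can be
admitted by flag). The pathogenic back-mutation report qualifies a variant
when it carries at least one pathogenic-evidence clinical term *or* its
HGMD class is DM (the class set is widenable). Term-level — rather than
site-group-level — qualification is deliberate: several of the packaged
reversion variants sit at sites that also carry benign annotations and
would vanish under a site-group rule, while their pathogenic assertions
are precisely what makes them interesting.

**Four-allele statistics.** At a non-degenerate site every nucleotide
change is non-synonymous, so three alternative-allele scores exist per
tool. The reference allele has no predicted effect, and the package's
default scores it 0 ("no change, no deleteriousness"). This choice is
consequential — it anchors every quartet at 0 and thereby sets the scale
of the coefficient of variation — and no convention is canonical, so two
alternatives are selectable (`mean-of-alts`, and `exclude-and-rescale`
which computes the statistics over the three alternatives with divisor 2)
and the pipeline emits the group-comparison report under every configured
convention, making sensitivity to the choice visible rather than silent.
The statistics are max(S) and CV = σ/μ with μ = ΣSᵢ/4 and
σ = √(Σᵢ(Sᵢ−μ)²/3) (divisor 3, i.e. the n−1 form). CV is undefined at
μ = 0 and is reported missing there, not as an error. Non-degeneracy is an
input flag: the package carries no transcript model and does not compute
codon degeneracy.

**Gene level.** Per-gene counts are *site* counts (a multi-allelic site
counts once). Disease-sensitive genes have >30% pathogenic sites among
annotated sites; the denominator of that proportion is ambiguous in
common usage, and the package uses annotated variant sites
(clinical + HGMD union) with the polymorphic-site count as a configurable
alternative. Disease-tolerant genes have no pathogenic and no DM site
despite >50 polymorphic sites (both thresholds strict). Tissue specificity
is the information content log₂n + Σpᵢlog₂pᵢ with p log p := 0 at p = 0;
base 2 is used in *both* terms so the score spans exactly [0, log₂n] — 0
for a uniform profile, log₂n for single-tissue expression. PPI degrees
enter as ascending rank fractions with mean ranks for ties, so the top
gene scores exactly 1 regardless of the degree distribution's heavy tail.
Gene groups (≥1 pathogenic site; >20 pathogenic sites; same on DM counts)
are compared against the full gene universe by two-sample
Kolmogorov–Smirnov tests. Comparing a subgroup against a universe that
contains it is conservative (the overlap attenuates D); it is used anyway
because "all analyzed genes" is the natural reference panel.

**Chromatin state.** State tracks are chromHMM-style BED intervals,
0-based half-open, with mutually exclusive states per epigenome; variant
positions are 1-based, and the single conversion point (position p covered
iff start ≤ p − 1 < end) is tested at interval boundaries against a
brute-force linear scan. The per-site statistic is the fraction of
epigenomes whose track covers the site in a given state; the repressed
PolyComb states are reported separately (ReprPC, ReprPCWk) and as the
union event, since figures in the field use both framings. Epigenomes with
no data on a chromosome count in the denominator by default ("percentage
of cell types"); a covered-only denominator is selectable. FN-vs-TP
comparisons restrict to truth-pathogenic variants and exclude no-calls
from both groups.

## Statistical engines

All group tests funnel through three engines with explicit small-sample
paths:

* Wilcoxon rank-sum, two-sided: exact distribution when both groups have
  fewer than 50 tie-free observations; with ties, complete enumeration of
  group assignments while the number of splits is ≤ 2×10⁵ (the two-sided
  p is the probability of a departure of U from nx·ny/2 at least as large
  as observed — with or without ties that distribution is symmetric, so
  this coincides with the usual doubled tail); otherwise the normal
  approximation with tie correction, without continuity correction.
* Two-sample KS: exact p below a combined n of 35 on tie-free data,
  asymptotic otherwise.
* Pearson chi-squared on 2×2 proportion tables, no continuity correction,
  with a degenerate-margin guard (all-high or all-low columns give
  chi2 = 0, p = 1).

Each engine is verified in the test suite against independent brute-force
oracles (full enumeration, contingency formula) on samples small enough to
enumerate, to 10⁻⁹.

## The synthetic cohort

The generator emulates the *statistical structure* the analyses assume,
not real genomes: plausible formatting (chromosome blocks, spaced
positions, HGVS-like strings) with no allele-frequency spectrum, no
linkage, and no real coordinates. Defaults define the study conditions:
500 genes, 1 + Poisson(3) variants per gene (≈2000 variants), site-group
fractions 0.25/0.35/0.05/0.35 (pathogenic/benign/both/other), a 60% DM
rate among pathogenic-type sites, 53 tissues, 127 epigenomes, 2% ancestral
reversions, 3% missing scores per tool, and a 1000-site quartet panel —
sizes chosen so every stage has comfortable power at desk scale while the
full test suite and acceptance script run in about a minute each.

Scores are Beta draws around tool-specific class means (pathogenic means
0.62–0.84 across the panel, benign 0.16–0.36, concentrations 5–18), which
makes pairwise agreement non-trivial rather than uniform. Four planted
effects give the pipeline recoverable signals:

1. *Conservation over-reliance*: for three tools (SIFT, MutationTaster,
   DANN by default) the emitted score is an even mixture of the
   class-driven draw and the site's vertebrate phastCons value — benign
   variants at conserved positions then score high, creating the
   FP-at-high-conservation enrichment.
2. *Site difficulty*: a standard-normal latent h per site depresses every
   tool's score at pathogenic-type sites through a logit shift (coefficient
   0.9) and raises the site's repressed-PolyComb propensity (logit
   coefficient 1.0 over a −1.6 baseline, +1.0 for pathogenic/DM sites);
   false negatives and PolyComb state are thereby linked, producing the
   FN-vs-TP contrast.
3. *Quartet effects*: alternative-allele scores at a site are
   m·(1 + δ) with multiplicative noise δ. Pathogenic sites get a higher
   location (0.45 + 0.3) and a smaller noise SD (0.35 − 0.27). Because CV
   is scale-invariant and the reference score is 0, the location parameter
   cancels from CV exactly (up to clipping), so the location effect moves
   only the maximum and the dispersion effect only the CV — the two
   recoveries are separable by construction, and a location-only
   configuration leaves the CV comparison null.
4. *Gene importance*: a standard-normal latent z per gene scales its share
   of pathogenic variants (log-weight 0.8·z, normalized so the expected
   class fractions are preserved) and its expression total (0.8·z),
   tissue concentration (−0.8·z on the Dirichlet concentration, so
   specificity rises with z) and PPI degree (1.2·z on a negative-binomial
   mean with size 4). Pathogenic-rich genes are thereby shifted in all
   three gene metrics. The degree coefficient is larger than the others
   because rank-transformed negative-binomial degrees retain the most
   noise; it was set (together with the size parameter) so that the
   planted shift is reliably recoverable at the default cohort size, which
   is the generator's purpose.

A `"null"` configuration zeroes every effect while leaving all marginal
distributions untouched. The validation battery (`recovery_rates()`)
defines detection as two-sided p < 0.05 *and* an observed difference in
the planted direction, and applies the identical rule under the null — the
recoveries are directional claims, and the directional type-I error
(~2.5%) is what the ≤2/20 null bound is checked against. At the default
conditions all seven planted recoveries run at or near 20/20 and the null
battery stays within 2/20.

What passing these tests shows — and does not show. They demonstrate that
the pipeline's statistics detect the effect structures they target at
realistic sizes and stay quiet in their absence. They do not demonstrate
calibration on real cohorts, where scores are not Beta, conservation has
spatial structure, gene annotation depth confounds pathogenic-site counts,
and clinical labels themselves embed ascertainment bias.

## Determinism and reproducibility

Every random draw flows from the single mandatory config seed; the quartet
panel uses the documented sub-stream seed + 1 so it can be regenerated
independently of the main bundle. The previous RNG state is saved and
restored around generation, and identical configurations produce
byte-identical bundles on disk. Pipeline reruns reproduce integer counts
exactly and floating statistics to 10⁻⁹ (the only float nondeterminism
would come from the platform's libm, not from the package).

## Known limitations

* No transcript model: non-degeneracy, HGVS strings and liftover are
  inputs, never computed.
* No recomputation of predictor scores or conservation tracks; the
  package consumes rank scores and phastCons/phyloP values as given.
* Gene-set enrichment of result gene lists, orthologue-tree inference and
  meta-predictor retraining are out of scope.
* The KS comparison of a gene group against the enclosing universe is
  conservative by construction; treat its p-values as lower bounds on
  evidence, not as exact.
* Figure rendering is limited to the tabular reports; plotting is left to
  the caller.
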