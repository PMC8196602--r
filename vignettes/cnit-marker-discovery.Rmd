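---
title: "Marker discovery for calcineurin-inhibitor nephrotoxicity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker discovery for calcineurin-inhibitor nephrotoxicity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnitpipe)
```

# The analysis problem

Calcineurin-inhibitor nephrotoxicity (CNIT) is a drug-induced injury of
kidney allografts whose histologic diagnosis is late and non-specific.
The marker-discovery design implemented here profiles biopsies from
four phenotypes — CNIT, histologically normal allografts, acute
rejection (AR) and interstitial fibrosis / tubular atrophy (IFTA) — on
gene-expression microarrays, plus a CNIT/Normal subset on miRNA arrays.
The two control-injury phenotypes are not an afterthought: any gene
that is differentially expressed in AR or IFTA as well is a generic
injury marker, and the specificity step removes it. The miRNA layer
then anchors the remaining CNIT-unique genes in a regulatory
interpretation: a miRNA that rises while its experimentally validated
target falls (or vice versa) is a candidate regulator of the lesion.

`cnitpipe` implements that workflow end to end. This vignette explains
the model behind each stage, the tunable parameters and their defaults,
the numerical conventions, what the synthetic-data generator does and
does not emulate, and the design decisions that were genuinely open.

# Hybridization quality control

Archival FFPE tissue yields fragmented RNA, so arrays are screened
before any statistics.

**Percent present (%P).** A probeset is called *present* in a sample
when its log2 intensity strictly exceeds the median of that sample's
negative-control probes plus a margin (default **1.0 log2 unit**,
i.e. twice the background median on the linear scale). %P is the
fraction of non-control probesets called present; a sample passes at
**%P ≥ 0.50**. The classical detection-call algorithm is a Wilcoxon
test on perfect-match/mismatch probe pairs; those pairs do not exist at
the probe-level-matrix interface this package ingests, so the
background-margin rule against negative controls is used instead. It is
a deliberate, documented stand-in with the same intent (distinguish
signal from background) and the same failure mode sensitivity (a
collapsed hybridization drops most probes to background, and %P
plummets). Samples with %P in a band of ±0.15 around the cutoff are
additionally flagged *borderline* in the QC report — the band is a
warning, the cutoff is the rule.

**GAPDH 3′:5′ ratio.** Degradation consumes transcripts from the 5′
end, so the ratio of 3′-end to 5′-end probeset intensities of a
housekeeping gene measures RNA integrity:
`ratio = 2^(mean log2 3′ − mean log2 5′)`, pass at **ratio ≤ 3**.

Both rules are conjoined; `apply_qc()` drops failing samples and never
alters retained values. %P is computed on raw (pre-normalization)
values: normalization equalizes the very distributions whose collapse
%P is meant to detect, so screening must precede it.

# Quantile normalization

After QC exclusion, `quantile_normalize()` forces every array to share
the across-sample mean empirical distribution (delegated to
`limma::normalizeQuantiles(ties = TRUE)`). Ties within a column receive
the mean of the reference values at the tied ranks — the convention of
the most widely used implementation, adopted because nothing in the
protocol constrains tie handling. The transform is idempotent and
preserves within-column rank order; both properties are asserted in the
test suite. The input contract is log2-scale intensities (a
`input_scale = "linear"` reader flag applies `log2(x + 1)` on load);
probe-level background correction of raw scanner files is outside this
package's interface, which begins at the probe-level matrix.

# Differential expression

**Test.** Per probeset, a two-sample pooled-variance (Student) t-test
on log2 intensities. The protocol names only "a t-test"; the pooled
form is the historical microarray default and is used here, with Welch
available via `var_equal = FALSE`. Degenerate probesets with zero
pooled variance return p = 1 when means are equal and p = 0 (with a
warning) when not, so constant fixtures behave deterministically.
No moderated/empirical-Bayes shrinkage is applied — the method is the
plain probeset t, matching the protocol rather than improving on it.

**Multiplicity.** Benjamini–Hochberg step-up q-values
(`q_(i) = min_{j≥i} m·p_(j)/j`), computed within each contrast and
platform separately, since results are reported per contrast.

**Thresholds.** A probeset passes iff `p < p_cutoff` (strict) and
`q ≤ 0.05` and linear `|FC| ≥ fc_cutoff`, with `p_cutoff` = 0.001 /
0.005 and `fc_cutoff` = 1.5 / 2.0 for mRNA / miRNA respectively. Fold
change is geometric — `2^(difference of log2 group means)` — because
testing happens on the log scale; the arithmetic-mean ratio is not
computed.

**Gene collapse.** A gene enters the DEG set when ≥ 1 passing probeset
maps to it. Conflicting directions among a gene's passing probesets are
resolved by majority sign, ties broken by the probeset with the largest
|log2 difference| — a deterministic rule chosen because downstream
accounting requires every gene to carry exactly one direction. Passing
probesets with no symbol are kept in an `unmapped` slot, never silently
dropped. The probe annotation is an explicit input (platform annotation
releases change over time), so no annotation is bundled.

# Marker specificity

`venn_partition()` performs exact set algebra on gene symbols over the
three contrasts' DEG sets; `unique_genes()` extracts the CNIT-only
region with directions inherited from the CNIT contrast. Membership is
**by symbol only**: a gene up in CNIT and down in AR is still "common",
because only symbol-level membership makes the unique/common accounting
internally consistent (unique + pairwise-only + triple regions must
reproduce each set's cardinality exactly, which the package asserts as
an invariant). "Common among all three" is implemented as the triple
intersection — the only reading under which the region counts of the
packaged accounting fixture sum correctly.

# miRNA–mRNA integration

`integrate_mirna_mrna()` classifies every candidate edge of a curated
target table exactly once. A pair is retained iff all four predicates
hold: evidence is `experimentally_observed`; the miRNA is in the DE
set; the target is in the CNIT-unique list; and the directions strictly
oppose. Rejected candidates carry the *first* failing predicate in the
fixed order `not_experimentally_observed`, `same_direction`,
`target_not_in_unique_list`, `mirna_not_de` — so the rejection audit is
unambiguous. Direction agreement is only assessable for genes present
in the unique list; an out-of-list target is therefore rejected for
list membership, never for direction. Pairing is by sign, not by
per-sample expression correlation: the design calls for validated
regulatory direction, not co-variation, and the two are deliberately
not conflated.

# Enrichment statistics

**Overlap p.** One-sided Fisher exact = hypergeometric upper tail
`P[X ≥ k]` for drawing `k` set members in a query of size `n` from a
universe of size `N`, BH-adjusted across the collection. The default
universe is the set of genes mapped on the platform annotation — the
defensible open analog of a curated reference set — and is
configurable. Queries outside the universe are clipped with a warning
rather than silently absorbed.

**Activation z.** Signed gene-set members encode the direction
consistent with activation (`SYM:+1` / `SYM:-1` in the package's GMT
dialect; bare symbols are unsigned and excluded). With `N⁺` consistent
and `N⁻` inconsistent overlapping members,
`z = (N⁺ − N⁻)/√(N⁺ + N⁻)`; `|z| ≥ 2` is the conventional reporting
threshold for an activated/inhibited call, and z is undefined
(`NA`, deliberately distinct from 0) when no signed member overlaps.
This is the simple unweighted consistency score; weighted or
bias-corrected variants are out of scope.

# Clustering and qPCR

"Supervised" clustering means supervised *feature selection*: the
sample dendrogram is built only on the DE features of a contrast, then
standard agglomerative clustering runs with correlation distance
(1 − Pearson r) and average linkage — the microarray-heatmap
convention; both are configurable, and correlation distance makes the
result invariant to positive scaling of features. The two-cluster cut
is scored against condition labels by best-permutation agreement
(defined for two-condition designs; `NA` otherwise).

qPCR validation compares ΔCt = Ct(target) − Ct(reference gene, GAPDH)
between groups with the same pooled t machinery (the equality of the
two code paths is a test invariant) and reports per-group means with
t-based 95% confidence intervals. Lower ΔCt means higher expression;
reports state this convention.

# The synthetic-data generator

Every stage is exercised on seeded generators
(`generate_cohort()`, `generate_venn_fixture()`,
`generate_integration_fixture()`, `generate_collapse_fixture()`); the
same seed yields byte-identical output, and the caller's RNG stream is
left untouched.

**Cohort model.** Per-probe baseline `b_p ~ Normal(8, 1.5)` log2 units;
observed value `b_p + condition shift + Normal(0, noise_sd)`; negative
controls at `Normal(4, 0.5)`; housekeeping 5′/3′ probes generated at a
configurable true ratio (default 1.5, an intact-RNA value). These are
artifact choices giving a realistic microarray dynamic range (~4
orders of magnitude linear), all surfaced in `cohort_config()`. The
default design mirrors the study structure: 38 gene-expression samples
(12 CNIT, 12 Normal, 7 AR, 7 IFTA) with the twelfth CNIT sample
generated under a hybridization-failure model — every non-background
probe depressed by 4 log2 units, which pins its expected %P near 0.27,
far below the 0.50 rule — and a miRNA arm of 10 CNIT + 5 Normal.
Planted effects default to 1.2 log2 (mRNA, 48% up) and 1.5 log2
(miRNA, 72% up) with noise SD 0.3 / 0.4; at the cohort sizes above
these give essentially complete recovery at the protocol thresholds,
which is the point — the generator calibrates the *machinery*, and its
truth tables make sensitivity/FDR accounting exact.

**What it does not emulate.** Probe-sequence effects, spatial
artifacts, batch structure, heavy-tailed noise, correlated genes, and
the true biological effect-size distribution. Passing tests therefore
demonstrate that the pipeline's logic and statistics behave as
specified under a clean generative model — not that real FFPE
microarray data would yield any particular marker list.

**Accounting fixtures.** The three-set fixture is deterministic (no
RNG): its seven regions are sized 1245/418/107 unique, 127/45/67
pairwise-only and 66 triple — the unique solution of the set-identity
equations given the per-set totals (1483/678/285) and unique counts —
with 714 of the CNIT set's genes assigned "up". The integration
fixture plants 13 true miRNAs whose experimentally observed,
direction-opposed targets cover exactly 33 distinct genes (pairs and
genes coincide by construction; target sharing across miRNAs is
deliberately avoided so the two counts are not conflated), 7 decoy
miRNAs carrying only failing pairs, and extra failing pairs cycling
every rejection reason. The collapse fixture maps 1837 passing
probesets many-to-one onto 1483 genes (354 genes carry two probesets).

# Numerical conventions and degenerate inputs

* Threshold strictness is exact: strict `<` on p, non-strict `≤` on q,
  non-strict `≥` on fold change; the detection call uses strict `>`.
* Gene symbols are matched case-sensitively and exactly; normalization
  is the caller's responsibility.
* Readers reject every invariant violation (duplicate ids, ragged
  rows, non-numeric cells, unknown enum tokens) with an error naming
  the offending line; there is no silent coercion.
* Quantile-normalization idempotence is asserted to 1e-9.
* An empty integration *result* is valid; an empty target *table* is
  an error — the two are distinguished on purpose.
* Deterministic output orders everywhere (miRNA then gene
  lexicographic for integration; p then set name for enrichment), so
  reruns are byte-stable and the pipeline manifest can hash outputs.

# Problem sizes used in the test suite

The packaged tests run the generator at the study's own design sizes
where the claim depends on them (38-sample QC fixture; 11-vs-12
recovery with 200 planted effects among 2000 probesets; 10 + 5 miRNA
clustering) and at reduced sizes (hundreds of probes) where only the
logic is under test, such as the end-to-end orchestration check. Null
behavior of the FDR machinery is measured over 200 simulated null
datasets of 200 probesets each. These sizes are the package's choice
of a fast, statistically adequate regression suite.

# Known limitations

* The detection call is a background-margin rule, not the
  perfect-match/mismatch algorithm; absolute %P values are not
  comparable to scanner-software output, only the pass/fail semantics.
* No moderated test: with very few arrays per group the plain t-test
  is noisier than shrinkage estimators.
* Enrichment depends entirely on the user-supplied (or synthetic) set
  collections; no curated knowledge base ships with the package, and
  per-annotation p-value *ranges* produced by proprietary annotation
  hierarchies are not reproducible here.
* The specificity step is symbol-level three-set algebra; direction-
  aware overlap classes and >3-way designs are out of scope.
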