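---
title: "tcrHLA methods: boundary rules and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tcrHLA methods: boundary rules and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the methodological boundary rules the package
commits to, and why. The README shows the workflow; here we document the
decisions a careful reader would otherwise have to reverse-engineer from
the code.

## Detection and the candidate universe

A clonotype counts as *detected* in a repertoire when its productive
frequency is **strictly greater than 2×10⁻⁶**. The inequality is strict:
a clone at exactly the threshold is not detected. The same rule defines
the repertoire-richness covariate `U = uniqueClones(x)` used by the
high-sensitivity calibration, and `u = log10(U)`.

The *candidate universe* for association testing is the set of
(TRBV family, CDR3β) features supported by **at least 2 templates in at
least one repertoire** (`candidateFeatures(..., minTemplates = 2)`).
Singleton clones are overwhelmingly private and would multiply the testing
burden by orders of magnitude without contributing public signal.

## Edit-distance-1 occurrence without all-pairs comparison

A feature's *edit-1* occurrence bit is set when a repertoire contains any
CDR3β within Levenshtein distance 1 of it (same TRBV family). Computing
this by pairwise `adist` over the candidate universe is quadratic; the
package instead builds an exact index (`buildEdit1Index`):

* **Substitutions** — every string is expanded into position-masked
  patterns (`CASS.G`, `CAS.LG`, …) whose key also carries the string
  length and masked position, so two strings share a key exactly when they
  differ by at most that one position.
* **Insertions/deletions** — every string is expanded into its deletion
  variants, and queries are joined *raw-against-variant* only. Joining
  variant-against-variant would produce false neighbors: `"AC"` and
  `"CA"` share the deletion variants `"A"` and `"C"` but are at distance
  2. The raw↔variant join structurally excludes this case.

The index is verified in the test suite against brute-force `utils::adist`
on exhaustive small alphabets and thousands of random CDR3β strings; the
neighbor sets are required to be *identical*, not merely similar.

## Association screen

Each feature × allele 2×2 table is tested with a two-sided Fisher exact
test implemented directly from the hypergeometric density (summing all
tables with probability ≤ the observed table's, with a relative slack of
1e-7 against floating-point ties). The test-side oracle is an independent
`lchoose`-based enumeration plus `stats::fisher.test`.

A feature passes the screen when all of the following hold:

* publicity (detections among subjects) ≥ 5;
* odds ratio > 1 (association must be positive);
* p < 1×10⁻⁸ (a hard genome-wide-style cut, not FDR — the downstream
  classifier tolerates missed features better than false ones);
* detection rate among allele-negative subjects < 0.10.

Edit-1 features whose *exact-mode* odds ratio is below 1 are pruned
(`pruneNonenriched`): a neighborhood that is associated only through its
variants while the center sequence itself is depleted is most often a
shadow of a different feature. An undefined exact odds ratio (zero cells)
prunes by default; `keepUndefined = TRUE` relaxes this.

## TCRdist and anchor selection

Distances between same-family features use a CDR3β-only TCRdist variant:
trim 3 residues from the front and 2 from the back (when length > 5),
score aligned positions as `min(4, 4 − BLOSUM62)` floored at 0, allow one
contiguous gap whose placement minimizes the cost, add 4 per gapped
position, and multiply by 3. Features in different TRBV families are at
infinite distance. Edges are drawn at distance ≤ 14.

Anchors are chosen greedily by descending degree; ties break by publicity,
then lexicographically, so the result is deterministic. Selection stops
when the maximum remaining degree is ≤ 1 (a degree-1 pair carries no
redundancy worth collapsing); `continueDegreeOne = TRUE` keeps going. The
selected anchors always form an independent set of the input graph.

## Classifier

`fitAlleleModel` fits an L1-penalized logistic regression with
*inverse-probability class weights*: each class's weights sum to exactly
1, so rare-allele models are not dominated by the negative class. The
penalty path is searched by 5-fold cross-validation that is **grouped by
subject** (a subject's repertoires never straddle folds) and stratified by
label, maximizing mean out-of-fold AUROC. The reported `lambda` is on the
sum-loss scale; internally `glmnet` receives `lambda / 2` to account for
its mean-loss parameterization. When several penalties tie on CV AUROC,
the package keeps the **smallest (densest) tied penalty**: with binary
features and IPW, ties almost always arise on plateaus where extra
features carry near-zero weights, and we prefer retaining weak real
features over dropping them, since the screen has already controlled false
features aggressively. The intercept is never penalized and the binary
design is not standardized.

## Calibration, gating, evaluation

Decision scores `f` become probabilities via Platt scaling
`p = σ(A·f + B)`. The *high-sensitivity* mode adds repertoire richness:
`p = σ(A·f + B + C1·u + C2·u²)` with `u = log10(U)`, fit on
computationally downsampled replicates (`downsampleRepertoire`,
`buildCalibrationSet`; default draw list 1, 5, 10, 25, 50, 100, 500 ×10³
— the full pipeline's `pipelineConfig` uses a shorter list matched to the
synthetic repertoire depth). Both fits minimize weighted cross-entropy with a tiny ridge
(1e-6) so separation cannot push parameters to infinity.

The confidence gate retains a prediction only when `p < 0.1` or
`p > 0.9`, with **strict** inequalities — boundary values are masked.
Expected calibration error uses 10 equal-width bins; AUROC uses the
Mann-Whitney statistic with ties counted one half; balanced accuracy is
`(TPR + TNR) / 2`.

## Meta-clonotypes

When genotypes are imputed rather than measured, newly discovered features
are screened against the reference feature set: any candidate within
edit distance ≤ 1 of a same-family reference feature is excluded as
rediscovery. The remainder are clustered at TCRdist ≤ 14 by the same
greedy anchor rule and rendered as anchored regular expressions: aligned
mismatches become character classes (`[LV]`), a length-1 gap becomes
`.{0,1}` (optional position) placed where total mismatch is minimal. Every
member of a cluster full-matches its regex by construction. Prevalence is
reported per exposure × genotype stratum (`+Ex/+HLA`, `+Ex/−HLA`,
`−Ex/+HLA`, `−Ex/−HLA`); empty strata are flagged rather than reported
as zero.

## Determinism

Every stochastic step takes an explicit seed; sorting uses radix order so
results do not depend on locale; model JSONs are written with 17
significant digits so a write/read cycle is bit-exact; and
`pipelineConfig` hashes every parameter except the output path, letting
`runAll` skip reruns and guarantee that a fixed seed + config produces
byte-identical artifacts.

## Synthetic study conditions

The generator defaults (`simulationConfig()`) define the package's study
conditions: 100 subjects, one allele at 30% prevalence, 10 exact-public
and 10 quasi-public planted features with penetrance 0.6 among carriers
and leak 0.02 among non-carriers, over 500 background clonotypes per
repertoire (geometric template counts, mean 3). Quasi-public features
plant an edit-1 variant of the canonical sequence in 90% of carrier
occurrences, so they are discoverable in edit-1 mode but mostly invisible
to exact matching — exactly the regime the edit-1 machinery exists for.

```{r}
library(tcrHLA)
co <- generateCohort(simulationConfig(seed = 1))
disc <- runDiscovery(co$repertoires, co$labels)
```
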