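---
title: "Hierarchical tissue-of-origin classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical tissue-of-origin classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tootree)
```

## The problem

A tumor's tissue of origin guides diagnosis, guideline-driven therapy, and
trial eligibility, yet 3%–5% of metastatic tumors present as cancers of
unknown primary (CUP), and a further slice of submitted diagnoses are
ambiguous or wrong. Molecular profiles carry a strong lineage signal: bulk
RNA expression reflects the cell of origin, and the pattern of reportable
somatic variants is enriched differently across cancer types. `tootree`
implements a hierarchical classifier over these inputs that either names a
cancer category at an adaptive level of granularity or abstains, plus the
evaluation, calibration, and clinical-review machinery around it.

## The label hierarchy

Cancer categories form a rooted tree (OncoTree-style). Depth-1 nodes are
*major* categories; deeper nodes are subcategories. The bundled default
configuration has 26 majors and 64 subcategories (90 reportable labels, 20
classifier branches); the category names are realistic but membership is
illustrative, since every algorithm here is topology-generic and arbitrary
hierarchies (any depth) can be supplied as JSON. Validation rejects
duplicate codes, orphan parents, multiple roots, and cycles, each with a
distinct error class, so malformed configurations fail loudly at load time.

```{r}
h <- default_hierarchy()
h
```

## Features

Each sample is encoded as a fixed-length vector with three blocks:

* **Variant block.** Gene-level one-hot indicators over a clinically curated
  panel (227 genes in the production-scale configuration). A gene is 1 iff
  the sample carries at least one *reportable* variant there: classified
  pathogenic or likely pathogenic, variant allele frequency ≥ 5%, and ≥ 5
  supporting read alignments (both comparisons inclusive, since the
  thresholds are stated as requirements). Allele frequencies themselves are
  deliberately not features.
* **Expression block.** The top-variance genes on log2(TPM+1) (≈10,000 at
  production scale; simulations here use 50–200). Platform harmonization is
  a per-platform, per-gene median shift to the cohort-wide gene median,
  followed by per-gene z-standardization fitted on training data. The
  median-shift form was chosen because it removes a multiplicative platform
  batch factor exactly on the median (the package tests this to 1e-6), is
  invertible, and needs only rank-robust statistics. Whether the production
  system log-transforms before normalizing is not public; the log2(TPM+1)
  choice here is documented as an assumption. Genes that are constant in
  training get their scale floored (they encode to 0), and genes missing
  from a profile are imputed as 0 on the standardized scale — i.e. at the
  training mean.
* **Sex.** male = 1, female = 0, unknown = 0.5 (the midpoint avoids biasing
  either class when sex is unrecorded).

Samples under 20% tumor content are flagged in QC rather than rejected: the
threshold mirrors the upstream laboratory exclusion, but a library should
not silently drop data.

## Branch classifiers

One softmax network is trained per *branch* — an internal node with two or
more children. A branch's training set is every sample whose truth path
passes through the branch parent and continues at least one level below it;
the class label is the child subtree containing the truth. Samples whose
truth *is* the parent (e.g. "carcinoma consistent with known breast
primary", no subtype) train ancestor branches but are excluded from that
node's branch, carrying exactly the information they have.

Each network has four dense layers (three hidden layers of width 256 by
default) with batch normalization, ReLU, and dropout (rate 0.25) on the
hidden layers, trained by Adam (learning rate 0.005) on multi-class
cross-entropy. Because branch outputs must be probability vectors that sum
to one — the propagation step depends on it — the output layer is a softmax
over the branch's children. Optimizer settings not fixed by the design
(epochs, batch size, initialization, early stopping) default to: at most 100
epochs, batch 256, He-style seeded initialization, early stopping with
patience 10 on a 10% validation split. All are configurable through
`training_config()`; the test suite and examples use smaller widths (32–64)
and epoch caps (25–40), which are ample for the simulated feature sizes.
Training is bit-reproducible given the seed; the ensemble derives one seed
per branch from the base seed so branches are independent but jointly
reproducible. An optional inverse-frequency class weighting is exposed
(default off) since it is not known whether the production system used one.

Internal nodes with exactly one child get no network: a softmax over one
label is constantly 1, so the child inherits the parent score. Branches
whose routed training data contain fewer than two child classes are recorded
as untrained and score uniformly at inference, with a warning.

## Score propagation and calling

Each branch emits child scores summing to 1. Walking the hierarchy top-down,
every child score is multiplied by its parent's propagated score. This
guarantees, by construction: major-category scores sum to 1; every internal
node equals the sum of its children (tolerance 1e-6 in all checks); terminal
scores sum to 1; and scores are non-increasing with depth. Branch vectors
are validated on entry (nonnegative, sum within 1e-4 of 1) and renormalized
exactly before use.

A call is a greedy descent from the root: at each node take the
highest-scoring child (ties broken lexicographically for determinism) and
keep descending while the score stays at or above the call threshold. The
reported label is the deepest node retained — so the granularity of the call
adapts to confidence — and a sample whose best major category is below
threshold is a no-call. The shipped operating threshold is 0.55, compared
inclusively. Thresholds ≤ 0.5 are rejected outright: since majors sum to 1,
a threshold above 0.5 makes the call provably exclusive (no two majors can
both qualify), and the package verifies this by exhaustive search over
simplex grids. A subcategory can never be reported without its parent
qualifying, by monotonicity; this is a structural property of the design,
not a separate rule.

## Hierarchical metrics

Per-sample metrics compare the predicted path `P` and truth path `T` (both
root-excluded, as node sets):

* hierarchical PPV = `|P ∩ C(T)| / |P|`, where the closure `C(T)` is `T`
  plus all descendants of the truth terminal;
* hierarchical sensitivity = `|T ∩ P| / |T|`.

The closure in the PPV numerator is what credits a prediction that is *more
granular* than the truth but stays inside the truth subtree — the right
behavior when specimens arrive labelled only to the major category. The four
canonical configurations (exact match; two-level prefix of a deeper truth;
wrong terminal under the right level-2 node; deeper-than-truth inside the
subtree) evaluate to (1, 1), (1, 2/3), (2/3, 2/3), and (1, 1), and are
frozen as fixtures in `worked_example_fixtures()`. Both metrics are also
checked against a brute-force set-arithmetic oracle on randomly generated
hierarchies and paths.

Cohort metrics (mean hPPV/hSens, top-1/top-2 major PPV, per-major PPV and
sensitivity, the depth-1 confusion matrix) are averaged over *called*
samples with a mapped non-CUP truth; no-call and CUP samples contribute to
the call rate only. On a flat hierarchy, mean hPPV reduces exactly to top-1
PPV, which the tests assert.

## Threshold calibration

`sweep_threshold()` applies the call logic over a grid (default 0.51–0.99,
step 0.02, respecting the > 0.5 exclusivity requirement) and reports call
rate and hPPV per threshold, optionally within a stratum (e.g. metastatic
cases). Call rate is non-increasing in threshold by construction. The
published operating point (0.55) was chosen on a qualitative balance of the
two curves; as a reproducible stand-in, `select_threshold()` defaults to
maximizing their harmonic mean, with a minimum-hPPV rule and a knee-point
rule as alternatives, and ties resolving to the lower threshold (more
calls). Which stratum the production choice used is not fully public, so the
stratum is an argument, not a fixture.

## Clinical triage rules

The review procedure is a deterministic, ordered rule engine
(`triage_case()`): (1) no call → no action; (2) concordant non-CUP call → no
action; (3) a discrepancy candidate (CUP called, or non-CUP mismatch) at or
above the discrepancy threshold opens a critical value discrepancy; (4) CUP
+ high score + at least one supporting orthogonal-evidence flag → eligible
for diagnosis change; (5) CUP + high score without support → discretionary
lineage change; (6) non-CUP discrepancy whose submitted label scores exactly
0, or with a high-scoring call → confirmatory testing; (7) anything else →
reported with a discretionary change offered. The discrepancy threshold
defaults to 0.90 but is configurable because the underlying procedure
explicitly leaves it to the reviewing pathologist's discretion. Rules (4)
and (5) gate on the 0.90 discrepancy threshold (not the 0.55 call
threshold), matching the requirement that diagnosis changes need a
high-confidence score. Every decision records all matched rule identifiers;
note that rule (3) only sets the discrepancy flag, so any case matching it
necessarily also matches one of the action rules (4)–(6) — the rules are a
flag-setter plus an action chain, not seven mutually exclusive outcomes.
Orthogonal evidence (IHC, hallmark fusions, viral reads, mutational
signatures, imaging/history) is consumed as curated tri-state flags and is
never a model input.

## The synthetic-cohort simulator

`simulate_cohort()` generates cohorts with the statistical structure the
classifier assumes, so everything above is testable without clinical data:

* every hierarchy node contributes a sparse log2-expression effect vector
  (default: magnitude 2 on 10% of genes), summed along the truth path, so
  sibling subtypes share their parent's signal and differ in finer genes —
  the nesting the branch architecture expects;
* within-class Gaussian noise (SD 1) inflated 1.5× for metastatic samples;
* multiplicative platform batch factors (two platforms, factors 1 and 2);
* panel variants drawn per gene at a label-enriched rate (0.4 in 2 enriched
  genes per label) or background rate (0.02), with VAF/support above the
  reportability thresholds, plus sub-threshold and benign/VUS noise records
  that exercise the filter;
* per-label sex priors drawn from Beta(2, 2);
* CUP samples (10%) simulated as ordinary tumors whose label is withheld
  from the metadata but recorded in the truth table for oracle evaluation.

These defaults were chosen once as a moderately separable regime — strong
enough that a correctly implemented pipeline separates classes, weak enough
that noise inflation and threshold effects are visible. The "null"
configuration used for chance-level checks removes *all* label-linked
signal: expression effects to 0, variant enrichment down to the background
rate, sex priors to 0.5 — otherwise variant and sex channels would keep
accuracy above chance by design.

What the simulator does **not** emulate: real gene identities or
co-expression structure, read-level noise, copy-number or fusion events,
intra-tumor heterogeneity, label noise in submitted diagnoses, or the class
imbalance of clinical archives (truth labels are uniform unless configured
otherwise). Passing tests therefore demonstrate correctness of the
algorithms and the recoverability of planted structure — not clinical
accuracy, which can only come from real cohorts.

## Numerical and engineering choices

* Probability-vector tolerance 1e-4 on input branch vectors, 1e-6 asserted
  on all conservation properties; batch-normalization epsilon 1e-5;
  standardization scales floored at 1e-8 (below that, the gene encodes 0).
* Tie-breaks everywhere are lexicographic by code (branch ordering, greedy
  descent, top-k majors), making serialization and predictions
  deterministic.
* Degenerate inputs have defined behavior: a root-only hierarchy has zero
  branches; a one-class branch refuses to train with an instructive error
  (pass-through/uniform is the correct treatment); an unknown platform at
  encode time gets identity parameters plus a warning; empty cohorts and
  empty strata raise typed errors.
* Model persistence is plain JSON at full double precision (an `-1` sentinel
  stands in for infinite scale floors, since JSON has no `Inf`), so a
  round-tripped model reproduces its predictions bit-for-bit.
* Test and example problem sizes (hundreds of samples, 25–100 genes, hidden
  widths 32–64, ≤ 40 epochs) were chosen so the planted structure is
  comfortably recoverable while the full suite runs in about a minute;
  production-scale dimensions (10k genes, width 256, 100 epochs) remain the
  defaults of the public API.

## Known limitations

* The dense-network trainer is written in base R matrix code. It is exact
  and reproducible, but not GPU-accelerated; production-scale training
  (hundreds of thousands of samples × 10k features) would want a compiled
  backend.
* The bundled 90-label topology is illustrative; users with a real ontology
  should load their own JSON.
* Diagnosis-string mapping is a lookup table plus a CUP/code fallback, not a
  clinical-grade normalizer.
* Scores are propagated softmax outputs, not calibrated probabilities;
  `sweep_threshold()` characterizes the operating trade-off but no
  probability calibration (Platt/isotonic) is applied.
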