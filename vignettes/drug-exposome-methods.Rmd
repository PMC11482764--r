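---
title: "Methods: drug spectral libraries, analog propagation and exposure readout"
author: "msDrugLib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug spectral libraries, analog propagation and exposure readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msDrugLib)
```

# Scope and model

`msDrugLib` implements three connected procedures for reading drug
exposure out of untargeted LC-MS/MS data.

**Library assembly.** Reference MS/MS spectra from open collections are
merged into `DrugRecord` objects. Deduplication uses the first
(2D-structure) block of the InChIKey when a structure is known, so salts
and stereoisomers of one active compound collapse into one record; when
only a name is known, the case-folded name is the key. The display name
follows the first-synonym convention of a supplied synonym index, because
common drugs carry hundreds of synonyms and a deterministic choice keeps
exports stable. Metabolite reference spectra whose names embed the full
drug name are captured by partial name matching (below). Metadata tables
are joined structure-first, name-second, fill-only-missing: a later or
weaker join never overwrites an earlier or stronger one, and records are
never dropped by enrichment.

**Analog propagation.** Unannotated corpus spectra are linked to library
drugs with the modified cosine. Writing $\Delta = m_B - m_A$ for the
precursor difference, fragment pairs may match unshifted
($|m_a - m_b| \le \tau$) or shifted ($|m_a + \Delta - m_b| \le \tau$);
pairs are assigned one-to-one and the score is the normalised dot product
of square-root-scaled intensities. The assumption is the usual one behind
spectral alignment: a structural modification moves the precursor and the
modification-bearing fragments by the same $\Delta$ while the unmodified
substructure fragments stay put. Candidate analogs then pass a
five-filter cascade in a fixed order — exposure source, curated
delta-mass list, known-library match, shared-parent structural
similarity, background-cohort prevalence — and each rejected candidate is
attributed to its *first* failing filter in the attrition report, which
makes the report additive (input = output + per-filter failures +
review).

**Exposure readout.** Feature spectra are annotated by same-precursor
cosine match against the drug/metabolite partition first and the analog
partition second; an analog annotation never overrides a library match.
Evidence is grouped by parent drug: the raw exposure value of drug $d$ in
sample $s$ is the sum of peak areas of all features annotated to $d$
(parent ion forms, metabolites, analogs), displayed as
$\log_{10}(x + 1)$. Detection is raw $> 0$. Stratification clusters
samples hierarchically (Ward linkage, Euclidean distance on the
log-abundance profiles); group statistics use Kruskal–Wallis plus
pairwise Wilcoxon with Benjamini–Hochberg adjustment; detection–covariate
association uses the Pearson chi-square without continuity correction.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `scoreThreshold` | 0.7 | — | conventional molecular-networking cutoff for confident alignment |
| `minMatchedPeaks` | 6 | peaks | guards against high-scoring sparse matches |
| `fragmentTolerance` | 0.01 | Da | high-resolution instrument fragment accuracy |
| `precursorTolerance` | 0.01 | Da | same-compound precursor agreement for clustering/annotation |
| `minPrecursorDelta` | 0.5 | Da | an "analog" must differ in mass from its parent; same-mass hits are library matches |
| `deltaTolerance` | 0.01 | Da | separates CH2 (14.0157) from neighbouring offsets at the two-decimal precision of the curated list |
| `minOffsetOccurrence` | 10 | pairs | rare offsets are unreliable at repository scale; scale down for small corpora (see below) |
| `tanimotoThreshold` | 0.5 | — | community default for "same scaffold" on folded circular fingerprints |
| `rtTolerance` | 0.1 | min | typical UHPLC peak width for co-elution |
| background `threshold` | per cohort | fraction | e.g. 0.5 for general-population feces, 0.7 for milk: a drug analog seen in most of an unexposed population is not an exposure signal |

All matching thresholds are surfaced in `analogConfig()` and in the CLI
script; none is hard-wired.

# Numerical and design choices

**Intensity scaling.** Square-root scaling before the dot product dampens
base-peak dominance; `scaling = "none"` is available for plain dot
products. Scores are clamped to $[0, 1]$ against floating-point drift.

**Greedy assignment.** Peak pairs are taken greedily by descending
intensity product with deterministic tie-breaks (query index, then target
index). Greedy can in principle fall short of the exhaustive optimal
one-to-one assignment when candidate pairs conflict; the test suite and
the acceptance script compare greedy against an exhaustive
branch-and-bound oracle on 1,000 random small spectra and observe zero
gap — conflicts require near-coincident fragment spacings that have
negligible measure for random spectra, though adversarial inputs can
create them.

**Degenerate inputs.** Empty spectra are errors for similarity;
duplicate m/z peaks are merged by intensity sum at construction, so the
strictly-ascending peak invariant holds on every path. Spectra without a
charge default to +1 (positive mode). A variable constant across all
samples gets $p = 1$ by convention in group comparisons. Expected
chi-square cells below 5 produce a recorded warning, never an automatic
correction.

**Partial-name boundary rule.** The drug name must occur inside the
candidate name *ending* at a word boundary (string edge, whitespace,
hyphen or comma); the left side may be fused. Metabolite nomenclature
fuses prefixes directly onto the drug name (*N*-desmethylvenlafaxine,
hydroxyibuprofen) while suffix modifiers are separated (venlafaxine
*N*-oxide, diclofenac glucuronide), so a right-boundary-only rule
captures both patterns; requiring a left boundary as well would lose the
fused-prefix metabolites that motivate the step. Short names embedded
mid-word ("val" in "valsartan acid") still fail the right-boundary
check. Equal-length matches to distinct drugs are never auto-linked; they
go to a review list, replacing the manual inspection step of a human
curation workflow with a deterministic rule plus an explicit queue.

**Occurrence counting.** The recurrence rule for mass offsets
("an offset must be seen at least *n* times across the run") counts
candidate–parent pairs after the list-membership check, run-wide. The
default *n* = 10 is meaningful at repository scale (tens of thousands of
candidate pairs); the synthetic fixture, with ~20 candidate pairs, scales
it to 2. The membership rule, not the recurrence rule, carries the
planted off-list decoys in the fixture; recurrence is exercised by a
dedicated counting test.

**Cluster determinism.** Spectral clustering visits spectra by descending
total intensity (ties by id) and joins the first eligible cluster, so the
partition is reproducible; the representative is the highest-intensity
member. Stratification labels are renumbered by decreasing group size
(ties by first sample id), making labels invariant to sample order.

**Choice of k.** The number of exposure groups is user-chosen.
`stratifyByExposure()` reports mean silhouette widths for $k = 2..8$ to
assist, but never auto-selects: co-occurrence group counts are a study
design decision, not an optimisation target.

**BH family.** Benjamini–Hochberg adjustment is applied over the pairwise
Wilcoxon family *within* one variable (all $k(k-1)/2$ group pairs), not
across variables. Max-standardisation (each variable scaled to its
maximum) is a display transform only; ranks, and hence all tests, are
computed on raw values.

**In-source fragments.** An analog co-eluting with its parent (median
|ΔRT| within tolerance over co-detected samples) at a *lower* precursor
mass is flagged as a probable in-source fragment. Flagged entries are
retained: whatever the ion's physical origin, its indication of drug
exposure is unchanged.

# What the synthetic fixtures emulate — and what they do not

The generators (`generateDrugLibrary()`, `generateAnalogCorpus()`,
`generateCohort()`, `generateBackgroundCohorts()`) produce, under a fixed
seed, a fully labelled world: random druglike formulas with [M+H]+
precursors; 8–20-peak spectra; analogs built by shifting a random 30–70%
of the parent's peaks and the precursor by a curated offset with 0.002 Da
Gaussian jitter; decoys for every filter class (endogenous-source
parents, off-list offsets, verbatim known-drug spectra via a
methylation-twin drug pair, an analog shared by two isobaric but
structurally dissimilar drugs, a background-ubiquitous analog); and a
60-sample cohort drawn from three disjoint regimen templates with
lognormal abundances and 10% detection dropout (at least one regimen drug
always remains detected — an exposed sample is assumed to leave some
trace). Planted effects sit several decision-threshold-widths away from
every default cutoff, so passing tests certify the machinery, not luck at
a knife edge.

Deliberately *not* emulated: realistic fragmentation chemistry (peaks are
random, so fragment positions carry no structural information),
retention-time prediction, correlated instrument noise, isotope
envelopes, chimeric spectra, and the long-tailed redundancy of real
repositories. Consequently, green tests demonstrate that the algorithms
recover planted structure under the stated noise model — they do not
certify annotation accuracy on real cohorts, where threshold choices and
library coverage dominate.

Fingerprints in the fixture path are generated directly as bit vectors
with controlled pairwise Tanimoto, which exercises the shared-analog
arbitration contract without a cheminformatics dependency; for real data
any folded circular fingerprint (e.g. from ChemmineR) can be supplied to
`filterSharedAnalogs()` as a named list of bit vectors.

# Problem sizes and determinism

The shipped validation runs use: 24 drugs + 24 metabolites, a
119-spectrum corpus (19 planted + 100 noise), a 40-sample background
cohort, a 60-sample cohort over 3 regimens, 1,000 random spectrum pairs
for the greedy-vs-optimal comparison, 1,000 null and 500 shifted
replicates for the Kruskal–Wallis calibration. These sizes give stable
statistics while keeping the full suite fast on a single CPU. All
randomness flows from explicit seeds; the acceptance script derives every
stream from its `--seed` argument.

# Known limitations

* The analog search is all-pairs; no index accelerates repository-scale
  corpora. For desk-scale corpora (thousands of spectra) this is fine.
* Clinical-phase conflicts between metadata sources are resolved by
  first-fill priority, not by source authority ranking.
* The background-prevalence filter implements the frequency rule only;
  expert plausibility judgments beyond frequency must be expressed as a
  manual exclusion list.
* Whether the delta-offset tolerance should be absolute or ppm-relative
  is an open question in the field's practice; the package uses absolute
  Da with the tolerance exposed.
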