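# msDrugLib

Empirical drug-exposure readout from untargeted LC-MS/MS metabolomics.

Clinical records of medication use are incomplete; untargeted tandem mass
spectrometry can establish drug exposure directly from biological samples,
but raw library annotations are hard to interpret (IUPAC names, no
pharmacology) and miss most drug **metabolites**, which often dominate in
feces, urine or milk. `msDrugLib` is an R toolkit for metabolomics
researchers that addresses both gaps:

1. **Library assembly** — merge open reference MS/MS collections into a
   drug library (deduplicated on the first InChIKey block, named by the
   first-synonym convention), capture metabolite spectra by partial name
   match ("N-desmethylvenlafaxine" → venlafaxine), and attach
   controlled-vocabulary metadata: exposure source (medical / endogenous /
   food / personal care / industrial), pharmacologic class, therapeutic
   area, indication, mechanism of action.
2. **Analog propagation** — find *unannotated* drug metabolites and
   transformation products in an MS/MS corpus by modified-cosine spectral
   alignment, then curate the candidates with a five-filter cascade.
3. **Exposure readout** — annotate cohort feature tables against the drug
   and analog libraries, build samples × drugs exposure tables, summarise
   by ontology, stratify samples by drug co-occurrence, and test
   exposure–metabolite associations.

## The methods at the core

**Modified cosine.** For spectra *A*, *B* with precursor difference
Δ = *m*<sub>B</sub> − *m*<sub>A</sub>, fragment pairs may match unshifted
(|*m*<sub>a</sub> − *m*<sub>b</sub>| ≤ τ) or shifted
(|*m*<sub>a</sub> + Δ − *m*<sub>b</sub>| ≤ τ). Pairs are assigned
one-to-one greedily by descending intensity product and the score is the
normalised dot product of √-scaled intensities, so a drug and its
modified form score highly even though the modified fragments moved by Δ.
With Δ = 0 the measure reduces exactly to the ordinary cosine.

**Five-filter curation cascade** applied to raw analog matches, in order:

| filter | rule |
|---|---|
| source | drop analogs whose parents have endogenous/food exposure sources |
| delta mass | offset must match a curated list (±0.01 Da; methylation +14.02, oxidation +15.99, glucuronidation +176.03, …) and recur run-wide |
| library match | drop candidates whose spectrum matches a known library compound at the same precursor |
| shared analog | an analog linked to several drugs requires pairwise parent Tanimoto ≥ 0.5 |
| background prevalence | drop analogs detected above a per-cohort frequency threshold in drug-free background cohorts |

Surviving entries carry a chemical interpretation of their mass offset;
retention-time co-elution additionally flags probable in-source fragments
(flagged, never deleted). Downstream statistics follow standard practice:
log10(x+1) peak areas, Ward/Euclidean hierarchical stratification,
Kruskal–Wallis + pairwise Wilcoxon with Benjamini–Hochberg correction,
Pearson chi-square for detection–covariate association.

## Worked example

Everything below runs on the built-in synthetic fixtures (planted ground
truth, no downloads):

```r
library(msDrugLib)
spec <- fixtureSpec(seed = 1)
lf  <- generateDrugLibrary(spec)
lf$library
#> DrugLibrary: 48 records (24 drugs, 24 metabolites), 48 spectra, 24 with metadata

cor <- generateAnalogCorpus(lf, spec)
raw <- analogSearch(lf$library, cor$corpus)          # 27 modified-cosine hits
res <- buildAnalogLibrary(raw, lf$library, defaultDeltaMassList(), cor$corpus,
                          config = analogConfig(minOffsetOccurrence = 2),
                          fingerprints = lf$fingerprints,
                          backgroundCohorts = generateBackgroundCohorts(cor, spec))
res$attrition
#>                        stage count
#> 1                      input    19
#> 2                fail_source     4
#> 3            fail_delta_mass     3
#> 4         fail_library_match     2
#> 5         fail_shared_analog     1
#> 6       review_shared_analog     0
#> 7 fail_background_prevalence     1
#> 8                     output     8
head(res$entries[, c("analog_id", "parent_drug_id", "delta_mass", "delta_interpretation")], 3)
#>       analog_id parent_drug_id delta_mass                    delta_interpretation
#> 1 corpus_true01         drug01   14.01565                             methylation
#> 2 corpus_true02         drug02   15.99492 oxidation (hydroxylation / oxygen gain)
#> 3 corpus_true07         drug07   14.01565                             methylation
```

The attrition report reads: 19 analog candidates entered the cascade; 4
were analogs of endogenous/food-sourced compounds, 3 carried offsets not
in the curated list, 2 were really known library drugs, 1 was shared by
two structurally dissimilar drugs, 1 was ubiquitous in a background
cohort — exactly the planted decoys — and the 8 genuine analogs survive
with their offsets interpreted (+14.016 methylation, +15.995 oxidation).

```r
coh <- generateCohort(lf, spec)                      # 3 planted regimens
ann <- annotateCohort(coh$table, lf$library)
et  <- buildExposureTable(ann, coh$table, lf$library)
stratifyByExposure(et, k = 3)
#> StratificationResult: 60 samples in 3 groups (ward.D2, euclidean)
#>   sizes: g1=20 g2=20 g3=20
head(summarizeByVocab(et, lf$library, "pharmacologic_class"), 3)
#>             term n_drugs n_samples  fraction
#> 1  antihistamine       2        37 0.6166667
#> 2 antiretroviral       2        35 0.5833333
#> 3   beta blocker       2        20 0.3333333
```

The three recovered groups are exactly the planted regimen templates
(adjusted Rand index 1.0), and the class summary reports, per vocabulary
term, how many drugs and what fraction of samples show a detection.

The mass engine backs all offset arithmetic, e.g. the proton-pump
inhibitor omeprazole:

```r
round(protonatedMz("C17H19N3O3S"), 3)   # [M+H]+  -> 346.122
round(monoisotopicMass("O"), 2)         # oxidation offset -> 15.99
```

A command-line wrapper for cohort work is installed at
`system.file("scripts", "drug_exposure_tool.R", package = "msDrugLib")`
with subcommands `annotate`, `exposure-table`, `summarize`, `stratify`,
`compare`.

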