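# pcsubtype

Tools for assigning and comparing two three-class transcriptome
subtyping schemes for prostate cancer on the same expression data:

* **PCS** (Prostate Cancer Classification System): PCS1
  (aggressive luminal), PCS2 (luminal), PCS3 (basal), operationalized
  through its 37-gene signature (PCS37);
* **PAM50**, adapted to prostate cancer by retaining only the Luminal A,
  Luminal B and Basal classes (LumB is the aggressive luminal class).

The package is aimed at computational oncology groups who want to apply
both classifiers to a cohort, quantify where the two partitions agree,
and compare their prognostic value — and at methodologists who want a
fully testable, simulation-backed implementation of that comparison.

## What it computes

Both schemes use the same nearest-centroid machinery. After per-gene
median centering (with an explicit choice of reference cohort), sample
*i* is assigned to the class *c* maximizing the Spearman correlation
between its signature-gene profile and the class centroid:

    class(i) = argmax_c  cor_spearman( x_i , centroid_c )

with confidence = top score − runner-up score, and centroids trained as
per-gene class means from a labeled reference cohort.

On top of assignment the package provides:

* **Concordance**: cross-scheme contingency table; per-cell
  hypergeometric enrichment p with odds ratios and Benjamini–Hochberg q;
  Euclidean distances between all six subtype centroids in z-scored
  union-signature gene space, with nearest cross-scheme pairing.
* **Enrichment**: from-scratch GSEA — signal-to-noise class-vs-rest
  ranking, weighted running-sum enrichment score (ES), phenotype
  permutation null, NES, permutation p and BH q — plus a luminal/basal
  marker separation index per scheme.
* **Survival**: Kaplan–Meier curves with at-risk tables, log-rank
  tests, univariable and Gleason-adjusted Cox models (Efron ties,
  hazard ratios with 95% Wald intervals) and Harrell's C-index, per
  endpoint (biochemical recurrence, metastasis, prostate-cancer-specific
  mortality).
* **Synthetic cohorts**: a generator planting three subtypes with
  known centroids, cross-scheme label concordance, marker architecture,
  subtype-dependent exponential hazards with calibrated censoring,
  Gleason–subtype association and cohort batch shifts — so the entire
  pipeline is testable without access to proprietary cohorts.

## Worked example

```r
library(pcsubtype)

reg <- builtin_signatures()
signature_overlap(reg$PCS37, reg$PAM50)
#> [1] "CCNB1" "CDC6"  "MKI67"

## a synthetic cohort standing in for a real expression matrix + clinical table
co   <- generate_cohort(cohort_spec(n_per_class = c(100, 100, 100)), seed = 1)
expr <- median_center(co$expression)            # single pooled reference

## classify both schemes
sub    <- subset_to_signature(expr, reg$PCS37)
calls  <- assign_subtypes(sub, train_centroids(sub, co$labels_a, reg$PCS37))
subB   <- subset_to_signature(expr, reg$PAM50)
callsB <- assign_subtypes(subB, train_centroids(subB, co$labels_b, reg$PAM50))
head(calls, 3)
#>   sample_id scheme class score_PCS1 score_PCS2  score_PCS3 confidence
#> 1     S0001  PCS37  PCS1  0.7200095 -0.5334282 -0.09981034  0.8198198
#> 2     S0002  PCS37  PCS1  0.6069227 -0.3947368 -0.31128497  0.9182077
#> 3     S0003  PCS37  PCS1  0.6249407 -0.2773826 -0.34186818  0.9023234

## where do the two schemes agree?
cross_tabulate(calls, callsB,
               classes_a = reg$PCS37$classes, classes_b = reg$PAM50$classes)
#> Cross-scheme contingency (n = 300):
#>      LumB LumA Basal
#> PCS1   93    6     1
#> PCS2    2   95     3
#> PCS3    7    0    93

centroid_distance_matrix(expr, calls, callsB,
                         genes = unique(c(reg$PCS37$genes, reg$PAM50$genes)))$nearest
#>      class_a nearest_b  distance
#> PCS1    PCS1      LumB 0.8162834
#> PCS2    PCS2      LumA 0.5618820
#> PCS3    PCS3     Basal 0.6500628

## survival: aggressive-vs-rest hazard ratio and concordance
rep <- subtype_outcome_report(calls, co$clinical,
                              class_order = reg$PCS37$classes,
                              endpoints = "PCSM")
rep$PCSM$scheme
#>     term     beta       hr ci_lower ci_upper       se       p_wald
#> 1 scheme 1.208957 3.349988 2.540609 4.417216 0.141101 1.052784e-17
rep$PCSM$c_index
#> [1] 0.6288648
```

Reading the output: the contingency diagonal shows each PCS class
pairing with its expected PAM50 partner (PCS1–LumB, PCS2–LumA,
PCS3–Basal; this cohort was generated with 10% cross-scheme label
corruption, hence ~90% diagonal); the nearest-centroid pairing recovers
the same structure in expression space; and the Cox model recovers the
planted aggressive-class hazard ratio (true value 3.0) with its 95%
interval.

The full pipeline (classification of both schemes → concordance → GSEA
→ markers → survival, with all tables and a manifest written to disk)
runs from one call or one config file:

```r
run_comparison(list(seed = 11, simulate = list(n_per_class = c(100, 100, 100))),
               out_dir = "results_run/")
```

or from a shell via the installed script
`system.file("exec", "pcsubtype-pipeline", package = "pcsubtype")`.

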