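# proteostrat

Proteogenomic stratification of chronic lymphocytic leukemia (CLL) cohorts,
as a tested R package.

## What this is for

Proteome profiling of CLL reveals patient subgroups that genetics and
transcriptomics miss — most importantly a poor-outcome subgroup ("ASB-CLL")
defined by high spliceosomal and low B-cell-receptor (BcR) signaling protein
abundance, present in roughly a fifth of patients. `proteostrat` implements
the statistical workflow behind that stratification for researchers who want
to run, audit, or extend it:

* a **synthetic multi-omics cohort generator** that plants the study's
  structure (six subgroups, chr12 gene-dosage effects, class-dependent
  mRNA~protein coupling, ASB-specific pathway and splicing shifts,
  group-dependent survival hazards) so every stage is testable without
  restricted patient data;
* **moderated differential abundance** (empirical-Bayes variance shrinkage:
  per-feature posterior variance `(d0*s0² + d*s²)/(d0 + d)`, moderated t on
  `d0 + d` df), gene-dosage profiles, per-gene mRNA~protein Spearman
  correlations, Fisher over-representation, chr12-based trisomy inference;
* **consensus clustering** (Monti-style subsampled re-clustering, consensus
  CDF delta-area k selection with a recorded override);
* **differential splicing**: percent spliced-in
  `PSI = (I/lI)/(I/lI + S/lS)`, rank-sum tests with the three filters
  (BH-adjusted p < 1%, |ΔPSI| > 0.1, mean inclusion counts > 20), and a
  label-permutation null for the number of significant events N_e with
  add-one p-value `(1 + #{null ≥ obs})/(n_perm + 1)`;
* **subtype classifiers**: a rank-based k-top-scoring-pairs (k-TSP)
  classifier with Monte Carlo cross-validated pair count and a
  missing-pair rule that lowers the vote threshold by one per unevaluable
  pair, and a PLS-DA classifier (NIPALS, leave-one-out AUROC component
  selection);
* **survival analysis** (Kaplan–Meier, log-rank, Cox with interaction
  designs such as `TP53 + ASB + TP53:ASB`), lymphocyte growth rates, and
  drug-screen viability normalization;
* a **protein co-abundance network** (top-SD features, positive-correlation
  edges, 3-core filter, Louvain modules at resolution 0.8, correlation-based
  module expansion).

## Worked example

```r
library(proteostrat)

# simulate a 68-sample discovery cohort and run the discovery pipeline:
# consensus clustering (k = 6), ASB characterization, splicing statistics
# with a 200-permutation null, survival, and the protein network
report <- run_discovery(cohort_config(), seed = 4, n_iter = 100)

report$cluster
#> $chosen_k    6          # biologically motivated override (elbow gave 4)
#> $ari_vs_truth 1         # adjusted Rand index vs planted labels
#> $asb_size    12         # recovered ASB-like cluster size (12/68 = 18%)
#> $asb_jaccard 1

report$differential$median_rho
#> 0.246                   # cohort-wide median mRNA~protein Spearman rho
report$differential$median_rho_by_class
#> background 0.207  IGHV 0.863  SF3B1 0.295  trisomy12 0.695

report$splicing
#> $n_significant_events 135   # exon-skipping events passing all 3 filters
#> $permutation_p 0.004975     # none of 200 permutations reached N_e = 135
#> $mean_psi_se_p 6.8e-08      # ASB has lower mean PSI over variable SE events

report$survival$logrank_ttnt_p
#> 0.0045                  # the six groups separate time to next treatment
```

Reading the numbers: the consensus partition recovers the six planted
subgroups essentially perfectly at this effect size; the ASB-like cluster
(identified as the one with the largest spliceosome-minus-BcR abundance
contrast) carries a genuine splicing phenotype (its significant-event count
is far outside the permutation null) and the groups differ in outcome. The
per-class coupling medians land on the calibration targets (0.69 for
trisomy-12-responsive, 0.86 for IGHV-responsive features).

Cross-cohort validation mirrors the deep-proteomics-to-DIA transfer:

```r
disc  <- simulate_cohort(cohort_config(seed = 11))
panel <- unlist(disc$gene_sets$sets[c("BCR", "SPLICEOSOME")])
model <- tsp_train_mccv(disc$protein$values, disc$truth, positive = "ASB",
                        panel = panel, seed = 3)
val   <- simulate_cohort(cohort_config(n_samples = 165, seed = 77))
run_validation(model, val)$ktsp$prevalence_pct
#> 20                      # percent of validation samples labeled ASB
```

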