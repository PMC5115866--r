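# ppilr — protein–protein interaction prediction by binned likelihood-ratio integration

`ppilr` is an R implementation of a naive-Bayes framework for genome-scale
protein–protein interaction (PPI) prediction. Heterogeneous evidence
channels — structural modeling (SM), protein–peptide (PrP), partner
redundancy (PR), gene-ontology similarity (GO), phylogenetic profile (PP),
orthology (OR) and cross-species expression correlation (EP) — are each
discretized into bins, converted into likelihood ratios against positive and
negative reference interaction sets, and multiplied into a single score:

```
LR(A,B) = max(LR_SM, LR_PrP) · LR_PR · LR_GO · LR_PP · LR_OR · LR_EP
```

where each per-channel LR for a bin *b* is

```
LR_b = P(score in b | interacting) / P(score in b | non-interacting)
```

estimated from the binned score distributions of the reference sets (with an
optional per-bin pseudo-count). Absent evidence contributes a neutral factor
of 1, so pairs with heterogeneous coverage remain comparable. A pair is
called a **reliable** prediction when its total LR strictly exceeds 600, and
a direct physical interaction when the structural component
`max(LR_SM, LR_PrP) · LR_PR` exceeds 600.

The package is aimed at computational biologists who want to (a) integrate
their own per-pair evidence tables into calibrated interaction scores,
(b) evaluate a predictor with ROC curves, reference-set recovery,
multi-protein-complex recovery and variant–interface enrichment, or
(c) annotate a protein's function from the gene sets enriched among its
top-ranked predicted interactors (preranked GSEA with a permutation FDR).
A seeded synthetic-interactome generator (`generate_world()`) emits every
input format the pipeline reads, with planted signal, so the entire stack is
testable end to end without any external database.

## What is implemented

| Area | Functions |
|---|---|
| Binned LR core | `fit_binned_lr`, `lookup_lr`, `combine_evidence`, `classify_reliable` |
| Orthology vectors + backoff | `orthology_vector`, `count_orthologous_interactions`, `fit_orthology_models`, `score_orthology` |
| Partner redundancy | `compute_pr_features`, `fit_pr_models`, `score_pr` |
| Cross-species expression | `s_pos`, `s_neg`, `s_orth`, `coxs`, `ep_score` |
| Evaluation | `roc_curve`, `recovery_fraction`, `build_compartment_negatives`, `shared_label_fraction`, `probability_true_vs_lr` |
| Complexes | `complex_recovery_lr`, `random_complex_null`, `seeded_member_prediction` |
| Function annotation | `rank_interactors`, `enrichment_score`, `enrichment_analysis`, `first_correct_rank` |
| Variant–interface statistics | `build_contingency`, `odds_ratio`, `log_odds_se`, `z_score` |
| Synthetic world | `world_config`, `null_world_config`, `generate_world` |
| Pipeline + I/O + CLI | `train_models`, `score_pairs`, `read_world`/`write_world`, `read_gmt`, `ppilr_cli` |

## Worked example

```r
library(ppilr)

# a 300-protein synthetic interactome with planted evidence
w      <- generate_world(world_config(n_proteins = 300, n_modules = 10, seed = 42))
models <- train_models(w)              # binned LRs from the training references
scores <- score_pairs(w, models)       # per-pair channel LRs + combined LR
sc     <- score_map(scores)

nrow(scores); sum(scores$reliable)
#> 7490 pairs scored, 603 reliable (LR > 600)

roc_curve(sc, w$refs_test)$auc
#> 0.992
recovery_fraction(w$refs_test$positives, sc, 600)   # planted positives recovered
#> 0.541
recovery_fraction(w$refs_test$negatives, sc, 600)   # compartment-crossed negatives
#> 0

combine_evidence(c(SM = 100, PrP = 50, PR = 2, GO = 3))
#> <combined_score: lr_total = 600, lr_structural = 200>

# variant-interface enrichment from a published 2x2 residue table
t <- contingency_table(n11 = 12151, n10 = 61401, n01 = 298442, n00 = 2387146)
round(odds_ratio(t), 2); round(z_score(t), 1)
#> 1.58   45.4

# the planted interface enrichment (theta = 1.6) is recovered from the world
round(odds_ratio(build_contingency(w$interfaces, w$variants)), 2)
#> 1.5
```

The test-set AUC of 0.992 and the ~54% positive recovery at LR > 600 (with
zero negative recovery) show the combined score separating planted
interactions from non-pairs; the odds ratio of 1.58 reproduces, to one
decimal, the published interfacial enrichment of disease-associated
variants.

## Command line

```sh
Rscript -e 'ppilr::ppilr_cli()' simulate --out world/ --seed 7 --n-proteins 500
Rscript -e 'ppilr::ppilr_cli()' train    --world world/ --out models.json
Rscript -e 'ppilr::ppilr_cli()' score    --world world/ --models models.json --out scores.tsv
Rscript -e 'ppilr::ppilr_cli()' evaluate --world world/ --scores scores.tsv --out eval/
Rscript -e 'ppilr::ppilr_cli()' snp-or   --table counts.tsv --out or_report.tsv
```

Subcommands: `simulate`, `train`, `score`, `evaluate`, `complexes`,
`annotate`, `snp-or`. All outputs are tab-separated with headers; reruns
with the same inputs and seed are byte-identical.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic world does and does not emulate, and known limitations.
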