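# oncorepurpose

An R implementation of a machine-learning drug-repurposing pipeline for
anti-cancer candidate discovery.  Given a drug catalogue with activity
flags, a drug–target interaction (DTI) matrix and a drug–drug
interaction (DDI) adjacency, the package:

1. **curates** positive/negative anti-cancer labels, excluding
   approved drugs that were in cancer trials or are chemically similar
   (Tanimoto ≥ 0.7 on Morgan fingerprints) to cancer-associated drugs;
2. **compresses** interactions into per-drug features — PCA of the
   DTI matrix to 64 dimensions, and a 256-dimensional logistic
   adjacency factorization with neighbor propagation
   (`p(i~j) = σ(uᵢ·uⱼ + bᵢ + bⱼ + c)`, then
   `zᵢ = (1−α)uᵢ + α·mean(uⱼ)`) of the DDI graph — imputing missing
   blocks from the chemically most similar drug, else the block mean;
3. **trains** a directed-bond message-passing neural network (D-MPNN)
   on the molecular graph, with the interaction blocks concatenated to
   the learned molecule vector, as an ensemble of two seeds, plus
   XGBoost and SVM fingerprint baselines;
4. **evaluates** with balanced Bemis–Murcko scaffold splits repeated
   three times, reporting AUC, AUPR, accuracy, Cohen's κ and MCC, and
   runs feature-ablation comparisons (no features / DTI / DDI /
   physchem);
5. **ranks** a candidate library by predicted activity score with
   competition ranks and flag-only exclusion of known actives.

A synthetic benchmark generator plants label signal jointly in a
structural motif, DTI class membership and DDI community membership,
and records the ground truth, so the full pipeline is testable without
licensed databases.

## Worked example

```r
library(oncorepurpose)

# synthetic study data: 500 drugs, 60 scaffolds, planted signal
bundle  <- make_benchmark(benchmark_config(n_drugs = 500, seed = 11))
dataset <- benchmark_dataset(bundle)

# interaction features: PCA(64) on DTI, 256-dim DDI embedding, imputation
pca  <- fit_pca(bundle$dti, k = 64)
amfp <- fit_amfp(bundle$ddi, d = 256, seed = 3)
feats <- build_feature_table(bundle$catalogue, bundle$dti, bundle$ddi, pca, amfp)
#> feature table: dti average=19 direct=450 neighbor=31 | ddi average=21 direct=450 neighbor=29

# ablation: structure-only vs structure + DTI + DDI, 3 scaffold splits
cfg0 <- model_config(hidden_dim = 64, message_depth = 2, epochs = 10,
                     learning_rate = 3e-3, seed = 1)
cfgA <- cfg0; cfgA$aux_blocks <- c("dti", "ddi")
report <- run_ablation(dataset, feats, list(no_features = cfg0, ddi_dti = cfgA),
                       n_repeats = 3, base_seed = 70)
print(report)
#> ablation over 3 repeats:
#>   no_features              AUC 0.573 AUPR 0.474 acc 0.660 kappa 0.079 MCC 0.146
#>   ddi_dti                  AUC 0.759 AUPR 0.654 acc 0.740 kappa 0.391 MCC 0.405
```

The `ddi_dti` row shows the point of the method: adding compressed
DTI/DDI information lifts test AUC well above the structure-only model
on scaffold-held-out drugs.  (The generator's oracle ceiling under 10%
label noise is ≈0.87, so 0.76 from a 10-epoch desk-scale network is a
strong recovery.)  Ranking the library with the trained ensemble:

```r
ens    <- train_ensemble(dataset, feats, cfgA, n_members = 2)
ranked <- rank_library(ens, dataset$molecules, feats)
head(ranked, 3)
#>   rank     id     score excluded exclusion_reason
#> 1    1 D00309 0.9992256    FALSE             <NA>
#> 2    2 D00401 0.9990498    FALSE             <NA>
#> 3    3 D00008 0.9988962    FALSE             <NA>
```

The head of the list is dominated by planted high-signal positives;
`apply_exclusions(ranked, known_ids)` flags documented actives without
disturbing ranks.

A thin CLI over the same functions ships in
`inst/scripts/oncorepurpose`
(`simulate` / `curate` / `featurize` / `evaluate` / `rank`).

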