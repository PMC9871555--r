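# pmifusion

Estimating the post-mortem interval (PMI) of rats from lab-on-chip
polypeptide profiles by multi-organ ensemble fusion.

Forensic pathologists need the time since death; protein degradation is one
of its most reliable molecular clocks. Microfluidic capillary gel
electrophoresis ("lab-on-chip") reports, for an organ sample, a table of
polypeptide peaks — migration time (s), molecular mass (kDa, 14–230 kDa
range) and peak height (fluorescence units). As tissue degrades, this
profile shifts systematically. `pmifusion` implements, end to end, a
pipeline that turns the peak tables of four organs (lung, liver, kidney,
skeletal muscle) of one animal into a single PMI call over 14 classes
(days 0, 1, 2, 3, 5, 7, 9, 12, 15, 18, 21, 24, 27, 30), plus a synthetic
cohort generator that reproduces the underlying study design (14 days × 6
rats × 4 organs = 336 training samples; 28-rat external cohort) so the
whole analysis runs without access to instrument data. It is aimed at
forensic/proteomics researchers evaluating classifier-fusion designs for
PMI estimation.

## The method

1. **Fragment confirmation.** Peaks are matched across samples by the
   migration-time identity rule |t − t̄_f| / t̄_f < 0.02 (greedy
   nearest-cluster assignment on running means, with a same-sample
   cannot-link constraint — one electropherogram resolves co-eluting
   fragments as distinct peaks). A fragment is kept for an organ only if
   detected in ≥ 5 of 6 biological replicates at some PMI day. The
   packaged reference catalog holds the 45 fragments with their organ
   memberships (21 / 22 / 19 / 23 in lung / liver / kidney / muscle).
2. **Per-organ sub-model search.** Rats are split 70/30 (by animal,
   stratified by day); features are z-scored on training statistics.
   Four selectors {LASSO, RFE, SFS, SBS} × five classifiers
   {LR, SVM, RF, GBDT, MLPC} = 20 sub-models per organ, each scored by
   accuracy, macro precision, macro recall and macro one-vs-rest AUC on
   the internal and external cohorts. The organ's best sub-model
   maximizes the rank-sum score: per metric column the best of M models
   scores M, the worst 1, ties share averaged positions; the total is the
   sum over the 8 columns (range [8, 8M]).
3. **Multi-organ fusion.** The four organ pipelines emit class
   probabilities p_o(y | x_o) per rat; combiners are soft voting
   (ŷ = argmax_y (1/4) Σ_o p_o), soft-weighted voting (weights ∝ member
   internal accuracy) and stacking (multinomial-logistic meta-learner on
   out-of-fold member probabilities). Greedy backward pruning removes a
   member only while removal strictly improves internal-validation
   accuracy.

## Worked example

The analysis lives in `analysis/01…06` — thin drivers over the package
functions, writing tables under `results/`. A compact session:

```r
library(pmifusion)

cat45 <- load_reference_catalog()
organ_membership_summary(cat45)$per_organ
#>   lung  liver kidney muscle
#>     21     22     19     23

cfg  <- experiment_config(seed = 1)                 # full study defaults
data <- prepare_study_data(cfg)                     # simulate -> match -> filter -> split
dim(data$organs$kidney$x_train)                     # 58 training rats x kidney fragments
```

Running the staged analysis (`Rscript analysis/03_submodel_search.R`, then
`05_multiorgan_fusion.R`) prints:

```
best sub-model per organ (rank-sum score, internal/external accuracy):
  lung    sbs+rf       score 154.0  acc 0.692 / 0.643
  liver   sbs+rf       score 144.0  acc 0.654 / 0.429
  kidney  sbs+rf       score 153.5  acc 0.808 / 0.643
  muscle  lasso+rf     score 157.0  acc 0.846 / 0.607

multi-organ fusion (internal / external accuracy):
  stacking               0.923 / 0.821
  soft_voting            0.846 / 0.821
  soft_weighted_voting   0.846 / 0.821

pruned member set: lung, liver, kidney, muscle (internal accuracy 0.923)
external misjudged rats (best combiner): 5 of 28
```

Read: random forests win every organ's sub-model grid; the kidney is the
strongest organ internally (0.808); fusing all four organs lifts external
accuracy from 0.643 (best single organ) to 0.821, and pruning retains all
four organs — each one contributes. The 20-seed replicate benchmark
(`analysis/06_replicate_benchmark.R`) summarizes the same comparison
across repeated experiments:

```
mean single-organ external accuracy: lung 0.614, liver 0.512, kidney 0.734, muscle 0.621
mean fused external accuracy: 0.811
fusion >= best single organ: 19/20 seeds
pruning removed exactly the adversary: 8/20 seeds
```

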