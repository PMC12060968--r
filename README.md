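# seqpka

Sequence-based prediction of protein residue pKa values with ensemble
shift regressors.

## What it does, and for whom

The pKa values of titratable side chains (Asp, Glu, His, Cys, Tyr, Lys)
determine protein charge states at a given pH — the input every
electrostatics calculation, constant-pH simulation, covalent-inhibitor
design and protonation-state assignment depends on. Classically these are
predicted from structure; `seqpka` implements the sequence-only
alternative for computational structural biologists: per-residue embedding
vectors from a protein language model are mapped to pKa values by small
regression ensembles, with no structure required.

The core model: an embedding backend turns a sequence into per-residue
features `x_i ∈ R^d` at a chosen transformer layer. Separately trained
acidic (Asp/Glu/Cys/Tyr) and basic (His/Lys) channels — each an ensemble of
M multilayer perceptrons (M = 200 by default) — regress the shift

    ΔpKa = pKa − pKa_sol(aa)

relative to model-peptide solution values. Ensembles are pretrained on a
large teacher-labelled corpus (shift predictions of a prior model) and
fine-tuned on experimental records at a reduced learning rate. Predictions
report the ensemble mean shift, its standard error (sd/√M), the
reconstructed absolute pKa, and a Henderson–Hasselbalch protonation class
at a reference pH: with f = 1/(1+10^(pH−pKa)) and thresholds 0.25/0.75 at
pH 7, a site is deprotonated below pKa 6.52, protonated above 7.48 and
titrating in the closed interval between.

The package also ships the full evaluation protocol (repeated
protein-grouped hold-out tests; RMSE/PCC/MAXE; protonation-state precision,
recall and critical error rate; the pretraining × channel-separation
ablation; transformer layer sweeps) and a synthetic planted-signal study
generator so that every stage is testable offline.

## Worked example

A complete run on a synthetic study — generate data, train both channels
with pretraining, predict, summarise, evaluate:

```r
library(seqpka)

spec  <- synthetic_spec(n_proteins = 60, n_teacher_proteins = 200, d = 16, seed = 7)
study <- synthetic_bundle(spec)
cfg   <- regressor_config(hidden = c(32, 16), epochs = 150, lr = 3e-3,
                          validation_fraction = 0.15, patience = 20)

models <- list(
  acid = train_channel(study$experimental, study$sequences, study$backend,
                       channel = "acid", layer = 1, teacher = study$teacher,
                       n_members = 10, config = cfg, seed = 1),
  base = train_channel(study$experimental, study$sequences, study$backend,
                       channel = "base", layer = 1, teacher = study$teacher,
                       n_members = 10, config = cfg, seed = 2)
)

pred <- predict_pka(NULL, study$sequences[1:2], study$backend, models)
head(pred, 5)
#> # A tibble: 5 × 8
#>   protein_id position aa    channel   shift stderr   pka class
#>   <chr>         <int> <chr> <chr>     <dbl>  <dbl> <dbl> <ord>
#> 1 P0001             4 ASP   acid    -1.41   0.0529  2.26 deprotonated
#> 2 P0001            12 GLU   acid     0.623  0.0479  4.87 deprotonated
#> 3 P0001            21 CYS   acid    -0.0150 0.0390  8.54 protonated
#> 4 P0001            22 HIS   base     1.79   0.0386  8.33 protonated
#> 5 P0001            26 ASP   acid    -1.60   0.0377  2.07 deprotonated
```

Each row is one titratable site: the predicted shift (pH units) relative
to the solution reference, the ensemble standard error, the absolute pKa
(`solution + shift`), and the protonation class at pH 7 — e.g. the His at
position 22 is up-shifted to 8.33, hence protonated, while the Asp sites
stay deprotonated.

```r
summarize_predictions(pred)
#> # A tibble: 6 × 5
#>   aa      sol  mode  mean     n
#>   <chr> <dbl> <dbl> <dbl> <int>
#> 1 ASP    3.67  2.65  3.53    21
#> 2 CYS    8.55  7.35  8.92     4
#> ...
```

`sol` is the model-peptide reference, `mode`/`mean` summarise the predicted
distribution per residue type, `n` counts sites (summing to `nrow(pred)`).

```r
ev <- run_holdout_evaluation(study$experimental, study$sequences, study$backend,
                             layer = 1, teacher = study$teacher, n_splits = 5,
                             test_fraction = 0.15, n_members = 5, config = cfg,
                             seed = 0)
ev
#> <pka_holdout_eval> 5 split(s) | RMSE 0.293 +/- 0.010 | PCC 0.994 +/- 0.000 |
#>   MAXE 0.879 +/- 0.058 | CER 0/180
```

The hold-out RMSE (0.293) sits at this study's observation-noise floor
(σ = 0.3), i.e. the model has recovered essentially all of the planted
signal; no critical protonation-state errors occur among the 180 evaluated
sites. `tidy(ev)`, `glance(ev)` and `autoplot(ev)` expose per-split
metrics, the one-row aggregate and the predicted-vs-true scatter.

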