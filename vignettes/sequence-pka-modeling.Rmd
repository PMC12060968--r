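---
title: "Sequence-based pKa prediction: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based pKa prediction: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqpka)
```

## The problem

The pKa of a titratable side chain (Asp, Glu, His, Cys, Tyr, Lys) controls
its charge at a given pH, and therefore catalysis, ligand binding, stability
and the choice of protonation states in molecular simulations. In a folded
protein the pKa is shifted away from its solution (model-peptide) value by
the local environment: desolvation, hydrogen bonding and charge-charge
interactions. `seqpka` implements a sequence-only prediction pipeline for
these values: per-residue embedding vectors from a protein language model
backend are regressed onto pKa *shifts* by ensembles of small feed-forward
networks, one ensemble for acidic residues (Asp, Glu, Cys, Tyr) and one for
basic residues (His, Lys).

## The model

For residue $i$ of a sequence, an embedding backend supplies a feature
vector $x_i \in \mathbb{R}^d$ at a chosen transformer layer. A channel
model is an ensemble of $M$ multilayer perceptrons $f_m$, each trained to
predict the shift

$$\Delta \mathrm{p}K_a = \mathrm{p}K_a - \mathrm{p}K_a^{\mathrm{sol}}(\mathrm{aa}),$$

never the absolute value: the solution reference already explains most of
the between-amino-acid variance, so regressing the shift focuses the model
capacity on the environmental signal. Predictions report

* `shift` $= \bar{f}(x) = \frac{1}{M}\sum_m f_m(x)$,
* `stderr` $= \mathrm{sd}_m\!\left(f_m(x)\right) / \sqrt{M}$ (ensemble
  standard error of the mean),
* `pka` $= \mathrm{p}K_a^{\mathrm{sol}}(\mathrm{aa}) + \bar{f}(x)$.

The default ensemble size is $M = 200$; members differ only in their seed
(weight initialization, data order and validation split), with a bootstrap
option available but off by default.

Two training stages mirror the transfer protocol for small experimental
datasets: **pretraining** on a large teacher-labelled corpus (pKa shifts
predicted for many proteins by a prior model), then **fine-tuning** on
experimental records by continuing optimization at a reduced learning rate
(one tenth of the pretraining rate by default). Training separate acidic
and basic channels reflects the opposite electrostatic response of the two
groups: burying an acid usually raises its pKa while burying a base lowers
it, so a pooled regressor must disentangle two conflicting mappings.

### Solution reference values

The packaged reference (`solution_pka()`) uses the alanine pentapeptide
(AAXAA) scale: Asp 3.67, Glu 4.25, His 6.54, Cys 8.55, Tyr 9.84,
Lys 10.40. Model-peptide scales differ by up to ~0.3 units between the GXG
and AAXAA families; all six values are configurable through a replacement
CSV, and every shift is computed against whatever table the caller passes,
so switching scale is a data change, not a code change.

### Protonation classes

At a reference pH the protonated fraction of an independent site is the
Henderson-Hasselbalch relation $f = 1/(1 + 10^{\,\mathrm{pH} - \mathrm{p}K_a})$.
Classes are assigned by thresholding $f$ at the reference pH
(defaults pH 7.0, 0.25 and 0.75):

* `protonated` when $f > 0.75$, i.e. pKa above the upper boundary;
* `deprotonated` when $f < 0.25$, i.e. pKa below the lower boundary;
* `titrating` for the closed interval in between — at the defaults,
  $6.52 \le \mathrm{p}K_a \le 7.48$ (boundary values are titrating).

A low pKa at pH 7 means the site is mostly deprotonated (the down-shifted,
nucleophilic cysteine thiolate is the canonical example) and a high pKa
means protonated (the up-shifted histidine cation); `classify_state()`
implements exactly this orientation. The *critical error rate* (CER) of a
prediction set counts only protonated-vs-deprotonated confusions; mistakes
into or out of the titrating band are not critical.

## Evaluation protocol

`run_holdout_evaluation()` repeats a train/test cycle over independent
random partitions of the *proteins* (never the residues: residue-level
splits would place near-identical embeddings of one protein on both sides).
Defaults are 20 splits with 10% of proteins held out, split $i$ seeded with
`seed + i`. RMSE, Pearson correlation and maximum error are reported per
split and aggregated as mean ± sd/√(number of splits); classification
counts are accumulated over all splits before precision, recall and CER are
computed, because the per-split class counts are tiny. The PCC of a
zero-variance vector is reported as `NA`, never coerced to 0, and the
per-amino-acid CER is suppressed when fewer than `min_class_count`
(default 5) accumulated truth sites are protonated or deprotonated.

`run_ablation()` evaluates the 2×2 design {pretraining, channel
separation} on one shared split table, so arm differences are paired.
`layer_sweep()` runs the same evaluation once per embedding layer and
reports the argmin layer overall and per amino acid. When pretraining is
active, teacher proteins that appear in a split's test set are excluded
from that split's pretraining (with disjoint teacher corpora the pretrained
ensemble is computed once and reused).

## The synthetic study generator

Because the experimental database and the multi-gigabyte language models
cannot ship with a package, `synthetic_spec()` defines a fully generative
stand-in that preserves the statistical structure the pipeline assumes:

* sequences with titratable positions drawn at the composition of the
  experimental database (Asp : Glu : His : Cys : Tyr : Lys ≈
  330 : 382 : 219 : 60 : 39 : 137);
* a latent true shift per site: acids from the mixture
  $0.75\,\mathcal{N}(0,1) + 0.25\,\mathcal{N}(2,0.7)$ — an enriched
  positive-shift mode, since strongly up-shifted buried carboxylates are
  the dominant feature of experimental shift distributions — and bases from
  the symmetric $\mathcal{N}(0,1)$;
* embeddings $x_i = s_i\, g_c\, w + \varepsilon$ with a unit planted
  direction $w$, channel gains $g_{\mathrm{acid}} = +1$,
  $g_{\mathrm{base}} = -1$, and isotropic noise
  $\varepsilon \sim \mathcal{N}(0, 0.1^2 I)$. The opposite gains encode the
  physical reason separate channels exist: the same environmental feature
  shifts acids and bases in opposite directions, which makes the pooled
  (no-separation) model genuinely harder, as in the real ablation;
* experimental observations $\mathrm{p}K_a = \mathrm{sol} + s +
  \mathcal{N}(0, \sigma^2)$ with $\sigma = 0.3$ by default (the order of
  inter-laboratory reproducibility of titration measurements), and teacher
  labels with $\sigma_t = 0.7$ (the error scale of a prior structure-based
  predictor) over a larger, disjoint protein pool;
* optional layer structure: the signal can be planted in a subset of
  layers, with all other layers pure noise, which gives the layer sweep a
  known argmin.

The embedding noise (0.1) is deliberately smaller than the observation
noise: the representation is treated as informative, measurement as the
dominant error source, giving a predictable noise floor of
$\sqrt{\sigma^2 + \tau^2} \approx 0.32$ at $\sigma = 0.3$ that the
end-to-end tests check against the band $[\sigma, 1.2\sigma]$.

All draws are purpose-keyed: sequences, latent shifts, site sampling and
each noise source use separate streams derived from the master seed, so
changing the noise level never moves site placement, and paired ablations
stay paired.

What the generator does **not** emulate: real embeddings are not one
planted direction plus noise — they encode residue identity, secondary
structure and much else, and their information is spread across thousands
of correlated coordinates. In particular, a real pooled model can infer the
channel from the embedding itself, so channel separation helps less on real
data than in this construction. Passing the synthetic tests therefore
demonstrates that the machinery (routing, training stages, splits, metrics,
uncertainty) is correct and that the estimator reaches the designed noise
floor — not that any particular accuracy will be reached on experimental
data.

## Numerical choices

* **Regressors.** Default architecture: two hidden layers (256, 64) with
  rectified-linear activations, suited to small-n tabular regression on
  wide (d ≈ 1280) embedding features; fully configurable, and the tests use
  (32, 16) or (16, 8) at their smaller widths. Optimizer: Adam
  (`lr = 1e-3`, batch 128, weight decay 1e-4 on weights only), minibatch
  order reshuffled every epoch from the member's seed.
* **Early stopping** on a 10% validation split (patience 20) guards both
  from-scratch training and fine-tuning against overfitting; it is also why
  fine-tuning on data from the pretraining distribution does not degrade a
  pretrained model.
* **Determinism.** All randomness (initialization, shuffles, splits,
  bootstrap) is drawn from R's RNG under seeds derived from the caller's
  seed; the C++ training loop is a deterministic function of its inputs, so
  train + predict is bit-for-bit reproducible on one platform.
* **Degenerate inputs.** Training requires at least two rows; a non-finite
  loss aborts with the offending epoch; a single hold-out split reports
  `NA` standard errors; histogram modes use bins anchored at zero with ties
  resolved toward the lowest bin; exact class-boundary pKa values classify
  as titrating (closed interval).
* **Problem sizes.** The test suite and the end-to-end checks run at desk
  scale, chosen as the smallest sizes at which each property is stable:
  2,000 sites / 10 members / 3 splits for the noise-floor check, 100
  fine-tune sites against a 6,000-site teacher corpus over 5 paired seeds
  for the transfer ablation, 150 proteins for the 3-layer sweep.

## Known limitations

* Coupled titration, tautomers (HID/HIE) and pH-dependent conformational
  change are out of scope; sites are treated as independent
  Henderson-Hasselbalch groups.
* Sequences at or above the backend maximum length (default 1022) are
  rejected, not windowed: windowing semantics for relative position are
  unspecified and silently truncated embeddings would misalign sites.
* Real protein-language-model adapters are thin plug-ins behind the backend
  contract (`new_pka_backend()`, `register_backend()`); the package does not
  ship or fine-tune any transformer weights.
* The production-quality accuracy of the approach on experimental databases
  depends on the embedding backend and cannot be established from the
  synthetic generator (see above).
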