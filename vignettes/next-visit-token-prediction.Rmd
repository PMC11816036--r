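---
title: "Next-visit token prediction for disease-onset risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Next-visit token prediction for disease-onset risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the reformulation

Disease-onset prediction from coded patient trajectories is conventionally a
binary classification task: encode the patient's visit history, pool it into
one vector, and attach a logistic head. When the encoder is a BERT-style
foundation model pretrained with a masked-code objective, that head is an
arbitrary new layer with no connection to what pretraining learned, and with
tens of labeled patients it must be learned from scratch.

This package implements the alternative: express onset prediction *in the
vocabulary of the pretraining task*. The outcome "will this patient develop
pancreatic cancer" is re-written as "will any of the eight pancreatic-cancer
diagnosis codes (C25.0-C25.4, C25.7-C25.9) appear in a future visit". Those
eight codes are tokens the encoder already has embeddings for, so their
embedding rows — the *label tensor* `L` of shape `[8, d]` — can act as a
verbalizer: futures are scored by dot product instead of by a fresh layer.

Three interchangeable heads share one encoder:

* **BC** (binary classification): `score = sigmoid(w . c + b)` on the pooled
  patient context vector `c` (the masked *sum* of contextualized position
  embeddings). The conventional head; `w, b` are new parameters.
* **Sum** (token prediction): `p = sigmoid(L c)`, eight probabilities, one
  per target code; the patient score is `max(p)`. No new parameters.
* **Mask** (next-visit masked-token prediction): a `[MASK]` token is
  appended at visit ordinal `i + 1` (the first future visit) and the
  contextual vector `h` at that position is scored as `p = sigmoid(L h)`,
  patient score `max(p)`. This makes fine-tuning literally a masked-code
  prediction problem — the same task pretraining optimized.

The formal link is exact, not rhetorical: with the tied output projection
and no bias, the mask head's eight logits equal the restriction of the
full-vocabulary masked-code scores at the mask position to the eight target
ids. The test suite asserts this equality to floating-point precision; it
is the package's central oracle.

## Encoder

A small BERT-style transformer: input representation = token embedding +
visit embedding (indexed by source-visit ordinal; the appended mask uses
ordinal last + 1), post-norm transformer layers with GELU feed-forward,
masked self-attention in which PAD positions neither attend nor are
attended to, and exact sum pooling over non-PAD positions. No additional
positional embedding is used beyond the visit ordinal: within-visit order
is clinically arbitrary, and the visit ordinal is the temporal signal the
data model defines. Defaults are desk-scale — `d = 32`, 2 layers, 2 heads,
feed-forward 64, sequence length 64 — chosen so that the full protocol
(pretraining plus a trimmed learning-curve ladder) runs in minutes on one
CPU; the architecture is dimension-agnostic.

Sequences are truncated to the most recent 64 codes (reverse-chronological
*retention*), then presented chronologically; visit-ordinal embeddings
require temporal order, and retention-of-the-recent is what a fixed-length
window over a trajectory means clinically. When the mask head is in use,
one of the 64 slots is reserved for the `[MASK]` token (effective history
63 codes) so tensor shapes stay uniform across heads. Unknown codes are a
hard error rather than an UNK token: the setting is closed-vocabulary by
construction, and silently mapping new codes to UNK would break the
token-reuse premise. The backward pass is hand-written and verified against
central finite differences in the tests.

## Masked-code pretraining

Pretraining follows the BERT recipe on code sequences: each real position
is selected with probability 0.15; a selected code is replaced by `[MASK]`
with probability 0.80, by a random ordinary code with probability 0.10,
and kept with probability 0.10. Loss is cross-entropy at selected
positions only, with the token-embedding table as the tied output
projection — tying is what makes embedding rows double as label scorers
downstream. Optimization is Adam at 0.001, batch 100, up to 30 epochs with
early stopping (patience 5) on a 10% held-out patient split whose
corruption draw is fixed so epochs are comparable; at these data sizes the
held-out loss typically improves throughout, so the epoch cap, not the
patience, usually ends training.

Two protocol points deserve emphasis:

* **Pretraining sees full trajectories.** Prediction-task inputs are
  censored (no target code at or before the index visit — a hard contract
  the codec enforces), but pretraining encodes complete trajectories
  including onset visits. Pretraining here plays the role of
  general-population pretraining, where future disease codes are observed;
  censoring the pretraining data would mean target-code embeddings are
  never trained at all and the verbalizer would be random noise.
* **Pretrain on the training split only.** Pretraining the encoder on
  patients later used for testing leaks label information: an onset visit
  seen during pretraining lets the encoder associate that patient's code
  profile with target codes, measurably inflating test-set discrimination
  at this scale. The package's workflows therefore pretrain on the
  training split and evaluate on patients the pretraining never saw.

## What the learned geometry actually looks like

A natural expectation is that pretraining pulls target-code embeddings
toward precursor-code embeddings. That is *not* what happens under a
softmax output: rare tokens are repelled from contexts where they are
usually the wrong answer, so the raw target-precursor cosine actually ends
slightly below the target-versus-random cosine. What pretraining reliably
produces instead — and what the heads exploit — is:

* the eight target embeddings become nearly parallel to one another,
  with a mean pairwise cosine far above the near-zero background
  similarity of ordinary codes, forming an effective "future onset"
  direction;
* precursor embeddings tend to cluster with each other, since they share
  contexts; and
* the *contextual* vector at the next-visit mask position aligns with the
  target direction precisely for precursor-heavy histories, giving the
  untuned mask head a zero-shot AUROC well above chance on patients
  pretraining never saw, while the untuned sum head starts near 0.5.

The acceptance-level tests assert the target-embedding clustering and the
zero-shot discrimination directly, rather than the naive cosine story.

## Fine-tuning loss for the token heads

The task formulation defines only the score, not the fine-tuning loss for
the Sum/Mask heads; both implemented policies are interpretations:

* `"max"` (default): binary cross-entropy of the max-probability patient
  score against the case label — the quantity evaluation uses.
* `"per_token"`: mean binary cross-entropy of the eight per-token
  probabilities against the multi-hot onset-code target.

Per-token supervision sounds richer, but under single-onset labels it
penalizes the seven non-onset target codes — whose embeddings pretraining
made nearly parallel to the onset code — and thereby erodes the shared
onset direction the max score depends on. In design experiments the
per-token policy's validation AUROC decayed monotonically from the first
epoch, so early stopping could do no better than return the zero-shot
model, while the max policy trained the mask head to a clear improvement
over its zero-shot start. Hence `"max"` is the default; `"per_token"`
remains available.
The label tensor stays tied to the embedding table during fine-tuning by
default (`label_trainable = TRUE`); freezing it preserves the pretraining
geometry exactly and is available as a flag.

## The synthetic cohort generator

Real pretraining corpora and disease cohorts are proprietary, so the
package ships a generator whose point is to make the head comparison
*testable*, not to imitate any specific health system:

* patients are ordered visits (4-12 by default) of 2-8 codes from a
  vocabulary of 200 ordinary codes (`D###`/`M###`/`P###`, mimicking the
  diagnosis/medication/procedure mix) plus the 8 reserved target codes;
* each patient draws a latent precursor propensity `pi ~ Beta(1, 9)`
  (mean share 0.1) and every code is a uniformly chosen precursor code
  (20 of the 200) with probability `pi`, otherwise a uniformly chosen
  other code. The latent propensity is what creates *comorbidity
  clustering* — precursor codes co-occurring within high-burden patients.
  Without it (uniform draws) the sequences carry almost no mutual
  information between codes and masked-code pretraining has nothing to
  learn, which we verified directly at design time;
* onset risk is logistic in the realized precursor count:
  `logit P(case) = b0 + 0.5 * count`, with `b0` calibrated by root
  finding so the expected case fraction is 0.4 (a roughly 2:3
  case-control mix, typical of matched onset cohorts); the 0.5
  log-odds-per-code effect puts the achievable AUROC around 0.8, a
  realistic regime for coded-trajectory onset prediction;
* cases receive exactly one uniformly chosen target code in a dedicated
  final onset visit, which is excluded from prediction inputs
  (`index_visit` points at the preceding visit), so inputs are always
  censored and `onset_target_code` supplies multi-token supervision.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: realistic code-frequency skew and
ontology structure, visit timestamps and billing lag, demographic
confounding, label noise from low diagnostic sensitivity, and class
imbalance at population prevalence. One structural consequence matters for
interpreting baselines: because the generative risk is exactly logistic in
a bag-of-codes count, the logistic-regression baseline is correctly
specified here and is a much stronger comparator than it is on real
trajectories, where risk is not a linear function of code counts.

## Experimental protocol

* **Split**: 7:1:2 at patient level; validation and test sizes are
  floored, training takes the remainder — the unique rule reproducing the
  printed cohort arithmetic (31,243 to 21,871/3,124/6,248 and 3,810 to
  2,667/381/762). No stratification; one shuffle per seed.
* **Few-shot sampling**: balanced case/control draws for both fine-tuning
  and validation at sizes up to 1000 (size 10 means 5 cases + 5
  controls); balanced fine-tuning with the full validation split above
  1000; and a size-keyed ladder of five regimes for small external-style
  cohorts. All draws are without replacement and seeded.
* **Learning curve**: every (model, size, run) cell fine-tunes from the
  same pretrained checkpoint (baselines train from scratch), evaluates on
  the complete test split, and reports AUROC; 3 runs per cell by default,
  aggregated as mean and standard deviation. The desk-scale ladder is
  [10, 20, 50, 100, 200, 500, 1000].
* **AUROC** is computed by midranks (Mann-Whitney; ties count half) and is
  tested against an O(n^2) pairwise oracle and against an established
  implementation.
* Fine-tuning uses Adam at 0.001 (1e-5 for the bidirectional recurrent
  baselines, following the stated settings), batch 100, at most 50 epochs
  with early stopping on validation AUROC (patience 5).

## Numerical and degenerate-input choices

* Attention logits into PAD positions are set to negative infinity before
  normalization; rows over real positions renormalize over real positions
  only, so appending padding provably leaves real outputs unchanged (a
  tested invariant). An all-PAD row yields zero attention output and is
  rejected by pooling.
* Sum pooling is an exact masked sum — no averaging — so the context
  vector scales with history length; that is the defined pooled
  representation, and PAD exclusion keeps it independent of padding.
* Binary cross-entropy clips probabilities at 1e-12; softmax subtracts the
  row maximum; the restriction oracle is kept exact by using no bias on
  the Sum/Mask logits (a bias flag exists for the full-vocabulary
  pretraining head only).
* Ties in the max-probability reduction resolve to the first index; the
  patient score is invariant to label-row permutation (tested).
* A patient with zero retained codes, a target code inside a censored
  window, an unknown code, a visit ordinal beyond the embedding table, or
  a single-class training set each raise an immediate, specific error.

## Desk-scale problem sizes

The shipped defaults are sized for a laptop CPU: cohorts of 2,000
patients, a `d = 32` two-layer encoder, pretraining for up to 30 epochs
(a few minutes), and learning-curve cells that fine-tune in seconds. The
acceptance workflow in `scripts/acceptance.R` and the behavioral test
suite use these sizes. Nothing in the implementation depends on them;
larger cohorts and encoders only cost time.

## Known limitations

* The generator's signal is a single scalar (precursor count) routed
  through one mechanism; real trajectories carry temporal and
  combinatorial signals the comparison here cannot exercise.
* Because bag-of-codes logistic regression is correctly specified for the
  generator, "pretrained heads versus baselines" contrasts are
  conservative here: the interesting margins are against the recurrent
  baselines and between the heads themselves.
* Clinical foundation models of this family typically add a second,
  non-MLM pretraining objective; the encoder here pretrains with the
  masked-code objective only.
* Checkpoints embed their configuration and seed but are R serializations,
  not a cross-language format.
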