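---
title: "Detecting AVG stenosis from bruits: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting AVG stenosis from bruits: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hemodialysis requires a vascular access — here an arteriovenous graft (AVG) —
that is punctured several times a week and fails most often by stenosis from
neointimal hyperplasia. A stenosed access produces turbulent flow whose sound
(the *bruit*) changes character; experienced staff can hear it. `bruitlearn`
implements a screening pipeline that learns this discrimination from
recordings of the bruit: weak labels derived from intervention timelines, a
log-mel spectrogram front end, a convolutional classifier, and contrastive
pre-training that exploits the fact that most recordings in a monitoring
program are unlabeled.

Because no clinical audio ships with the package, a seeded simulator
generates corpora with the same statistical shape, so every stage — and every
claim the test suite makes — is checkable offline.

## Weak labeling from PTA timelines

Percutaneous transluminal angioplasty (PTA) reopens a stenosed access, so an
intervention date is an objective anchor: shortly *before* a PTA the access
was stenosed (abnormal bruit), shortly *after* it was patent (normal bruit).
`assign_labels()` implements exactly this:

* abnormal iff some event of the same patient satisfies
  `0 <= event_date - timestamp <= pre_window_days`;
* normal iff `post_start_days <= timestamp - event_date <=
  post_start_days + post_window_days`;
* otherwise unlabeled. If two close interventions make both windows match,
  abnormal wins (for a screening tool the conservative error is the false
  alarm, not the missed stenosis) and a warning is raised.

Defaults: `pre_window_days = 7` (one weekly visit), `post_start_days = 4`
(the access needs a few days to settle after ballooning), and
`post_window_days = 21`. The last default is the one genuinely open choice:
with a weekly recording cadence a 21-day window captures about three
post-PTA visits per intervention, which reproduces the roughly 3:1
normal:abnormal ratio seen in weekly-monitored cohorts; a 10-day reading
(about one visit) is equally defensible clinically and available through
`label_policy()`. Labels never see the simulator's ground truth.

## The synthetic bruit model

`generate_recording()` builds each recording as

1. a **base pulse**: a 90 Hz tone under a Gaussian systolic envelope
   repeating at `heart_rate` (default 1.2 Hz, 72 bpm) — all of its energy
   sits far below 200 Hz;
2. a **murmur**: Gaussian noise band-limited to `murmur_band` (default
   300–800 Hz), amplitude-modulated by the same cardiac envelope, with linear
   gain `murmur_gain` (default 0.15) when stenotic and
   `patent_murmur_frac * murmur_gain` (default 0.25×) when patent — a healthy
   access still has a soft bruit;
3. white sensor noise (`noise_sd`, default 0.05);
4. log-normal gain jitter per patient (sd 0.15) and per recording (sd 0.2),
   standing in for anatomy and probe placement;
5. peak normalization to at most 0.9 full scale (never upward, so the
   zero-noise configuration remains exactly the analytic pulse).

The clinical literature motivates the *direction* of this contrast —
stenosis shifts bruit energy toward higher frequencies — but no published
acoustic model exists for AVG bruits, so the model above is deliberately the
simplest construction with that property, and every parameter is exposed in
`synth_config()`. The default sample rate is 4 kHz: bruit energy lives below
1 kHz, and desk-scale tests do not benefit from more bandwidth (rates up to
32 kHz are supported for compatibility with full-scale audio checkpoints).

`generate_corpus()` arranges per-patient weekly timelines: 45 patients × 15
weeks by default; a patient drawn into a stenosis episode (probability 0.6)
sounds stenotic for 1–3 weeks, receives a PTA dated 2 days after the last
stenotic visit, and reverts to patent. Under the default policy this yields
approximately the 85 normal / 26 abnormal / ~560 unlabeled split of a
45-patient weekly cohort. The whole corpus is a pure function of the config,
including its seed.

**What the simulator does not model:** venous- vs arterial-side differences,
hemodynamic realism (no CFD), inter-device coloration, background clinic
noise with structure (speech, alarms), or gradual stenosis progression
within a week. Consequently, passing tests demonstrate that the pipeline's
machinery is correct and that pre-training helps *on a task of this shape*;
they say nothing quantitative about clinical accuracy.

## Front end

`melspec()` frames the signal with a Hann window (default 64 ms) at hop
10 ms, zero-padding the final frames, for exactly `floor(n_samples / hop)`
frames — so a 10-s clip at the default 100 frames/s is the canonical
1000 × 64 input and shifting the input by one hop shifts frames by exactly
one. Power spectra pass through 64 HTK-style triangular mel filters
(`2595 log10(1 + f/700)`, unit peak) between `fmin = 20` Hz and Nyquist, then
`10 log10` with a −100 dB floor. Silence maps to the floor everywhere;
scaling a waveform by 10 adds exactly 20 dB to unfloored cells. The mel bin
count (64) is the one fixed contract with the model; frame count is free
because the network pools globally over time–frequency.

Augmentation happens in the audio domain only (random 5-s crops of the
middle-20-s segment); there is no spectrogram-domain masking.

## The classifier

The backbone is the 14-layer audio CNN: six blocks of two
(3×3 conv → batch-norm → ReLU) layers with widths 64–2048, 2×2 max pooling
after blocks 1–5, global pooling, a 2048-unit ReLU embedding and a 2-unit
sigmoid head (class 2 = abnormal; the abnormal sigmoid is the ROC score;
argmax predicts, with ties resolved to normal). Design points the
architecture table leaves open, and how they were fixed:

* **Global pooling** is the sum of the global mean and the global max over
  the remaining time–frequency extent — the standard audio-CNN compromise
  between robustness (mean) and peak sensitivity (max).
* **Two independent sigmoids** with one-hot binary cross-entropy, rather
  than a softmax: this follows the head the architecture specifies and keeps
  the abnormal score usable as an independent alarm threshold.
* **Projection head**: during contrastive pre-training an optional
  SimCLR-style head (2048 → 512 → 128 before width scaling) is attached and
  discarded afterwards. Contrasting on a projection rather than on the
  embedding itself usually preserves more classification-relevant
  information in the embedding; both paths are implemented
  (`projection_head = FALSE` contrasts on the embedding directly).
* **Width scaling**: `width_scale` divides every width, shrinking conv
  parameters by about its square while preserving the layer structure, so
  desk-scale experiments exercise the identical architecture.

The engine (forward, batch-norm, pooling, analytic gradients, InfoNCE) is
implemented in RcppArmadillo; gradients are verified against finite
differences in the test suite. Batch norm uses batch statistics during
training (momentum 0.1 running updates, ε = 1e-5) and running statistics in
eval mode, which makes inference deterministic and independent of batch
composition. Log-mel inputs are affinely rescaled by (x + 60)/20 before the
first convolution so activations start O(1).

## Contrastive pre-training

Each unlabeled recording contributes two random 5-s crops per epoch — a
positive pair; crops of different recordings are negatives. With 2N
L2-normalized projections `z` and temperature τ, the pair loss is

$$\ell(i,j) = -\log \frac{\exp(\mathrm{sim}(z_i, z_j)/\tau)}
{\sum_{k \ne i} \exp(\mathrm{sim}(z_i, z_k)/\tau)},
\qquad
L = \frac{1}{2N} \sum_{k=1}^{N} \big[\ell(2k{-}1, 2k) + \ell(2k, 2k{-}1)\big],$$

with `sim` the cosine. Numerical and protocol choices:

* embeddings are L2-normalized before similarity, making `sim` exactly the
  cosine; the softmax uses log-sum-exp stabilization;
* τ defaults to 0.5 (a standard mid-range value for normalized embeddings;
  it is logged and exposed);
* the last incomplete minibatch is dropped — the loss assumes exactly N
  pairs;
* crops are taken from the middle-20-s segment, not the raw minute,
  consistent with the handling-noise rationale for the middle extraction;
* a checkpoint (with running loss) is written every `checkpoint_every`
  epochs; since nothing in the protocol says which checkpoint to fine-tune,
  the package holds out 10% of the unlabeled recordings and selects the
  checkpoint with the lowest validation InfoNCE loss.

Closed forms used as oracles: L = 0 at N = 1; L = log(2N−1) when all
embeddings coincide; the N = 2 orthogonal-pairs value log(1 + 2/e).

## Training arms and evaluation

Three initializations are compared under identical fine-tuning: random
(scratch), an externally supplied full-scale checkpoint (loaded through a
documented key mapping; the classification head is never imported), and the
contrastive checkpoint. Supervised training uses the middle-20-s
spectrograms with no augmentation, Adam at 1e-4, batch 16, for 40 epochs
from scratch or 20 from any checkpoint.

Evaluation is stratified 5-fold cross-validation (per-fold class proportions
within one recording of the global proportion); each held-out recording is
scored individually. The per-fold "leave-one-out testing" reading — retrain
once per held-out recording — was considered and rejected: with a
deterministic eval-mode network both readings give identical scores at ~100×
the cost. Pooled counts give accuracy, precision, recall, F1 (abnormal =
positive); AUC is the trapezoidal ROC integral, which the tests verify
equals Mann–Whitney pair counting with half credit for ties. Arms are
compared by an exact McNemar test on paired per-recording correctness (the
protocol names no test; McNemar is the standard choice for paired binary
outcomes on a shared test set). Reported values render at 4 decimals,
half-up.

`reconstruct_confusion()` closes the loop on published tables: given a
printed (accuracy, precision, recall) row and the class sizes, it
exhaustively searches integer confusion matrices whose metrics render to the
printed values (half-up or truncated at 4 decimals). On a 111-recording test
set the counts are usually unique, making printed rows auditable; a row no
integer matrix can produce is flagged as inconsistent rather than resolved —
the bundled reference rows contain exactly one such row, which the audit
surfaces.

## Desk-scale problem sizes

The package's experiments run on one CPU, so `desk_profile()` fixes a
scaled-down configuration used by the test suite and the acceptance script:
30 patients × 15 weeks (about 60 labeled and 390 unlabeled recordings),
4 kHz audio, mel frames at 25/s (a 20-s segment is 500 × 64), CNN14 at width
1/16, pre-training for 6 epochs (checkpoints every 3), and supervised epochs
12 from scratch / 6 from a checkpoint — the full-scale 40/20 protocol scaled
down with its 2:1 ratio preserved.

One desk parameter deliberately departs from the full-scale values:
pre-training uses minibatches of 32 recordings at lr 1e-3 (instead of 64 at
1e-4). The full-scale protocol performs on the order of a thousand optimizer
steps over 200 epochs; a 6-epoch desk run at the original batch size and
learning rate performs ~30 steps and leaves the InfoNCE loss at its
no-information baseline log(2N−1) — the arm under test would simply not be
pre-trained. Halving the batch doubles the steps per epoch at the same cost,
and the larger learning rate compensates for the ~50× shorter schedule; the
pre-training loss trace (logged per epoch) descending well below the
baseline is the check that the mechanism is actually operating.

These sizes were chosen once, as the smallest configuration that still
exercises every stage of the full protocol end to end; the benchmark asserts
only the *direction* of the comparison (contrastive ≥ scratch in median over
three seeds), never the full-scale magnitudes, which derive from private
clinical data and are out of reach of any synthetic reconstruction.

## Known limitations

* The acoustic model is generative shorthand, not physiology; transfer of
  the benchmark's ordering to clinical audio is an assumption, not a result.
* Weak labels inherit the window subjectivity: both the pre-PTA window
  length and the normal-window reading are conventions, exposed as policy.
* The desk profile's short training schedules favor initialization quality
  by construction; that is the property under test, but it means desk
  accuracies should not be quoted as the pipeline's performance.
* Checkpoint selection by validation InfoNCE loss is a proxy; selecting by
  downstream validation accuracy would require labeled data the pre-training
  stage is assumed not to have.
* Single-channel audio only; arterial- vs venous-side fusion is out of
  scope.
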