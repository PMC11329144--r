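# bruitlearn

Detecting arteriovenous graft (AVG) stenosis from blood-flow sounds.

Hemodialysis patients depend on a patent vascular access; stenosis from
neointimal hyperplasia is its dominant failure mode and is audible as a
change in the *bruit* — the sound of turbulent flow through the access.
`bruitlearn` is for researchers and engineers building acoustic screening
tools for dialysis monitoring: it implements the complete pipeline from raw
WAV recordings to a cross-validated classifier comparison, plus a seeded
synthetic bruit simulator so everything runs and is testable without
clinical audio.

## What it computes

**Weak labels from intervention timelines.** A percutaneous transluminal
angioplasty (PTA) reopens a stenosed access, so intervention dates anchor
objective labels: a recording within `pre_window_days` (default 7) before a
PTA of the same patient is *abnormal*; one between `post_start_days`
(default 4) and `post_start_days + post_window_days` (default 4 + 21) days
after it is *normal*; everything else is *unlabeled* — in a weekly
monitoring program, the vast majority.

**A CNN14 classifier on log-mel spectrograms.** Recordings keep only their
middle 20 s (the edges carry handling noise), become frames × 64 log-mel
matrices, and pass through the 14-layer audio CNN: six blocks of two
(3×3 conv → batch-norm → ReLU) layers with widths 64–2048, 2×2 max-pooling
between blocks, global (mean + max) pooling, a 2048-unit embedding and a
2-unit sigmoid head. `width_scale` shrinks every width for desk-scale work.

**Contrastive pre-training on the unlabeled majority.** Two random 5-s
crops of the same recording form a positive pair; crops of different
recordings are negatives. With 2N L2-normalized embeddings *z* and
temperature τ,

    l(i, j) = -log[ exp(sim(z_i, z_j)/τ) / Σ_{k≠i} exp(sim(z_i, z_k)/τ) ]
    L = (1/2N) Σ_k [ l(2k-1, 2k) + l(2k, 2k-1) ],    sim(u, v) = u'v / (||u|| ||v||)

is minimized by Adam; the resulting weights initialize supervised
fine-tuning. Closed forms (L = 0 at N = 1, L = log(2N−1) for identical
embeddings) serve as test oracles.

**Evaluation.** Stratified 5-fold cross-validation, pooled confusion matrix
(abnormal = positive), accuracy / precision / recall / F1, trapezoidal
ROC–AUC (equal to Mann–Whitney pair counting), and an exact McNemar test
between training arms. `reconstruct_confusion()` additionally inverts
*printed* metric rows into the unique integer confusion matrix behind them,
turning published tables into auditable objects.

## Worked example

Simulate a desk-scale monitoring cohort, then compare training from scratch
against contrastive pre-training under 5-fold cross-validation:

```r
library(bruitlearn)

prof <- desk_profile(seed = 1)       # 30 patients x 15 weekly recordings
corp <- generate_corpus(prof$synth, "corpus")
ex <- run_experiment(corp$records, corp$events,
                     arms = c("scratch", "contrastive"), profile = prof)
print(ex)
```

```
Cross-validated bruit classification (5-fold)
Arm                    Accuracy Precision   Recall       F1      AUC
scratch                  0.9107    1.0000   0.6429   0.7826   0.9728
contrastive              0.9643    0.8750   1.0000   0.9333   1.0000
McNemar scratch vs contrastive: p = 0.4531
```

This corpus has 56 labeled recordings (14 abnormal). Both arms fine-tune
identically, but the contrastive arm starts from weights pre-trained with
InfoNCE on the ~390 unlabeled recordings and recovers all 14 stenotic
recordings (recall 1.0000) where the scratch arm misses five — the
initialization, not the labeled data, makes the difference. With 56 paired
recordings the McNemar test is underpowered (p = 0.45); the package asserts
the *direction* of the comparison across seeds, not significance at desk
scale.

Auditing printed metric rows works from the rounded values alone:

```r
audit_reference_metrics()
```

```
      method TP FP FN TN f1_implied consistent unique
     scratch 17  6  9 79     0.6939       TRUE   TRUE
       panns 18  4  8 81     0.7500       TRUE   TRUE
 contrastive NA NA NA NA         NA      FALSE     NA
      human1 22 28  4 57     0.5789       TRUE   TRUE
      human2 18 16  8 69     0.6000       TRUE   TRUE
flagged inconsistent row(s): contrastive (printed metrics match no integer confusion matrix)
```

Each consistent row's printed accuracy/precision/recall pins down exactly
one integer confusion matrix on the 85 + 26 test split, and the F1 implied
by those counts reproduces the printed F1; the flagged row's printed
metrics cannot arise from any integer counts — a rounding defect the audit
surfaces instead of resolving.

A command-line entry point wraps the same stages
(`inst/exec/bruitlearn simulate|label|features|pretrain|train|evaluate|audit-reference`).

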