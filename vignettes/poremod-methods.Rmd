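---
title: "Detecting RNA modifications from nanopore signal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RNA modifications from nanopore signal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(poremod)
```

## The problem

Direct RNA sequencing (DRS) reads native RNA strands through a nanopore, so
modified bases — N6-methyladenosine (m6A), 5-methylcytosine (m5C),
pseudouridine and others — are still present when the molecule translocates.
A modified base perturbs the ionic current: typically the mean and median
current level of the affected 5-mer shift, the signal spread and the dwell
time (number of raw samples spent on the base) change in a
modification-specific direction, and the basecall quality drops. `poremod`
turns these perturbations into per-read, per-site modification calls.

The package deliberately starts *after* basecalling and resquiggling: its
input is an event table with one row per aligned reference base of each read,
carrying the raw current samples assigned to that base plus the basecall
quality. Producing such tables from raw signal files is an upstream concern;
a documented TSV dialect keeps the boundary explicit and testable. Positions
are 0-based internally; all user-facing prediction and site tables are
written 1-based.

## From events to model instances

**Normalization.** Current levels drift between molecules and devices, so
every read is normalized as a whole (all events concatenated) before any
window is cut. The default is median/MAD ("MMAD"): subtract the read median
and divide by the plain median absolute deviation — deliberately without the
1.4826 normal-consistency factor, since the scale is arbitrary anyway.
Min-max and z-score normalization are available for comparison; MMAD is
the default because it is robust against the heavy tails that modified bases
themselves introduce. A read with zero MAD (constant signal) is degenerate
and rejected; a read containing any non-finite sample is skipped.
Normalizing the whole read first (rather than per event) is a deliberate
choice: per-event scales would erase exactly the level shifts the classifier
must see.

**Resampling.** Dwell varies per base, so each event's samples are resampled
to a fixed length l = 100 by first-order (linear) spline interpolation: the k
samples are placed at equally spaced knots of an interval, and the
interpolant is evaluated at 100 equally spaced points including both
endpoints, so the first and last raw values are preserved exactly.
Single-sample events are duplicated to k = 2 rather than rejected, because
real resquiggles do emit them. The resampler is checked in the test suite
against an independent brute-force piecewise-linear oracle to 1e-9.

**Per-base statistics.** Each event additionally contributes its mean,
standard deviation (population convention, divisor n — fixed for test
determinism), median, dwell and basecall quality, plus the integer-encoded
reference base (A=0, C=1, G=2, U=3).

**Window assembly.** One model instance is built per interior base with two
aligned flanking bases on each side, provided the read's aligned positions
are contiguous across the window and the 5-mer fits inside the transcript.
The instance holds 5 × 100 = 500 resampled current values (bases ordered
5'→3') and 5 × 6 = 30 base-level values. Scaling into the base vector: base
code / 3, quality / 40, dwell capped at 200 samples and divided by the cap;
mean/std/median stay on the normalized signal scale. The documentation of
the upstream feature design is ambiguous between 25 and 30 base-level
values; this package commits to 30, treating the encoded base as a sixth
per-base value, which lets the classifier learn sequence-context-specific
baselines.

An optional read-length filter (default cutoff 600 aligned bases, off unless
requested) reflects that classification accuracy degrades on short reads
whose signal quality is poor at both ends.

## The classifier

The model is a two-branch network.

* **Current branch** — the 500-value signal passes through stacked 1D
  convolutions (ReLU, non-overlapping max pooling after each stage), a
  bidirectional LSTM over the pooled sequence, and an additive
  (Bahdanau-style) attention unit whose context vector summarizes the time
  steps. The context vector *replaces* the final LSTM state rather than
  being concatenated to it; the attention weights let the model emphasize
  the time steps where the modification distorts the squiggle.
* **Base branch** — a bidirectional LSTM over the 5 bases' 6 features (final
  hidden states of both directions). Internally the scalar base code is
  expanded to a one-hot vector before entering the LSTM; this is purely a
  model-side encoding (the instance format is unchanged) and makes the
  sequence-context correction much easier to learn than from a single
  ordinal value.

The concatenated representations feed a fully connected stack with dropout,
ending in 2 logits (unmodified / modified). Softmax converts logits to
probabilities; training minimizes class-weighted cross-entropy
(weight-normalized mean of `-w[y] log p[y]`) with Adam at learning rate
0.001. Class imbalance is handled by a weighted random sampler: every
instance gets weight 1 / (count of its class) and each epoch draws with
replacement, so minibatches are balanced in expectation regardless of the
raw class ratio.

Labeled instances are split 4:1 into training and validation; after every
epoch the validation ROC-AUC is computed, and training stops after
`early_stop_patience` epochs without improvement, returning the best
checkpoint. Given identical data, spec and config, training is bit-for-bit
reproducible (all randomness flows from the config seed).

**Default sizes.** Convolutions [16, 32] with kernel 3 and pool 5 (500 → 20
time steps), current LSTM 32 per direction, base LSTM 24 per direction,
attention dimension 16, classifier [96, 2], dropout 0.3, batch size 64
(~29k parameters). These defaults are sized so the bundled simulation
studies — thousands of instances, not the hundreds of thousands a production
run would use — train in minutes on a single CPU core in interpreted R; every
width is exposed in `model_spec()` for larger data. The whole network,
including backpropagation and Adam, is implemented in base R with
BLAS-backed matrix operations; gradients of every block are verified against
finite differences in the test suite, and the loss against an independent
weighted log-softmax oracle.

## Transfer learning

Different modification types distort the signal in related ways, so a model
trained on one type can be reused for another: the feature-extracting layers
(convolutions and pooling, both LSTMs, attention — the default frozen set)
are kept bit-identical and only the fully connected classifier is
re-optimized on the new type's labels. In the bundled study this reaches a
0.90 validation ROC-AUC within one epoch using half the labeled instances
that training from scratch needs, mirroring the data- and time-efficiency
that motivates transfer here. A caveat the simulation makes visible: a
frozen extractor only transfers well to windows it has seen the like of.
Transfer between two modifications of the *same* center base works
immediately; transferring to a different center base at this training scale
leaves the extractor out-of-distribution, and would need pretraining data
covering windows of all center bases (as large-scale practice does).

## Read-level and site-level calls

`predict_reads()` emits one probability per instance. Two composable filters
control false positives:

1. **Paired probability cutoff** (`apply_paired_cutoff()`): probabilities
   strictly below `low` are unmodified, strictly above `high` modified, and
   the uncertain middle is discarded. (0.5, 0.5) degenerates to plain
   thresholding. Discarding the middle trades coverage for accuracy; on the
   simulated data the ROC-AUC of the retained reads is consistently at least
   that of all reads.
2. **Site aggregation** (`call_sites()`): per (transcript, position), a read
   counts as modified when its probability is at least 0.95 — deliberately
   conservative versus the generic 0.5 — and the site passes only with
   strictly more than 10 supporting reads and a modification rate of at
   least 0.2. The mixed strict/inclusive boundary semantics ("more than 10",
   "at least 0.2", "at least 0.95", paired cutoffs strict) are fixed and
   tested. A read contributing several instances at one site keeps only its
   highest-probability instance. Sites are keyed per transcript; no isoform
   collapsing is attempted.

The site rate k/n estimates the stoichiometry (fraction of modified
molecules). In the bundled mixture study (stoichiometries 0–1 in steps of
0.2, ~70 sites, 200 reads each) the called rates correlate with truth at
r > 0.9; rates are underestimated at high stoichiometry (the conservative
0.95 threshold misses soft positives), while in the low band the predicted
level tracks the truth closely — the same asymmetry the thresholding logic
predicts.

## Differential modification

For two conditions, each shared site contributes a 2×2 table of (modified,
unmodified) read counts per condition, tested with Fisher's exact test. The
point probability of a table a,b/c,d is hypergeometric,
`choose(a+b, a) choose(c+d, c) / choose(n, a+c)`; the two-sided p sums, in
log space, the point probabilities of all same-margin tables not exceeding
the observed one (relative tolerance 1e-7 for floating-point ties). Writing
the table with disjoint (modified, unmodified) columns, rather than
(total, modified), keeps the margins honest counts of disjoint reads.
Sites with p below 0.05 are flagged, with direction the sign of the rate
change; no multiple-testing correction is applied by default
(Benjamini–Hochberg is available as an option). The implementation is
checked exhaustively against hypergeometric enumeration for all tables with
total at most 30, and against `stats::fisher.test` on random tables.

## Feature importance

To ask which of the five window bases the classifier actually uses, each
base's inputs (its 100 current values and 6 base values) are zeroed in turn
and the instances re-scored; the importance of a base is the accuracy drop
against the unablated baseline. On a reference designed so only the center
base can carry class signal (every candidate site flanked by non-target
bases), the center ablation dominates by a wide margin. Two caveats about
reading the flank deltas as "information": zeroing a hundred contiguous
inputs is a large off-manifold perturbation, so a compact model trained on
small data loses some accuracy for any ablated base; and under per-read
current drift the flank levels serve as legitimate within-window reference
anchors for the center level, so some flank sensitivity is a property of
the inference problem, not a leak. The probe therefore supports ordinal
claims (which base matters most), not calibrated per-base effect sizes.

## The squiggle simulator

All studies run on synthetic data with known truth, generated by
`simulate_reads()`:

* a seeded pore model assigns each of the 1024 5-mers a baseline level
  drawn uniformly from [-2, 2] (arbitrary normalized units);
* per base, dwell is a shifted geometric draw (minimum 2 samples) with mean
  8, and samples are Gaussian around the 5-mer level with sd 0.35;
* a modification adds `mean_shift` to its own base's level, multiplies the
  noise sd and expected dwell by factors, and shifts the basecall quality
  (baseline uniform 12–18 phred, clamped at 1). Because 5-mer windows share
  samples, the shift also propagates into the flanking windows that overlap
  the modified base;
* each read is independently modified with probability equal to the chosen
  stoichiometry; in a modified read *every* occurrence of the target base
  carries the modification (the in-vitro labeling design, where one
  nucleotide species is wholly replaced);
* a per-read offset (sd 0.2) and log-scale jitter (sd 0.05) emulate current
  drift between molecules and devices, making per-read normalization
  genuinely necessary.

Default effect sizes: mean_shift 2.0, sd_factor 1.25, dwell_factor 1.3,
quality_shift -2. The directions follow the documented phenomenology of
common modifications (raised mean/median, altered spread and dwell, lowered
quality); the magnitudes are free parameters of the simulator, chosen once
to make the main study learnable but not trivial, and never adjusted per
experiment. The transfer study's "second modification" uses mean_shift 1.5,
sd_factor 1.15, dwell_factor 1.6, quality_shift -3 on the same center base —
the analogue of transferring between two chemically related cytosine
modifications.

What the simulator does *not* emulate: picoampere-scale realism, pore
translocation kinetics, homopolymer-specific artifacts, basecalling or
alignment errors (mismatches/indels are deliberately out of scope as
features too), isoform structure, or motif-biased modification placement.
Passing the bundled studies therefore demonstrates that the pipeline's
machinery — feature extraction, learning, calling, statistics — recovers
planted signal under controlled conditions; it does not certify accuracy on
any particular real dataset.

## Study conditions and problem sizes

The bundled studies (test suite and `scripts/acceptance.R`) use: a
composition-balanced reference of 4 × 220 bases (~210 usable target sites,
~52 on the transcript used for mixtures; `synthetic_reference()` fixes each
base at one quarter of the transcript so site counts are stable across
seeds); 50 fully modified plus 50 unmodified reads, subsampled to 4,000
labeled windows with the remainder held back as an independent test set;
training for at most 90 epochs with patience 20 for the main model — the
validation ROC-AUC saturates early but site-rate calibration keeps
sharpening, so the main study trains well past AUC convergence (the
label-permuted control and the transfer pair use the default patience 5,
and the transfer run caps at 25 epochs). The label-permuted control is
scored on the held-back windows against their own permuted labels: scoring
it on the selection-validation split would inherit the optimistic bias of
argmax checkpoint selection (the max of ~10 null AUC draws sits near 0.56,
not 0.50). Mixtures run at stoichiometries {0, 0.2, 0.4, 0.6, 0.8, 1} with
200 reads each on one transcript; the false-positive study draws 160
modification-free reads over the full study reference (~210 sites at
coverage ~40) — in-distribution by design, mirroring the modification-free
evaluation a trained caller receives on its own transcript pool; the
ablation study uses a 400-base reference with an isolated target site every
8th position in varied non-target context. These sizes are the package's
scaled-down study design — large enough for the statistical claims being
checked, small enough to run on a laptop core.

## Known limitations

* Training is CPU-bound interpreted R; production-scale corpora (hundreds of
  thousands of instances) call for re-implementing the inner loops in
  compiled code or a tensor library. The algorithms and file formats would
  not change.
* Binary head only: one model per modification type. Multi-class typing in a
  single head is out of scope.
* Site calls are per transcript position; genome liftover and isoform-aware
  aggregation are left to downstream tools.
* The conservative 0.95 read threshold biases site rates downward at high
  stoichiometry; interpret rates comparatively, or lower the threshold when
  calibrated stoichiometry matters more than the false-positive rate.
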