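---
title: "Multi-scale k-mer transformers for RNA modification sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale k-mer transformers for RNA modification sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Post-transcriptional RNA modifications — N1-methyladenosine (m1A),
N6-methyladenosine (m6A) and pseudouridine (Ψ) — are written at specific
transcript positions, and the local sequence context around a candidate
site carries much of the signal that decides whether a site is modified.
`modsite` treats site prediction as binary classification of fixed-width
sequence windows centred on a candidate nucleotide, using a biological
language-model approach: the window is read as a sentence of overlapping
k-mer "words", encoded by a bidirectional transformer, and classified from
a pooled sequence representation.  The package also asks the converse,
interpretability question: which positions in the window did the model
rely on, and do they form motifs?

## Tokenization

A window of length $L$ is converted from RNA to DNA spelling (U→T, so a
DNA-trained vocabulary applies), then split into the $L-k+1$ overlapping
k-mers of a stride-1 sliding window, for scales $k \in \{3,4,5,6\}$.  The
vocabulary at scale $k$ contains all $4^k$ k-mers plus five special
tokens, $4^k + 5$ entries in total.  Token streams are framed
`[CLS] … [SEP]` and padded with `[PAD]`; the `[CLS]` position serves as
the sequence-summary anchor.  We include the `[SEP]` terminator in
single-sequence framing (standard BERT practice; the alternative of
omitting it would only shift one position index).  Special-token ids are
fixed at `[PAD]` = 0, `[UNK]` = 1, `[CLS]` = 2, `[SEP]` = 3, `[MASK]` = 4;
putting padding at id 0 makes the attention mask and the padding pattern
coincide.  Sequences whose framed stream exceeds `max_len` are rejected
rather than silently truncated, because silent truncation would break the
assumption that the candidate site sits at the window centre; an explicit
centre-preserving truncation mode is available.

## Encoder

The encoder is a post-layer-norm BERT stack: per layer, multi-head
self-attention with a residual connection and layer normalization,
followed by a GELU feed-forward block with its own residual and layer
normalization.  Learned token and position embeddings are summed at the
input.  Two presets are provided:

* `full` — 12 layers, 12 heads, hidden width 768, feed-forward 3072,
  up to 512 tokens: the geometry of the DNA language models this design
  follows.  It is built and introspected in the tests but not trained
  there.
* `tiny` — 2 layers, 4 heads, hidden 64, feed-forward 128, up to 64
  tokens: the desk-scale model used for every training experiment in the
  package.  The feed-forward width of 2× hidden (rather than the usual
  4×) halves the dominant matrix products with no measurable loss on the
  package's benchmarks.

All forward and backward passes are written in plain matrix algebra
(BLAS-backed), with manual backpropagation verified against central
finite differences in the unit tests.  Dropout
defaults to 0 in the tiny preset, making forward passes bit-reproducible;
every source of randomness (initialization, fold assignment, batch
shuffling, masking, FGM) flows from explicit integer seeds.

When a scale *pair* `c(k1, k2)` is requested, both streams pass through
one shared-weight encoder (separate token-embedding tables per scale,
shared position table and layers).  Sharing keeps the desk-scale model
trainable and expresses the assumption that the grammar of k-mer context
is scale-coherent; per-scale encoders would double the parameters without
a testable benefit at this scale.  Pooling uses the `[CLS]`
representation by default (a mask-aware mean is available via
`pooling = "mean"`).

## Fusion gate

The two pooled scale representations $h_{kmer1}$, $h_{kmer2}$ are blended
by a learned sigmoid gate

$$F = \sigma(W_1 h_{kmer1} + W_2 h_{kmer2}), \qquad
  h_M = F \odot h_{kmer1} + (1 - F) \odot h_{kmer2},$$

so each component of $h_M$ is a convex combination of the corresponding
scale components.  $W_1, W_2$ are full linear maps producing a vector
gate; a scalar gate (one shared component) is available via
`gate = "scalar"`.  The vector gate strictly generalizes the scalar one
and matches standard gated-fusion practice.  With zero weights
$F \equiv 1/2$ and the gate reduces to plain averaging — the
initialization we use, so training starts from an unbiased blend.

## Classification and FGM adversarial training

A logistic head maps the pooled (or fused) representation to the
probability $p$ of the positive class, trained by binary cross-entropy
$L_{CE} = -y\log p - (1-y)\log(1-p)$ (probabilities clamped to
$[10^{-7}, 1-10^{-7}]$ for numerical stability).

Adversarial fine-tuning follows the fast gradient method: after the clean
forward/backward pass, the gradient $g$ of the loss with respect to the
embedding output (the sequence representation) defines a perturbation of
fixed L2 magnitude $\xi$,

$$r_{adv} = +\,\xi\, g / \lVert g \rVert_2,$$

which is added to the embedding output for a second forward/backward
pass; both passes' gradients are summed for one Adam update.  The
embedding tables themselves are never modified, so no restoration step
can be missed.  Two conventions deserve a note:

* **Sign.**  The descent-sign formula $-\xi g/\lVert g\rVert_2$ sometimes
  seen in print *decreases* the loss and therefore cannot produce
  worst-case perturbations; the method's purpose requires the ascent
  direction, which is our default.  `paper_literal_sign = TRUE` switches
  to the descent sign for comparison.
* **Normalization granularity.**  $g$ is normalized over the whole batch
  tensor (the common FGM-for-text recipe), so $\xi$ is a per-batch
  perturbation budget.

Defaults: $\xi = 0.1$, Adam with learning rate $10^{-3}$, 10 epochs,
batch 32.  These were chosen for from-scratch training of the tiny
preset: the conventional fine-tuning values (learning rate of order
$10^{-4}$, $\xi = 1$) presuppose a pretrained encoder, and with random
(sd 0.02) embeddings they leave the tiny model on the ln 2 loss plateau
within a desk-scale budget, whereas at small $\xi$ FGM acts as the
intended mild regularizer.  The swept values 0.1/0.5/1.0 remain
available through `adversarial_config(xi = )`.

An optional masked-language-model warm-up (`pretrain_mlm()`) implements
the BERT 80/10/10 masking recipe at small scale; genome-scale pretraining
is out of scope, and an import hook (`load_checkpoint()`) accepts
externally trained weights with a matching configuration instead.

## Data policy and evaluation

Training sets whose negative:positive ratio exceeds 10 (worse than 1:10)
are randomly under-sampled to a 1:1 target by default — the balanced
training sets seen in published site-prediction work suggest 1:1 where
sampling occurred; the target is configurable.  Test sets are never
re-balanced: evaluation respects the natural imbalance.  Cross-validation
uses label-stratified five-fold splits (per-class fold sizes differ by at
most one).

Threshold metrics are sensitivity, specificity, accuracy and Matthews
correlation coefficient at a configurable threshold (default 0.5, ties
predicted positive); a zero factor in the MCC denominator yields MCC = 0
by the usual convention, and a rate whose class is absent is reported as
`NA`, never silently 0.  AUC uses the rank-based Mann–Whitney
formulation with half-weight ties — exactly the trapezoidal ROC area,
without a finite threshold grid.  Cross-species evaluation trains one
model per dataset on a stratified training split and scores every
dataset's held-out test split, so diagonal cells never see training
records; single-class test splits are recorded as missing.

## Interpretation

Per-token importance is read from the encoder's attention: by default the
final layer's `[CLS]` row averaged over heads (the softmax weight the
summary anchor assigns to each k-mer token).  Layer/head policies are
configurable and recorded; which component of the original architecture
produced published attention visualizations is generally under-specified,
so the choice is exposed rather than hidden.  Token scores map to
nucleotide positions by coverage averaging — position $i$ receives the
mean score of the k-mers covering it — followed by min–max normalization
to $[0,1]$ (a constant nonzero profile maps to all ones; an all-zero
profile stays zero).  For fusion models the two per-scale position
profiles are averaged after normalization, then re-normalized.

Downstream of the profiles:

* `harvest_motif()` extracts, per sequence, the width-$w$ window with the
  largest summed score (kept when its peak exceeds the sequence's
  $q$-quantile, default 0.75) and stacks the windows into a position
  frequency matrix over `A,C,G,U`.  Motifs are reported in RNA alphabet.
* `export_meme_minimal()` writes the letter-probability matrix in MEME
  minimal format for motif-comparison tools (TOMTOM-compatible); a parser
  supports round-trip checks.
* `substrate_scan()` enumerates wildcard patterns (width 5, up to 2
  wildcards by default) anchored near the candidate site, counts matching
  sequences in the positive and background sets, and scores enrichment by
  a one-sided binomial test of the positive count against an add-one
  smoothed background rate, Bonferroni-corrected across the enumeration.
  Column-compatible lower-ranked patterns are greedily removed.  This is
  an enrichment scan in the spirit of motif-x; the iterative chi-square
  refinement of that tool is deliberately not replicated.

## The synthetic benchmark

`generate_dataset()` plants a wildcard motif (default `U.AAU`, width 5)
near the centre of positive windows: negatives are i.i.d. draws from the
background composition (uniform by default), positives additionally have
the motif's literal bases written at an offset jittered uniformly within
±3 nt of the centre, with probability `plant_prob`.  Wildcard positions
stay background draws and are *not* forced to differ from any consensus —
the simpler null model.  Window length defaults to 41 nt, the most common
window among published site predictors.  Ground truth (planted flag and
0-based start) is written to a sidecar table, never into FASTA headers,
so a model cannot leak it.  `generate_species_family()` builds
pseudo-species that share or differ in their planted motif, emulating
within- versus across-taxonomy conservation of a modification's sequence
determinant.

What the generator does *not* emulate: transcriptome context and base
composition bias, secondary structure, homologous near-duplicate windows,
multiple co-occurring motifs, or label noise.  Passing the planted-motif
experiments therefore shows that the full pipeline — tokenization,
encoder, gate, FGM training, evaluation, attention mapping — can recover
and localize a genuine sequence determinant; it does not certify
performance on real transcriptome data.

## Test-bench problem sizes

The package's experiments use sizes chosen to keep a CPU run short while
leaving the conclusions stable: the planted-motif recovery benchmark uses
200 positives + 200 negatives (five-fold CV, tiny preset, fusion scale
pair [3, 5]), its no-signal null the same geometry with
`plant_prob = 0`; interpretability checks use 120 fresh held-out
positives; the cross-species family uses three pseudo-species of
150 + 150 with a 25% test split.  At these sizes the planted signal is
recovered with CV AUC well above 0.9, the null sits at chance, and
same-motif transfer is clearly separated from different-motif transfer.

Two observations from this bench are worth recording:

* **Scale choice matters for interpretation.**  At k = 3 no single token
  spans the 5-wide wildcard motif, so `[CLS]` attention concentrates on
  the motif's fully literal trigram and harvested windows land a couple
  of nucleotides right of the true start.  At k = 5 (and in the [3, 5]
  fusion) one token covers the whole motif and harvested windows align
  with it almost exactly.  This is why the fusion pair is the package's
  default experimental configuration: the coarser scale localizes, the
  finer scale sharpens.
* **Different-motif transfer is anti-correlated, not independent.**
  Writing a motif into positives shifts their local base composition
  away from another motif's determinant, so a model trained on one
  pseudo-species scores a different-motif species' positives
  systematically *below* its negatives — transfer AUC falls below 0.5
  rather than sitting at it.  The effect is inherent to planted-motif
  generators and is visible in the cross-species matrix's off-taxonomy
  cells.

## Known limitations

* The from-scratch tiny encoder is a study vehicle, not a production
  predictor; real-data performance requires genome-scale pretraining and
  the original curated datasets, both outside this package's scope.
* Attention weights are an importance *proxy*; the package reports them
  as such and provides the planted-motif ground-truth check rather than
  claiming causal attribution.
* The binomial substrate scan assumes independent sequences; homologous
  windows would inflate enrichment (redundancy reduction is assumed done
  upstream).
* Training is CPU-bound R; the design favours exactness and auditability
  over throughput, and large-corpus training is explicitly a non-goal.
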