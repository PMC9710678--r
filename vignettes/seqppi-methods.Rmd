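---
title: "seqppi: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqppi: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

seqppi predicts whether two proteins physically interact using nothing but
their amino-acid sequences. This vignette is the package's own account of
the underlying models, the tunable parameters that matter, what the
synthetic benchmark does and does not establish, and the design decisions
taken where the design was genuinely open. It states no empirical result
that the test suite does not itself compute.

## The descriptor: autocorrelation over physicochemical scales

An amino-acid *scale* assigns each of the 20 standard residues a real
number (hydrophobicity, polarity, side-chain volume, ...). Seven such
scales are bundled: hydrophobicity (Kyte–Doolittle), hydrophilicity
(Hopp–Woods), side-chain volume, polarity (Grantham), polarizability
(Charton–Charton), solvent-accessible surface area (Rose) and the net
charge index of the side chains — a set in long-standing use for
sequence-based interaction prediction. Each scale is normalized over its
20 values to mean 0 and *population* standard deviation 1 (divisor 20):

$$P'_i = \frac{P_i - \bar P}{\sigma_P},\qquad
  \bar P = \tfrac1{20}\sum_i P_i,\qquad
  \sigma_P^2 = \tfrac1{20}\sum_i (P_i-\bar P)^2 .$$

Normalization makes the descriptor invariant under positive affine
transformations of a scale, which also means the handful of closely
related hydrophobicity tables in the literature are interchangeable here;
the bundled tables are the package's documented choice, editable as plain
two-column text files under `inst/extdata/scales/`.

A sequence of length $n$ is translated through every scale $j$ into a
numeric column $S_{\cdot j}$, and summarized by its lagged
autocorrelation

$$\mathrm{AC}_{\mathrm{lag},j} =
  \frac{1}{n-\mathrm{lag}}
  \sum_{i=1}^{n-\mathrm{lag}}
  \frac{(S_{i,j}-\bar S_j)(S_{i+\mathrm{lag},j}-\bar S_j)}
       {\sigma_{S_j}^2},
  \qquad \mathrm{lag}=1,\dots,30,$$

with $\bar S_j$ and $\sigma_{S_j}$ the mean and population standard
deviation of the *full* column (a literal reading of the printed formula;
the windowed alternative was not used). Thirty lags per scale give a
210-dimensional descriptor per sequence and a 420-dimensional ordered
concatenation per pair. The descriptor is independent of sequence length
and — because the sum is symmetric under index reversal — invariant under
reversing the sequence.

Numerical conventions, chosen where the formula is silent:

* `lag >= n`: the entry is 0 (the unbiased "no signal" value), with a
  warning.
* $\sigma_{S_j}=0$ (e.g. a homopolymer): all entries of that scale are 0
  rather than NaN. Constant columns are detected by direct value
  comparison, not via the computed variance, so floating-point
  accumulation cannot manufacture a spurious variance.
* Sequences shorter than 16 residues are computed but warned about; the
  method was tuned for length ≥ 16.
* Feature order is scale-major (30 lags of scale 1, then scale 2, ...),
  serialized in model metadata so a trained model detects configuration
  mismatches at load time.

## The random-forest classifier

Training pairs are expanded four ways — $(A,B)$, $(B,A)$,
$(A,B_\mathrm{inv})$, $(B,A_\mathrm{inv})$, with $X_\mathrm{inv}$ the
character-reversed sequence — all inheriting the pair's label. Because the
descriptor is reversal-invariant, the two inverse representations are
feature-identical to the two direct ones; the quadrupling is implemented
exactly as stated and the identity is documented (and tested) rather than
exploited. The forest itself is standard: 750 unpruned classification
trees grown on bootstrap samples, Gini impurity, a random subset of
`mtry = 20` of the 420 features considered at each split
($\lfloor\sqrt{420}\rfloor$, the usual classification heuristic; the
method description fixes only $m \ll 420$). The score of a pair is the
fraction of trees voting "binder", averaged over the four
representations, which makes `predict_pair(A, B)` exactly equal to
`predict_pair(B, A)` by construction. No class reweighting is applied;
the intended datasets are near-balanced.

The forest is implemented in C++ inside the package (no forest package is
a declared dependency), single-threaded and fully deterministic under the
configuration seed, with its own RNG so R's global RNG state is never
disturbed.

## The graph neural network

The alternative predictor never builds the 420-dim descriptor. Each
sequence becomes a chain graph: one node per residue carrying its 7-scale
profile, adjacent residues joined by *two directed edges* (one per
direction) so both neighbours message each other. Node profiles are
encoded by a learned two-layer map into 32 dimensions; edge features are
32-dimensional and initialized to ones. Five rounds of message passing
update, in order, the edges (from source node, destination node, edge),
the nodes (from the mean of incoming updated edges and the node) and a
128-dimensional graph-level feature (from the means of nodes and edges and
its previous value). The final round's global feature is the graph
readout; the two 128-dim readouts of a pair are concatenated to 256
dimensions and mapped by a final MLP (one hidden layer of 64) through a
sigmoid to a binding propensity. All activations are leaky rectifiers
(slope 0.01) except the final sigmoid; parameters use fan-based (He)
uniform initialization.

Open points, fixed as follows:

* *Aggregations* are means — length-robust for proteins of widely varying
  size, and invariant to edge storage order (a tested property).
* *Update MLPs* are two layers of the corresponding width (32 for
  node/edge, 128 for global); depths/widths are unstated in the method
  description and exposed in `gnn_config()`.
* *The global feature* is maintained and updated every round, with the
  final round's value as the readout.
* *Scoring order*: the 256-dim concatenation is ordered, so the raw GNN
  score is order-sensitive; a `symmetrize` flag averages both orders and
  is off by default.

Training minimizes binary cross-entropy with AdamW (decoupled weight
decay 0.01). The published schedule — learning rate $10^{-5}$ for 350
epochs, then $10^{-7}$ for 50 — is the `gnn_config()` default and is
calibrated for a ~70 000-pair dataset, i.e. roughly 2 000 optimizer steps
per epoch. A 2 000-pair desk-scale run takes ~60× fewer steps per epoch,
so `gnn_desk_config()` compensates with a proportionally larger rate
($10^{-3}$) over 200 epochs; this step-count scaling was fixed before the
acceptance suite was written. Gradients are hand-derived and implemented
in single-precision C++ for one-CPU throughput; the test suite checks
them against finite differences of the independent double-precision R
forward pass, and checks that the two forward implementations agree.

## The consensus combiner

RF and GNN scores have quite different distributions, so a linear blend is
not ideal; a minimal fully connected network (2–8–8–1, leaky-ReLU hidden
layers, sigmoid output, exactly 105 parameters) maps the two scores to one.
It is trained with binary cross-entropy and Adam (decoupled weight decay,
rate $10^{-3}$, at most 500 full-batch epochs, early stop on plateau).
The scores used to train it must come from data the base models never saw;
the package supports the clean protocol (split the training set, fit base
models on one part, fit the consensus on the other part's predicted
scores) via `split_train_test()`, and the CLI's consensus training
consumes two already-fitted model files so it cannot silently leak.

## Dataset curation

Sequence identity is estimated by an internal global (Needleman–Wunsch)
alignment — match +1, mismatch 0, gap −1 — as
$\max(0,\text{score})/\max(|a|,|b|)$. The score equals the number of
identical aligned positions whenever the optimal alignment is ungapped and
is a well-defined optimum even when co-optimal alignments disagree about
the raw match count; dividing by the longer length makes the measure
symmetric (the printed definition does not name which length). CD-HIT and
BLAST are deliberately not dependencies; an optional shared-k-mer
prefilter accelerates clearly unrelated comparisons.

Redundancy is controlled at the *pair* level: the two sequences are
concatenated in canonical order (lexicographically smaller id first, so
$(A,B)$ and $(B,A)$ concatenate identically) and greedily clustered by
descending concatenated length, keeping a pair only if its similarity to
every kept representative is at most the threshold (default 0.5, i.e. at
most 50 % identity). Negative sampling draws candidates in seeded random
order under the same constraint. Train/test splitting is label-stratified
and seeded, and unordered-pair disjointness is an invariant. The
two-dataset redundancy audit computes, for every cross pair of pairs, the
better of the two sequence-assignment combinations and bins the two
similarities into a 2-D histogram; for properly separated sets all mass
sits in the low-similarity corner.

## The synthetic benchmark: what it emulates and what it does not

Every learnability statement in the test suite refers to a seeded
generator, not to curated interaction databases. Binder pairs receive a
*matching hydrophobic k-mer* — a fresh draw per pair, length 8, over the
extreme Kyte–Doolittle tail {I, V, L, F} — inserted at a random position
in both sequences; non-binders are background only. The signal therefore
lives exactly where the method looks: in low-lag autocorrelation of the
hydrophobicity channel (with correlated traces in the other scales, since
real residues score on all seven). `signal_strength` is the per-position
probability that a motif position carries a tail residue rather than a
background draw, so 0 reduces binders exactly to background and 1 plants
the intact motif.

Stated-world defaults, chosen once: uniform background composition
(configurable to natural frequencies); lengths uniform in 32–70 residues —
single-domain scale, above the 16-residue minimum, long enough that all 30
lags are informative, and small enough that the full benchmark (2 000
training pairs, 500 test pairs, forest + 200-epoch GNN) runs in
CPU-minutes on one core, which is the regime the acceptance criteria
prescribe. Early pilots were used only to confirm the planted signal is
scale-detectable; generator parameters were frozen before the acceptance
suite was written and not revisited afterwards.

The label-permutation null permutes labels across the whole dataset
*before* splitting, so the held-out evaluation is against permuted labels
too. Scoring a permuted-label model against the true labels of a
signal-bearing test set would not be a clean null: whatever spurious use
the model makes of the hydrophobicity channel correlates, in one
direction or the other, with the true labels, and the resulting AUC can
drift far from 0.5 without any real learning.

A green learnability test establishes that the full pipeline — scales,
descriptors, augmentation, forest/GNN, evaluation — can recover a known,
planted, descriptor-aligned signal from sequence alone, and that a
label-permuted null stays at chance. It does *not* establish accuracy on
real interactomes: real binding signal is weaker, distributed, and
confounded with homology structure that the generator deliberately does
not emulate (no taxonomic structure, no shared-partner hubs, no
compositional bias). Published full-data figures are reproducible only
with the original large-scale datasets, which are out of scope here.

## Evaluation and scanning

AUC is computed by the rank method (equal to trapezoidal integration of
the ROC curve and to the probability that a random positive outranks a
random negative, ties counted half) and is tested against explicit pair
enumeration at $10^{-12}$. Confusion statistics use "binder iff score ≥
threshold", default 0.5; stricter operating points (0.7/0.8/0.9) are a
flag away. Proteome scanning scores a query against every entry of a
FASTA database, warns on sub-16-residue sequences but scores them, skips
untranslatable entries with an explicit skip report, and breaks score
ties by target id so the ranking is a deterministic, complete permutation
of the database. Permutation feature importance shuffles one scale's
30-lag block (in both halves of the pair vector) across the evaluation
set and reports the resulting metric deltas.

## Known limitations

* The similarity measure is a score-based identity estimate, not a
  CD-HIT/BLAST reimplementation; absolute identity values can differ from
  those tools near the threshold.
* The greedy pair clustering is quadratic in the worst case; the k-mer
  prefilter mitigates but large-scale curation is better done with
  dedicated tools, for which the filter is a faithful stand-in.
* GNN training is single-precision and single-threaded by design;
  bit-identical reproducibility is guaranteed on a given platform, not
  across differing BLAS builds.
* The 13/15-scale GNN profiles are supported mechanically
  (`profile_count` plus user-supplied tables) but no extra tables are
  bundled, since their identities are not published.
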