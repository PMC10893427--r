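---
title: "Detecting and validating macro-activities with graph link prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating macro-activities with graph link prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maglink)
```

## The problem

Sensor-based human activity recognition typically classifies short,
homogeneous windows of inertial data into *micro-activities* — a single
table-tennis stroke, one "cut" step while preparing a meal. Complex
*macro-activities* (a full training exercise, a complete recipe) are ordered
sequences of such micro-activities, and two questions arise the moment a
recognizer runs on a continuous stream: is the sequence observed so far a
*complete* macro-activity, and can the incoming micro-activity *extend* it
into something still meaningful? `maglink` answers both with a single
multi-task graph neural network and turns the answers into a streaming
segmentation procedure.

## Sequences as star graphs

A sequence of `T` micro-activity embeddings becomes a directed star graph:
each embedding is a vertex, every vertex sends one edge to the last vertex,
and the last vertex carries a self-loop. The adjacency matrix is zero except
for a last column of ones, so the graph always has exactly `T` edges and a
single message-passing step concentrates the whole sequence in the final
vertex.

The price of this sparsity is that the topology carries no temporal
information: permuting all vertices but the last one produces the identical
graph. The package therefore adds sinusoidal positional encodings to the
vertex features before the attention layer,

$$PE(t, f) = \begin{cases}\cos\left(t / 10000^{2f/F}\right) & f \text{ even}\\
\sin\left(t / 10000^{2f/F}\right) & f \text{ odd,}\end{cases}$$

with `t` the 1-based temporal vertex index and `f` the 0-based feature
index. Two conventions differ from the classic transformer table and are
kept deliberately, exactly as used in this line of work: cosine is assigned
to the *even* features (the transformer uses sine there), and the exponent
uses the raw feature index `f` rather than the pair index `floor(f/2)`. Both
affect only which fixed, injective encoding is added — any injective,
deterministic code restores order information — so the package implements
the printed form verbatim and exposes `t_offset` for 0-based ablations.
Encodings are added to graph vertices only, never to the candidate next-link
embedding, which represents an activity that has no position yet.

`test-model.R` verifies the symmetry argument directly: without encodings
the pooled embedding is invariant to permutations of the non-final vertices
(to numerical precision), and with encodings it is not.

## The network

The embedding block is a single graph-attention layer with `H = 5` heads and
a total output width of `2F`. "Five heads with 2F channels" is read as
concatenation: per-head width `2F/H`, which is integral for all study
dimensions (`F` ∈ {5, 15, 25} gives 2, 6, 10); if a user picks an `F` not
divisible this way, the implementation falls back to full-width heads that
are averaged. Attention scores use the standard leaky-rectifier form with
slope 0.2 over (source, destination) projections; because only the last
vertex has in-edges, the layer is computed for that vertex alone and *Last
Vertex Pooling* returns its row as the graph embedding. The attention layer
output is linear (the customary choice for a network's last attention
layer); all subsequent hidden layers use ReLU.

Both task heads share one shape: three hidden ReLU layers of width `2F` and
a one-unit sigmoid output. The validator consumes the graph embedding
(width `2F`); the link predictor consumes the concatenation of the graph
embedding and the candidate embedding (width `3F`). Decisions threshold the
sigmoid at 0.5 (no threshold is otherwise specified anywhere, and both
training tasks are balanced, so the symmetric point is the natural choice).

No dropout or normalization layers are used — none are part of the stated
architecture — and initialization is Xavier-uniform throughout, seeded.
Since no deep-learning runtime is involved, forward and backward passes are
exact, hand-derived matrix expressions; `test-model.R` checks every
parameter block against numerical differentiation (the check jitters the
zero-initialized biases first, because a dead ReLU layer otherwise parks a
pre-activation exactly on its kink, where one-sided differences and
subgradients legitimately disagree).

## The grammar oracle

A grammar is the list of valid macro-activity sequences over the class
alphabet. Validity is exact membership; *possibility* of appending class `c`
to prefix `p` means `p∥c` is a prefix (proper or full) of at least one
grammar sequence. Possibility is judged against the **whole grammar** rather
than any single sequence: distinct macro-activities may share prefixes, and
a streaming recognizer cannot know which one is underway. A prefix that
happens to equal a complete shorter macro-activity is *both* valid and
extendable; the streaming case table handles this without special-casing.
Queries go through a hashed prefix trie and are property-tested against
brute-force scans of the sequence list.

## The synthetic-data generator

The generator emulates the study conditions under which the model family is
evaluated:

* **Class-conditional embeddings.** Each class `i` has a prototype mean
  `μ_i`; embeddings are drawn from an isotropic Gaussian `N(μ_i, σ)` —
  independent per-coordinate normals with one shared, pre-defined σ (the
  isotropic reading matches the circular σ-contours used to visualize such
  prototypes). Study values are `F` ∈ {5, 15, 25} and σ ∈ {0.05, 0.15,
  0.25}. Prototypes can be fitted from windowed features through a pluggable
  deterministic projector; fitting a UMAP on the original sensor data is out
  of scope (one of the two source data sets is closed), so tests use a
  linear projector and seeded random prototypes with a controlled minimum
  pairwise distance.
* **Prefix expansion.** For every grammar sequence and every repetition
  (default 30), one embedding is drawn per position and all `T` prefix
  slices are emitted; prefixes of one repetition share the identical drawn
  vectors.
* **Labels.** The validator label is the oracle's validity verdict. Each
  graph receives one possible link per successor class — the same
  repetition's next drawn embedding when the successor continues this
  sequence, otherwise a same-split embedding of that class — and
  `n_imp` impossible links drawn from the same split's pool restricted to
  non-successor classes, where `n_imp` is the split-wide rounded mean
  possible-link count (minimum 1), or `round(0.1 · pool size)` for graphs
  with no successors at all. Rounding is half-up. Interpreting the
  "previously generated" pool as the *same split's* pool is a deliberate
  tightening: it prevents identical drawn vectors from appearing on both
  sides of the train/test boundary.
* **Split.** The 60/20/20 rule is applied to repetitions (largest-remainder
  rounding), never to individual prefixes, so the split is leak-free by
  construction. Tests verify that no (sequence, repetition) pair straddles
  splits and that the shipped cooking-style grammar yields exactly
  `30 × (11+11+11+9+9+9+14) = 2220` samples, 210 of them valid.

What the generator does *not* emulate: real windows with mixed activity
content (the main reason real cooking-data prototypes overlap), embedding
drift within a session, and class-imbalanced streams. Passing tests
therefore demonstrate that the architecture and training procedure recover
grammar structure from well-modelled embeddings — not that any fixed
accuracy carries over to a particular real sensor deployment.

## Training

Each optimization step takes one batch per task: the validator batch
contributes its binary cross-entropy to the validator head, the link batch
(each sample reusing its parent graph's embedding) to the link head, and the
shared embedding block receives the unweighted sum of both — the loss sum is
implemented by routing both gradient flows into the block within one
backward pass, and `test-training.R` checks the isolation (a link-only batch
leaves the validator's gradients at exactly zero, and vice versa).

Class balancing resamples the minority class of each task up to the majority
size, per epoch, with reshuffling (oversampling). An undersampling mode is
retained, but oversampling is the default: the impossible-link class
outnumbers the possible-link class several-fold, and discarding the majority
surplus each epoch wastes most of the generated data — at desk-scale budgets
this visibly starves the link predictor, while oversampling trains on every
sample every epoch.

Optimization is Adam at learning rate 0.001 with batch size 128, up to 500
epochs, early stopping with patience 10. The monitored quantity — not pinned
down by the training recipe itself — is the *validation* sum
`loss_V + loss_L` on the natural (unbalanced) label distribution, and the
best-validation parameters are restored on stop. Probabilities are clipped
at `1e-7` inside the cross-entropy. All randomness (generation,
initialization, balancing, batching) flows through R's global RNG, so a
single seed reproduces a run bit-for-bit.

## Streaming segmentation

Given the current sequence and an incoming embedding, the validator verdict
`v` and link verdict `l` select exactly one of four actions: grow
(`¬v ∧ l`), emit and reset (`v ∧ ¬l`), emit and grow (`v ∧ l` — the sequence
is a complete macro-activity *and* a prefix of a longer one; later
completions emit separately, and deduplication is left to the consumer), or
interrupt (`¬v ∧ ¬l` — the embedding of the abandoned sequence is archived
and a new sequence starts). Two under-specified corners are resolved
explicitly: after a plain emission the new sequence starts with the incoming
micro-activity (mirroring the interrupt case; without a reset the pipeline
would stall), and the archive is unbounded by default with an optional FIFO
retention bound (`max_archive`). Re-splicing interrupted sequences back into
the stream is deliberately not implemented. At stream end, a terminal
validator check emits or interrupts the residual sequence.

The case logic is tested with oracle-mocked heads (the grammar stands in for
the learned model), which makes the event traces exact and hand-checkable.

## Evaluation and study grids

Both tasks report accuracy and macro F1 — the unweighted mean of the
per-class F1 of the positive and negative class, the only reading that is
informative under the strong label imbalance the generator produces; an F1
with an empty denominator is defined as 0. Metrics are computed on the
natural test distribution by default. `run_sweep()` crosses `F`, σ, the
positional-encoding switch and seeds, aggregating mean and standard
deviation per cell over seeds, with per-cell failures recorded rather than
fatal.

Two built-in benchmark grammars drive the package's own studies
(`benchmark_grammar()`):

* **separable** — 6 sequences (lengths 3–6) over 8 classes with no
  structural ambiguity; with prototypes at least 10σ apart, both tasks are
  exactly learnable and a trained model is compared against the oracle.
* **order_ambiguous** — sequences containing *permuted-prefix* pairs such as
  `a,b,c,d` vs `b,a,c`: the invalid prefix `a,b,c` and the valid sequence
  `b,a,c` have the same class multiset and the same last element, so under
  star symmetry a model without positional encodings receives identical
  inputs with contradictory labels and cannot exceed chance on them. Note
  that two full sequences that are mere permutations of each other (e.g.
  `a,b,c` vs `c,b,a`) do **not** create this collision — their last vertices
  differ, and the last vertex is special in the star topology — which is
  why the benchmark uses permuted prefixes of unequal-length sequences.

Desk-scale study budgets are 10 repetitions per sequence and at most 100
epochs with seeds 1–3 (`benchmark_cell()`); the full-scale defaults (30
repetitions, 500 epochs) remain the package defaults. In the noise studies
the prototype means are a function of the seed only, never of σ, so the
noise axis is not confounded with class separation; the separation floor is
a minimum pairwise distance of 1 between class means.

## Known limitations

* The attention layer is single-step: information flows only one hop into
  the last vertex. Deeper GATs, edge features and alternative poolings are
  out of scope.
* The link predictor needs a candidate embedding; it cannot propose classes.
  `successors()` provides the exact oracle counterpart when a grammar is
  available.
* Grammars are exact-match prefix structures; fuzzy matching (edit
  distances, substring matching) is out of scope.
* The generator's Gaussian model is a deliberate idealization; see above for
  what passing tests do and do not establish about real data.
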