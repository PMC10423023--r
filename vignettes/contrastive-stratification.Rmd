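---
title: "Contrastive data stratification for interaction prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive data stratification for interaction prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the idea

Predicting whether a compound interacts with a protein sequence is usually
attacked with two encoders — a graph network over the molecular graph and a
1D CNN over the sequence — whose outputs are concatenated and fed to a
classifier. `csistrat` implements a data-centric refinement of this recipe:
before any predictor is trained, the interaction dataset is *stratified*
into keyed groups of congruent views, and the encoders are pretrained
contrastively so that views belonging to the same key embed close together
and views from different keys embed apart. The frozen encoders then feed an
MLP predictor.

Three stratification families are supported:

* **Compound keys.** Each compound `c` with interacting sequence set `S_c`
  yields views `[c, (s_i, s_j)]` for every unordered pair of its partners.
  Under a lock-and-key binding picture, two proteins bound by the same
  compound share binding features, so the pair is an alternative view of the
  compound.
* **Sequence keys.** The mirror image: `[s, (c_i, c_j)]` over unordered
  compound pairs.
* **Reaction-feature keys.** For enzymatic data each biochemical reaction
  `b = {R, E, P}` (reactants, enzymes, products; treated as bidirectional)
  provides three views: reactant–product pairs, compound–sequence pairs with
  the compound drawn from `R ∪ P`, and pairs of catalyzing enzymes. Keys can
  be the reaction itself, its RCLASS (biotransformation pattern), or its EC
  number; a key covering several reactions pools (and deduplicates) their
  view lists rather than nesting sub-strata.

## Pair orientation and singleton keys

The view pairs are *unordered with i ≤ j under lexicographic id order*.
Ordered pairs would double every stratum with mirror-image tuples and hence
duplicate gradient signal without adding information. A key with a single
partner keeps a self-pair view `(x, x)` so that no interaction is discarded;
these strata still contribute as non-congruent candidates for other keys.

# The contrastive machinery

The discriminator between two view embeddings is the temperature-scaled
cosine exponential `h(z1, z2) = exp(cos(z1, z2) / τ)`. The directed loss over
a batch of `k` aligned rows is the InfoNCE form

```
L(V1 → V2) = (1/k) Σ_n [ −log h(z1_n, z2_n) / Σ_m h(z1_n, z2_m) ]
```

with the congruent term included in the denominator, and the total loss is
the sum of both directions. With three views the total loss is applied to
each unordered view pair and summed with equal weights. The per-anchor term
is taken as the expectation over the empirical batch itself — no extra
sampling happens inside the loss. Negatives are strictly *in-batch*: a batch
is assembled from `k` distinct keys, one sampled view tuple per key, so the
other `k − 1` columns are non-congruent by construction and no explicit
negative mining is needed.

Numerical choices: log-sum-exp with max subtraction; cosine norms floored at
1e-12 but an exactly-zero vector is a hard error; `τ` defaults to 0.07 (the
best value on a 0.05–0.08 grid) and is freely configurable. The analytic
gradients of the loss are verified against finite differences in the test
suite.

# Encoders

* **Molecules** are parsed from SMILES with rdkit (invoked in batch through
  a bundled helper script) into heavy-atom graphs carrying the standard
  node features (atom-type one-hot over C/N/O/S/P/F/Cl/Br/I/other, mass,
  valence, ring membership, formal charge, radical electrons, chirality,
  degree, hydrogen count, aromaticity) and bond features (type, ring,
  conjugation, stereo). The encoder is a stack of Kipf-style graph
  convolutions `H ← relu(Â H W)` over the symmetrically normalized
  adjacency with self-loops, a symmetric pooling readout (mean by default)
  and two fully connected layers; the embedding is therefore invariant to
  node reindexing. Bond features are stored and validated but not consumed
  by this GCN variant.
* **Sequences** are tokenized over the 20 standard residues plus one unknown
  symbol (index 0 = padding), right-padded/truncated to a fixed `L_max`
  (default 1000; the synthetic benchmark uses 128), embedded through a
  learned residue table, passed through same-padded 1D convolution blocks
  with ReLU, a global max pool and one fully connected layer. By default
  convolutions run over the padded tensor; a masking flag restricts them to
  the original length.
* **Siamese pair encoders** apply the same weights to both inputs and
  concatenate the two arm outputs in argument order.

**Dimension matching.** Within one contrastive phase both views must embed
in the same space. The convention here: a lone-object encoder emits `2d'`
and each Siamese arm emits `d'`, so both views have total dimension `2d'`
(`d'` = `embed_dim`, default 64). Phase 1A (compound keys) trains a lone GCN
and a Siamese CNN; Phase 1B (sequence keys) trains a Siamese GCN and a lone
CNN; the two phases share no parameters. The paper-scale layer sizes
(3 GCN layers of width 128, CNN channels 32/64/96 with kernel 7, residue
embedding 32) are the package defaults; all are configurable.

# Two-phase training

**Phase 1** iterates epochs over the shuffled key set in chunks of
`batch_size` (`k`); each step samples one view tuple per key, computes the
(multiview) total loss and takes one Adam step (learning rate 1e-3). A final
chunk shorter than `k` runs at reduced batch size with a logged message;
chunks of a single key are skipped because the loss is identically zero
there. Weight initialization is a seeded uniform fan-in scheme; every entry
point takes an explicit seed and two runs with the same seed produce
bit-identical trajectories on a fixed BLAS.

**Phase 2** freezes the encoders (asserted by SHA-256 checksum of the
serialized weights before and after), precomputes per-entity view
embeddings, and trains an MLP on the concatenated features of
(compound, sequence) pairs. The loss is cross entropy in which each positive
example carries weight equal to the negative-to-positive training ratio
(default 5:1). Positives are split train/validation/test at 8:1:1; training
stops early when validation loss has not improved for 10 epochs and the best
weights are restored.

**Inference-time composition.** The predictor input is
`(z_v1,comp ⊕ z_v2,comp) ⊕ (z_v1,seq ⊕ z_v2,seq)`. The Siamese encoders were
trained on pairs, so a lone entity is fed to both arms (the duplicated-pair
convention): `z_v2,comp` for a single sequence `s` is the Phase-1A Siamese
CNN applied to `(s, s)`, and `z_v1,seq` for a single compound is the
Phase-1B Siamese GCN applied to `(c, c)`. This preserves the dimensions the
encoders were trained with and is applied consistently at training and
prediction time. Reaction-feature models compose analogously from their
three view encoders (`6d'` input).

**Negative sampling** draws uniformly without replacement from `C × S`
excluding known positives and labeled negatives (most compound–protein
pairs do not interact). Train/validation pools use the training ratio, the
test pool a configurable ratio (1:1 by default; 5/10/25:1 probe harder
regimes). The three pools are disjoint, all derived from the master seed.
Labeled negatives in the input (e.g. known inhibitors) join the training
negatives as-is and are excluded from the sampler. Assembled example lists
are row-shuffled (seeded) so that tied scores can never inherit the label
order through the stable tie-break.

**Unseen split.** To probe generalization, the fraction (default 5%) of
compounds and of sequences with the fewest positive interactions can be held
out entirely; ties in frequency break lexicographically by id so the split
is reproducible. Every positive touching a held-out entity moves to the
unseen table; the remainder trains.

**Baseline.** The no-stratification baseline uses the same GCN and CNN
architectures (each emitting `2d'`), concatenated and trained end to end
jointly with the MLP under identical splits, negatives and loss — the only
difference is the absence of the contrastive phase and of freezing.

# Evaluation

Overall average precision and R-precision are computed over the scored pair
list; MAP, mean R-precision, MAP@3 and Precision@1 are computed per query
group (by compound and by sequence) and averaged unweighted over groups
containing at least one positive; groups without positives are skipped and
counted. MAP@k truncates the ranking at `k` and normalizes by `min(R, k)`
(the standard IR convention; with `k ≥` list length it equals MAP).
Precision@1 is the indicator that the top item is positive. Ties break by
stable original-order index — deterministic, but metric values then depend
on input order for exactly tied scores, which is documented rather than
hidden. All metrics are verified against independent brute-force oracles.

# The synthetic benchmark

No external datasets ship with the package; a block-model generator stands
in. Compounds and sequences are split evenly across `G` latent groups;
each (c, s) cell is a positive independently with probability `p_in` when
the groups match and `p_out` otherwise. Group identity is detectable from
the raw inputs: each compound is a random alkane/ether backbone carrying a
group-specific functional-group motif (carboxyl, amide, chloro, thiol, ...)
with probability `motif_strength`, and each sequence carries a
group-specific 6-mer at a random position with the same probability. Thus
congruent views share mutual information (group identity), which is exactly
the structure contrastive pretraining is meant to exploit. A reaction
generator layers reaction records on top: each reaction draws reactants,
products and enzymes from one group, and RCLASS/EC labels are pinned to
groups so that same-label reactions share a group.

Default study conditions: `G = 4`, 80×80 entities, `p_in = 0.3`,
`p_out = 0.01`, `motif_strength = 0.9`, sequence lengths 50–120, molecule
sizes 8–20 heavy atoms, `L_max = 128`. The benchmark trains with 50
contrastive epochs, 30 predictor epochs, `k = 8`, `τ = 0.07` across seeds
0–2 — sizes chosen so a complete stratified-vs-baseline comparison runs on
a laptop-class single CPU in minutes. At this scale the encoders are scaled
down accordingly (`d' = 16`, 2 GCN layers of width 16, CNN channels 8/16,
residue embedding 8; `small_encoder_config()`).

What the generator does *not* emulate: realistic chemistry (valence-diverse
scaffolds, synthesizability), protein families, degree heterogeneity
(hub compounds), or assay noise. Within-group interactions are exchangeable,
so group identity is the *only* generalizable signal and the best achievable
test AP is well below 1: cross-group positives (rate `p_out`) cannot be
separated from cross-group negatives by any function of the inputs.
Benchmarks passing here show that the machinery works and that contrastive
pretraining recovers latent block structure — not that the method reaches
any particular accuracy on real drug–target data.

## A note on the baseline at desk scale

The group-match signal is bilinear (an AND across the two input sides). An
end-to-end concat-MLP must discover it from scratch through a
ratio-weighted loss whose nearest attractor is the constant base-rate
predictor; with a narrow MLP head this basin is rarely escaped in 30
epochs. The MLP head is therefore comparatively wide (512 units in the
benchmark) for both the stratified model and the baseline — width is what
makes random-feature conjunctions linearly accessible — while the learning
rate stays at the Adam default of 1e-3. This is an architecture choice of
the benchmark, applied identically to both models.

# Known limitations

* The GCN consumes node features and topology only; edge features are
  parsed and validated but not aggregated (a relational/edge-conditioned
  variant would use them).
* Training is single-threaded CPU R; the implementation targets method
  fidelity and desk-scale experiments, not GPU throughput.
* Exact bitwise determinism holds for a fixed BLAS; across different BLAS
  builds results agree only to floating-point reassociation.
* `MAP@k` normalization follows the standard IR convention; other
  conventions (normalizing by `R` always) would give smaller values on
  truncated lists.
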