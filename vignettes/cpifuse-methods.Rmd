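---
title: "cpifuse: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cpifuse: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the two-phase compound–protein interaction (CPI) model, the
assumptions behind each stage, the tunable parameters and their
defaults, what the synthetic fixtures do and do not emulate, and the
design decisions taken where the architecture was genuinely open.

## 1. The two-phase model

### Phase 1: making a graph encoder 3D-aware

Molecular graphs are cheap; reliable 3D conformations at training scale
are not. The pretraining phase therefore teaches a 2D graph encoder to
*predict agreement* with 3D geometry rather than to consume geometry at
inference time. Two encoders are trained jointly:

- a **PNA encoder** on the molecular graph. Node features are one-hot
  element, degree, formal charge, hybridisation, an aromaticity flag and
  scaled Pauling electronegativity (27 columns); bond features are
  one-hot bond order plus a ring flag. Each layer aggregates incoming
  messages with four aggregators (mean, max, min, population std) and
  rescales each by three degree scalers — identity, amplification
  `log(deg+1)/log(avg_deg+1)` and its inverse (attenuation) — before a
  linear update. Graph embeddings pool node states with min/max/mean/sum
  readouts. `avg_deg` is computed once from the pretraining molecules.
- a **3D encoder** on each conformer. It sees coordinates only through a
  16-centre Gaussian radial-basis expansion of interatomic distances
  (centres on 0–8 Å, width 0.6 Å) gating learned messages over all atom
  pairs, for three rounds. Because only distances enter, the embedding
  is invariant to global rotations and translations *by construction* —
  the tests assert this to numerical precision rather than relying on
  augmentation.

The NT-Xent objective treats the `c` conformer embeddings of molecule
`i` as positives for its graph embedding and all conformers of other
molecules as negatives, with cosine similarity and temperature `tau`
(default 0.1). Two conventions exist for the denominator; this package
defaults to the form in which the positive terms are *excluded* (so the
loss of an all-identical batch with one conformer each is exactly
`log(N-1)` and can be negative), with `exclude_positive = FALSE`
switching to the canonical form that includes them. The default was
chosen to match the loss as printed in the method this package follows;
both variants are exercised against a brute-force double-loop oracle in
the tests.

### Phase 2: fusing "what" and "where" views

Both molecule and protein contribute a local, atomic-resolution view
("what") and a global, positional view ("where"), fused by multi-head
cross-attention in which "where" queries attend over "what" keys/values:

- **Compound.** Keys/values are the PNA node states (pretrained, then
  fine-tuned); queries are learnable embeddings of the set bits of a
  Morgan fingerprint (radius 2, 2048 bits by default). One embedding row
  per set bit — a lookup table, not an MLP over the dense bit vector —
  because fingerprints are extremely sparse and a per-bit table lets
  gradient flow only into observed substructure slots.
- **Protein.** From a PDB structure (the package consumes structures;
  predicting them is upstream of its scope) it builds the atomic one-hot
  matrix `A` (38 standard heavy-atom names + other, 20 amino acids +
  other, 5 elements; every block sums to 1 per row) and the Cα distance
  map `D`, expanded channel-wise by the Fourier map
  `γ(d) = [d, sin(d)/2⁰, cos(d)/2⁰, ..., cos(d)/2^(F-1)]` (default
  F = 4, so 9 channels). A three-layer 1D convolution tower over the
  atom rows of `A` (kernel 7, max-pool 4) produces keys/values; a
  three-layer 3×3 convolution tower over `γ(D)` (2×2 pool) produces one
  query row per surviving spatial cell.

Attended queries pass through a residual connection and layer
normalisation, are mean-pooled to fixed-width vectors `x_comp` and
`x_prot`, concatenated, and scored by a two-layer MLP head
(`z = relu(W_z [x_comp; x_prot] + b_z)`, then a linear output — passed
through a logistic only for classification). The training loss is MSE
for regression and logit binary cross-entropy for classification. The
standalone `cross_attention()` operation is exactly
`softmax(QK'/sqrt(C/h))V` per head (no residual), so its single-key and
equal-logit identities hold as closed forms; residual and normalisation
live in the encoder blocks.

### Freezing

`freeze_mask(fraction, cfg)` covers the first
`floor(fraction * n_layers)` PNA layers counted from the input, with
`fraction` restricted to [0, 0.95]; frozen tensors are excluded from
Adam updates and remain bitwise unchanged, which the tests assert after
ten optimisation steps.

## 2. Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fp_radius`, `fp_nbits` | 2, 2048 | Morgan environment radius / bit-vector length (field convention) |
| `tau` | 0.1 | NT-Xent temperature |
| `hidden_dim`, `emb_dim` | 16, 16 | PNA widths (tests/fixtures use 8 for speed) |
| `fourier_F` | 4 | frequency pairs in γ(D), giving 2F+1 channels |
| `embed_dim`, `n_heads` | 16, 2 | cross-attention width C and heads h (C divisible by h) |
| `conv1d_*` | 3 layers, kernel 7, pool 4 | atom-matrix tower |
| `conv2d_*` | 3 layers, kernel 3, pool 2 | distance-map tower |
| `lr`, `epochs` | 1e-4, 50 | Adam fine-tuning defaults (`patience` enables early stopping when a validation set is supplied) |
| `butina_cutoff` | 0.6 | Tanimoto-*distance* neighbourhood radius for compound clustering |
| `sim_threshold` | 0.3 | similarity above which training interactions are removed in the hard settings |
| `freeze_fraction` | 0 | fraction of PNA depth pinned during fine-tuning, in [0, 0.95] |

Angstrom units throughout for coordinates and distances; residue and
atom indices are 1-based in R.

## 3. What the synthetic fixtures emulate

`make_toy_molecules()` draws from a fixed library of valid drug-like
SMILES built from five structurally distant scaffold families
(benzenesulfonamides, pyridine amides, piperidine carboxylates, indoles,
aliphatic amino-esters) crossed with small substituents, so Butina
clustering at the default cutoff separates several clusters. Conformers
are embedded by a seeded distance-geometry scheme that targets
covalent-radius bond lengths with a soft nonbonded repulsion: it yields
chemically plausible bonded distances (C–C ≈ 1.52 Å, all bonds within
0.9–1.8 Å) and bit-reproducible coordinates, but makes no claim about
force-field energy minima or realistic torsion populations.

`make_toy_protein()` builds an ideal α-helix (rise 1.5 Å, 100°/residue,
radius 2.3 Å) with four heavy backbone atoms per residue and a seeded
random sequence, serialised as standard PDB text. Consecutive Cα
distances are ≈ 3.8 Å and the distance map is Toeplitz by construction
— useful exactness for testing, unlike real folds.

`make_toy_dataset()` plants a linear signal:
`y = w_c[butina_cluster(compound)] + w_p · composition(protein) + noise`
where the protein summary is its hydrophobic/charged/aromatic residue
fractions. The signal is deliberately expressible through features the
model can reach (fingerprint bits separate clusters; the amino-acid
block of `A` carries composition), so "beats the constant predictor" is
a meaningful end-to-end recovery check. Passing these tests shows the
pipeline can extract a recoverable structure–label relationship at desk
scale; it says nothing about binding physics, real affinity landscapes,
assay noise structure, or transfer to experimental benchmarks.

Fixture-scale study conditions used by the tests: 50 compounds × 10
proteins (500 interactions, noise sd 0.1) for the end-to-end learning
check, 20 × 10 (200 interactions) for split contracts, widths of 8 and
a few dozen epochs throughout — sizes chosen so the whole suite runs on
one CPU in minutes while leaving the planted signal clearly above the
noise floor.

## 4. Numerical choices

- **Automatic differentiation.** No R neural-network framework is part
  of the package's dependency footprint; training runs on an included
  ~600-line reverse-mode engine over dense matrices (tape of closures,
  one primitive per algebraic step, Adam optimiser). Its single oracle
  is central finite differences, enforced at 1e-6 relative error over a
  composite network touching every primitive.
- **Hidden activations** are leaky ReLU (slope 0.01) in the encoders and
  towers so that tiny fixture-scale networks cannot silently die; the
  MLP head uses plain ReLU as specified for the interaction stage.
- The PNA **std aggregator** uses the population variance with eps 1e-5
  inside the square root for a finite gradient at zero spread; empty
  neighbourhoods aggregate to zero, and the attenuation scaler is set to
  0 for degree-0 nodes where its log ratio is undefined.
- **NT-Xent at the all-identical point** is exercised in tests: cosine
  normalisation adds eps 1e-12 under the square root, keeping gradients
  finite.
- **Convolutions** are im2col gathers with "same" zero padding via a
  single appended zero row; pooling is segment-max with ceiling-division
  group sizes, so short inputs survive all three layers.
- **Fourier map.** The printed form scales the *amplitude* of the k-th
  sine/cosine pair by 2^-k while the argument stays `d`; the common
  positional-encoding alternative scales the *argument* by 2^k. The
  package implements the printed form as default and exposes
  `scale_argument = TRUE` as an option, since the surrounding text
  ("high frequencies") arguably describes the latter.
- **Concordance index.** The printed indicator set is internally
  inconsistent about ties; the default scores prediction ties as 0.5
  (Harrell's convention) and `ties = "strict"` matches the literal
  strict-inequality formula. Spearman's ρ uses the classical
  rank-difference closed form on average ranks; with ties this deviates
  from the Pearson-on-ranks estimator, which the documentation states.
- **BEDROC** uses the exponential rank-weighting formulation, min–max
  normalised so a perfect ranking scores exactly 1 and the worst exactly
  0. A precision–recall-curve reading of BEDROC exists, but α = 80.5 is
  only meaningful in the exponential formulation, and the analytic
  random expectation of that formulation (≈ 0.0222 at the DUD-E Diverse
  composition) matches the published random-guessing reference, which
  settles the ambiguity.
- **Enrichment factor** uses a top window of `ceiling(fraction·N)` and
  stable index tie-breaking, making EF deterministic under score ties.
- **Butina clustering** breaks neighbour-count ties by original index,
  making labels deterministic; k-means uses seeded k-means++
  initialisation followed by Lloyd iterations.
- **Protein similarity** for the 0.3 removal rule is normalised global
  alignment identity (match +1, mismatch 0, linear gap −1, score divided
  by the longer length) via Biostrings; a 3-mer-descriptor cosine is
  available as a faster alternative (`protein_sim = "descriptor"`) and
  is what the pipeline uses on fixtures. The similarity measure the
  original experiments used for proteins is not documented, so it is
  configurable.
- **Fold construction** assigns whole clusters to folds by greedy
  balancing of *interaction counts*, largest cluster first, index
  tie-break (balancing by entity count is the other defensible choice;
  interaction balancing keeps fold losses comparable).
- **Checkpoints** are versioned JSON (text, portable, diffable);
  parameters round-trip at ~1e-15 relative error, which matters only for
  bit-reproducibility across save/load boundaries, not accuracy.

## 5. Known limitations

- The conformer embedder is a geometric sketch, not a conformer
  ensemble generator; pretraining on its outputs demonstrates the
  mechanism, not chemistry-grade 3D augmentation.
- `parse_structure` handles single-model PDB ATOM records (altloc by
  highest occupancy, hydrogens dropped); mmCIF and multi-model NMR files
  are out of scope.
- The hard-setting removal rule is exhaustive over train×test pairs and
  alignment-based protein similarity is O(L²) per pair — fine at
  hundreds of entities, slow beyond; swap to the descriptor similarity
  for large sets.
- Full-batch training is intentional at fixture scale; there is no
  mini-batching, GPU path, or hyperparameter search.
- Per-target metric aggregation mirrors the screening-table convention
  (mean of per-protein values) but bootstrap confidence intervals are
  not implemented.
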