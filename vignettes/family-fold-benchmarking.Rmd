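---
title: "Benchmarking generalization of learned RNA structure prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking generalization of learned RNA structure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

RNA secondary structure — the set of canonical A–U, G–C and wobble G–U
base pairs a single strand forms with itself — is strongly conserved
within an RNA family even where sequences have diverged below 60%
identity. That conservation is a trap for machine-learning benchmarks:
a model evaluated under k-fold cross-validation sees near-identical
structures in training and test, so high scores may reflect family
memorization rather than any grasp of folding. `shadowfold` packages a
complete apparatus for separating the two claims: a deliberately simple
learned predictor, the pseudo-energy coupling that lets it steer a
thermodynamic folder, both split strategies, slippage-tolerant scoring,
and a tree-edit-distance audit of how much structure a split leaks.

## The model and its couplings

**Shadow CNN.** The network predicts each nucleotide's probability of
being paired — the structure's *shadow*, with no partner identities.
Sequences are one-hot encoded as 4 × L matrices (row order A, C, G, U;
ambiguity letters become all-zero columns, indistinguishable from the 3'
zero padding) and shadows as 0/1 vectors, both padded to a fixed width.
The architecture is two same-padded width-3 convolutions of 256 filters
with ReLU and spatial dropout 0.25 between them, then a flatten, a dense
ReLU layer of 512 units with dropout 0.25, and a final dense sigmoid
layer whose width equals the padded length, aligning output positions
with target positions. Training uses Adam (lr 0.001, β₁ 0.9, β₂ 0.999,
ε 1e-8), binary cross-entropy over *all* output positions (padding is
labelled unpaired), mini-batches of 256 and early stopping on validation
loss with patience 5, restoring the best epoch. Two points were design
choices rather than givens: (a) the dense block acts on the *flattened*
convolution output — the final layer then matches the 1 × L target
exactly; a per-position dense mode is available as a config switch; and
(b) the loss includes padded positions (their targets are zero by
construction) while every reported AUC excludes them, since scoring
padding would trivially inflate it. The network is implemented directly
in R matrix algebra (im2col convolutions over BLAS, hand-written Adam
and backpropagation), which keeps the dependency surface at zero and
makes every training run bit-reproducible from its seed on one platform.

**Pseudo-energies.** A predicted shadow becomes SHAPE-like reactivities
via α(i) = 1 − ŷ(i) — high reactivity means likely unpaired, matching
the chemistry convention — and then per-nucleotide free-energy terms
ΔG′(i) = m·ln(α(i)+1) + b (natural log). Applied to shadow-derived
reactivities this is identically m·ln(2 − ŷ(i)) + b, an equivalence the
test suite asserts to machine precision. The defaults m = 1.8,
b = −0.6 kcal/mol are the values fit on experimental SHAPE data and are
deliberately **not** refit: the validation set shares families with
training, so refitting the free parameters invites exactly the
overfitting the benchmark is designed to expose. An 11 × 11 grid search
(`run_grid_search`) is provided for inspection; its default axes
m ∈ {0.0, 0.3, …, 3.0}, b ∈ {−1.5, −1.3, …, 0.5} bracket both published
optima for experimental SHAPE (1.8/−0.6 and 2.6/−0.8). Ties prefer the
weakest intervention (smallest |m|, then |b|).

**Folding backends.** The default *reference* backend is an O(n³)
interval dynamic program over non-crossing structures with minimum
hairpin j − i > 3: per-pair base energies (GC/CG −3, AU/UA −2, GU/UG −1,
model units) plus, when a profile is present, ΔG′(i) + ΔG′(j) added once
per formed pair. Two simplifications are deliberate and documented: the
energy model has no nearest-neighbour stacks, so the per-stack
application of ΔG′ used by thermodynamic engines is replaced by its
per-pair analogue; and energies are carried at full floating precision,
which matters for the nudge sweep because stock external engines round
uniform offsets to tenths of kcal/mol. Traceback ties prefer the pairing
branch, then the smallest partner index, so outputs are deterministic.
The *external* backend shells out to RNAstructure `Fold` or ViennaRNA
`RNAfold` (whichever the PATH offers) through their Deigan-style SHAPE
slope/intercept options, preserving exact nearest-neighbour semantics
when an engine is installed.

## Splits, scoring and the audit

`kfold_split` is a seeded uniform shuffle into k = 5 near-equal folds —
unstratified, because the intra-family benchmark is meant to mirror
common (flawed) practice. `familyfold_split` leaves one family out per
fold; no family label ever crosses the train/test boundary.
`carve_validation` moves a seeded 10% of the training pool (round to
nearest, floor one) into a validation set used only for early stopping
and grid search; for family-fold plans that validation set *still shares
families with training* — deliberately, since the downstream lesson is
that such a validation set cannot catch the failure to generalize.

Structure accuracy is F1, the harmonic mean of PPV and sensitivity,
with the field's slippage tolerance: pair (i, j) matches (i±1, j) or
(i, j±1), each side counted independently with no one-to-one
assignment. Edge conventions: an empty prediction against a nonempty
reference scores 0; two empty structures score 1 (a correctly predicted
unpaired molecule — absent from real corpora, but the generator can
produce it). Shadow quality is rank-based ROC AUC per record, ties at
half, undefined (and excluded, with counts) when a record is entirely
paired or unpaired. Per-family reports average over sequences within
each family and then take the **unweighted** mean across families — a
1283-member family counts no more than a 15-member one, which is what
makes the overall rows of per-family tables reproducible from their
printed values. Differences between conditions use two-tailed paired
t-tests at the 0.05 level, uncorrected across the nudge grid (matching
the analysis this package reproduces); zero-variance differences are
flagged degenerate rather than silently dropped.

The homology audit encodes each structure as an ordered rooted tree —
pairs become internal nodes, unpaired bases leaves under their innermost
enclosing pair, children in 5'→3' order — after stripping pseudoknots to
the maximum-cardinality non-crossing subset of pairs (computed by
dynamic programming; deterministic and structure-maximizing). Distances
are Zhang–Shasha ordered tree edit distances with unit costs, checked in
the tests against an independent textbook forest recursion, and
summarised as the mean over test records of the distance to the nearest
training record. All-vs-all distance is quadratic in corpus size, so the
audit subsamples (seeded) above configurable caps and reports the sizes
used. The specific tree encoding and costs are this package's own
instrument choices: audit numbers are comparable across splits computed
here, not against figures produced by other encodings.

## What the synthetic corpus does and does not show

`generate_corpus(default_corpus_specs())` builds six families × 40
members, lengths 60–200 nt. Each family draws one random non-crossing
consensus structure (recursive stem/loop construction: geometric stems
of mean 4 pairs, loops uniform on 3–8 nt, branching probability 0.2 —
constants calibrated so the mean paired fraction over 500 draws at
length 100 sits near 0.5, inside the 0.3–0.8 band typical of real
structures) and one consensus sequence; every member keeps the exact
consensus pair set while a fraction of its positions is re-drawn under
the same canonical-pair constraints. The default resample fraction of
0.25 yields ~59% mean pairwise identity — the conserved-structure /
diverged-sequence regime that makes intra-family evaluation leaky.
Pair types favour G–C (weights 0.35/0.35/0.12/0.12/0.03/0.03) so the
reference folder's MFE structures stay close to the consensus, giving
the pseudo-energy stage signal to improve on.

Structure conservation within a family is *exact* here, with no
per-member drift — the cleanest instantiation of the premise, making the
intra/inter contrast maximally interpretable. Real corpora add
covariation, indels, length variation within families, pseudoknots in
references, and family sizes spanning two orders of magnitude; none of
these are emulated. Passing the packaged experiments therefore shows
that the *pipeline and the benchmark logic* behave as designed, and that
the memorization failure mode is real and reproducible — it does not
certify performance numbers on any real corpus.

## Problem sizes and numerical choices

The packaged experiments and the acceptance script train the desk-scale
configuration `shadow_config_desk()` — 32 filters, 128 dense units,
padding 256, batches of 64, at most 20 epochs — on the 240-record
fixture; a full benchmark (11 trainings) completes in a few minutes on
one CPU. The full-scale architecture (67,572,224 parameters) remains the
package default, is constructed and parameter-counted in the tests, and
trains identically, just slower. Other numerics: BCE probabilities are
clamped at 1e-12; early stopping requires a strict validation-loss
improvement of 1e-9; DP traceback treats energies within 1e-9 as tied;
the nudge grid builder requires the step to divide the range to within
1e-9 and rounds grid values to 10 decimals so the endpoints are exact
to hundredths. Degenerate inputs are signalled, not patched: constant
vectors refuse min–max normalization, single-class shadows yield NA
AUCs, zero-variance t-tests are flagged.

## Known limitations

The reference folder's energy model is intentionally minimal — no
stacks, loops penalties or dangles — so its baseline F1 sits well below
what a nearest-neighbour engine achieves; conclusions should rest on
*contrasts* (intra vs inter, steered vs baseline), which is how every
packaged experiment is framed. The external backend treats the engine's
stack-level ΔG′ accounting as a black box. Pseudoknots are preserved in
records, shadows and scoring, but no backend predicts them, and the
audit removes them before tree encoding. Rfam-clan-aware splitting —
the next rigor step beyond family-fold — is out of scope.
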