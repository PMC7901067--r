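---
title: "Adaptive training data for GAN-based molecular search: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive training data for GAN-based molecular search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Generative adversarial networks trained on a fixed molecular library tend to
mode-collapse: after an initial burst the generator mostly re-emits molecules
it has already produced, which defeats the purpose of using it to *search*
chemical space. `molevolve` implements a genetic-algorithm view of GAN
training that counteracts this: the training set is treated as a population,
and between training intervals chemically valid, never-seen-before generated
molecules *replace* population members — uniformly at random, or guided by a
molecular score so that only strictly better candidates displace the weakest
incumbents. Optionally, generated molecules are first *recombined* with
population members by adjacency-matrix slice crossover. As the data adapts,
the generator is continually pulled toward regions adjacent to what it has
already discovered, sustaining novel-molecule production and shifting the
score distribution of its output upward.

# Molecular representation

A molecule is a square categorical matrix of edge length `max_atoms`:
diagonal entries code the atom type (empty slot, C, N, O, F), off-diagonal
entries the bond order (none/single/double/triple). Hydrogens are implicit;
aromatic systems are kekulized on encoding, so three bond orders suffice.
The discriminator sees a flattened one-hot expansion with one 5-channel block
per diagonal cell and one 4-channel block per unordered atom pair — each pair
owns a single block, so any discretized output is symmetric by construction,
and raw generator output is discretized by per-cell argmax with ties broken
toward the lowest channel index (deterministic across platforms).

Decoding applies the package's sanitization rules: at least one atom, every
atom within its neutral default valence (C 4, N 3, O 2, F 1), and a single
connected component — disconnected graphs are invalid, with no
largest-fragment rescue, which is the strictest reading of "the toolkit can
build the molecule". For neutral C/N/O/F molecules these rules coincide with
standard toolkit sanitization; every accepted molecule is additionally
round-tripped through OpenBabel to produce its canonical SMILES, so nothing
unparseable can slip through. Canonical SMILES (stereo and isotope labels
stripped) define molecular identity throughout, in particular for novelty.

# The GAN

Both networks are 4-layer fully connected maps (three rectified hidden
layers plus a linear output): the generator takes an 8-dimensional standard
normal latent vector to the one-hot layout, the discriminator maps the
layout to one real score, trained with the non-saturating form of the
standard minimax loss and Adam at learning rate 1e-4. Layer widths
(generator 64-128-256, discriminator 256-128-64) are configuration choices,
as are the batch size and the activations — only the depth, latent dimension,
loss and learning rate are fixed by the method being reproduced.

Two output-representation choices matter enough to be options:

* the generator's final layer applies a **per-cell softmax** over each
  channel block (`output = "softmax"`, the default), so its output lives on
  the same per-cell simplex as the one-hot data rather than on an unbounded
  linear scale;
* generated samples are **hardened to one-hot** (per-cell argmax, gradient
  passed straight through) before the discriminator sees them
  (`hard_fakes = TRUE`, the default). The discriminator is described as
  receiving "the one-hot representation of the adjacency matrix", and
  comparing real and generated molecules in the same representation is both
  the faithful reading and empirically necessary at small scale: with soft
  fakes the discriminator separates real from generated by output softness
  alone and the generator never enters the chemically valid region.

# Scores

* **Drug-likeness (QED)** — the weighted-geometric-mean desirability score
  over eight properties (molecular weight, Crippen logP, H-bond acceptors
  and donors, polar surface area, rotatable bonds, aromatic rings,
  structural alerts), using the published desirability-function constants.
  logP and TPSA come from OpenBabel; MW, HBD, HBA, rotatable bonds and
  aromatic rings are computed natively on the graph (HBA with a simplified
  acceptor rule: every O; N except amide-, non-aromatic-imine- and
  pyrrole-type). The alert count uses a compact panel of 20 substructure
  predicates — the subset of the reference alert collection that can occur
  in neutral C/N/O/F chemistry, where it accounts for essentially all
  firings. Against the reference implementation this QED agrees to
  |difference| < 0.05 (mean ~0.01) on this chemical space.
* **Synthesizability (SA)** — an Ertl-style score: a fragment-familiarity
  term over radius-2 circular atom environments minus size, spiro,
  bridgehead and macrocycle penalties, mapped to the conventional 1-10 scale
  and normalized to [0, 1] (higher = easier) as in prior molecular-GAN work.
  The reference fragment-frequency table is replaced by a calibration
  counted on a reference corpus — by default the run's initial training
  population — so scores are comparable within a run; the calibration object
  is part of the scorer configuration.
* **Solubility** — Crippen logP clipped to [-2.12178879609, 6.0429063424]
  (the clamp constants conventional in this lineage of work, recorded in the
  score configuration) and rescaled to [0, 1].
* **Fingerprints** — Morgan-style circular fingerprints (radius 2, 2048
  bits) computed by iterative neighbourhood hashing on the graph, with
  Tanimoto distance for nearest-training-neighbour analyses.

Scores are intrinsic to a molecule and computed once, at insertion.

# The evolutionary layer

Per training epoch the generator emits `samples_per_epoch` graphs; with
recombination enabled, a fraction (default half) is crossed with population
parents first. Crossover copies the parent matrix and overwrites its first
`k` rows and columns with the generated matrix, `k` uniform on 1..L, drawn
per pair; for guided runs parents are drawn with probability
`softmax(scores)` over the raw metric scores (no temperature), otherwise
uniformly. Candidates — valid, novel after canonicalization, deduplicated —
pool over the interval (5 epochs by default) and are applied to the
population at the interval boundary:

* **control** — no replacement (the traditional-GAN baseline);
* **random** — each candidate overwrites a uniformly chosen slot; colliding
  candidates are allowed, the last write wins;
* **guided** — incumbents sorted ascending, candidates descending; the best
  candidate replaces the weakest incumbent only if strictly better, stopping
  at the first failure. The population's sorted score vector is therefore
  pointwise non-decreasing over intervals, which is asserted in the tests.

Novelty is counted against the original training set plus everything
produced so far; molecules displaced from the population stay in the ledger,
so re-generating a replaced molecule never counts as new. (Whether "the full
training set" means the original or the current data is immaterial under
this superset convention, since replacements come from produced molecules.)
Crossover products pass through the same validity/novelty filter as direct
samples.

# Reduced-scale study conditions

The desk-scale experiment used in the tests and in `scripts/acceptance.R`
runs populations of 2000 fixture molecules (`max_atoms = 9`), 10 intervals
of 5 epochs, 500 generator samples per epoch and 3 replicates per condition
(seeds offset by replicate index). Two harness choices adapt the method to
this scale, both fixed here and used everywhere:

* **batch size 32** — an epoch over 2000 molecules is ~60 optimizer steps
  rather than the ~780 a 100k-molecule epoch provides; the smaller batch
  restores enough steps per interval for the generator to track
  training-data updates at the method's learning rate (1e-4);
* **burn-in of 60 epochs** — plain training before interval bookkeeping
  starts, so the generator is already in its productive regime (a stable
  few-percent valid fraction) when sampling begins, mirroring what happens
  inside the first full-scale interval. The burned-in generator states are
  produced once per replicate seed (`gan_pretrain`) and shared across the
  strategies being compared, so every condition starts from the identical
  trained generator.

The fixture generator emulates the essential structure of a small-molecule
training set: heavy-atom counts skewed toward the atom budget, element
frequencies approximating a C-rich organic library (C 0.70, N 0.12, O 0.16,
F 0.02), a random spanning tree for connectivity plus occasional
ring-closing edges, mostly single bonds, rejection-sampled through the
sanitization gate and deduplicated. What it does **not** emulate: the strong
structural regularities of enumerated chemical databases (functional-group
statistics, ring-system distributions, near-exhaustive coverage of the small
chemical space). The last point matters for interpretation: a real ~100k
library nearly exhausts the ≤9-heavy-atom C/N/O/F space, so a fixed-data GAN
plateaus partly because little *remains* to discover, whereas a 2000-molecule
fixture leaves the space mostly empty. Reduced-scale runs therefore
demonstrate the *ordering* of strategies (replacement sustains novelty and
raises produced-molecule scores relative to control) rather than the
absolute magnitudes or curve shapes of a full-scale run.

# Numerical choices and degenerate inputs

* Argmax ties in discretization go to the lowest channel index; softmax uses
  max-subtraction; the binary-cross-entropy terms use the stable softplus
  form; all randomness flows through R's seeded RNG (replicate seed =
  master seed + replicate index), so a fixed configuration reproduces every
  table bitwise.
* Guided replacement with ties is a no-op (strict inequality); an empty
  candidate pool leaves the population untouched; `n_intervals = 0` returns
  empty tables; an all-invalid sample batch leaves the ledger unchanged.
* Two all-zero fingerprints have Tanimoto distance 0; histogram bins are
  left-closed right-open with the terminal bin closed.
* The fixture generator aborts with a classed error when its attempt budget
  is exhausted (tiny atom budgets or element sets).

# Known limitations

* Validity checking and encoding are restricted to neutral C/N/O/F
  molecules with kekulizable bonds; charged species are rejected at
  encoding.
* Aromaticity perception is a simplified Hückel rule on the smallest set of
  smallest rings; exotic fused systems may be classified differently than by
  a full toolkit (irrelevant below ~10 heavy atoms, rare below 20).
* The SA calibration is corpus-relative; absolute SA values are not
  comparable across scorers, only within one.
* Full-scale reproduction (100k molecules, many hundreds of epochs) is
  supported by the same code paths (`samples_per_epoch = 10000`, batch size
  128) but is a multi-hour computation and not part of the test surface.
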