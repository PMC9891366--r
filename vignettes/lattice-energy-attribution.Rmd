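---
title: "Attributing molecular-crystal lattice energies to functional-group motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing molecular-crystal lattice energies to functional-group motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticemotifs)
```

## The problem

The stability of an organic molecular crystal is summarized by its lattice
(binding) energy

$$\Delta_c \;=\; E_c \;-\; \sum_m E_m,$$

the total energy of the periodic crystal minus the energies of its relaxed
gas-phase molecules; negative values mean the crystal binds.  Per atom we
write $\delta_c = \Delta_c / n_c$ and work in kJ per mol of atoms
throughout.  Crystal engineers reason about stability in terms of
functional-group motifs — carboxylic-acid dimers, water networks, stacked
aromatic rings — but a quantum-chemical total energy offers no such
decomposition.  This package builds one from data: a linear model of
$\delta_c$ on atom-centered structural descriptors, whose predictions
decompose exactly into per-atom contributions that can then be averaged
over SMARTS-defined motifs and organized on supervised latent-variable
maps.

## Descriptors and the remnant representation

Each atom is described by a rotation-invariant three-body power spectrum
(a SOAP-style descriptor): the neighbor density within a cutoff
$r_\mathrm{cut}$, each neighbor smeared by a Gaussian of width
$\sigma_\mathrm{atom}$, is expanded in an orthonormalized Gaussian radial
basis times real spherical harmonics and contracted per species pair into
$p_{nn'l}$.  The descriptor of any collection of atoms (molecule, crystal,
motif) is the plain average of its atoms' descriptors, so collection
descriptors of a crystal, its molecules and its atoms are consistent by
construction (this identity is asserted to machine precision in the test
suite).

Because the lattice energy is a *difference* of phases, the model is built
on the **remnant descriptor**

$$x^{(s-g)} = x^{(s)} - x^{(g)},$$

the solid-phase minus the gas-phase descriptor of the same atoms, aligned
atom by atom through the crystal-to-molecule index maps.  The remnant
vanishes for an atom whose environment is unchanged upon crystallization
and therefore concentrates exactly on conformational change plus
intermolecular packing.  Alternatives kept for comparison are the solid
descriptor alone, the gas descriptor alone, and the concatenation of both.

Tunable descriptor parameters (defaults in parentheses): cutoff
$r_\mathrm{cut}$ (5 Å), radial basis size $n_\mathrm{max}$ (6), angular
band limit $l_\mathrm{max}$ (4), density smearing $\sigma_\mathrm{atom}$
(0.3 Å), per-atom L2 normalization (on).  These defaults are deliberate
desk-scale choices, not a claim of equivalence with any particular
published feature space; every result carries the configuration hash so
descriptor sets from different configurations cannot be mixed silently.
Synthetic studies in this vignette and in the tests use smaller bases
($n_\mathrm{max}$ 2–3, $l_\mathrm{max}$ 2–3, $r_\mathrm{cut}$ 4 Å) — the
properties being checked (invariances, recovery, ordering) do not depend
on basis richness, and the smaller basis keeps a full study in minutes on
one core.

## Energy models

Per-atom total energies are dominated by composition, so before any
descriptor regression a **composition baseline** — a least-squares fit of
$e_\sigma = E_\sigma/n_\sigma$ on element count fractions — is subtracted.
Because a crystal and its constituent molecules share one composition,
any such baseline cancels exactly in $\Delta_c$; the tests verify that
shifting all energies by arbitrary per-element constants changes no
lattice-energy prediction.

The regression itself is the linear ansatz $y = x_\sigma w$, fitted by
ridge regression with the SVD path: features and targets are centered on
the training set (the intercept), and the regularization strength is
chosen to minimize 5-fold cross-validated RMSE on a logarithmic grid
$\lambda \in \{0\} \cup 10^{-12 \ldots 2}$ in half-decade steps.  Including
$\lambda = 0$ (minimum-norm least squares through the pseudo-inverse)
matters: on noise-free synthetic data with planted linear energies the
cross-validation selects it and held-out predictions reproduce the planted
lattice energies to better than $10^{-6}$ kJ per mol of atoms.  Folds are
assigned round-robin in row order, so fits are deterministic.

Two routes to the lattice energy are provided:

* **combined** — independent models of the crystal energy (solid
  descriptors) and the molecular energy (gas descriptors), subtracted;
* **direct** — a single model of $\delta_c$ on any of the four feature
  spaces (solid, gas, concatenated, remnant).

Training sets are picked by farthest point sampling (greedy max-min in
feature space, deterministic given the start index), mirroring the
practice of training on maximally diverse structures and testing on a
random remainder.

## From predictions to atoms and motifs

Linearity gives the decomposition for free: $\delta_a = x^{(s-g)}_a w$,
and the mean over a structure's atoms *equals* the structure prediction
(machine-precision contract, tested).  The intercept, when present, is
shared equally by all atoms so the contract survives centering.

Raw $\delta_a$ values are gauge-like — the model only constrains sums, so
bonded atoms can carry large canceling contributions.  The **Gaussian
filter** suppresses this: each atom's raw contribution is redistributed
over its neighborhood within 2 Å with weights
$f(a,b) = \exp(-d_{ab}^2 / 2\varsigma^2)$, $f(a,a) = 1$, normalized over
the recipients of each donor (a column-stochastic smoothing matrix).  Two
numerical points are deliberate:

* the exponent is negative — a kernel growing with distance would be
  meaningless — and the docs flag this prominently;
* normalizing over each donor's recipients is one consistent reading of an
  under-specified normalization; it is the reading that conserves
  $\sum_a \tilde\delta_a = \sum_a \delta_a$ *exactly*, which is the stated
  contract ("regularize without changing the regression results"), and the
  tests hold it to $10^{-10}$ relative on every fixture.  For two mutually
  bonded atoms with contributions $(x, -x)$ the filter has the closed form
  $\pm x (1-g)/(1+g)$, $g = e^{-d^2/2\varsigma^2}$, used as a unit oracle.

The filter width $\varsigma$ defaults to 0.5 Å — below the 2 Å graph
cutoff, strong enough to quench nearest-neighbor cancellation; the
reference value being unknown, it is configurable.

A **motif contribution** is the arithmetic mean of the filtered
contributions over the atoms matched by a SMARTS pattern (times 3 for the
conventional per-water-molecule value).  Because motifs overlap and are
averages, motif contributions do not sum to the crystal's lattice energy —
this caveat is stated wherever they are reported.  SMARTS matching runs
through RDKit (a bundled Python helper; no R substructure matcher exposes
atom-level matches), with symmetry-duplicate matches collapsed and, by
default, matched heavy atoms grown with their bonded hydrogens.  The
shipped motif table is a reconstruction of the common classes (water,
carboxylic acid, nitro/nitroso, amines, amide, ether, alkyl groups,
benzene-like rings, azoles, imide) and is an editable TSV — motif *counts*
against any particular curated dataset are explicitly not a reproduction
target.

Hydrogen bonds are detected geometrically: X–H···A with H···A < 2.5 Å and
an X–H···A angle above 150°, donors and acceptors N and O by default
(sulfur is off by default and switchable), minimum-image distances,
intermolecular only by default.  "Angle at the hydrogen" is our reading of
the criterion; it is the standard hydrogen-bond angle.

## Latent maps (PCovR)

Motif environments are arranged by principal covariates regression: with
standardized motif-averaged remnant features $X$ and ridge predictions
$\hat y$ of the motif contributions, the latent space is the leading
eigenspace of

$$G = \alpha\, XX^\top + (1-\alpha)\, \hat y \hat y^\top .$$

At $\alpha = 1$ this is exactly PCA (tested against `prcomp` to $10^{-8}$);
at $\alpha = 0$ the single component is perfectly correlated with the
prediction.  The supervised block uses the ridge *predictions* rather than
the raw targets, per the standard formulation.  The stored projection is
linear, so training rows map onto their own scores, the training mean maps
to the origin, and out-of-sample motifs (e.g. a new polymorph) can be
placed on an existing map.  Determinism is enforced by fixed eigenvalue
ordering and a sign convention (largest-magnitude loading positive).
Defaults $\alpha = 0.5$ and $k = 4$ components; similarity queries use the
Euclidean distance over *all* retained covariates — a point extremal in a
plotted 2-D slice need not be extremal in full-space distance, and the
tests construct exactly such a counter-example.  No trace rescaling is
applied to the two blocks of $G$, so the meaning of $\alpha$ depends on
the relative scales of $X$ (standardized) and $y$; this keeps the
$\alpha = 1$ limit exactly PCA.

## The synthetic generator: what it emulates, and what it does not

Real curated datasets of DFT-quality crystal and molecular energies cannot
be redistributed or recomputed at desk scale, so the package ships a
generator whose datasets have the same *statistical shape* as such a
study: total energies dominated by composition (per-element baselines of
order $-10^2$ to $-10^3$ kJ per mol of atoms), and a small lattice-energy
signal (SD scaled to 2 kJ per mol of atoms) riding on top.  Concretely,
molecules drawn from small rigid templates (water, formaldehyde, ammonia,
methane) are placed with random rigid rotations in cubic periodic boxes
(side 5.0–6.5 Å per 2–4 molecules, rejection-sampled against a 1.8 Å
minimum intermolecular contact), each instance receives a Gaussian
conformational distortion of 0.15 Å whose topology is checked against the
covalent bond graph, and the gas-phase reference of every molecule is the
*same* conformer.  Per-atom energies are a composition term plus a fixed
linear function of that atom's descriptor; Gaussian noise is added last.

Two consequences are designed in:

* the planted $\delta_c$ is *exactly* linear in the remnant descriptor
  (conformational terms cancel atom by atom), making noise-free recovery a
  sharp correctness probe of the whole pipeline;
* the conformational jitter feeds the solid-phase descriptor with
  variation that is irrelevant to the lattice energy but inseparable from
  packing, so the feature-space comparison reproduces the qualitative
  ordering remnant ≤ concatenated ≤ solid-only, with gas-only far worst —
  for the same physical reasons as on real data.  The jitter amplitude,
  box sizes and the 0.2 kJ per-mol-of-atoms observation noise used in the
  ordering study were chosen once so that this ordering is the systematic
  outcome across generator seeds, and are fixed as the generator defaults.

What the generator does *not* emulate: real dispersion-bound energetics
(an optional Lennard-Jones-like "hard mode" term exists purely to probe
model misspecification), space-group symmetry, polymorph statistics, or
chemical diversity beyond C/H/N/O.  Passing the synthetic studies
therefore demonstrates pipeline correctness — descriptors, alignment,
fitting, decomposition, filtering, mapping — not predictive accuracy on
real crystals.

## Problem sizes and determinism

The study-scale checks use 200 crystals (training 120–150 by farthest
point sampling, the rest held out), 5 repeated noise draws where spread
matters, and the reduced descriptor bases noted above; the full test suite
runs in a few minutes on one core.  All generator randomness flows from a
single integer seed (the global RNG state is saved and restored), fits are
deterministic, and rerunning any pipeline step with an unchanged
configuration hash reuses its outputs.

## Known limitations

* Bond perception uses covalent radii with a 1.2 scale factor; the rule a
  given curated dataset used to split crystals into molecules is unknown,
  so ours is a replacement, not a reconstruction.
* CIF support is minimal (cell, symmetry operators, fractional sites) —
  enough for P1 expansion of small-molecule files, not a general CIF
  parser.
* The descriptor hyperparameters and SMARTS table are reconstructions;
  numeric equivalence with any specific published feature space or motif
  census is out of scope.
* Motif contributions inherit the gauge ambiguity of any atom-wise energy
  decomposition; the filter regularizes but does not remove it.  Only
  sums over whole structures are gauge-free.
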