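# latticemotifs

Data-driven attribution of molecular-crystal lattice energies to
functional-group motifs, in R.

## The problem

The stability of an organic molecular crystal is measured by its lattice
(binding) energy,

    Delta_c = E_c - sum_m E_m        (kJ/mol; negative = binding)

the total energy of the periodic crystal minus the energies of its relaxed
gas-phase molecules.  Practitioners reason about stability in terms of
functional-group motifs — carboxylic-acid dimers, water networks, stacked
rings — but a total energy carries no such decomposition.  This package
builds one from data:

1. **Atom-centered descriptors.**  Every atom gets a rotation-invariant
   three-body power spectrum (SOAP-style) of its Gaussian-smeared neighbor
   density; the descriptor of any collection of atoms is the mean over its
   atoms.  The lattice-energy model uses the **remnant** representation
   `x^(s-g) = x^(s) - x^(g)` — solid minus gas phase, aligned atom by atom —
   which vanishes wherever crystallization changes nothing and so
   concentrates on conformational change plus intermolecular packing.
2. **Linear energy models.**  Composition-baselined, cross-validated ridge
   regressions `delta_c = x^(s-g)_c w` (per atom, kJ per mol of atoms),
   with farthest-point-sampled training sets; solid-only, gas-only,
   concatenated and combined two-model variants are kept for comparison.
3. **Per-atom attribution.**  Linearity decomposes each prediction exactly
   into atomic contributions `delta_a = x^(s-g)_a w`, which are then
   smoothed by a conservation-preserving Gaussian filter over 2 Å
   neighborhoods (the total is unchanged to machine precision).
4. **Motifs and maps.**  SMARTS-matched functional groups (via RDKit)
   average the filtered contributions into motif energies; geometric
   hydrogen-bond detection (H···A < 2.5 Å, X–H···A angle > 150°) supplies
   interpretive properties; principal covariates regression (PCovR) lays
   motif environments out on supervised latent maps with out-of-sample
   projection and full-space similarity search.

A synthetic-crystal generator with planted, descriptor-linear atom
energies makes the entire pipeline testable end to end without any
external dataset.

## Worked example

```r
library(latticemotifs)

# a small synthetic study: 40 toy molecular crystals with planted energetics
spec <- synthetic_spec(seed = 42, n_crystals = 40, noise_sigma = 0.2)
ds <- generate_synthetic(spec)
#> <synthetic_dataset: 40 crystals, templates water/formaldehyde/ammonia,
#>  noise sd 0.2, sd(delta_c) 1.986>

# remnant-descriptor model of the per-atom lattice energy
X <- do.call(rbind, lapply(ds$remnants, function(r) r$collection$x))
y <- ds$energy$delta_c
train <- fps_select(X, 30)
test  <- setdiff(seq_along(y), train)
model <- fit_energy_model(X[train, ], y[train], feature_space = "remnant")
evaluate_model(predict(model, X[test, ]), y[test])
#> # A tibble: 1 × 4
#>    rmse   mae sd_truth     n
#>   <dbl> <dbl>    <dbl> <int>
#> 1 0.969 0.846     1.32    10
```

The held-out RMSE (0.97 kJ per mol of atoms, against a target spread of
1.32) is what 30 training crystals buy; at the study scale used by the
acceptance script (200 crystals) the same model reaches about 0.37.  Per-atom
and per-motif attribution of one held-out crystal:

```r
s <- ds$records[[test[1]]]$crystal
att <- atomic_contributions(ds$remnants[[test[1]]], model, s) |>
  gaussian_filter(s)
att
#> <attribution 'synth_0002': 10 atoms, prediction 1.1025 kJ/mol-atom,
#>  filtered (varsigma = 0.5)>
head(tidy(att), 4)
#> # A tibble: 4 × 5
#>   structure_id  atom element delta delta_filtered
#> 1 synth_0002       1 O        3.01         3.98
#> 2 synth_0002       2 H        2.62         2.61
#> 3 synth_0002       3 H        8.23         7.26
#> 4 synth_0002       4 O        1.18         0.0222
```

`delta` is the raw atomic contribution and `delta_filtered` its smoothed
value; their mean equals the crystal's predicted per-atom lattice energy
exactly, and their sums agree to machine precision.  Matching the default
SMARTS motif table on the crystal's molecules and averaging the filtered
contributions per match:

```r
#>   molecule_id pattern  n_atoms    eps
#> 1 mol1        water          3  4.62
#> 2 mol2        water          3 -0.428
#> 3 mol3        carbonyl       4 -0.387
```

(`eps` in kJ per mol of atoms; multiply a water motif by 3 for the
per-water-molecule convention.  Positive values resist crystallization —
this particular toy crystal is planted as unstable.)  `fit_pcovr()`,
`pcovr_map_points()` and `similar_motifs()` then arrange motif
environments on a latent map and rank their similarity; `run_featurize()`
→ `run_train()` → `run_attribute()` → `run_map()` chain the same steps
over a dataset directory with a YAML config (see
`inst/cli/latticemotifs.R` for the command-line wrapper).

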