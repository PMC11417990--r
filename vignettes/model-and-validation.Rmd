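---
title: "A pH-aware coarse-grained model for His-rich disordered proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A pH-aware coarse-grained model for His-rich disordered proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Histidine is the only standard residue whose side-chain pKa (~6.3 for the
free residue) sits inside the physiological pH range. Below the pKa the
imidazole ring is protonated (His⁺, +1 e, a cation); above it the ring is
neutral (His⁰, a π system). By the Henderson–Hasselbalch relation about 93%
of free histidines are neutral at pH 7.4 (`his_neutral_fraction(7.4, 6.3)`).
The two states interact differently: His⁺ repels other cations and attracts
acidic residues electrostatically and can act as the cation in cation–π
pairs; His⁰ can stack with aromatics (π–π) and act as the π partner for
Arg/Lys (cation–π). Residue-level coarse-grained (CG) models for
intrinsically disordered proteins (IDPs) usually collapse this into one
"average" His bead with a fractional charge (+0.375 e or +0.5 e), which
cannot respond to pH and, more subtly, averages away the short-range
His⁰–His⁰ and His⁰–Arg attractions. For His-rich IDPs those terms matter:
they compact the chain at high pH, and removing them decouples the computed
size from the His content.

`idpsim` implements a 21-type CG model that treats His⁰ and His⁺ as
separate residue types, plus the ablation ("control") and averaged-His
modes needed to isolate what the two-state treatment adds.

## The model

One bead per residue, centred on Cα, mass 1 (reduced). The potential is

E = E_bond + E_angle + E_dihedral + E_contacts + E_elec

* **Bonds**: `k_b (d - d0)^2` with `d0 = 3.8` Å (the Cα–Cα virtual bond)
  and `k_b = 20` energy/Å² — note the convention without the ½ factor.
* **Angles**: `k_a (θ - θ0)^2` with `θ0 = 2.12` rad and a soft
  `k_a = 2` energy/rad², appropriate for a flexible disordered chain.
* **Dihedrals**: present only for four-bead windows containing a proline,
  `K (1 - cos(φ - φ0))` with `K = 1`, `φ0 = -1.3` rad. Non-proline
  windows carry no dihedral term.
* **Contacts**: every pair with sequence separation `|i - j| > 3`
  interacts through the Lennard-Jones 10-12 potential
  `ε_ij [5 (σ_ij/r)^12 - 6 (σ_ij/r)^10]`, whose minimum of depth `-ε_ij`
  sits exactly at the optimal distance `σ_ij`. `σ_ij` is the arithmetic
  mean of the two residue diameters unless a parameter file overrides a
  pair explicitly.
* **Electrostatics**: the same `|i - j| > 3` pairs interact through the
  Debye–Hückel screened Coulomb potential
  `B(κ) K_c q_i q_j exp(-κ r) / (ε_r r)` with `K_c = 332` kcal·Å/mol,
  `ε_r = 80`, `B(κ) = 1` by default. `κ` is computed from the ionic
  strength by the standard aqueous relation (`debye_kappa()`; 8.9 Å
  screening length at 120 mM, 300 K).

**Units.** Lengths are in Å. Energies are in reduced units chosen so that
the thermal energy at the 300 K reference temperature equals 0.45 — the
conventional reduced simulation temperature of this model family, i.e.
`T = 0.45` "is" room temperature. Electrostatics are evaluated in kcal/mol
and converted once by `kcal_to_reduced()` (≈ 0.755 reduced units per
kcal/mol). One MD step is nominally mapped to 50 fs.

### Protonation modes

`assign_protonation(sequence, mode)` resolves every plain `H`:

| mode | His type | His charge | notes |
|---|---|---|---|
| `high_pH` | His⁰ | 0 | full two-state model, pH > pKa |
| `low_pH` | His⁺ | +1 | full two-state model, pH < pKa |
| `control_high` | His⁰ | 0 | His⁰–His⁰ and His⁰–Arg contact ε zeroed |
| `control_low` | His⁺ | +1 | same ablation (inert at low pH) |
| `mpipi` | averaged H | +0.375 | single-His-type comparator |

Explicit `h0`/`h+` tokens in the input (or a per-position `overrides`
table) survive the mode, so mixed-protonation chains — e.g. protonating
only the first His of a peptide — are one argument away. The control modes
isolate the electrostatic consequence of the His charge state from the
His⁰-specific short-range terms; the averaged-His mode reproduces the
fixed-charge treatment that cannot respond to pH.

### His contact strengths by linear rescaling

The two contact strengths that distinguish the two-state model —
His⁰–His⁰ (π–π) and His⁰–Arg (cation–π) — are not free parameters. They
are produced by `calibrate_pair_strength()`: an ordinary least-squares
line is fitted from reference mean binding energies to the model's
existing strengths for the same interaction class (the π–π series
Phe–Phe, Phe–Tyr, Phe–Trp, Tyr–Tyr, Tyr–Trp, Trp–Trp; the cation–π series
Arg–Phe, Arg–Tyr, Arg–Trp) and evaluated at the His pair's reference
energy. The packaged reference series places His⁰–His⁰ at an energy
comparable to Phe–Phe and His⁰–Arg comparable to Arg–Phe, which is the
qualitative ordering reported by quantum-chemical binding-energy studies
of these side-chain dimers.

### The synthetic parameter set

The packaged parameter files (`inst/extdata/forcefield_*_synthetic.yaml`)
are a **synthetic** stand-in constructed for this package, not a published
table. Construction (see `data-raw/make_forcefield.R`):

* base strengths `ε_ij = 0.20 (λ_i + λ_j)/2` from a normalized hydropathy
  scale (Trp/Phe/Tyr high, Glu/Lys low);
* additive π–π enhancements among Phe/Tyr/Trp (~0.3 reduced units) and
  cation–π enhancements for Arg (strong), Lys (weak) and His⁺ (slightly
  above Arg, matching the reported ordering of His⁺–Phe vs Arg–Phe);
* His⁰ participates in π–π contacts with the standard aromatics; its
  His⁰–His⁰ and His⁰–Arg entries come from the calibration above;
* the averaged-His set keeps His–aromatic π contacts but has no His–His
  or His–Arg enhancement — reproducing the known weakness of averaged-His
  models for exactly those pairs;
* residue diameters are the standard CG van-der-Waals diameters
  (4.5–6.8 Å).

The overall scale (0.20) was fixed once, before any benchmark was
measured, by requiring a generic 50-residue chain of typical disordered
composition to approach the empirical Flory size `2.54 N^0.52` Å
(`data-raw/calibrate_scale.R`). A limitation of the pure 10-12 form is
that repulsion and attraction share `ε`, so a weakly attractive chain
cannot be pushed into a genuinely good-solvent regime: the generic chain
saturates roughly 10% below the Flory reference (17.5 Å vs 19.4 Å), and
the scale was frozen at the value that gets closest while keeping a
meaningful excluded-volume core.

## Dynamics

`simulate_chain()` integrates Langevin dynamics with the BAOAB
velocity-Verlet splitting; with `friction = 0` it reduces exactly to
plain velocity Verlet, which the energy-conservation tests exploit.
Defaults: `dt = 0.01` reduced time, `temperature = 0.45`,
`friction = 0.05` (low friction accelerates conformational sampling;
equilibrium ensembles are friction-independent, and the friction is
recorded in every trajectory's settings). Initial velocities are
Maxwell–Boltzmann at the set temperature; replicates
(`run_replicates()`) differ only in their seed, i.e. in initial
velocities and noise — the conventional replicate mechanism for this
model family. Chains start from the extended conformation, which is free
of steric overlap; a seeded random-walk start is available for analyses
that need conformational variety.

Numerical safeguards: the integrator aborts with the step index if a
coordinate becomes non-finite; the torsion force uses a floored normal
magnitude (sin² θ ≥ 1e-4) so that the well-known dihedral singularity at
three collinear beads stays bounded; contact interactions are truncated
at `3 σ_ij` and electrostatics at 35 Å, both chosen so that truncation
error is far below the test tolerances (verified against the no-cutoff
reference evaluator `reference_energy()`).

## Ensemble analysis

* `summarize_rg()` reports the arithmetic mean Rg over all
  post-equilibration frames pooled across replicates (a replicate-mean
  variant is available), with the error given by the standard deviation
  of per-replicate means.
* `delta_rg(low, high) = 100 (Rg_low - Rg_high)/Rg_high` %: positive
  means expansion on acidification.
* `contact_map()` uses a 10 Å cutoff and masks `|i - j| <= 3`;
  probabilities are symmetric and in [0, 1]. Difference maps and paired
  probability scatters (`contact_correlation()`, optionally restricted
  to aromatic/cationic/anionic/His residues) follow the field's
  conventions for model comparison.
* `mean_pair_energy()` sums the 10-12 contact energy over labeled pair
  classes (His–His, His–Arg, His–Phe/Tyr by default) per frame and
  reports mean ± SD across frames; a class with no pair in the sequence
  is absent, not zero.
* `rg_mse()` is the mean squared deviation (Å²);
  `rg_chi2()` weights each squared deviation by the squared experimental
  uncertainty and reduces to `n·MSE` with unit errors — the convention
  used when uncertainties are not reported.
* `flory_rg(N) = 2.54 N^0.52` Å and `normalized_rg_distribution()`
  (Freedman–Diaconis bins by default) support size comparisons against
  the generic-IDP expectation.

Indexing is 1-based everywhere a user sees it (contact maps, overrides),
matching sequence-position conventions.

## What the benchmarks do and do not show

The packaged benchmark sequences are the 24-residue His-rich salivary
peptide Histatin 5 (7 His, net +5 at high pH, +12 at low pH), its exact
48-residue tandem duplication, and His→Gln substitution variants
(`hst5_variant()`; the published variant series is described only by His
content and placement, so placement is exposed as a parameter rather than
hard-coding unverifiable sequences; the "Q" substitution is typed as
glutamine — neutral, similar size, hydrogen-bond capable — which is what
the one-letter code Q denotes).

The test suite validates, in increasing scale:

1. closed-form identities and oracle equivalence (analytic forces vs
   finite differences at 1e-5; vectorized vs brute-force energies at
   1e-10; LJ minimum `-ε` at `σ` for every pair; zero-friction energy
   drift < 1e-4 over 1e5 steps; harmonic-dimer equipartition
   `var(d) = k_B T / 2k_b` within 5%);
2. the Henderson–Hasselbalch neutral fraction (93% at pH 7.4);
3. scaled-down simulation benchmarks: the control-model Histatin 5
   ensemble settles near 13.5 Å — essentially the Flory size of a
   24-mer — and the two-state tandem repeat expands by ~50% from high to
   low pH. The tests use 3 replicates of 2–2.5 × 10⁶ steps (the
   acceptance script uses 2 × 10⁷ / 6 × 10⁶ steps), sizes chosen so the
   replicate scatter is well inside the stated ±15% tolerances; these
   are the package's validation problem sizes, far below the
   2 × 10⁸-step production protocol the model family uses.

Passing these benchmarks shows that the machinery — protonation typing,
energetics, integrator, estimators — is correct and that the synthetic
parameter set reproduces the qualitative physics (His⁰-driven compaction
at high pH, charge-driven expansion at low pH, near-Flory control
behavior). It does **not** validate the parameter values against real
SAXS data: the full 18-IDP mean-squared-error benchmark and the CPEB4
(448-residue, 9-His cluster) ensembles require the published experimental
Rg table and IDR sequences, which are accepted as user-supplied inputs
(`score_rg()` on a `name, computed, experimental[, error]` table; FASTA
via `read_fasta()`), plus cluster-scale sampling.

## Known limitations

* The parameter set is synthetic (see above); quantitative agreement
  with published per-protein Rg values is outside what it can claim.
* His protonation is static per run (all-His⁰ or all-His⁺, with manual
  per-position overrides); fluctuating, constant-pH protonation is out
  of scope.
* Single chains only — no multi-chain or condensed-phase systems, no
  periodic box.
* `ε` couples repulsion and attraction in the 10-12 form: pairs with
  `ε = 0` (the control ablation) also lose their excluded-volume core,
  and weakly attractive chains sit slightly below the empirical Flory
  size (by ~10% for a generic 50-mer).
* `B(κ)` defaults to 1 (point-charge Debye–Hückel); a salt-dependent
  coefficient can be supplied through the parameter file.
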