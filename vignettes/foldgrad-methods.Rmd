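---
title: "foldgrad: a differentiable knowledge-based protein force field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foldgrad: a differentiable knowledge-based protein force field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldgrad)
```

## The model

`foldgrad` estimates the conformational energy of a protein (or complex)
as the sum of eleven knowledge-based interaction and stabilisation
classes, and — the point of the package — carries a closed-form analytic
gradient of that sum with respect to every atom coordinate. The gradient
makes the energy usable as an objective for gradient-based structure
relaxation over Cartesian coordinates or over torsion angles, and as a
differentiable physics penalty inside larger pipelines.

The eleven classes, per residue and in kcal/mol:

1. **Hydrogen bonds.** For each donor hydrogen H and acceptor A within
   3.5 Å, `E = w_hb · f_dist(d) · f_DHA(θ) · f_lp(φ)`, with `f_dist` a
   negative Gaussian well of depth 1 centred at the optimum H···A
   distance of 1.9 Å (width 0.25 Å), `f_DHA = ((1 − cos θ)/2)^3` a cosine
   power on the donor–H···acceptor angle (optimum linear) and `f_lp` a
   Gaussian factor on the H···A–antecedent angle around the acceptor's
   hybridisation optimum (120° sp2, 109.5° sp3, width 35°). Each hydrogen
   is assigned to (essentially) its best acceptor through a soft-min with
   temperature 0.1 kcal/mol, so the assignment itself is differentiable;
   the temperature leaves a residual of order 10⁻⁴ relative to a hard
   minimum.
2. **Electrostatics.** Screened Coulomb,
   `E_ij = 332 · q_i q_j / (ε d_ij) · exp(−d_ij K)`, over charged-atom
   pairs within 12 Å, excluding same-residue and 1–2/1–3 bonded pairs.
   `K = sqrt(8π e² N_A I / (1000 k_B T))` is the Debye–Hückel parameter
   evaluated in CGS units and converted to Å⁻¹; at I = 0 it vanishes and
   the interaction is unscreened. (The textbook screening constant has
   the solvent dielectric inside the root; the form used here follows
   the convention of the empirical potentials this term descends from,
   giving a somewhat shorter screening length.) Distances below 10⁻³ Å
   are clamped (the clash term owns that regime).
3. **Disulfide bonds.** SG–SG pairs within 2.5 Å score
   `−w_ss · g(d) · (1 + sin² χ_SS)/2` with `g` a Gaussian centred at
   2.05 Å (width 0.15 Å) and `χ_SS` the CB–SG–SG–CB dihedral (optimum
   ±90°). The distance Gaussian multiplies the geometry factor so the
   term decays smoothly to zero at the pair cutoff; the minimum at ideal
   geometry is exactly −w_ss.
4. **Polar** and **5. hydrophobic solvation.** Residue-type transfer
   coefficients times the residue-level solvent exposure: exposed polar
   residues stabilise (negative coefficients), exposed hydrophobic
   residues destabilise (positive coefficients).
6. **Van der Waals.** Residue coefficients (negative) realised in
   proportion to atom burial: `c_vdw(type) · mean(1 − exposure(atom))`.
7. **Clashes.** For every atom pair within 5 Å — excluding covalently
   bonded pairs (except the disulfide bond itself), angle-rigid 1–3
   pairs, rigid units (aromatic rings, the proline Cδ against the
   preceding carbonyl) and same-residue backbone pairs — the contact gap
   `g = d − (R_i + R_j)` is compared with its contact group's fitted
   correction `t_g`, and pairs tighter than the correction pay
   `w · exp(10 · (t_g − g))`, exactly `w` on the threshold. The six
   groups are: same-residue, hydrogen-bond pairs, disulfide pairs,
   consecutive-residue backbone pairs, donor–acceptor pairs not forming a
   hydrogen bond, and everything else.
8. **Backbone entropy.** `w1 · (−ln KDE_ω(ω)) + w2 · (−ln KDE_t(φ, ψ))`
   per residue, with a 1-D periodic density for ω (bimodal at ±180°, as
   trans peptides dominate the reference data) and per-residue-type 2-D
   densities over (φ, ψ). Masked angles (termini, missing atoms)
   contribute nothing.
9. **Side-chain entropy.** An amino-acid-specific cost S(type) scaled by
   side-chain burial, `S · (1 − (1 − g) · exposure_sc)`, where the gate
   `g` rises to 1 when the side chain is locked by interactions. Each
   interaction class has its own smooth channel — hydrogen-bond magnitude
   (threshold 0.3 kcal/mol, temperature 0.08), attractive electrostatics
   (threshold 1.0, temperature 0.25) and disulfides (threshold 0.5,
   temperature 0.1) — and the channels combine as
   `g = 1 − Π(1 − g_x)`, so any one firing channel forces the full
   entropy cost, matching the qualitative rule that hydrogen bonds,
   strong electrostatic pairs or disulfides each suffice.
10. **Peptide-bond violation.** For every peptide bond, the squared
    standardised deviations of the CA–N–Cp angle, the CAp–Cp–N angle and
    the N–Cp bond length from Gaussians fitted on the reference set,
    summed and halved. The constant normalisation offset
    `Σ ln(σ√(2π))` is removed so the penalty is exactly zero at the
    means — a reporting convention with identical gradients. Bonds longer
    than 2.5 Å are treated as chain breaks and contribute nothing.
11. **Side-chain conformation violation.** `−w · ln KDE_χ(χ₁..χ_k)` under
    the residue type's fitted chi density, offset by the density's
    log-maximum bound so the penalty is non-negative; residues without
    valid chi angles contribute zero.

All per-term weights default to 1.0 and live in the parameter file. In
the original formulation of this family of potentials the weights are
tuned against an external reference predictor on a mutation dataset;
reproducing that tuning is out of scope here, so the weights are exposed
as configuration instead.

## Differentiability

There is no automatic differentiation in this stack, so every term
carries a hand-derived gradient: analytic derivatives of pair distances,
bond angles (via the cosine form), dihedrals (the classic four-point
formulas, validated against central differences), the exposure field
(chain rule through the neighbour sigmoids), the von Mises mixture
log-densities, the soft-min acceptor assignment and the entropy gate
channels. The package's central correctness property — enforced in the
test suite — is that the assembled gradient of the total energy matches
central finite differences (step 1e-4 Å) to a relative error below 1e-4
on a 10-residue fixture.

Two places intentionally keep non-smooth boundaries: the clash gate
(below the threshold the penalty starts at `w`, as the calibrated
formula prescribes; a `continuous` configuration flag subtracts `w` on
the active branch for users who prefer a continuous surface) and the
chain-break exclusion of the peptide term. Degenerate dihedrals
(collinear supports) are masked with zero gradient contribution instead
of propagating NaN, guarded at a cross-product norm of 1e-8.

## Solvent exposure

Tabulated solvent accessibility is not differentiable, so exposure is a
smooth occlusion surrogate:
`exposure_i = exp(−κ Σ_j s(d_ij))` over heavy-atom neighbours in other
residues (an atom's own residue and direct covalent partners are part of
its frame, not packing), with `s` a falling sigmoid of midpoint 5.0 Å
and width 0.5 Å, and κ = 0.085. These defaults were calibrated once on
the ideal 20-mer helix fixture so that an isolated atom reads 1, a core
atom reads below 0.2, surface atoms read above 0.7, and an atom enclosed
by 30 neighbours at 3.5 Å reads below 0.1. Solvation uses the
residue-level mean (following the residue-wise wording of the solvation
description), the van der Waals term uses atom-level exposure, and the
side-chain entropy uses the side-chain-only mean.

## Calibration and the synthetic reference set

Clash corrections, torsion densities and peptide Gaussians are fitted
from a reference set of structures. The original work fits on 5000
high-resolution (<1.5 Å) crystal structures; this package ships no
structural data and instead fits, by default, on a deterministic
synthetic reference set (`buildReferenceSet`), with a pluggable path
(`cmdFit --refdir`) for fitting on real PDB files where available.

The generator emulates, at desk scale, the statistical features the fits
consume:

* helix and strand peptides with wrapped-normal torsion jitter (sd 8°
  backbone, 12° chi) around the preset values, so fitted densities have
  known ground-truth modes;
* peptide-bond internal coordinates jittered (sd 1.5° on the two bond
  angles, 0.01 Å on the bond length) to emulate the spread observed in
  crystal structures — without it the fitted Gaussians would degenerate
  to the floor width;
* two-chain disulfide-bridged constructs (S–S bond 2.05 ± 0.06 Å) so the
  disulfide contact group has samples;
* two-chain packed dimers pressed to a target minimum contact gap of
  −0.25 ± 0.1 Å, emulating tertiary packing; without them the "other"
  contact group would contain almost no genuine contacts and its 10th
  percentile would sit near zero.

Sequences are uniform over the 20 amino acids, lengths 16–28, default
mix 25% helix, 15% strand, 35% disulfide dimers, 25% packed dimers,
n = 200. What passing tests on these fixtures do **not** show: the
synthetic set has no loops, no real rotamer correlations, no resolution
or B-factor structure, and its density modes are the generator's presets
rather than empirical Ramachandran statistics. Fits on real structures
will move the corrections and densities; the machinery is unchanged.

The clash correction is stored as
`t_g = 10th percentile of (d − (R_i + R_j))` per group, with the linear
interpolation (type 7) percentile convention, and the penalty fires when
a pair's gap falls below its group's percentile. Written with the
stored sign, the penalty exponent is `10 (t_g − g)`: the published form
of the exponent is recovered by reading its correction constant as the
negative of the stored percentile — with the percentile itself plugged
in verbatim every routinely observed hydrogen bond would register as an
enormous clash, so the sign convention that keeps the gate sentence
("pairs closer than their group's value") physically meaningful is used.

Angle-rigid 1–3 pairs are excluded from clash collection along with
covalent 1–2 pairs. In fixed-geometry fixtures every 1–3 distance is a
constant, so a 1–3 pair type falling below its group percentile would
incur a large irreducible penalty; in real structures these distances
are vibrationally narrow too, and treating them as part of the covalent
frame rather than as contacts is the consistent reading.

## Density estimation

The torsion densities are mixtures of product von Mises kernels, one
per (optionally subsampled, at most 5000, seeded) observation, with
per-dimension concentration `1/h²` from a circular Silverman-style rule
`h = c · σ_circ · n^(−1/(d+4))` (σ_circ the circular standard deviation,
c = 1 by default, h clamped to [0.015, 1.5] rad). Von Mises kernels make
the mixture exactly normalised on the periodic domain — the quadrature
checks in the tests are verification, not enforcement — and the
log-density and its gradient are closed-form. A density floor of 1e-12
is added inside the logarithm so log-densities stay finite everywhere.
This kernel mixture stands where richer neural density estimators
(normalising flows) are sometimes used; it is simpler, exactly
normalisable and isolated behind the `DensityModel` interface, so such
an estimator could be substituted without touching the energy terms.

One structural choice: the ω density is fitted once, pooled across
residue types, rather than per type. ω is a two-state (cis/trans)
degree of freedom whose statistics barely vary by type at this
resolution, and the pooled fit is better sampled; the per-type (φ, ψ)
densities follow the per-type prescription.

The side-chain violation offset deserves a note: the penalty is
`w · (ln f_max − ln f(χ))` with `f_max` the product-kernel upper bound
`Π_d e^{κ_d}/(2π I₀(κ_d))`. Since the mixture never actually attains
that bound (centers are spread), the minimum attainable violation is a
positive per-type constant. The offset guarantees non-negativity and
does not touch the gradient; absolute values of this term are therefore
comparable within a residue type, not across types.

## Optimisation

`relaxCartesian` moves all coordinates along the negative analytic
gradient; `relaxTorsion` optimises φ, ψ, ω and rotatable χ. A torsion
update is applied as a rigid rotation of the downstream atom set about
the torsion axis (downstream = the connected component of the bond graph
on the far side of the axis, so disulfide macrocycles and the proline
ring automatically freeze the torsions they close). For heavy atoms this
is mathematically identical to re-running forward kinematics with the
incremented angles, conserves every bond length and bond angle exactly
(to round-off), and makes the chain-rule torsion gradient
`dE/dθ = Σ_a (k̂ × (x_a − x_axis)) · dE/dx_a` exact for the
parameterisation, hydrogens included.

The default optimiser is gradient descent with backtracking step
control: a proposed step that raises the energy (possible, because the
clash exponential can assign astronomically large energies to overlapped
inputs) is halved until it descends, and the step recovers by a factor
1.5 after successes, capped at the configured size. This keeps the
trajectory non-increasing by construction while remaining purely
gradient-based and deterministic. An adaptive-moment (`adam`) option is
exposed; it bounds step length by the learning rate instead and is the
easy way to exercise the divergence guard (energies above 1e6 kcal/mol
abort a CLI relaxation with a diagnostic). Convergence is declared when
|ΔE| stays below 1e-4 kcal/mol for 10 consecutive steps.

`rotateChi` applies the same rotation machinery as a standalone mutation
operator: side-chain atoms distal to each chi axis rotate, the backbone
and all other residues are bit-identical, and +δ then −δ composes to the
identity.

## Fixtures and conventions

* Peptides are built by natural-extension-reference-frame placement from
  a shipped internal-coordinate template (ideal bond lengths and angles
  for all twenty residue types). The CB branch uses the fixed improper
  `dihedral(CB, CA, N, C) = −122.6°`, which selects the L enantiomer
  (verified against the priority-rule definition of (S) configuration).
* Angle convention: radians in (−π, π] everywhere; densities and torsion
  extraction share the same wrap. The torsion angle is invariant under
  order reversal of its four defining atoms (this is a property of the
  standard convention; the sign flips under mirror reflection, and both
  properties are tested).
* The carbonyl O of the final residue has no measurable ψ; builder and
  rebuilder both place it with the fallback torsion (ψ = −47°), keeping
  build → extract → rebuild exact.
* `buildPeptide`'s coordinate noise parameter is the per-atom RMS
  displacement (each coordinate gets sd `noise/√3`).
* Default chi presets are common rotamers (χ₁ = −60°, higher χ trans;
  β-branched types use χ₁ away from −60° to avoid backbone contacts in
  helices; the guanidinium χ₅ is 0 so NH1 is cis to CD).
* Default physical conditions: T = 298 K, I = 0.05 M, ε = 80 — standard
  aqueous conditions; none are printed in the source formulation, all
  are configuration entries.
* Charges are formal charges split over equivalent atoms (Asp/Glu
  carboxylate oxygens −0.5 each, Arg NH1/NH2 +0.5 each, Lys NZ +1,
  histidine neutral in the Nε2-H tautomer); radii are a single
  per-element table (H 1.10, C 1.70, N 1.55, O 1.52, S 1.80 Å). Both are
  stand-ins for unpublished tables and are config-overridable.

## Problem sizes

The shipped defaults are desk-scale by design: calibration on n = 200
synthetic structures (a few hundred thousand contact pairs, thousands of
torsion samples per residue type), energy/gradient checks on 10-residue
fixtures, relaxations of 100–200 steps. These sizes make every fitted
group exceed its 50-sample floor with margin and keep full-suite runs in
minutes; all of them are arguments, not constants.

## Known limitations

* The synthetic reference set stands in for curated crystal structures;
  corrections and densities are internally consistent but not empirical.
* Per-term weights are untuned defaults (1.0); absolute totals are not
  comparable to any published scale, and ΔΔG prediction against
  experimental datasets is explicitly out of scope.
* The exposure surrogate is a packing proxy, not a solvent-accessible
  surface area; its parameters were chosen against the helix fixture.
* Only polar hydrogens are modelled; protonation states are fixed
  (His neutral, no pKa logic).
* mmCIF, nucleic acids and ligand parameterisation are out of scope;
  PDB input uses the first MODEL, highest-occupancy alternate locations,
  and drops waters.
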