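# foldgrad

A knowledge-based protein force field in which every energy term carries
an analytic gradient with respect to the atom coordinates.

Empirical (statistics-calibrated) energy functions of the FoldX family
score a protein conformation as a sum of physically motivated terms —
hydrogen bonds, screened electrostatics, disulfides, solvation, van der
Waals burial, steric clashes, backbone and side-chain entropies — but
their classical implementations are black boxes to gradient-based
optimisation. `foldgrad` re-expresses such an energy function so that
the map from coordinates **X** to energy *E* is differentiable end to
end: the exact gradient ∂E/∂X (and, by the chain rule through rigid
axis rotations, ∂E/∂θ for backbone and side-chain torsions θ) is
available in closed form. That makes the energy usable for structure
relaxation by plain gradient descent and as a differentiable physics
penalty inside larger model-fitting pipelines.

The eleven energy classes (kcal/mol, per residue):

| term | form |
|---|---|
| hydrogen bonds | `w · f_dist(d_H···A) · f_geom(θ_DHA, θ_lone-pair)`, soft-min acceptor choice |
| electrostatics | `332 q_i q_j / (ε d) · e^(−dK)`, `K = √(8π e² N_A I / 1000 k_B T)` |
| disulfide | distance Gaussian at 2.05 Å × S–S dihedral factor (optimum ±90°) |
| solvation (polar, hydrophobic) | residue transfer coefficients × solvent exposure |
| van der Waals | residue coefficients × atom burial (1 − exposure) |
| clash | `w · e^(10 (t_g − gap))` below the group's fitted 10th-percentile gap `t_g` |
| backbone entropy | `−w₁ ln KDE_ω(ω) − w₂ ln KDE_t(φ, ψ)`, periodic von Mises mixtures |
| side-chain entropy | `S(type)` scaled by burial, full cost when interactions lock the chain |
| peptide violation | squared standardised deviation of the two peptide angles and the N–C bond |
| side-chain violation | `−w ln KDE(χ₁..χ₅)` under the residue type's chi density |

Clash corrections, torsion densities and peptide Gaussians are fitted
from a reference structure set; a deterministic synthetic generator
(ideal-geometry peptides, disulfide-bridged and packed dimers with
controlled torsion jitter) supplies calibration-grade reference sets
with no downloads, and a directory of real PDB files can be used
instead. See the methods vignette (`vignettes/foldgrad-methods.Rmd`)
for the functional forms, parameter defaults and design decisions.

## Worked example

```r
library(foldgrad)

params <- defaultParameters()

# calibrate from the synthetic reference set (~40 s at n = 200)
refs  <- buildReferenceSet(200, seed = 42, params = params)
calib <- fitCalibration(refs, params, seed = 1)

# an ideal 10-residue helix, scored
helix <- addPolarHydrogens(
  buildPeptide("ADKELVRAML", preset = "helix", params = params), params)
totalEnergy(helix, calib)
#> EnergyBreakdown: 10 residue(s), total = 170.6828 kcal/mol
#>   hbond                     -2.3849
#>   electrostatics             0.0014
#>   disulfide                  0.0000
#>   solvation_polar           -2.4041
#>   solvation_hydrophobic      3.0124
#>   vdw                       -9.3614
#>   clash                    159.4649
#>   entropy_backbone          -0.4956
#>   entropy_sidechain          4.6856
#>   peptide_violation          0.0045
#>   sidechain_violation       18.1601
```

Reading the breakdown: the helix hydrogen-bond network stabilises
(−2.4), burial of side chains realises van der Waals stabilisation
(−9.4), exposed hydrophobics cost (+3.0). The clash row is large because
all term weights default to 1.0 — in this family of potentials the
weights are normally tuned against external data, which is out of scope
here, so absolute totals are only comparable between conformations
scored with the same calibration. That comparison is exactly what
relaxation uses:

```r
# perturb the helix and relax over torsion angles
noisy <- addPolarHydrogens(
  buildPeptide("ADKELVRAML", preset = "helix", noise = 0.3, seed = 17,
               params = params), params)
relaxTorsion(noisy, calib, steps = 100, stepSize = 1e-4)
#> RelaxResult: 44 step(s), E 43942.2153 -> 6785.4828 kcal/mol, converged: TRUE
```

Torsion-mode relaxation preserves every covalent bond length and angle
exactly (updates are rigid rotations about the torsion axes); Cartesian
mode (`relaxCartesian`) moves all coordinates freely. `energyGradient`
returns ∂E/∂X directly, and `rotateChi` rotates a residue's side-chain
χ angles differentiably.

A command-line interface wraps the same functions:

```sh
foldgrad fit    --output calibration.yaml --ref-n 200 --seed 42
foldgrad energy --input model.pdb --calibration calibration.yaml --outdir out/
foldgrad relax  --input model.pdb --calibration calibration.yaml \
                --mode torsion --steps 100 --outdir out/
```

(installed under `exec/foldgrad` in the package directory; run via
`Rscript $(Rscript -e 'cat(find.package("foldgrad"))')/exec/foldgrad ...`.)

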