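Package: foldgrad
Title: Differentiable Knowledge-Based Protein Force Field
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A knowledge-based conformational energy function for proteins
    (hydrogen bonds, screened Coulomb electrostatics, disulfide bonds,
    polar and hydrophobic solvation, van der Waals burial, steric clashes
    calibrated from reference-structure contact statistics, backbone and
    side-chain entropies from periodic torsion-angle kernel densities, and
    peptide-geometry violation penalties) in which every term carries an
    analytic gradient with respect to the atom coordinates. The gradient
    supports structure relaxation by gradient descent over Cartesian
    coordinates or over backbone and side-chain torsion angles, a
    chi-rotation mutation operator, calibration of clash corrections and
    torsion densities from reference sets, and deterministic synthetic
    peptide fixtures built by internal-coordinate forward kinematics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, bio3d, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
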