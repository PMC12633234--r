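Package: cryosim
Title: Linear Image Formation Simulation and Differentiable Refinement for Cryo-EM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cryo-electron microscopy particle images under the weak-phase
    linear contrast model: projection of an electrostatic potential (represented as a
    Gaussian mixture over atoms or as a Fourier voxel grid), in-plane translation,
    modulation by an astigmatic contrast transfer function, and scaling by the
    electron interaction constant. Includes SO(3) pose parametrizations (z-y-z Euler
    angles and unit quaternions), Fourier-slice projection with trilinear
    interpolation, white and colored Gaussian noise models calibrated by
    signal-to-noise ratio, radial power spectra, Fourier shell correlation, a
    voxelwise mismatch score, and gradient-based refinement of Gaussian centers
    against observed image stacks via a normalized cross-correlation loss and the
    AdaBelief optimizer. Reads atomic coordinates from PDB/mmCIF, reads and writes
    MRC volumes and stacks, and ships a command-line interface for simulation and
    refinement workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    ggplot2,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
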