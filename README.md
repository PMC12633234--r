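# cryosim

Simulation of cryo-electron microscopy particle images under the weak-phase
linear contrast model, and gradient-based refinement of coarse-grained atomic
structures against image stacks — in plain R.

## Who this is for

Method developers and structural biologists who need a transparent, fully
scriptable forward model of cryo-EM image formation: to generate synthetic
particle stacks with known ground truth, to prototype analysis ideas
(likelihoods, losses, noise models) against that forward model, and to study
how much structural signal survives realistic noise. Everything is seeded and
deterministic, so experiments are reproducible to the byte.

## The model

An image of a particle with electrostatic potential *U* at pose (*R*, *t*),
*t* = (tx, ty, 0), is simulated as

```
C(x, y) = σe · F⁻¹[ sin χ(q) · F ∫ dz U(R r′ + t) ]
```

projection of the rotated potential along the beam, in-plane translation
(applied as a Fourier-space phase ramp), multiplication by the contrast
transfer function sin χ, and scaling by the electron interaction constant σe.
The aberration function follows the CTFFIND-style astigmatic model

```
χ(q, φ) = −π λ Δf(φ) |q|² + (π/2) Cs λ³ |q|⁴ + phase shift,
Δf(φ)   = ½ [du + dv + (du − dv) cos 2(φ − φa)]
```

with relativistic electron wavelength λ(V). Amplitude contrast *w* enters as
`√(1−w²) sin χ + w cos χ` and defaults to 0, recovering sin χ exactly.

Two interchangeable volume representations are provided: a **Gaussian
mixture** (one isotropic 3D Gaussian per atom, projected analytically) and a
**Fourier voxel grid** (projected by central-slice extraction with trilinear
interpolation, per the Fourier slice theorem). Poses are z-y-z Euler angles or
unit quaternions; both convert to one SO(3) rotation type internally.

For analysis the package provides white/colored Gaussian noise calibrated by
per-pixel-variance SNR, radial power spectra, Fourier shell correlation (FSC),
the voxelwise mismatch score `s = 2U₀/(U₀+U) − 1`, and refinement of Gaussian
centers against an observed stack by minimizing a normalized cross-correlation
loss with exact closed-form gradients and the AdaBelief optimizer.

## Worked example

Generate a synthetic refinement experiment — a 20-atom ground truth imaged 16
times at SNR 0.1 with a fixed CTF, and a starting model jittered by 3 Å per
coordinate — then refine the centers for 100 gradient steps:

```r
library(cryosim)

fx <- make_refinement_fixture(n_atoms = 20, n_images = 16, snr = 0.1,
                              perturbation_scale = 3, seed = 1)
fx$stack
#> <image_stack> 16 images of 64 x 64 px at 1.000 A

trace <- refine_centers(fx$problem, steps = 100)
trace
#> <refinement_trace> 100 steps, loss -4.156381 -> -4.814961
```

The stack loss is the sum over images of −NCC(model, observed), so −4.16 → −4.81
means the average per-image correlation improved from 0.26 to 0.30 at SNR 0.1.
Whether that corresponds to a better *structure* is what the FSC answers:

```r
truth_vol   <- rasterize_gmm(fx$truth, side = 64, voxel_size = 1)
start_fsc   <- fourier_shell_correlation(truth_vol, rasterize_gmm(fx$start, 64, 1))
refined_fsc <- fourier_shell_correlation(truth_vol, rasterize_gmm(trace$model, 64, 1))
head(data.frame(q = start_fsc$q, start = round(start_fsc$fsc, 3),
                refined = round(refined_fsc$fsc, 3)), 8)
#>          q start refined
#> 1 0.000000 1.000   1.000
#> 2 0.015625 0.990   0.999
#> 3 0.031250 0.950   0.998
#> 4 0.046875 0.763   0.989
#> 5 0.062500 0.501   0.881
#> 6 0.078125 0.375   0.669
#> 7 0.093750 0.312   0.559
#> 8 0.109375 0.189   0.426
```

The refined model decorrelates from the truth at a markedly higher frequency
than the start (the start crosses FSC = 0.5 near q ≈ 0.06 Å⁻¹, the refined
model near 0.1 Å⁻¹): the optimization recovered the low-resolution structure
from images dominated by noise. `plot_fsc(list(start = start_fsc,
refined = refined_fsc))` and `plot_loss_trace(trace)` draw the curves.

Single images are simulated directly from any volume representation:

```r
img <- simulate_image(fx$truth, euler_pose(30, 60, 0),
                      ctf_params(defocus_u = 10000, cs = 2.7,
                                 amplitude_contrast = 0.07),
                      image_config(64, 1))
#> <simulated_image> 64 x 64 px at 1.000 A   (pixel range [-0.0348, 0.0136])
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/cryosim.R`
(subcommands `fixture`, `simulate`, `project`, `ctf`, `refine`, `fsc`; flat
`key = value` config files with `--key value` overrides; every run logs its
resolved configuration and seeds):

```sh
Rscript inst/cli/cryosim.R fixture --out_prefix toy --n_atoms 20 --n_images 16 --seed 1
Rscript inst/cli/cryosim.R refine --stack toy_stack.mrc --metadata toy_metadata.csv \
    --coords toy_start.csv --truth toy_truth.csv --steps 100 --out_prefix run
```

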