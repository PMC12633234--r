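---
title: "The cryosim image model: conventions, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cryosim image model: conventions, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryosim)
```

# The forward model and its assumptions

cryosim simulates particle images under the weak-phase approximation, in
which contrast forms linearly: the electrostatic potential $U$ is projected
along the beam at pose $(R, t)$, translated in plane, filtered by the
contrast transfer function $\sin\chi$, and scaled by the electron
interaction constant $\sigma_e$,

$$C(x, y) = \sigma_e\, \mathcal{F}^{-1}\!\left[\sin\chi(\vec q)\cdot
  \mathcal{F}\!\int\! dz\, U(R\vec r^{\,\prime} + \vec t\,)\right].$$

The assumptions this buys and their limits:

* **Linearity in the potential.** Multiple scattering, dynamical effects,
  and intensity/electron-count statistics are outside the model; the output
  is contrast, in arbitrary units unless $\sigma_e$ and the potential scale
  are calibrated. Doubling $\sigma_e$ doubles every pixel exactly, which is
  why the refinement loss is deliberately scale-invariant (below).
* **Flat Ewald sphere.** Central-slice projection is exact only when the
  curvature of the Ewald sphere is negligible — fine at the resolutions and
  box sizes the package targets (tens of pixels to a few hundred).
* **No envelope by default.** Spatial/temporal coherence envelopes, detector
  DQE, dose weighting and radiation damage are not modeled; a Gaussian
  B-factor envelope `ctf_envelope()` is available for noise-matching
  experiments but is never applied implicitly.

# Conventions, fixed once

Every geometric ambiguity in this domain was resolved once and is relied on
by the tests:

* **Rotations are active**: a pose rotates the particle into the laboratory
  frame, so the rotated volume is $U(R^{-1}\vec r)$ and a Gaussian center
  $c$ projects to the first two components of $R c$.
* **Euler convention z-y-z**, applied $\phi$ first (about z), then $\theta$
  (about y), then $\psi$ (about z): the rotation is
  $R_z(\psi) R_y(\theta) R_z(\phi)$. Angles are degrees at every interface,
  radians internally. At gimbal lock ($\theta \in \{0°, 180°\}$) only a
  combination of $\phi$ and $\psi$ is identifiable;
  `euler_from_rotation()` returns the canonical solution with $\psi = 0$ so
  metadata round-trips are deterministic.
* **Quaternions are scalar-first** $(w, x, y, z)$, normalized on entry, and
  $q$ and $-q$ are treated as the same rotation in every comparison,
  removing the double-cover ambiguity from tests and metadata.
* **Grid origin at index $n/2$** (0-based) on every axis — the FFT-center
  convention — for real space and frequency space alike, with even sides
  required. Real-space samples sit at $(i - n/2)\Delta$; spectra are stored
  centered, with the zero-frequency coefficient equal to the plain sum of
  samples (unnormalized forward transform).
* **Images are indexed `[y, x]`**, volumes `[x, y, z]`; extracted Fourier
  slices are laid out `[qy, qx]` so their inverse transform matches image
  layout. MRC files store x fastest, and the writer/reader transpose image
  stacks accordingly.
* **CTF signs**: $\chi = -\pi\lambda\Delta f |q|^2 + \frac{\pi}{2} C_s
  \lambda^3 |q|^4 + \text{ps}$, positive $\Delta f$ meaning underfocus, the
  spherical-aberration term opposing the defocus term. Because downstream
  contrast sign is convention-dependent, `evaluate_ctf()` exposes one
  global `sign` flag rather than hiding a choice.
* **Defocus canonicalization** $d_u \ge d_v$ with the astigmatism angle
  wrapped to $[0°, 180°)$, removing a two-fold parameter degeneracy before
  it can bite refinement or file round-trips.

# Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `pixel_size` / `voxel_size` | Å | user-set | physical sampling; Nyquist is $1/(2\Delta)$ |
| `sigma_e` | arbitrary | 1 | potentials are in arbitrary units; only overall scale |
| `defocus_u`, `defocus_v` | Å | 10000 | typical single-particle underfocus (1 µm) |
| `cs` | mm | 0 (`ctf_params`), 2.7 (fixture) | 2.7 mm is the common Titan-class value |
| `voltage` | kV | 300 | standard high-end microscope |
| `amplitude_contrast` | fraction | 0 (model), 0.07 (fixture) | 0 recovers pure $\sin\chi$; 0.07 is the conventional cryo value |
| Gaussian `variance` | Ų | 16 (fixture) | $\sigma = 4$ Å resolves coarse-grained C$\alpha$ atoms at 1 Å pixels and satisfies the band limit $\sigma \ge 2\Delta$ |
| `step_size` (AdaBelief) | Å-scale | $10^{-2}$ | with betas 0.9/0.999 and $\epsilon = 10^{-16}$; AdaBelief's variance adaptation makes effective steps much larger when gradients are consistent |
| `mask_frac` (mismatch score) | fraction of max $U_0$ | $10^{-3}$ | the score is undefined on empty space; the mask mirrors scoring only where density exists |

Gaussian mixtures are **unit-integral per component** before amplitude
scaling, so the integrated potential is the sum of amplitudes; the
alternative (unit peak) would change only the overall image scale.
A single $(a, b)$ pair per center keeps the data model minimal; atoms
described by sums of several Gaussians (tabulated scattering factors) are
expressed by repeating centers, and `gmm_from_atoms()` accepts per-atom
vectors.

# Noise and the SNR definition

`SNR` here is the ratio of **per-pixel signal variance to noise variance** —
stated prominently because band-limited power-ratio definitions also exist
and give different numbers. `add_noise_at_snr()` scales a sampled field so
its variance is `var(signal)/snr` in expectation: exactly the white-noise
variance, and the frequency-grid mean of the profile for colored noise.

Colored noise is white noise shaped in Fourier space by
$\sqrt{\text{profile}(|q|)}$, so its expected radially averaged power
spectrum equals the profile in the same normalization as white noise of
that variance. A two-parameter power-law-plus-constant family
(`noise_profile_power_law()`) plus a least-squares fitter
(`fit_noise_profile()`) support the empirical workflow of tuning noise
parameters until a simulated spectrum aligns with a measured one; the
target spectrum is always user-supplied, and no claim is made that this
family matches any particular microscope.

# Numerical choices

* **Trilinear interpolation** for central-slice extraction — the minimal
  standard scheme; all slice-accuracy tolerances in the tests are set for
  it. Requested frequencies outside the volume's Nyquist box are zeroed and
  counted (`n_clipped`). Points landing exactly on the upper grid face are
  valid cell corners, not clipped — an easy off-by-one that the
  identity-slice exactness test pins down.
* **Fourier oversampling.** `fourier_from_real(vol, pad = k)` zero-pads the
  real volume about its center before transforming. The default is `pad = 1`
  (no padding, bounded memory). For compact, well-resolved scenes,
  unpadded slice projections agree with analytic projections to NCC
  > 0.999. When the comparison runs through the full CTF model — which
  up-weights mid frequencies where trilinear error concentrates —
  agreement at `pad = 1` drops to ≈ 0.999, and the package's
  dual-representation checks use `pad = 2` (the standard oversampling in
  single-particle software), giving NCC ≥ 0.9999.
* **Translation is periodic** (a DFT phase ramp), applied before the CTF —
  both are Fourier-diagonal so the order is immaterial, fixed for
  documentation. Keep particles centered; wrap-around is exact for the
  shift theorem but unphysical at box edges.
* **Gradients are closed-form, not numerical.** The loss gradient with
  respect to centers chains the analytic Gaussian projection derivative
  through the adjoint of the (linear, Fourier-diagonal) translation-and-CTF
  filter, with one forward and one backward FFT per image regardless of the
  atom count. The correctness contract — agreement with central finite
  differences (step $10^{-3}$ Å) to relative error below $10^{-4}$ — is
  asserted in the tests; in practice agreement is ≈ $10^{-7}$.
* **NCC, not raw correlation.** The refinement loss is the negative
  normalized cross-correlation, invariant to the arbitrary $\sigma_e$
  scale and to constant offsets, which makes the noiseless optimum an exact
  stationary point (gradient norm $< 10^{-6}$ there, also asserted).
* **FSC shells are one Fourier voxel wide**, with no masking or tapering;
  the self-FSC is 1 in every nonempty shell by construction, and empty
  shells are reported as `NA` rather than invented.
* **Degenerate inputs** fail loudly: zero-variance images in the loss,
  non-cubic grids, odd sides, zero quaternions, non-positive variances and
  SNRs are all validation errors, not silent coercions.

# The synthetic experiment generator

`make_refinement_fixture()` *is* the study design, not a tuning knob. Its
defaults encode the demonstrated refinement setting: **100 images at
SNR = 0.1**, equal weight and variance per atom, one fixed CTF (300 kV,
1 µm defocus, $C_s$ 2.7 mm, 7% amplitude contrast), uniformly random
orientations, zero in-plane shifts (refinement assumes known poses; shifts
would be absorbed by the known-pose assumption anyway), and a starting
model jittered by an isotropic Gaussian of 3 Å per coordinate. Truth
centers are drawn uniformly in a 10 Å ball so that a 64-box at 1 Å contains
every $\sigma = 4$ Å atom with ≥ 5σ margin, keeping rasterized integrals
and FSC comparisons clean.

The package's recovery experiment is a scaled-down version of the full
demonstration: 20 atoms and 16 images of 64² rather than thousands of atoms
and 100 images of 200². These sizes were chosen so the complete experiment
(fixture, 100 optimization steps, FSC) runs in seconds while still being
noise-dominated (SNR 0.1) and genuinely three-dimensional; the same code
path scales to the larger setting unchanged.

What the generator emulates — projection geometry, CTF modulation,
SNR-calibrated noise, pose diversity — and what it does not: real
micrograph backgrounds (structured ice, contamination), pose/CTF estimation
error (poses and CTFs are known exactly by construction), particle
heterogeneity, and detector effects. Passing tests therefore demonstrate
correctness of the forward model and optimizer, not robustness to the
error sources a real pipeline must face.

# Design choices that were genuinely open

* **Active vs passive rotations** and intrinsic vs extrinsic Euler
  composition are not fixed by convention alone; cryosim fixes active z-y-z
  and verifies internal consistency (round-trips, dual-representation
  agreement), claiming no bit-compatibility with any other package's pose
  bookkeeping.
* **AdaBelief hyperparameters** follow the published defaults; only the
  step size is exposed, since it carries the Å length scale of the problem.
* **Amplitude/variance freezing.** Only centers move during refinement,
  matching the coarse-grained use case; `loss_gradient_wrt_centers()` is
  the only gradient implemented, and unfreezing shape parameters would be
  a model change, not an option toggle.
* **CSV metadata** (documented column schema, one row per image) rather
  than a STAR dialect: diffable, testable, and convertible; the MRC files
  carry the pixel size redundantly as a cross-check.

# Known limitations

Single-threaded R; the brute-force real-space projector is a test oracle
and scales poorly beyond ~100³. No pose or CTF refinement, no
heterogeneity, no Ewald-sphere curvature, no physical intensity models, no
tabulated scattering-factor ingestion (per-atom Gaussian parameters are
caller-supplied). Colored-noise fields are Gaussian by construction and
cannot reproduce non-Gaussian micrograph statistics.
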