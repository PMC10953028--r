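---
title: "Wave-encoded time-of-flight MR angiography: model, solvers and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave-encoded time-of-flight MR angiography: model, solvers and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavemra)
```

## The encoding model

Time-of-flight (TOF) angiography renders arteries bright against saturated
static tissue without contrast agent.  Accelerating a 3D TOF slab by
undersampling the two phase-encoding axes (ky, kz) trades scan time against
noise amplification and aliasing.  Wave encoding plays two sinusoidal
gradients with a pi/2 relative phase on the phase (y) and partition (z)
axes during every readout, so each readout line becomes a corkscrew through
k-space.  In hybrid space — data Fourier-transformed along the readout only,
coordinates (kx, y, z) — the whole effect of the wave gradients is a
unit-modulus point spread function

    PSF[kx, y, z] = exp(-i 2 pi (ky_wave(kx) y + kz_wave(kx) z)),

where `ky_wave`, `kz_wave` are the integrated gradient deflections in
cycles/m.  The measured multi-coil k-space is then

    k = M . F_z . F_y . PSF . F_x . C . s,

with `C` the coil sensitivities, `F_*` (centered, orthonormal) Fourier
transforms, and `M` the binary (ky, kz) sampling mask.  Because every factor
is unitary or diagonal, the adjoint used by the iterative solvers is exact;
`encode_forward()` / `encode_adjoint()` pass an inner-product adjoint test
at 1e-10 and match a brute-force non-uniform DFT on small grids.

The PSF displaces the signal of a voxel at (y, z) along the readout by up
to `(g_max / G_read) (|y| + |z|)`, where `G_read` is the readout gradient
implied by the per-pixel bandwidth.  `psf_spread_extent()` reports this
spread-out range as the sum of the per-axis peak displacements at the FOV
corner (one-sided).  Conventions for this number vary — the maximal
instantaneous displacement (quadrature combination of the two axes) is
about 11% smaller — so the function documents and pins the per-axis-sum
convention; tests assert that brute-force point-source displacement never
exceeds it.  The readout must be oversampled (factor `os_factor`) so the
displaced signal does not wrap: we require
`os_factor >= 1 + 2 * spread / FOV_x`.

```{r spread}
wp <- wave_params(g_max = 10, n_cyc = 15, bw_per_pixel = 121, n_read = 256,
                  os_factor = 6)
psf_spread_extent(wp, fov_x = 200, fov_y = 200, fov_z = 26.4)
```

A note on the corkscrew's reference line: integrating the sine-axis
gradient from the first ADC sample would give a one-sided deflection of
twice the nominal amplitude.  `nominal_trajectory()` therefore demeans the
deflections — the corkscrew winds symmetrically about the Cartesian
readout line, as when the wave gradient starts ahead of the ADC window —
and `estimate_trajectory()` reconstructs trajectories under the same
convention (only relative phase is observable in calibration anyway).

## Gradient moments and flow ghosting

`compute_moments()` integrates the zeroth moment m0 (position phase: the
PSF above) and first moment m1 (velocity phase).  For a pure sinusoid m0
oscillates with a constant envelope while the m1 envelope grows roughly
linearly across the readout.  Spins moving with velocity v acquire
`phi(t) = 2 pi gamma (m1_y v_y + m1_z v_z)`; because this phase oscillates
*within* each readout, it replicates flowing-spin signal along the
frequency-encoding direction — unlike conventional pulsatility ghosts,
which appear along phase encoding.  Large-amplitude, few-cycle waveforms
(e.g. 25 mT/m, 6 cycles) produce a large m1 envelope and visible vessel
ghosts; the protocol choice of 10 mT/m with 15 cycles keeps the peak flow
phase below ~0.4 rad at 200 mm/s and the ghosts are negligible.  Moments
are integrated by the trapezoid rule on a 10x spline-refined grid, keeping
them within 1e-6 of a high-resolution quadrature.

`simulate_acquisition(flow_on = TRUE)` inserts `exp(i phi(t))` per readout
sample for every constant-velocity vessel branch, and
`ghost_to_signal_ratio()` quantifies the resulting readout-line ghosting
(mean magnitude on vessel readout lines, outside a dilated vessel margin,
over mean vessel magnitude).

## Reconstruction

Two solvers operate on the same encoding operator:

* `recon_least_squares()` solves `min_s ||A s - k||_2^2` with LSQR
  (tolerance 1e-3 on the relative residual, at most 200 iterations).  With
  the wave PSF this is the wave-CAIPI reconstruction; without it, 2D-CAIPI
  (Cartesian SENSE).  With noisy data the residual tolerance is typically
  unreachable and the solver runs to the iteration cap, exactly as the
  reference settings intend.
* `recon_cs()` solves
  `min_s ||A s - k||_2^2 + gamma_G ||G s||_1 + gamma_W ||W s||_1`
  with smoothed-L1 nonlinear conjugate gradients (Fletcher-Reeves with
  restart every 50 iterations, Armijo backtracking with one
  quadratic-interpolation refinement, |x| ~ sqrt(|x|^2 + 1e-15)).
  `G` is a three-axis forward-difference gradient (zero boundary) and `W`
  an orthonormal 3-level Haar wavelet.  Both weights default to 3e-4 on a
  normalized scale: the data are scaled so the zero-filled image has unit
  peak magnitude before solving, and rescaled after.  The objective is
  monotone non-increasing across accepted iterations, and the default
  tolerance 3e-3 acts on the relative gradient norm.

On grids up to 16 x 16 x 4 the LSQR solution is checked against a dense
normal-equations solve; with both regularization weights at zero the NLCG
solution coincides with LSQR.

## Sampling patterns

`caipi_mask()` builds the staggered 2D-CAIPIRINHA lattices; the default
factorizations R = 4 -> (2, 2, shift 1), 6 -> (2, 3, 1), 8 -> (2, 4, 1)
follow the lowest-mean-g-factor choice for lattices of equal acceleration.
`poisson_disc_mask()` draws variable-density Poisson-disc patterns with
exclusion radius `r(k) = r0 (1 + 2 |k|/|k|_max)`; `r0` is solved by
bisection so the achieved acceleration lands within 5% of the target, and
the whole pattern is reproducible from its seed.  On the coarse desk grids
the discrete geometry makes the radial density profile a staircase rather
than a smooth law; the tests therefore check monotone decay statistically
across seeds.

## Trajectory calibration

Gradient-chain imperfections (timing delays, exponential eddy-current
lags; `apply_imperfection()`) bend the real corkscrew away from the
nominal one, and even a 1 microsecond timing shift moves the trajectory by
far more than the reconstruction can tolerate.  The calibration emulated
by `simulate_calibration_scans()` measures thin slices at known offsets
with and without the wave gradient, per axis; `estimate_trajectory()`
unwraps the with/without phase difference along time and fits its slope
across slice offsets (weighted least squares through the origin; a
single-reference variant is also provided).  Noiseless round trips recover
a delayed trajectory to better than 1% of the peak deflection, and at
calibration SNR 100 the RMS error stays below 2%.

## The digital phantom and what it does (not) emulate

`make_vessel_phantom()` builds the study object: an ellipsoidal head
ellipse with a suppressed static background (intensity 0.25 against vessel
intensity ~1) carrying two-scale smooth texture (SD 30% of the background
level), and twelve random-walk vessel trees running through the slab with
tapering radii from 1.5 to 5 mm — deliberately spanning sub-voxel distal
vessels, because those carry the diagnostic content that aggressive
regularization degrades.  Each branch carries a constant axial velocity
drawn from 100-300 mm/s.  `make_coil_maps()` arranges 16 loop coils in
three rings around the slab with compact anisotropic lobes, so coil
sensitivity varies in all three directions; this mimics the conditioning
of a multi-row head array, which the acceleration regime of the study
requires (with substantially fewer or smoother coils, every R = 8
reconstruction is noise-dominated and method comparisons degenerate).
K-space noise defaults to SD 0.01 per complex sample against a unit
vessel, i.e. background SNR near 25 — a typical clinical TOF level.

Features deliberately not emulated: inflow saturation and TONE excitation
(the TOF contrast is imposed, not Bloch-simulated), pulsatile flow, B0/B1
inhomogeneity, motion, and realistic vascular anatomy.  Passing tests
therefore demonstrate the encoding/reconstruction machinery and the
relative behaviour of the sampling schemes under controlled conditions,
not clinical image quality.

## The retrospective comparison

`run_retrospective_experiment()` replays the retrospective design: one
fully sampled wave acquisition is simulated; the fully sampled Cartesian
reference is synthesized from it by PSF deconvolution
(`deconvolve_to_cartesian()`, exact because the PSF is unit-modulus);
masks at R = 4, 6, 8 are applied to the wave data (wave methods) or the
Cartesian data (conventional methods); and each cell is scored by CBR
(vessel-background contrast over background SD), SSIM of the MIPs against
the reference MIP, and vessel-masked SSIM (the SSIM map averaged over the
segmented vessel mask, which tracks radiological reading of angiograms
better than whole-image SSIM).  The vessel mask is thresholded at
mean + 2 SD of the reference MIP with components under 5 pixels removed;
the CBR background is the object support minus the vessel mask dilated by
2 voxels.

Problem sizes: the packaged comparisons run on a 32 x 32 x 16 grid with a
136 x 136 x 48 mm FOV — the same 4.25 mm voxels, wave spread ratio, noise
level and coil array as the 48 x 48 x 16 default phantom, on which the
same orderings were confirmed.  The g-factor Monte Carlo
(`gfactor_pseudo_replica()`) reconstructs noise-perturbed replicas of the
same underlying k-space through the accelerated and fully sampled
pipelines and reports `SD_accel / (SD_full sqrt(R))` per voxel; because
the residual tolerance is unreachable on noisy data, the replica
reconstructions use a fixed, matched LSQR iteration budget (30-40
iterations) in both pipelines, which is what determines the effective
regularization of the comparison.

## Numerical choices

* FFTs: centered (DC at `floor(N/2)`), orthonormal on every axis; for even
  lengths the center shifts are folded into alternating-sign
  multiplications.  Voxel centers sit at `(i - N/2) * delta` (0-based i)
  in every module.
* The phase convention is `exp(-i 2 pi k . r)` in the forward model and
  `phi = +2 pi gamma m1 . v` for flow; a single global pair, so only
  magnitudes and orderings are convention-free.
* Degenerate inputs: zero wave amplitude reduces the operator to Cartesian
  SENSE encoding exactly; zero k-space reconstructs to zero; an all-ones
  mask at R = 1 reproduces the reference; empty vessel masks and
  zero-variance backgrounds raise errors rather than returning NaN.
* Haar levels fall back to the largest depth the grid dimensions divide;
  the finite-difference transform uses a zero boundary and its exact
  adjoint.

## Known limitations

The least-squares solvers regularize only through early stopping, so at
high acceleration with weak coil encoding the solution is
iteration-budget-dependent (visible as semi-convergence); ESPIRiT-grade
sensitivity calibration is replaced by a low-resolution RSS-normalized
estimate that is accurate for smooth reference-scan sensitivities but
degrades for sharply varying arrays (truth maps are always available in
simulation); and the CS solver is the classic NLCG — robust but slower
than modern proximal methods, which are out of scope here.
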