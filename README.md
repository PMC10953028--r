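# wavemra

Wave-encoded time-of-flight (TOF) MR angiography, in silico: an R toolkit
for simulating and reconstructing highly accelerated 3D TOF acquisitions
with wave encoding, and for quantifying what the technique buys.

## The problem and the model

3D TOF angiography renders intracranial arteries without contrast agent,
but full sampling of a high-resolution slab is slow. Undersampling the two
phase-encoding axes accelerates the scan at the price of noise
amplification (parallel imaging) or regularization artifacts (compressed
sensing). Wave encoding plays two sinusoidal gradients — amplitude `G_max`,
`N_cyc` cycles, pi/2 phase offset — on the phase (y) and partition (z) axes
during every readout, turning each readout line into a corkscrew through
k-space. In hybrid `(kx, y, z)` space this is a unit-modulus point spread
function

```
PSF[kx, y, z] = exp(-i 2 pi (ky_wave(kx) y + kz_wave(kx) z))
```

and the acquisition model becomes

```
k = M · F_z · F_y · PSF · F_x · C · s
```

(`C` coil sensitivities, `F` centered orthonormal Fourier transforms, `M`
the ky–kz sampling mask). The wave spreads each voxel along the readout by
up to `(G_max / G_read)(|y| + |z|)`, letting the reconstruction exploit
coil sensitivity variation in all three directions. Four schemes are
implemented on this one operator:

* **wave-CAIPI** — staggered 2D-CAIPIRINHA lattice + LSQR least squares;
* **2D-CAIPI** — the same without the wave (Cartesian SENSE);
* **CS-wave** — variable-density Poisson-disc mask + L1 (gradient + Haar
  wavelet) regularized nonlinear conjugate gradient;
* **CS** — the same without the wave.

The package also models the technique's characteristic artifact: the
oscillating first-order gradient moment imprints a per-sample phase
`phi(t) = 2 pi gamma m1(t) · v` on flowing spins, replicating vessel signal
along the *frequency*-encoding direction; large-amplitude few-cycle
waveforms ghost, the protocol choice (10 mT/m, 15 cycles) does not.
Evaluation tools include pseudo-replica g-factor maps,
contrast-to-background ratio (CBR), SSIM and vessel-masked SSIM of maximum
intensity projections, a projection-based trajectory calibration, and a
digital vessel phantom (TOF-bright tubes, textured suppressed background,
multi-ring coil array, complex Gaussian noise, constant-velocity flow).

## Worked example

```r
library(wavemra)

wp <- wave_params(g_max = 10, n_cyc = 15, bw_per_pixel = 121, n_read = 256,
                  os_factor = 6)
wp
#> Wave-encoding parameters
#>   amplitude G_max : 10 mT/m
#>   cycles N_cyc    : 15
#>   readout         : 256 px at 121 Hz/px (T_read = 8.264 ms), oversampling x6
#>   wave frequency  : 1815.0 Hz
check_hardware_limits(synthesize_waveforms(wp))
#> Hardware check: peak amplitude 10.00 / 80 mT/m, peak slew 114.0 / 200 T/m/s -> PASS
psf_spread_extent(wp, fov_x = 200, fov_y = 200, fov_z = 26.4)
#> [1] 311.1868
```

The waveform is hardware-feasible and spreads the PSF over ~311 mm of
readout, which is why the protocol oversamples the readout 6x. A desk-scale
retrospective comparison at acceleration R = 8:

```r
spec  <- phantom_spec(dims = c(32, 32, 16), fov = c(136, 136, 48), seed = 1)
ph    <- make_vessel_phantom(spec)
coils <- make_coil_maps(spec$n_coils, spec$dims, ph$support, spec$fov)
wave  <- desk_wave_params(spec)
sim   <- simulate_acquisition(ph, coils, wave = wave, seed = 1)
kcart <- deconvolve_to_cartesian(sim$data, sim$op)      # Cartesian reference
mask8 <- caipi_mask(32, 16, R_y = 2, R_z = 4, caipi_shift = 1)

rec_wave <- recon_least_squares(sim$data, with_mask(sim$op, mask8))
rec_cart <- recon_least_squares(kcart, cartesian_operator(sim$op, mask8))
ref      <- recon_least_squares(kcart, cartesian_operator(sim$op))
refmip   <- mip(ref$image)
rbind(quality_report(rec_wave$image, refmip, ph$vessel_labels, ph$support, "wave-caipi", 8),
      quality_report(rec_cart$image, refmip, ph$vessel_labels, ph$support, "2d-caipi", 8))
#>       method R      cbr      ssim vessel_ssim
#> 1 wave-caipi 8 7.405677 0.9346413   0.9855016
#> 2   2d-caipi 8 3.605003 0.4531732   0.6559525
```

At eightfold acceleration the wave reconstruction keeps the vessel-to-
background contrast (CBR 7.4 vs 3.6) and the MIP fidelity (SSIM 0.93 vs
0.45) that the plain 2D-CAIPI reconstruction loses to noise amplification —
the core claim of the method. `run_retrospective_experiment()` runs the
full 4-method x {R = 4, 6, 8} grid and returns the metric table;
`gfactor_pseudo_replica()` quantifies the underlying noise-amplification
difference; `inst/cli/wave-mra.R` exposes `simulate`, `psf`, `mask`,
`recon` and `experiment` subcommands for shell use.

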