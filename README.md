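# permstrut

Transport measurement and oxygen-limited growth prediction for
tissue-engineering scaffolds built from stacked, patterned struts — the
kind produced by direct-write electrospinning or extrusion printing, where
the strut material itself can be permeable to oxygen.

The package addresses two questions scaffold designers ask together:

1. **How fast do solutes actually diffuse in the scaffold material?**
   Fluorescence recovery after photobleaching (FRAP) traces from a bleached
   disk are converted to diffusion coefficients via the uniform-disk
   half-time relation, and a measured macromolecule ratio is rescaled to an
   oxygen diffusivity estimate through the fibre-obstruction model.
2. **How deep into the scaffold can cells grow before oxygen runs out?**
   A voxelized 3D model of alternating 90°-rotated strut layers is coupled
   to quasi-steady oxygen diffusion with Michaelis–Menten consumption and
   Monod doubling kinetics, yielding saturated-depth and saturation-time
   metrics as functions of strut permeability, volume fraction and
   arrangement.

## The models in brief

**FRAP.** For an instantaneous uniform bleach of a disk of radius ω in a
2D film, recovery follows f(t) = e^(−2τ/t)[I₀(2τ/t) + I₁(2τ/t)] with
τ = ω²/4D, which gives the estimator

    D = 0.224 ω² / t_half .

**Obstruction rescaling.** A fibrous matrix attenuates diffusion as
D/D₀ = exp(−φ_v r_s / r_f); one probe measurement identifies the lump
κ = φ_v/r_f, and any other probe rescales as D = D₀ e^(−κ r).

**Scaffold growth.** Oxygen: ∇·(D∇C) = ρ V_max C/(K_m + C) with C = C₀ at
the media-exposed top, a bottom wall, mirror-symmetric lateral faces, and
D = D_t (culture) or D_s (strut). Cells: ρ ← min(ρ_max, ρ·2^((r_g − k_d)Δt))
with doubling rate r_g = r_(g,max) C/(K + C), r_(g,max) = 1/t_d, and an
optional first-order decay k_d. Defaults follow published kinetic
constants (V_max = 3.3×10⁻¹⁶ mol cell⁻¹ s⁻¹, K_m = 3.79×10⁻³ mol m⁻³,
K = 3×10⁻³ mol m⁻³, C₀ = 0.1 mol m⁻³, t_d = 36.5 h,
D_t = 2.0×10⁻⁵ cm² s⁻¹, D_w = 2.68×10⁻⁵ cm² s⁻¹).

See `vignettes/permstrut-methods.Rmd` for the full account of the numerics
(finite-volume discretization, Picard/conjugate-gradient solver, the
spectral FRAP generator) and every modelling choice.

## Worked example

Simulate a noisy FRAP experiment at the water diffusivity of a 3-kDa
dextran probe, analyze it, and rescale the measured ratio to an oxygen
estimate:

```r
library(permstrut)

cv <- simulate_recovery(bleach_scenario(D_true = 1.28e-6, omega = 50,
                                        noise_sigma = 0.02, seed = 7))
frap_analyze(cv)
#> <frap_result> t_half = 4.414 s, D = 1.269e-06 cm^2/s (omega = 50 um, interpolation)
```

The analyzed D lands within 1% of the generator's input. Rescaling a
measured in-sample ratio D/D₀ = 0.59 of the 1.2 nm dextran probe to
oxygen (0.14 nm, D₀ = 2.68×10⁻⁵ cm²/s at 37 °C):

```r
par <- obstruction_parameter(D_ratio = 0.59, r_probe = 1.2)
par
#> <obstruction_params> kappa = 0.4397 1/nm (from D/D0 = 0.59 at r = 1.2 nm)
rescale_diffusion(par, r_new = 0.14, D0_new = 2.68e-5)
#> 2.52e-05   # cm^2/s, i.e. ~94% of the free-water value
```

A scaled scaffold run (300 μm thick, pitch 120 μm, permeable struts at
0.93 D_w) takes a few seconds:

```r
sp <- scaffold_spec(total_thickness = 300, pitch = 120, alpha = 0.5,
                    voxel_size = 10)
p  <- kinetic_params(d_s = 0.93 * D_W_OXYGEN)
s  <- run_simulation(sp, p, dt_growth = 4, t_end = 1000,
                     stop_when_steady = FALSE)
s
#> <sim_series> 251 checkpoints over 1000.0 h (dt = 4 h)
#>   converged: FALSE
#>   top/bottom density at end: 1.5e+14 / 1.86e+13 cells/m^3
saturated_depth(s$rho_profile[, length(s$times)], p$rho_max, 10)
#> [1] 170   # μm: depth to which mean culture density reached 0.99 rho_max
```

The top slab has reached the maximum density (1.5×10¹⁴ cells/m³) while the
bottom, 300 μm from the media, is still far below it — the oxygen-limited
gradient the model exists to quantify. `sweep_scaffolds()` tabulates the
same metrics over strut permeabilities, volume fractions and arrangements.

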