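# psoct

Simulation and depth-resolved reconstruction for polarization-sensitive
optical coherence tomography (PSOCT), covering both benchtop raster
scanning and endoscopic imaging through a rotating fiber probe inside a
rigid cannula.

Myelinated white matter is birefringent: light polarized along the fiber
axis sees a refractive index that differs from the orthogonal polarization
by Δn ≈ 10⁻³, and the in-plane axis angle θ tracks the fiber orientation.
PSOCT measures the polarization state of backscattered light for two
illumination states orthogonal on the Poincaré sphere; each depth pixel of
thickness δz acts as a linear retarder with single-pass retardation

    φ = 2π · Δn · δz / λc ,   Stokes rotation vector  φ·(cos 2θ, sin 2θ, 0)

and the measured cumulative round trip at depth m is T_m = t(J_m)·J_m with
J_m = ΔJ_m ⋯ ΔJ_1. The package is for researchers developing or validating
depth-resolved PSOCT processing: it provides the exact SU(2)/SO(3)
retarder algebra, ground-truth phantoms (layered slabs and white-matter
tract-like structures), a forward measurement model (two-state
polarization modulation, spectral binning, static system and rotating
catheter distortions, ball-lens/surface reference reflections, speckle and
additive noise), and the matching reconstruction chain:

1. per-pixel Stokes rotation estimation from the two measured states;
2. symmetrization — fitting static corrections so that round trips have
   linearly polarized eigenstates (rotation axes in the QU plane);
3. catheter compensation by the retarder square root of the ball-lens
   round trip;
4. spectral-bin alignment and fusion;
5. iterative layer peeling into local Δn(z) and θ(z);
6. degree-of-polarization (DOP) masking and axis referencing to the
   sheath or another structure of known orientation;
7. composite hue/brightness rendering (θ → hue over a period of π, Δn →
   brightness over 0–1.3·10⁻³) and en-face / cross-sectional / rotational /
   unwrapped / tangential views with standard mean-projection extents.

The methods vignette (`vignettes/depth-resolved-polarimetry.Rmd`) explains
the model, the calibration identifiability analysis, all defaults, and the
limitations.

## Worked example

Simulate an endoscopic pullback through a two-layer birefringent phantom
surrounding the cannula — layer 1 with Δn = 5·10⁻⁴ at 20°, layer 2 with
Δn = 1.2·10⁻³ at −60° — through an unknown random system transmission and
a rotating catheter whose retardation varies sinusoidally with the
rotation angle, at 30 dB SNR, then reconstruct:

```r
library(psoct)
layers <- data.frame(
  thickness = c(250, 250), dn = c(5e-4, 1.2e-3),
  theta = c(20, -60) * pi / 180, reflectivity = c(1, 2)
)
phantom <- make_layered_phantom(layers, stacking = "cylindrical",
                                r_inner = 435 + 9.6,
                                voxel_pitch = c(20, 10, 10), x_extent = 300)
geometry <- make_scan_geometry("helical",
  aline_rate = 12800, rotation_rate = 50, pullback_speed = 1,
  n_rev = 2, depth_pixels = 128, delta_z = 4.8, probe_od = 870,
  x_start = 120, axis_center = phantom$cylindrical$axis_center,
  sheath = list(n_px = 2, dn = 8e-4, reflectivity = 2)
)
geometry
#> <psoct_geometry> helical: 2 rev x 256 A-lines/rev, 128 depth px (dz 4.8 um)
#>   pitch 20 um/rev, probe OD 870 um (2.6 Fr)

truth <- sample_ground_truth(phantom, geometry)
config <- measurement_config(snr_db = 30, n_spectral_bins = 1,
                             system = "random", seed = 7,
                             catheter = list(ret_mean = 0.4, ret_amp = 0.3,
                                             axis_mean = 0.3, axis_amp = 0.4))
tomogram <- synthesize_tomogram(truth, config = config)
tomogram
#> <psoct_tomogram> 512 A-lines x 128 depth px, 2 states, 1 spectral bin(s), ball-lens reference

map <- reconstruct_tomogram(tomogram, recon_config(
  axis_reference = list(mode = "sheath", known = 0, smooth = 65)
))
map
#> <psoct_polmap> 512 A-lines x 128 depth px; dn range [0, 0.0131564]; 14.1% masked

sel <- truth$dn > 1e-4 & map$mask
median(abs(map$dn[sel] - truth$dn[sel]))
#> 4.24e-05
median(abs(wrap_axis_angle(map$theta - truth$theta))[sel]) * 180 / pi
#> 3.55  # degrees
rgb <- composite_map(map)   # theta -> hue, dn -> brightness (0 - 1.3e-3)
```

The masked 14% are the pixels beyond the phantom (no backscatter, DOP
below threshold). The median birefringence error of ≈ 4·10⁻⁵ and axis
error of ≈ 3.5° are noise-limited; with noise disabled the same pipeline
recovers Δn to 10⁻⁶ and θ to well under 0.1° at every unmasked pixel.
`export_composite_png()`, `export_map_tiff()`, `as_volume()` and
`extract_view()` turn the map into display products; `inst/cli/psoct`
exposes `simulate` / `reconstruct` / `render` subcommands over YAML
configurations and containers.

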