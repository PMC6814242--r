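# gastrudyn

Signaling dynamics and fate patterning in micropatterned human
gastruloids.

Micropatterned human embryonic stem cell colonies treated with BMP4
self-organize concentric germ-layer territories: an extra-embryonic
CDX2+ ring at the edge, a BRACHYURY+ mesodermal ring, and a pluripotent
SOX2+ center. The signals that pattern them are dynamic: BMP activity is
uniform for ~12 h and then restricts to the colony edge, after which
waves of WNT and NODAL signaling move toward the colony center at
constant speeds. `gastrudyn` provides the computational tools for
studying this system:

* **Colony geometry** — circle/triangle/pacman/custom masks on a lattice,
  Euclidean edge-distance fields, and radial binning
  (`make_mask()`, `edge_distance()`, `edge_bins()`).
* **Activator-inhibitor reaction-diffusion** — the two-species model
  $\partial_t A = D_A\nabla^2 A + s_A A^2/(k_I I(1+\kappa_A A^2)) + k_A - kd_A A$,
  $\partial_t I = D_I\nabla^2 I + s_I A^2 - kd_I I$, with production
  confined to the colony and periodic boundaries, integrated by a
  compiled forward-Euler stepper (`rd_params()`, `simulate_rd()`).
* **Turing analysis** — homogeneous steady states, Jacobians, dispersion
  relations $\lambda(k)$, and the inside/outside classification with
  critical wavenumber $k_c^2 = (D_I f_A + D_A g_I)/(2 D_A D_I)$
  (`classify_turing()`, `dispersion_relation()`).
* **BMP→WNT→NODAL cascade** — WNT driven by a parametric BMP input with
  subcritical autoactivation, NODAL with threshold-gated autoactivation
  that makes its inward wave self-propagating; chemical perturbations as
  instantaneous parameter switches (`cascade_params()`,
  `simulate_cascade()`, `perturb_ldn()`, `perturb_iwp2()`).
* **Fate mapping** — duration-based phenomenological rules assigning
  EXE/MESO/CENTER territories from signaling histories, calibrated once
  on the 700-µm circle and applied unchanged to other sizes and shapes
  (`fate_rules()`, `assign_fates()`, `corner_expansion_metric()`).
* **Quantification** — DAPI-normalized nuclear radial profiles with
  120-µm local averaging, non-membrane profiles, half-maximum wave-front
  tracking with linear fits, cell-track statistics, and the
  similarity index (`nuclear_radial_profile()`, `track_wave()`,
  `track_stats()`, `similarity_index()`).
* **Gene-set selection** — DE filtering (p ≤ 0.05, FC ≥ 2, FPKM ≥ 1),
  union-of-top-100 set construction, Venn overlaps, correlation
  matrices, and the lineage-specificity filter (`filter_de()`,
  `union_top_set()`, `venn_overlap()`, `lineage_specific_genes()`).
* **Synthetic data** — seeded generators for wave profile series, colony
  image stacks, cell tracks, and expression matrices, each emitting its
  ground truth (`gen_wave_series()`, `gen_colony_images()`,
  `gen_tracks()`, `gen_expression()`).

## Worked example

```r
library(gastrudyn)

# Is the printed parameter set inside the Turing regime?
classify_turing(rd_params(D_A = 0.0025))
#> <turing_report> steady state A* = 8, I* = 80
#>   stable without diffusion: TRUE; Turing unstable: TRUE
#>   k_c = 0.4359 /px, wavelength = 14.41 px, max growth rate = 0.0004202
classify_turing(rd_params(D_A = 0.014))
#> <turing_report> steady state A* = 8, I* = 80
#>   stable without diffusion: TRUE; Turing unstable: FALSE

# Simulate the BMP-driven WNT/NODAL cascade on a 700-um colony and
# track the inward WNT wave (analysis window after BMP edge restriction)
mask <- make_mask("circle", 700, lattice_size = 128, pixel_size = 14)
sim  <- simulate_cascade(cascade_params(), mask, bmp_input())
track_wave(window_series(sim_profile_series(sim, "u"), t_min = 24))
#> <wave_track> threshold 0.209; front fit: 3.55 um/h x t + 54.4 um,
#>   R^2 = 0.993 (window 24-46 h)

# Predict fate territories with rules calibrated on this control run
rules <- calibrate_fate_rules(sim, meso_extent = 160)
fate_map_from_sim(sim, rules)
#> <fate_map_result> area fractions:
#>    EXE   MESO CENTER   NONE
#>  0.194  0.545  0.261  0.000

# Recover a planted 6.02 um/h signaling wave from synthetic profiles
gw <- gen_wave_series(times = seq(24, 44, 1), speed = 6.02, noise_sd = 0.01)
track_wave(gw$series)$fit$slope
#> [1] 6.186402
```

The first report says the spot-forming parameter set is diffusion-driven
unstable with a ~14-pixel pattern wavelength, while raising the activator
diffusivity to 0.014 leaves the same fixed point stable — in that regime
an edge-seeded activator expands inward instead of forming a pattern,
which is the behavior the signaling data show. The cascade run
reproduces the control phenotype: the WNT active domain's inner front
advances inward at a constant ~3.5 µm/h (R² = 0.99) while NODAL fills
the interior, and the calibrated fate rules partition the colony into
the concentric EXE/MESO/CENTER territories. The last line shows the wave
tracker recovering a planted 6.02 µm/h front within 3%.

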