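---
title: "Models and methods: signaling waves and fate patterning in micropatterned gastruloids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: signaling waves and fate patterning in micropatterned gastruloids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastrudyn)
```

# The biological system

Micropatterned human embryonic stem cell colonies treated with BMP4
("gastruloids") self-organize concentric germ-layer-like territories: a
CDX2+ extra-embryonic ring at the colony edge, a BRACHYURY+ mesodermal
ring inside it, and a pluripotent SOX2+ center. Live imaging shows that
the patterning signals are not static gradients: BMP signaling is uniform
for roughly the first 12 hours and then becomes restricted to the colony
edge, after which WNT and NODAL signaling activities sweep from the edge
toward the colony center at constant speeds. This package implements the
computational machinery for studying that process: reaction-diffusion
simulators, linear stability (Turing) analysis, fate-territory
prediction, the image-quantification recipes that produce radial
intensity profiles and wave-front fits, and the gene-set selection
procedures used to characterize the edge fate transcriptionally. A
synthetic-data module generates every input with known ground truth, so
the full analysis chain is testable without any external data.

# The activator-inhibitor model and Turing analysis

`rd_params()` parameterizes a two-species activator-inhibitor system on a
lattice with periodic boundary conditions:

$$\partial_t A = D_A \nabla^2 A + \frac{s_A A^2}{k_I\, I\,(1+\kappa_A A^2)} + k_A - kd_A\, A,
\qquad
\partial_t I = D_I \nabla^2 I + s_I A^2 - kd_I\, I .$$

Production is confined to the colony mask; outside it both species
degrade at `kd_out` and continue to diffuse, so the colony boundary is an
absorbing-ish rim rather than a wall. The default parameter set
(`s_A = 0.01, k_I = 1, k_A = 0, kd_A = 0.001, D_I = 0.4, s_I = 0.01,
kd_I = 0.008`, with `D_A` either `0.0025` or `0.014`) has a positive
homogeneous fixed point at $A^\* = 8$, $I^\* = 80$. Linear stability
analysis (`classify_turing()`) applies the standard two-species
conditions: the state must be stable without diffusion
($\mathrm{tr}\,J<0$, $\det J>0$) and destabilized by it
($D_I f_A + D_A g_I > 2\sqrt{D_A D_I \det J}$). With `D_A = 0.0025` the
system is Turing-unstable with critical wavenumber
$k_c^2 = (D_I f_A + D_A g_I)/(2 D_A D_I)$, i.e. a pattern wavelength of
about 14.4 px; with `D_A = 0.014` it is stable. Simulations agree: the
unstable set forms spots of the predicted wavelength; the stable set
relaxes to homogeneity, and an activator seeded at the colony rim expands
inward at a near-constant rate, ending in an interior that differs from
$A^\*$ only through diffusive boundary loss. Saturating the activator
production (`kappa_A > 0`, `rd_params_stripes()`) converts spots into
labyrinthine stripes, which `pattern_morphology()` distinguishes by the
area-weighted eccentricity of thresholded components.

Numerical scheme: forward Euler with a 5-point periodic Laplacian,
implemented in compiled code; the default step is 80% of the 2D explicit
diffusion stability bound. The unit tests hold this stepper to a
straight-loop R re-implementation at $10^{-12}$. Negative concentrations
are clamped at zero, and the inhibitor in the activator-production
denominator is floored at `i_floor = 1e-3` so that inhibitor-free initial
conditions remain finite; both choices act only in the first few steps of
edge-seeded runs. Wave analyses of simulated fields discard a short
initialization transient (the seeding spike of the edge-high initial
condition) before thresholding, mirroring the experimental situation in
which recording begins well after treatment.

Two estimator notes. The dispersion relation's most unstable wavenumber
(argmax of $\lambda(k)$) does not coincide with $k_c$ (the argmin of the
Hurwitz polynomial $h(k^2)$) — for the default set they are 0.32 and
0.44/px — so wavelength comparisons use $k_c$, which matches both the
brute-force minimizer and the simulated spot spacing. The simulated
wavelength itself is measured as a power-weighted centroid of the
radially averaged spectrum around its peak, because on a 64x64 lattice
the raw spectral bins near the pattern frequency are ~25% apart.

# The BMP-WNT-NODAL cascade model

`cascade_params()` defines the three-component model: an imposed BMP
input $b(x,t)$ drives WNT signaling $u$, which drives NODAL signaling
$v$:

$$\partial_t u = D_u \nabla^2 u + \beta_u + \alpha_b b
 + \alpha_u \frac{u^2}{K_u^2+u^2} - \gamma_u u,
\qquad
\partial_t v = D_v \nabla^2 v + \alpha_w u
 + \alpha_v\,[v \ge v_{th}]\,\frac{v^2}{K_v^2+v^2} - \gamma_v v .$$

Production acts inside the colony; clearance outside the colony
(`gamma_out_u`, `gamma_out_v`) represents dilution into the bulk medium
and keeps periodic images decoupled. Only the forward couplings
BMP→WNT→NODAL are modeled — no feedback on upstream signals.

The BMP input (`bmp_input()`) is parametric: uniform at
`uniform_level * amplitude` until `t_restrict = 12` h, then
`amplitude * exp(-d/edge_width)` with `edge_width = 40` um, where $d$ is
distance from the colony edge. The default `uniform_level = 0.15` makes
the restricted edge signal stronger than the early uniform phase. This
asymmetry is load-bearing: if the uniform phase matched the edge
amplitude, the 12-hour uniform exposure would leave every interior pixel
with at least as much accumulated drive as the edge retains after
diffusion, and no purely local nonlinearity could then seed activation at
the edge first. It is also consistent with the measured dynamics, in
which edge signaling after restriction is at least as strong as the early
uniform response.

The calibrated defaults encode two distinct wave mechanisms:

* **WNT is a slow integrator.** `gamma_u = 0.02`/h means WNT signaling
  decays with a ~2-day time constant, so the field near the edge
  accumulates the sustained BMP drive for the remaining 34 hours and ends
  5-6x above the decaying interior preload. The observation that WNT
  activity persists and keeps spreading for 30+ hours after its secretion
  is blocked motivates this slow turnover. The active domain (everything
  above half the spatiotemporal maximum, evaluated after the uniform-BMP
  transient, window start 24 h) then has an inner front that advances
  inward at a near-constant few um/h with $R^2 > 0.99$, driven by the
  combination of growing amplitude and diffusive penetration
  (`D_u = 400` um^2/h). WNT autoactivation (`alpha_u = 0.005`) is weak
  and subcritical: it raises the peak by a few percent but does not
  regenerate the wave. Consequently, switching it off at 15 h (the IWP2
  simulation) lowers the steady-state peak while leaving the peak
  position and the front speed within 10% of control — the experimentally
  observed dissociation. Setting the BMP coupling to zero at time zero
  (the LDN simulation) leaves WNT at less than 1% of the control
  threshold.

* **NODAL is a gated, self-propagating wave.** Below `v_th = 0.32` NODAL
  is driven only by WNT (`alpha_w = 0.7`); above it, autoactivation
  (`alpha_v = 0.5`, `K_v = 0.5`) makes the high state self-sustaining and
  the front invades the interior. The gate is crossed first near the
  edge, around hour 19-20, once the WNT ring has grown; blocking WNT
  secretion (both `alpha_u` and `alpha_w` to zero) before that leaves
  NODAL at zero, while the same block applied after the wave is
  established (the late block is simulated at 31 h, when the activated
  region is robustly above the self-sustaining level) does not prevent it
  from filling the colony — the binary early/late phenotype. At 46 h
  NODAL is high across the interior with a pronounced dip at the rim.
  The strict reading "rim below threshold" is not attainable at 14-um
  pixels: with `D_v = 1000` um^2/h the boundary layer over which the
  latched interior could fall below `v_th` is about one pixel wide and is
  fed diffusively from inside; the package therefore documents and tests
  the rim as a >2.5-fold dip rather than a sub-threshold strip.

All cascade parameter values were calibrated once, on the 700-um circular
colony, to reproduce the control dynamics (WNT ring near the edge,
linear inward front, interior NODAL activation initiating around hour
20), and are used unchanged for every perturbation, size, and shape.
Discretization: 14 um/pixel (the radius-25 px simulated colony maps to
the 700-um experimental colony), 128-pixel lattices for 700-1100 um
colonies, explicit Euler capped at dt = 0.02 h. Doubling the spatial
resolution changes the steady-state profile shape by under 3%; the
overall amplitude shifts by a few percent per resolution halving because
the discrete edge-distance convention (zero on the outermost pixel ring)
enters the BMP input with an O(dx) offset.

# Fate mapping

`fate_rules()` encodes duration-based phenomenological rules:
extra-embryonic (EXE) fate where cumulative above-threshold BMP exposure
reaches 20 h (the experimental minimum for CDX2+ differentiation);
mesodermal (MESO) fate where cumulative WNT *and* NODAL exposures both
reach a required duration; pluripotent CENTER elsewhere; precedence
EXE > MESO > CENTER. `calibrate_fate_rules()` fixes the level thresholds
from the control run itself (half the BMP amplitude; half the WNT
spatiotemporal maximum — the same convention as the active signaling
domain; the NODAL gate) and grid-searches the single free duration so the
mesodermal ring reaches 160 um from the edge on the 700-um circle, the
depth consistent with the reported BRA territory. The calibrated rules
are then applied without modification to a 200-um circle (the center
fate disappears), and to triangular and pacman colonies area-matched to
the 700-um circle, where the mesodermal territory reaches deeper at
corners than at edge midpoints: signaling from two converging edges
superposes along the corner bisector, so threshold crossings happen
earlier and exposure durations are longer there.

`corner_expansion_metric()` reports, per angular sector about the
centroid, the maximum edge distance reached by MESO together with the
maximum depth the sector offers at all. `corner_vs_midpoint()` compares
corner and midpoint sectors, normalizing by available depth only when the
two differ by more than 15% — raw extents are meaningful for the triangle
(whose corner and midpoint sectors offer equal depth) but meaningless for
the pacman mouth sectors, whose available depth is a fraction of the deep
sectors'. Measured ratios are ~1.24 (triangle) and ~1.59 (pacman),
against ~1.00 on circles.

# Quantification recipes

`nuclear_radial_profile()` implements the normalized nuclear intensity
recipe: nuclear-pixel extraction, local marker and DAPI means over
nuclear pixels within a 120-um disc, their ratio, edge-distance binning
(default 10 um) per colony, and cross-colony mean with standard error.
The 120-um default matches 700-um colonies; synthetic-recovery tests on
smaller colonies use a smaller radius, since the local average is a
smoothing operator whose bias on a sharp planted ring is otherwise the
dominant error. `nonmembrane_profile()` subtracts a membrane mask before
binning — the WNT-activity readout for membrane-localized reporters.

`track_wave()` defines the active signaling domain as the contiguous run
of bins above half the spatiotemporal maximum (the run containing the
maximum, when several exist), interpolates the run boundaries to the
sub-bin threshold crossing, and fits the inner front by ordinary least
squares over the advancing phase — from when the front leaves its initial
position until it reaches the deepest bin, permanently stops advancing,
or the series ends. $R^2$ is the standard coefficient of determination;
a never-advancing front reports a zero/NA slope by convention.

`track_stats()` computes per-cell displacement, signed radial
displacement (negative inward), arc displacement, and the 0/2/3/4 progeny
encoding from parent links, excluding single-observation tracks into a QC
count. `similarity_index()` is the fraction of cells whose within-62-um
neighborhood exceeds 60% same-type cells, over cells with at least one
neighbor.

# Gene-set selection

`de_table()` computes per-gene linear fold changes on condition means
with a 0.01 pseudocount; significance is pluggable (precomputed calls
from a count-based DE tool are the intended input; a replicate t-test
with BH correction is built in for synthetic data). `filter_de()` keeps
significant genes with fold change >= 2 (inclusive) and abundance >= 1
FPKM in at least one condition. `union_top_set()` takes the top 100 up-
and top 100 down-regulated genes per treatment (ties broken by gene id)
and returns the union; `venn_overlap()` counts all seven regions of the
three-set Venn. `lineage_specific_genes()` selects, per blastocyst
lineage, genes more than 5-fold (strict) above at least one other
lineage, not differentially expressed across that lineage's time points,
and expressed at >= 10 RPKM in at least two of three time points. Whether
ranking uses linear or log fold change is immaterial for positive values;
the package ranks on the linear ratio.

# The synthetic-data module

Generators are deterministic functions of their seed (a top-level seed
fans out through `derive_seed()`), restore the session RNG state, and
emit their ground truth alongside the data. `gen_wave_series()` builds
profile series whose half-maximum front advances at a planted speed;
`gen_colony_images()` builds DAPI/marker/membrane channels around
planted radial mean functions, returning the exact nuclear and membrane
masks used; `gen_tracks()` plants radial drift and a division hazard
(founders and first-generation daughters may divide, reproducing the
0/2/3/4 progeny codes); `gen_expression()` plants up/down gene sets with
controlled overlap on a log-normal baseline with multiplicative
log-normal replicate noise (sd 0.2). Its default overlap structure —
77 up- and 54 down-regulated genes shared by all three treatments, with
pairwise and unique complements summing to a 284-gene union of the
per-treatment top-100 lists — mirrors the reported counts, so the
selection machinery can be checked against them exactly.

What passing on synthetic data does and does not show: the generators
emulate the *structure* of the real inputs (radial organization, wave
kinematics, planted effect sizes) but not microscopy artifacts
(illumination gradients, segmentation errors, z-projection effects) or
count-level RNA-seq noise; recovering planted truth validates the
estimators' correctness, not their robustness to those artifacts. Masks
for synthetic images come from thresholding, not from a trained pixel
classifier; real classifier masks can be supplied since all masks are
explicit inputs.

# Problem sizes and determinism

Default analysis sizes: 64x64 lattices for homogeneous-domain pattern
tests, 96-128 px for masked colonies, 30,000 Euler steps for
activator-inhibitor steady states, 46 h of cascade time at dt <= 0.02 h.
All simulations are deterministic given the seed; the cascade model has
no noise source at all, so its perturbation comparisons are exact
reruns. Known limitations: the BMP input is a parametric stand-in rather
than the measured signaling movie (a user-supplied field can replace
it); the WNT model does not include the BMP-mediated edge repression of
WNT, so simulated early-BMP-block runs do not shift the WNT peak
outward as experiments do; and fate rules are calibrated to territory
boundaries, not to marker intensity levels.
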