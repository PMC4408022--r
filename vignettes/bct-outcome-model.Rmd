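---
title: "A multifactorial model of breast contour after breast-conserving therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multifactorial model of breast contour after breast-conserving therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Breast-conserving therapy (BCT) removes the tumour with a margin of
healthy tissue (lumpectomy) and irradiates the remaining breast.  The
cosmetic outcome — the contour of the treated breast months later — is
shaped by the interplay of gravity acting on soft tissues, the cavity
left by the resection, seroma pressure and tissue stiffening during
inflammation, wound healing that progressively fills the cavity with
scar, and radiotherapy-induced stiffening.  `bctshape` implements a 2D
(sagittal-plane) model of this chain and a calibration pipeline that
recovers a small set of patient-specific parameters from breast-profile
contours, one healing phase at a time.  Because no patient images are
distributable, the package ships a synthetic phantom generator that
emulates the structure of such data; every claim the test-suite makes is
a claim about the pipeline on that phantom.

## Tissue mechanics

The breast cross-section is modelled as a quasi-incompressible,
isotropic Neo-Hookean solid in plane strain.  The strain energy density
is

$$ W = \frac{\mu}{2}\left(J^{-2/3} I_1 - 3\right)
     + \frac{K}{2}\left(J - 1\right)^2 , $$

with $\mu = E/(2(1+\nu))$ and $K = E/(3(1-2\nu))$ derived from a Young
modulus and a Poisson ratio per tissue class (fat, glandular, skin,
scar, inflamed tissue).  All tissues use $\nu = 0.49$; densities are
0.9 kg/L for fat and 1 kg/L otherwise.  Gravity enters as a body force
in the reference configuration; seroma pressure is a follower traction
on the cavity wall.  The chest wall is clamped: the pectoral muscle is
orders of magnitude stiffer than breast tissue.

A plane-strain formulation replaces the common device of extruding a 2D
slice into a thin 3D mesh with out-of-plane displacements suppressed;
the two are equivalent, and the native 2D form avoids the detour.
Displacement-only quadratic (6-node) triangles with 3-point quadrature
carry the discretisation; with the penalty-type volumetric term and
$\nu=0.49$ they stay usefully far from volumetric locking, which the
acceptance checks confirm by bounding $|J-1| \le 0.05$ under seated
gravity.  The nonlinear system is solved by full Newton steps with a
cached sparse Cholesky factorisation; the residual typically spikes once
after the first step and then converges quadratically, so the solver
accepts non-monotone steps and backtracks only when a step inverts an
element, leaving robustness to adaptive load stepping (ramping gravity
in at most ~10 increments).  The convergence criterion is a relative
residual below $10^{-8}$.

Imaging happens under load (prone in the scanner), so the stress-free
geometry is not observed.  `estimate_unloaded()` recovers it by the
classical fixed-point iteration: subtract the forward-model mismatch
from the reference coordinates and re-solve, until loading the estimate
reproduces the observed nodes (default 0.05 mm, at most 30 cycles).
The package also supports the simpler convention of declaring the
prone/phantom geometry stress-free, which is what the synthetic study
uses; both conventions are exposed because the correct one depends on
how the images of a given study were acquired.

## Geometry: phantom, segmentation, mesh

`generate_phantom()` builds a tissue label map at MRI resolution
(0.7031 mm pixels): a perturbed half-ellipse breast profile on a
vertical chest wall, a 1 mm skin film, glandular tissue as smoothed
seeded blobs biased toward the retro-areolar region (the clinically
typical picture of a mostly-fatty breast with scattered glandular
tissue; no quantitative distribution is imposed, so phantom realism is
heuristic by construction), and an elliptical tumour bed (12 × 9 mm
default) above the nipple.  `generate_mri_image()` adds
class-mean intensities and Gaussian noise for the segmentation stage;
`fuzzy_cmeans()` performs the standard 3-class fuzzy C-means
segmentation (fuzziness m = 2, tolerance 1e-5 on centroid movement,
seeded percentile initialisation; these are conventional defaults), `tikhonov_smooth()` smooths the skin line with an
exact second-difference (curvature) penalty, and `extract_contour()`
traces region boundaries along pixel edges so that the polygon area
equals the pixel count times the pixel area exactly.

`build_mesh()` aggregates pixels into square cells no larger than the
requested element size and splits each cell into two quadratic
triangles (interior angles 45°–90°, so mesh quality is structural).
One resolution caveat matters: the 1 mm skin film is thinner than a
practical element, so boundary cells with at least a 25% skin-pixel
share become skin elements — the skin band is resolved at one element
width and its calibrated modulus absorbs the thickness ratio.  The
virtual lumpectomy removes the cells whose centre falls inside the
effective cavity ellipse.  The surgical margin is added radially to the
semi-axes (12 × 9 mm bed + 5 mm margin → 22 × 19 mm full axes), the
convention that matches how surgical margins are quoted clinically.

## Wound healing

Healing operates on the unloaded geometry, on a hexagonal lattice
(axial coordinates, spacing fixed at the MRI pixel pitch so lattice and
image live at the same resolution).  Sites are empty (wound) or
occupied (tissue).  A generic growth factor obeys

$$ \partial_t c - D \Delta c + \Lambda c = \chi_{a.l.} , $$

with $D = 0.05\,\mathrm{cm^2/day}$, $\Lambda = 0$, unit production
inside an *active layer* of occupied sites within a fixed width of the
wound edge, no-flux at the wound wall and a homogeneous Dirichlet
far-field on the lattice rim.  The solver is implicit Euler on the
7-point hexagonal Laplacian ($\tfrac{2}{3h^2}\sum_j (c_j - c_i)$), so
arbitrarily large steady-state steps are stable; the steady state is
declared when the per-day change falls below $10^{-6}$.

Cell division fills the wound: an empty edge site becomes occupied when
at least one adjacent occupied active-layer site succeeds in an
independent division attempt with probability

$$ p = F(c)\,\bigl(\alpha_0 + \alpha_1 \hat{E}\bigr), $$

where $F$ is a hard threshold on the local growth-factor concentration
(default: 10% of the steady active-layer level; the gate's shape is a
free modelling choice and the hard threshold is the simplest), and $\hat E \in [0,1]$ is the strain-energy density of
the loaded configuration normalised by its maximum and mapped onto the
lattice by nearest reference material point.  The fill probability of
an edge site is therefore $1 - \prod_o (1 - p_o)$, which makes the
expected area closed per sweep exactly the sum of fill probabilities
times the site area — the quantity the Monte-Carlo tests check — and
guarantees that $p \equiv 1$ peels exactly one lattice ring per sweep.

Two clocks are free conventions of the discretisation.  The CA
performs one division sweep per week (the coupling interval): division
probabilities then read as per-cell-cycle probabilities, and with the
fitted $\alpha_0 = 0.17$ the 22 × 19 mm cavity is still open at week
19 (about 9 × 8 mm loaded), the clinically observed regime for such cavities.  A
daily sweep at the same $\alpha_0$ would close the cavity in five
weeks.  Likewise the front speed is proportional to the lattice
spacing; fixing the spacing at the imaging resolution makes the speed a
property of the data resolution rather than a free dial.  Both choices
are made once, here, and used everywhere.

`coupling_loop()` alternates weekly: solve the loaded mechanics,
normalise the stress, map it to the lattice, integrate the growth
factor to steady state, run the division sweep, extract the wound
polygon and rebuild the mesh with the healed ring labelled scar.  With
$\alpha_1 = 0$ (the default, as the stress effect is secondary) the
trajectory does not depend on the mechanics, and the per-interval solve
is skipped as an optimisation; the loaded state is recomputed for the
final geometry.  `level_set_reference()` provides an independent
inward-front-propagation oracle used only for cross-checks.

## Calibration

Observed and simulated breast profiles are compared after rasterising
both onto a square ROI at the MRI resolution; the objective

$$ f(\alpha, s) = \sum_{i,j} \bigl\| C^{model}_{i,j}(\alpha)
   - s \cdot C^{obs}_{i,j} \bigr\| $$

counts mismatched raster cells (the per-cell norm is the absolute
difference of the indicator values, i.e. the symmetric difference —
the simplest choice, exposed as a pluggable metric).  The
nuisance $s$ absorbs the unknown photograph scale; it is minimised per
grid point over a fixed scale grid on [0.5, 2] that contains 1 exactly,
and the scaling is taken about the observed contour's centroid, which
also makes $f$ exactly invariant to common rigid translations of both
contours.  The ROI is anchored to the observed contour so the raster
grid translates with the data.

Each healing phase has its own forward model and 2–3 unknowns:

| phase | configuration | unknowns |
|---|---|---|
| 0 | pre-surgery, seated gravity | E_fat, E_glandular, E_skin (kPa) |
| I | cavity + 5 mm inflamed ring at 80 kPa, seroma pressure | λ₁ (fat/glandular stiffening), P (Pa) |
| II | healing for 19 weeks, pressure resorbed | λ₂ (stiffening), α₀ |
| III | wound closed, cavity filled with scar | λ₃ (stiffening), E_scar (kPa) |

Fitting is an exhaustive grid search that records the full objective
surface (the "surface response"), so sensitivity structure is read off
the same object as the argmin.  Phase fits thread forward: the phase-0
moduli become the baseline for phases I–III, phase II restarts from the
relaxed baseline with zero cavity pressure, and phase III assumes a
closed wound.  The λ scalings apply to the internal soft tissues only: inflammation
and radiotherapy predominantly affect fat and glandular tissue, so the
skin keeps its baseline modulus from phase I on.  Scar tissue in phase II inherits the glandular baseline times
λ₂, since no separate scar modulus exists before phase III introduces
one.  With α₁ = 0, the phase II wound trajectory depends only on α₀
and the seed, so trajectories are cached across the λ₂ axis.

The default synthetic study plants a clinically plausible reference
parameter set as ground truth — baseline moduli 3.7/9.5/25 kPa, λ₁ = 2.0 with P = 120 Pa, λ₂ = 1.2 with α₀ = 0.17, λ₃ = 1.7 with
E_scar = 24 kPa — generates noiseless observations from the forward
model, and requires the grid search to recover every planted value
exactly with f = 0 (`default_study_design()` spaces the grids so each
truth lies on a grid point).  On the phantom, all nine parameters are
recovered exactly and the zero set of each surface is the single truth
cell.  With 0.5 mm contour noise, recovery of the strongly identified
directions (the moduli and the λ scalings) is required only to one
grid cell.  The expected sensitivity anisotropy — f varies strongly in λ₁ but
weakly in P (the seroma bulge is local while f is a global contour
metric), and strongly in λ₂ but weakly in α₀ (closure saturates over a
valley of α₀ values) — is asserted as range ratios (> 5) along the
axis slices through the minimum, with the α₀ range read over its
no-selection valley [0.15, 0.5] on the noisy-observation study, since
a noiseless self-consistent observation has an exact-zero spike at the
truth cell that no measured surface has.

## Cosmesis metrics

Three simple readouts track the phases: the absolute vertical nipple
height difference between treated and control contours (the nipple on a
2D profile is the most anterior point, ties broken downward); the
breast area inside a disc of fixed radius centred on the nipple
(fixed radius, default 60 mm, evaluated by grid quadrature at r/400 resolution, accurate to well
under 1%); and the principal axes of the deformed cavity via the exact
area moments of its boundary polygon (for an ellipse the area
covariance is diag(a²/4, b²/4)).  Surface temperature series are handled as pass-through data only; the
package contains no thermal model.  `phase_classifier()` segments a metric series into three
linear-trend pieces by exhaustive least squares, flagging monotone or
constant series as degenerate.  The single simulated breast has no
contralateral control, so the phase-0 baseline contour serves as the
control in all synthetic metric comparisons.

## Problem sizes and numerical choices

The default study meshes the phantom at 2.8 mm elements (~1600
quadratic triangles, ~13k degrees of freedom), which keeps a warm-started
Newton solve near 0.2 s and the full four-phase grid study (616 + 143 +
88 + 231 forward solves plus 8 healing trajectories) under ten minutes
on one CPU; tests and the acceptance script use exactly these sizes.
Mesh-convergence and linear-oracle checks bound the discretisation and
solver error at this size (< 2% and < 1% respectively).  Degenerate
inputs are handled explicitly: zero-pressure/zero-gravity loads return
the trivial equilibrium, a closed wound yields zero-dimension cavities
flagged `closed`, empty contours and multi-component masks are errors,
and a tumour bed whose effective ellipse reaches the skin or chest wall
is rejected at phantom and lumpectomy stages.

## Limitations

The model is 2D: out-of-plane tissue recruitment, 3D cavity shape and
photograph-to-plane registration are all collapsed into the plane and
the scale nuisance.  The phantom emulates the topology and composition
of a sagittal breast section, not MRI physics or real glandular
morphology, so passing tests demonstrate pipeline correctness and
identifiability on phantom data — not clinical validity.  The CA clock
and lattice spacing are resolution conventions (see above); absolute
healing rates inherit them.  Contact, anisotropy, viscoelasticity and
residual stress are out of scope, as are Bayesian or gradient-based
calibration.
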