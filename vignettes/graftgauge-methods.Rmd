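---
title: "Methods: shape factors, quasi-1D wall shear stress, and migration risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape factors, quasi-1D wall shear stress, and migration risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftgauge)
```

## The problem

After endovascular repair of an abdominal aortic aneurysm (AAA), pulsatile
blood flow drags on the implanted stent-graft. Migration of the prosthesis is
a recognised late complication, and the drag force scales with both the
shear stress the flow exerts and the surface it acts on — that is, with the
*spatial configuration* of the graft relative to the aneurysm. `graftgauge`
turns 3-D lumen surfaces into a small set of dimensionless descriptors and a
per-patient long-versus-short-body comparison.

## Reference cylinders and shape factors

Every object (aneurysm AAA, long-body graft SL, short-body graft SS) is
summarised by its **reference cylinder**: the cylinder with the object's
axial height $h$ whose lateral surface equals the object's side surface $A$,
hence diameter $d = A/(\pi h)$. Heights are axis-aligned extents along the
cranio-caudal axis (default $+z$), not centreline arc lengths — the
common-height convention below treats height as one scalar distance per
patient. Side surfaces exclude end caps: synthetic lumens are generated
open-ended, and capped external meshes should pass through `strip_caps()`
(default angular tolerance 15°, end band 1% of the axial extent).

The per-object **shape factor** is

$$\varphi_{\mathrm{ref}} \;=\; \frac{V_{\mathrm{reference\ cylinder}}}{V_{\mathrm{object}}},$$

equal to 1 for a perfect open cylinder. The volume-based form is a design
choice: among the candidates consistent with "factor $>$ 1 when the real
geometry encloses less volume than its reference cylinder", it is the most
direct, and a diameter-based variant remains available through the
`definition` argument of `shape_factor_vs_cylinder()` should a different
convention be needed.

Aneurysm and graft are compared at the aneurysm's height
($h_{\mathrm{aneurysm}} = h_{\mathrm{graft}}$; the generator enforces this to
$10^{-6}$ mm, and `shape_factor_pair()` warns and uses the aneurysm height if
an external graft mesh is taller by more than 1%). The pair report carries

$$\varphi_{A\text{–}S} = \frac{A_{\mathrm{aneurysm}}}{A_{\mathrm{graft}}}
\qquad\text{and}\qquad
\frac{V_{\mathrm{graft}}}{V_{\mathrm{AAA}}},$$

both orientations of the side-surface ratio being exposed through the
`direction` argument (the reciprocal is sometimes the more natural report,
e.g. when quoting graft-to-aneurysm relations below 1).

**A geometric caveat worth knowing.** For a smooth axisymmetric lumen
$r(z)$, $\varphi_{\mathrm{ref}}$ is *not* guaranteed to exceed 1: writing
$A = 2\pi\int r\sqrt{1+r'^2}\,dz$ and $V = \pi\int r^2 dz$, the slope factor
$\sqrt{1+r'^2}$ pushes the factor up while Cauchy–Schwarz pulls
$(\int r\,dz)^2 / (h\int r^2 dz)$ below 1. Shallow, wide bulges can therefore
score marginally below 1 (we observe 0.97–0.99 for a few jittered synthetic
aneurysms), whereas bifurcated grafts — whose limbs add lateral surface at
little volume — always score well above 1. Cohort-level tests therefore
assert the expectation structurally for grafts and as a mean for aneurysms.
Patient-derived surfaces, being lumpier than the smooth synthetic family,
sit comfortably above 1 in practice.

## Blood rheology and the quasi-1D WSS surrogate

Blood is a Quemada shear-thinning fluid,

$$\mu(\dot\gamma) = \mu_p\left(1 - \tfrac12 k(\dot\gamma)\,\mathrm{Hct}\right)^{-2},
\qquad
k(\dot\gamma) = \frac{k_0 + k_\infty\sqrt{\dot\gamma/\dot\gamma_c}}
                     {1 + \sqrt{\dot\gamma/\dot\gamma_c}},$$

with defaults $\mu_p = 1.2\times10^{-3}$ Pa·s, $k_0 = 4.33$,
$k_\infty = 2.07$, $\dot\gamma_c = 1.88\ \mathrm{s^{-1}}$,
$\mathrm{Hct} = 0.40$ (the hematocrit of the modelled patient group) and
$\rho = 1050\ \mathrm{kg/m^3}$ — literature-typical whole-blood values, all
configurable via `rheology_params()`. Validity requires
$\tfrac12 k_0\,\mathrm{Hct} < 1$ so the zero-shear viscosity stays finite.

Full 3-D CFD is deliberately out of scope. The surrogate keeps the
assumptions of the flow problem — incompressible, laminar, rigid walls,
velocity inlet, pressure outlets — but solves them in reduced form:

1. **Tube reduction.** `tube_from_mesh()` slices the lumen at `n_stations`
   axial stations (default 33, placed at bin centres so the open ends are
   never sliced) and assigns each the equivalent radius
   $r = \sqrt{A_{\mathrm{slice}}/\pi}$. Below a bifurcation the two limb
   loops pool into one equivalent tube ($A$ summed). Slice areas come from an
   oriented shoelace sum over the mesh–plane intersection segments, with
   segment orientation taken from axis × facet normal; vertices exactly on a
   slice plane are nudged to the positive side deterministically.
2. **Quasi-static pulsatility.** A periodic inlet waveform $v(t)$ (templates
   `flat`, `sharp`, `real`; `n_steps` = 64 samples per cycle by default) sets
   $Q(t) = v(t)\,\pi r_{\mathrm{inlet}}^2$; incompressibility carries the
   same $Q$ to every station. Each (station, time) pair is treated as steady,
   fully developed pipe flow. Reverse-flow samples use $|Q|$: WSS is reported
   as a magnitude.
3. **Rabinowitsch–Mooney inversion.** For a generalized Newtonian fluid,
   $Q = \frac{\pi R^3}{\tau_w^3}\int_0^{\tau_w}\tau^2\dot\gamma(\tau)\,d\tau$.
   Substituting $\tau = \tau(\dot\gamma)$ makes the integrand explicit;
   `wall_shear_stress_tube()` evaluates it by adaptive quadrature
   (`stats::integrate`, relative tolerance $10^{-10}$, relaxed to $10^{-9}$
   for integrands with an endpoint derivative singularity such as power
   laws) and solves for the wall shear rate by bracketed root finding
   (relative tolerance $10^{-8}$, bracket expanded from $10^{\pm2}$ around
   the Newtonian value). $Q = 0$ returns exactly 0. Because the relation
   depends on $Q$ and $R$ only through the reduced flow
   $\Gamma = 4Q/(\pi R^3)$, the per-series evaluation solves each distinct
   $\Gamma$ once; when a series needs more than 48 distinct values, 48 exact
   solves on a logarithmic grid are interpolated with a natural spline in
   log–log space. The map is exactly linear (hence exactly interpolated) for
   Newtonian fluids, and for the Quemada law the interpolation error is
   orders of magnitude below the 0.5–1% oracle tolerances.
4. **Aggregation.** The instantaneous series value is the
   lateral-area-weighted mean of the station stresses;
   $WSS_{\mathrm{tot}} = \frac1n\sum_k WSS(\Delta t_k)$ is the cycle average
   (the time integral over one period divided by the period, since steps are
   uniform); the drag force is $F = WSS_{\mathrm{tot}}\cdot A$ with the side
   surface converted to m². A printed form of the WSS definition that mixes
   force and area units is resolved the only dimensionally consistent way:
   WSS is the mean shear traction in Pa, and force is recovered as
   $\tau\cdot A$ in N.

At 64 steps/cycle the cycle totals change by less than 0.5% when recomputed
at 256 steps; the trapezoid-quadrature agreement is asserted in tests at
$n = 512$.

**Scale caveat.** Quasi-1D Poiseuille-type stresses in a 20 mm aorta at
0.4 m/s peak are of order 0.1–1 Pa. Published 3-D CFD workflows for this
application report cohort WSS means orders of magnitude larger (hundreds of
Pa, presumably aggregated differently); no numeric matching of absolute WSS
levels is attempted — ratios ($\varphi_{WSS}$), orderings and regression
structure are the meaningful outputs.

## Waveform templates

`flat` is the constant plateau at peak velocity; `sharp` is a raised-cosine
systolic burst of full width $T/4$ centred at $T/8$ over a 10%-of-peak
baseline (time mean $\approx 0.21\times$ peak); `real` is a triphasic
infrarenal template — systolic $\sin^2$ lobe (30% of the cycle), one brief
reverse phase at −15% of peak (15% of the cycle), then a low diastolic
forward lobe at 5% of peak. The templates are parametric stand-ins with the
qualitative shapes used to standardise inflow across patients; measured
Doppler waveforms can be supplied as 2-column CSV via `read_waveform()`.

## Migration-risk rule

Per patient, both graft configurations are evaluated under every requested
waveform; the configuration with the lower mean drag force is flagged
(`long_lower_risk` / `short_lower_risk`). The comparison itself carries no
published threshold, so a 1% relative indifference band avoids resolving
numerical coin flips (`indeterminate`). Swapping the two graft meshes
provably flips the verdict, which the tests assert. On the default synthetic
cohort the short body — which departs more from a cylinder and carries more
lateral surface low in the sac — collects the higher drag in every patient;
the clinical literature reports the direction of this comparison
inconsistently, so the package reports it rather than asserting it.

## The synthetic cohort: what it emulates, what it does not

`make_cohort()` stands in for a 20-patient CT-angiography cohort that cannot
be redistributed. Defaults are clinical-scale: neck radius 10 mm, sac radius
27.5 mm (the 55 mm surgical threshold), height 130 mm, limb radius 6 mm,
bifurcation angle 15°, long/short trunk fractions 0.6/0.25. The AAA is a
surface of revolution with a C¹ raised-cosine bulge (centre 0.45, width 0.5
of height) — smooth by construction to avoid meshing artefacts. Grafts are
luminal surfaces only (no struts or fabric thickness): WSS acts on the
flow-facing wall. Limb tubes start with a 5% clearance between their circles
at the bifurcation so the two surfaces never touch (tangent circles would
weld a shared vertex and corrupt the virtual end-capping used by the volume
computation). Per-patient variability is multiplicative log-normal jitter
(σ = 0.08) on the dimensional parameters, with one RNG stream per patient id
so cohorts are reproducible and order-insensitive; the anatomical ordering
sac > neck > limb is re-imposed after extreme draws.

What the generator does **not** emulate: non-axisymmetric and thrombus-lined
sacs, neck angulation, iliac tortuosity, surface roughness of real
segmentations, or calibrated covariance between anatomy and hemodynamics.
Passing tests on this family therefore demonstrate correctness of the
geometric and hemodynamic operators and of the pipeline's statistics on
realistic scales — not clinical validity on patient data.

## Imaging QA choices

`region_grow()` uses 6-connectivity and an adaptive criterion
(|intensity − running region mean| ≤ tolerance), grown breadth-first, with a
final fixed-point sweep so the result is independent of visit order.
`fill_holes()` flood-fills the background from the grid border and promotes
unreachable cavities. The noise entering BI and CNR is, by default, the SD
pooled over the outside-body ROIs; the acquisition-protocol phrasing "ratio
of ROI mean and standard deviation" admits a second reading, available as
`noise_definition = "mean_over_sd"`. ROIs are in-plane circles of the stated
physical areas (80 mm² object, 100 mm² noise) given the voxel spacing, with
per-slice object means averaged across slices. The default phantom (bright
sphere, object 249, background 205.2, σ = 10 on an 80³ grid at CT-like
spacing 0.78/0.78/0.8 mm) reproduces the image-quality regime of the
motivating acquisitions — BI ≈ 25, CNR ≈ 4.4 — at which region growing with
tolerance 3σ recovers the object volume within 5% of ground truth.

## Statistics

`mean_sem()` uses the $n-1$ SD estimator; `pearson_cor()` delegates to
`stats::cor.test`; `spearman_cor()` is the Pearson correlation of mid-ranks
with the same $t$-transform p-value at every $n$ (chosen over the exact
permutation p for consistency across tied and untied samples; the rank
statistic itself matches `stats::cor(..., method = "spearman")` exactly).
`linear_fit()` is OLS via `stats::lm` with SEs from the residual variance at
$n-2$ df. The cohort regressions pair the volume ratio graft/AAA (x) with
the WSS ratio graft/AAA (y), one row per graft type per waveform — three
hemodynamic conditions, hence three rows per type. The conventional
significance threshold 0.05 is only ever reported, never used to filter.

## Problem sizes and runtime

Default meshes use 64 × 80 segments (~10k faces per object), chosen so that
discretisation errors of areas and volumes (≲ 0.1%) sit far below the 1–2%
tolerances of the geometric contracts; oracle tests refine to 20k–80k faces
where convergence itself is the claim. The 20-patient, 3-waveform demo
(`run_demo()`) evaluates 60 meshes and 180 WSS series in roughly a minute on
one CPU and is byte-reproducible for a fixed seed. Phantom experiments use
80³ grids (~0.5M voxels).

## Known limitations

- The quasi-1D surrogate has no secondary flows, no entrance effects, no
  recirculation in the sac — exactly the phenomena full CFD would add; its
  absolute WSS values are surrogate-scale (see above).
- Shape factors collapse geometry to one number; two different lumens can
  share a factor.
- The migration verdict compares drag magnitudes only; fixation forces,
  neck quality and device mechanics are out of scope.
- The imaging module validates on synthetic phantoms; DICOM ingestion of
  real series is intentionally not bundled.
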