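---
title: "Models and methods: FRPE indentation, inverse fitting, and µCECT partition analysis"
author: "frpecect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: FRPE indentation, inverse fitting, and µCECT partition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the constitutive model and its assumptions, the numerical machinery, the
design choices made where the method description leaves room, and what
the synthetic-data generators do and do not emulate.

## The material model

Cartilage is modelled as a fibril-reinforced poroelastic (FRPE) solid.
The total Cauchy stress is the sum of a non-fibrillar
(proteoglycan-dominated) matrix stress, a collagen fibril network
stress, and pore fluid pressure:
$\sigma_t = \sigma_{nf} + \sigma_f - p\,I$.

**Non-fibrillar matrix.** A compressible Neo-Hookean law,
$\sigma_{nf} = \tfrac12 K_{nf}\frac{J-1}{J} I +
\frac{G_{nf}}{J}(F F^T - J^{2/3} I)$, with
$K_{nf} = E_{nf}/(3(1-2\nu_{nf}))$ and
$G_{nf} = E_{nf}/(2(1+\nu_{nf}))$, $\nu_{nf} = 0.42$.
One property of this particular volumetric term deserves emphasis: its
small-strain linearisation has an **effective bulk modulus of
$K_{nf}/2$**, not $K_{nf}$ (expand $\tfrac12 K (J-1)/J \approx
\tfrac12 K\,\mathrm{tr}\,\varepsilon$). Related constitutive families
write $\tfrac12 K (J^2-1)/J$, which linearises to $K$. We implement the
law exactly as printed for this model and use the law-consistent
linearisation $(K_{nf}/2,\,G_{nf})$ wherever a linear-limit reference is
needed (the consolidation coefficient of the verification column, the
drained elastic oracle). This is a property of the implemented law, not
a numerical approximation.

**Fibril network.** Individual fibrils are tension-only and nonlinear:
$\sigma_{f,i} = \tfrac12 E_f^\varepsilon \varepsilon_{f,i}^2 +
E_f^0 \varepsilon_{f,i}$ for $\varepsilon_{f,i} > 0$, zero otherwise.
The network has 4 primary fibrils forming a mesh parallel to the
articulating surface and 13 secondary fibrils along the axes and all
45° diagonals; primary fibril stress is scaled by the relative density
$\rho_z C$ with $C = 12.16$ and $\rho_z = 1$ (homogeneous tissue).
Two details are not fixed by the model description and were decided
here:

* *Fibril strain measure*: logarithmic strain of the fibre stretch,
  $\varepsilon_f = \ln \lambda_f$, consistent with the
  finite-deformation framework.
* *Assembly*: each fibril contributes a rank-one Cauchy term
  $s\,(m \otimes m)$ along its deformed unit direction $m$, averaged
  within each family (weights 1/4 and 1/13). In the axisymmetric
  setting the in-plane/hoop shear components of these dyads cancel
  exactly over the symmetric direction set and are not tracked.

**Fluid flow.** Darcy flow with a void-ratio power law,
$k = k_0((1+e)/(1+e_0))^M$. With incompressible constituents the void
ratio follows the volume change, $e = (1+e_0)J - 1$, so
$k = k_0 J^M$ at a material point. The initial void ratio $e_0 = 3.5$
corresponds to a 78% fluid volume fraction.

## The finite-element solver

An axisymmetric displacement/pore-pressure formulation in total
Lagrangian form: bilinear quadrilaterals with equal-order pressure
("linear pore pressure continuum elements"), 2×2 Gauss integration,
backward-Euler time stepping, and a monolithic Newton iteration whose
element tangents are formed by central differences on the element
residual (steps: 1e-10 m on displacements, 1e-2 Pa on pressures — both
far below solution scales, far above round-off). The linear system is
banded (structured grid, nodes numbered along columns) and solved with
LAPACK's banded LU; factors are reused across Newton iterations while
the residual contracts faster than a factor 0.4 per iteration, and
refreshed otherwise (modified Newton). Convergence requires the
residual to fall below 1e-8 of its initial value, with absolute floors
of 1e-12 N (momentum) and 1e-20 m³/s (mass). A failed step is retried
with recursive halving of both the time step and the prescribed
displacement increment (up to 6 levels).

Equal-order u/p elements admit spurious checkerboard pressures in the
nearly undrained limit; a pressure-projection stabilisation
(Bochev–Dohrmann type) with coefficient 0.1 relative to the confined
modulus is applied by default (`feControl(stab = )`; 0 disables). The
verification against the consolidation series bounds the error this
introduces: under 1% at the test resolutions.

**Mesh.** A structured graded mesh of the cartilage layer: spacing is
geometrically refined on both sides of the indenter edge (the stress
concentration of the flat-ended punch) and mildly towards the
articulating surface. The default density, 25 × 14, gives the
converged 350-element mesh; refining to 1400 elements moves equilibrium
forces by under 2%.

**Boundary conditions.** The indenter is prescribed axial displacement
on surface nodes within the contact radius with free radial sliding
(frictionless bonded-normal contact; after the 40 kPa pre-stress the
indenter remains in full contact, so no inequality contact search is
needed). The bottom is fully fixed (samples screwed to the holder
through bone); the axis is a symmetry line. Free draining ($p = 0$)
applies on the articulating surface outside the contact and on the
lateral edge; the contact zone, axis, and bone interface are
impermeable.

**Protocol driver.** The pre-stress displacement is found by secant
iteration on drained equilibrium solves until the mean contact pressure
is within 0.5% of 40 kPa (measured deformations of a few tens of µm,
consistent with the experimental range). The pre-stress state is
simulated and kept, i.e. its stress state is the baseline
(`prestressMode = "simulated"`; `"reference"` starts unstressed).
Each of the four ramps compresses 4% of the *remaining* thickness —
interpreted as initial thickness minus total imposed compression,
including the pre-stress displacement, so amplitudes shrink slightly
step to step — at 100% of thickness per second, resolved with at least
20 uniform substeps; each 600 s hold is integrated on a geometric grid
(default 60 steps) whose first step continues the ramp resolution. The
output curve carries every solver sample; `resampleLogGrid()` maps it
onto a log-spaced reporting grid (e.g. 1000 points per hold) when a
dense fixed-format export is wanted.

The sample radius is not part of the protocol description (plugs were
quartered from 8.5 mm cylinders); the default is 2 mm. At that radius
the lateral boundary is several contact radii away; halving or doubling
it moves the simulated forces by well under the fitting tolerances, and
it is exposed as `sampleRadius` for sensitivity work.

## Inverse identification

`fitFRPEParameters()` minimises the mean-squared relative force error
over relaxation steps 2–4 (ramp start of step 2 through the end of hold
4), the samples weighted uniformly on the reporting grid — the
geometric hold grid by itself emphasises early relaxation where the
information about permeability lives. The optimiser is bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) on the relative-residual
vector; $k_0$ is optimised in $\log_{10}$ space because its plausible
range spans orders of magnitude. Bounds: $E_f^0 \in [0,5]$,
$E_f^\varepsilon \in [0,100]$, $E_{nf} \in [0.01,5]$ MPa,
$k_0 \in [10^{-17},10^{-13}]$ m⁴/(N·s), $M \in [0,50]$ — the reported
cartilage ranges with wide margin. Multistarts are Latin-hypercube
draws over the bounds (seeded, default 8); each start is screened with
a single forward solve and the best few (default 3) are polished with
the full local optimisation. This screening keeps the cost of the
multistart layer proportional to the number of *promising* basins
rather than all starts; on noiseless synthetic curves the truth is
recovered to numerical precision, and each parameter within 10% is the
acceptance-level requirement.

Fit quality is reported as $R^2$ over the fitting window. Samples whose
best fit falls below a configurable floor (default 0.8) are flagged
with a warning, never silently excluded — the exclusion decision
belongs to the analyst.

## µCECT partition analysis

The bulk partition is
$100 \times (\overline{HU}_{96h} - \overline{HU}_{0h}) /
HU_{bath}$ over the full-depth cartilage mask ("bulk cartilage
attenuation" is taken as the mask mean; the mask is supplied, or comes
from the phantom generator). The formula is invariant to any global
additive HU offset present at both timepoints.

Dual-contrast data use an affine calibration
$(HU_{low}, HU_{total})^T = A\,(C_{Ta}, C_I)^T + b$ fitted by least
squares to mixtures of known concentrations (the model is affine — the
background term $b$ is estimated, not assumed zero — and the fit
reports its condition number and residual RMS). Concentrations are
recovered by inverting the 2×2 system; for partitions the 0 h volumes
are subtracted first, so the offsets cancel and tissue background drops
out. Negative decomposed concentrations are retained in voxel maps and
truncated at zero only in bulk summaries, with a message. Only the low
(10–80 keV) and total (10–120 keV) bins are used; a high bin, if
present, is ignored. Bath concentrations are configuration constants:
30 mg/mL Ta₂O₅ for single-contrast, 20 mg/mL Ta₂O₅ + 40 mg(I)/mL for
dual. The combined partition divides the Ta partition by the iodixanol
partition per sample; cohort summaries average these per-sample ratios.

## Statistics

Spearman correlation is the Pearson correlation of mid-ranks; p-values
come from the exact permutation distribution of the rank statistic for
$n \le 10$ without ties (a compiled enumeration) and the
t-approximation otherwise. Mann–Whitney U uses rank sums with mid-rank
ties; the two-sided p is exact (null distribution of U) when there are
no ties and $n_1 n_2 \le 400$, and a tie-corrected normal approximation
with continuity correction otherwise. Confidence intervals are t-based
(mean ± $t_{0.975,n-1}\,s/\sqrt n$) — the reporting convention does not
state whether its intervals are t-based or bootstrap; t-based is chosen
and labelled. No multiple-testing correction is applied by default,
matching the reporting convention; `holm = TRUE` adds Holm-adjusted
p-values to the correlation table.

## What the generators emulate — and what they do not

`generateForceCurve()` is the forward solver plus multiplicative
Gaussian force noise (load-cell relative error; the experimental noise
model is not documented, so multiplicative noise at a configurable
coefficient of variation is a modelling choice). Ground truth always
travels with the data.

`generateDualEnergyPhantom()` voxelises an osteochondral plug (bone
base, cartilage layer) in a contrast bath and renders HU as an affine
map of local agent concentrations plus Gaussian noise. The attenuation
coefficients are synthetic constants chosen to put the bath near
3000 HU — the pipeline requires only affine consistency between
generator and calibration, not physical cross-sections. The 96 h state
prescribes cartilage concentrations as configured partitions times bath
concentrations; the 96-hour diffusion *process* is intentionally not
simulated, so time-course questions are out of reach of these phantoms.
Nor do they include beam hardening, scatter, or partial-volume effects
— passing the phantom tests shows the analysis algebra is right, not
that the method is robust to those acquisition physics.

`generateCohort()` draws three latent factors per sample — proteoglycan
content, porosity, collagen organisation — and maps them through
monotone log-linear links to the five parameters and the partitions,
with location entering as a latent mean shift. Marginal scales are
anchored to the reported group means and confidence intervals; the
loadings were pre-tuned once (using the Gaussian-copula relation
$\rho = 2\sin(\pi\rho_s/6)$ and the balanced two-group pooled-covariance
identity) so that the default pooled Spearman correlations approximate
the reported set — most tightly the single-contrast tantalum partition
against $E_{nf}$ (0.84) — and then frozen. Because the iodixanol
marginal is very tight while its location separation is large, the
within-arm iodixanol correlations sit somewhat below their reported
magnitudes; they are sign-correct and the monotone structure is what
the downstream checks rely on. The generator makes no attempt to model
measurement error correlations between the biomechanics and imaging
arms.

## Problem sizes used in the tests

The suite chooses sizes that keep each experiment's statistical or
numerical question answerable at desk scale: the consolidation
verification uses a 40-element-high column with 40 substeps per output
time; recovery experiments run on an 8 × 5 mesh with 30 hold steps per
600 s hold (the "coarse demo" configuration — generator and fit share
it, so discretisation error cancels out of the recovery question);
phantoms are 48³-ish grids; cohort-structure checks use 500 samples per
location; the Mann–Whitney null calibration uses 2000 replicates at
n = 15/15. The production mesh (350 elements) and hold resolution are
the package defaults.

## Known limitations

* Homogeneous tissue: no depth-dependent composition, no osmotic
  swelling, no fibril viscoelasticity.
* Frictionless bonded-normal contact; no large sliding, no subchondral
  bone compliance, no inertia.
* The fitted model and the generator share the constitutive family, so
  recovery experiments quantify identifiability, not model adequacy for
  real tissue.
* Equal-order u/p stabilisation trades a small consistent perturbation
  for pressure stability; pressure fields at extremely coarse meshes
  and tiny time steps should be read with that in mind.
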