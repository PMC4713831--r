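---
title: "Silhouette-based 3D fish tracking and inverse dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silhouette-based 3D fish tracking and inverse dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fishtrack3d)
```

# The problem

Undulatory swimmers such as larval zebrafish move in three dimensions:
they yaw, pitch and roll while bending their body into travelling waves
and escape bends. Quantifying that motion from multi-camera high-speed
video — and turning it into resultant forces and torques — requires a
body representation whose pose and deformation can be optimised against
images, plus an inverse-dynamics formulation valid for a *deforming*
body, whose moment of inertia changes from frame to frame.

`fishtrack3d` implements that chain end to end:

1. a parameterised 3D body model built from digitised cross-sections;
2. pure-bending deformation driven by a midline curvature profile;
3. calibrated virtual cameras rendering binary silhouettes;
4. gradient-based segmentation of the real (or synthetic) video;
5. per-frame Nelder–Mead optimisation of the 13-parameter state
   (snout position, Tait–Bryan head angles, curvature at 7 control
   points) against the silhouettes;
6. penalised least-squares smoothing and polyhedral inverse dynamics
   (centre of mass, mass, resultant force, angular momentum, resultant
   torque).

Because ground truth is unobtainable for a real fish, the package ships
two fully synthetic verification experiments (a prescribed swimming
sequence rendered to degraded images, and a rigid cylinder driven by
known forces and torques) that regenerate themselves from code.

# Body model and deformation

A model is a longitudinal series of `M` cross-sections (default 51),
each a closed contour of `P` circumferential points (default 40) in its
local section plane. Sections are assembled from up to three
*components*: the trunk (a closed periodic cubic spline through
digitised control points), the eyes (a mirrored pair of superellipses,
i.e. Lamé curves $|y/a|^n + |z/b|^n = 1$), and the median fin fold (an
ordinary ellipse). Components are merged by their *outermost contour*:
`P` rays from the section origin, keeping the farthest crossing of any
component. Sampling all sections at the same canonical ray angles
(starting dorsally, winding consistently) lets corresponding points be
stitched into quadrilateral faces; terminal sections collapse to single
points so the triangulated surface is watertight, which the volume
integrals require. Component parameters are interpolated along the body
with natural cubic splines, clamped to zero outside each component's
longitudinal extent.

The shipped `zebrafishModel()` is a synthetic stand-in whose
proportions follow a 5 mm larva (big head with bulging eyes, slender
trunk, tall median fin fold, displaced volume just under 1 mm³); no
measured cross-section tables were available, so the fixture is
documented as synthetic and every quantitative check uses either it or
primitive solids with closed-form properties.

Deformation follows the pure-bending assumption: the body bends only
laterally, and transverse sections stay planar and perpendicular to the
deformed centreline. Curvature $\kappa(s)$ is prescribed at 7 control
points, interpolated by a natural cubic spline, and pinned to zero over
the stiff anterior 10% of the body. The local tangent angle
$\theta(s) = \ell \int_0^s \kappa(u)\,du$ is obtained *analytically*
from the per-piece quartic antiderivatives of the spline; centreline
points follow by marching segments of conserved length rotated by the
midpoint tangent angle, so arclength is preserved exactly by
construction. Bending happens in a head-fixed frame (snout at the
origin, `x` increasing caudally, `z` dorsal); the posed surface is that
frame rotated by the intrinsic yaw–pitch–roll matrix
$R = R_z(\psi) R_y(\vartheta) R_x(\varphi)$ and translated to the snout
position. Yaw and pitch are thus the azimuth and (negated) elevation of
the snout-to-tail axis; positive curvature bends the tail toward the
head frame's $+y$. Both interpolation and integration are linear in the
control values, so the deformation machinery is precomputed as two
small matrices and a full posed mesh costs a handful of matrix
products — the tracker evaluates it thousands of times per frame.

# Cameras and rendering

The default camera is orthographic: the emulated rig uses collimated
back-light (shadowgraph imaging), which makes magnification independent
of depth; a standard perspective pinhole is available through
`cameraModel(type = "perspective")`. The verification rig is one
vertical camera and two cameras at 30° to horizontal (azimuth ±90°),
all with a 15 mm field of view. Rendering uses the pixel-centre rule: a
pixel belongs to the silhouette iff its centre falls inside at least
one projected, filled triangle. For closed meshes only front-facing
triangles are rasterised (their union already covers the silhouette).
Rasterisation and the symmetric-difference count are compiled code; the
rest of the pipeline is plain R.

# Segmentation

Larval fins are translucent: intensity thresholding fails, but their
edges still carry spatial gradient. Frames are therefore segmented by
thresholding the Sobel gradient magnitude, filling all holes, and
keeping the largest connected component. Illumination flicker is
removed beforehand by normalising each frame's fish-free background
mean by its sequence maximum. The default threshold is 0.35 of the
robust (99.9th percentile) maximum gradient, which makes the result
invariant to global affine intensity rescaling; the band of
supra-threshold pixels straddles the true edge by roughly its
half-width, so a final morphological erosion of 2 px (matched to that
half-width) restores edge placement — on the synthetic verification
chain this raises the silhouette IoU against the clean rendering from
about 0.95 to 0.98 or better. Both threshold and erosion radius are
per-dataset configuration.

# The tracking objective and optimiser

The per-frame objective is
$f_\mathrm{tot}(\Omega) = f_\mathrm{GoF}(\Omega) + f_\mathrm{reg}(\Omega)$:
the total count of pixels that differ between rendered and segmented
silhouettes over all cameras (union minus intersection), plus a
regulariser
$f_\mathrm{reg} = \int_0^1 w(s)\, (\mathrm{d}\kappa/\mathrm{d}s)^2\,
\mathrm{d}s$ with $w(s) = c_0 e^{-c_1 s}$, which suppresses
unrealistically steep curvature gradients, most strongly near the head.
Because the spline is linear in the control values, $f_\mathrm{reg}$ is
a quadratic form whose matrix is precomputed once with Gauss–Legendre
quadrature per spline piece. Defaults $c_0 = 40$ (px² units,
commensurate with the pixel counts) and $c_1 = 1.5$ put the penalty at
a few percent of a typical misfit and weight the head about four times
more strongly than the tail — enough residual weight at the weakly
observed tail tip to suppress spurious curvature spikes there. When the
first control point sits at the stiff-head boundary, the transition
from the clamped (zero-curvature) region is charged as a linear ramp
over half a control spacing; without it the first control value is a
free hinge that trades off against yaw. Both constants are
configuration and are recorded in the output metadata.

The binary pixel count is piecewise constant below the pixel scale,
which starves simplex optimisers near convergence, and it is multimodal
for strongly bent poses. The optimiser therefore works in two stages
per frame. The *coarse* stage runs re-centred Nelder–Mead passes
(`stats::optim`) over the rigid-motion subspace, the curvature
subspace, and the joint space, on a *smoothed surrogate*: the observed
masks are downsampled 2× and Gaussian-blurred (σ = 0.75 px), and the
cost becomes $\sum |\mathrm{rendered} - \mathrm{observed}|$, which is
identical to the symmetric difference for binary masks but gains
sub-pixel sensitivity at graded edges. The *fine* stage, with ten-fold
reduced tolerance, runs an adaptive Nelder–Mead (`pracma::anms`) over
the joint space on the surrogate and then polishes on the exact binary
objective at full resolution, so reported objective values are the
plain pixel counts. Parameters are scaled so an initial simplex step is
a few pixels of position, about half a degree of angle, and a curvature
step of the same pixel order.

Frames are initialised by linear extrapolation from the two previous
solutions (one previous state is copied, with curvature clamped to a
physiological ±2.5 /mm; the first frame comes from clicked snout/tail
pixels triangulated by least squares). Quadratic extrapolation was
evaluated and rejected: it amplifies single-frame estimation noise
roughly threefold and destabilises the feedback loop between fitting
and prediction. If a frame's objective exceeds a baseline — 1.3 times
the best objective of the last 12 frames, the headroom covering the
legitimate rise of the misfit floor as the body bends — by more than
the restart threshold (default 25%), the fit is retried from
randomised perturbations of the prediction (1% body length, ~4°, 20%
of the curvature range, escalating per retry); retries alternately
shift the curvature profile by one control point (targeting
travelling-wave phase locks, the recurring local-minimum family of
undulatory motion) or reset it to zero (recovering from runaway
curvature oscillations). The previous frame's solution is also tried
as an alternative start. A frame that exhausts its retries is flagged
but still returned.

The tracker deliberately fits a coarser tessellation (P = 28, M = 35)
than the renderer uses in the synthetic experiments: in real use the
model never matches the imaged fish exactly, and the mismatch keeps the
verification honest.

# Smoothing and inverse dynamics

Derived quantities need second time derivatives, so the raw tracked
parameters are smoothed with a Whittaker penalised least-squares
smoother with a fourth-order difference penalty (cubic polynomials pass
unchanged); nothing downstream is smoothed again. The default penalty
weight places the smoother's half-power frequency at 150 Hz (for
2000 fps data): above the tail-beat frequency and its first harmonics,
below the frame-rate noise band. Per-column generalised
cross-validation is available (`lambda = NA`) but is not the default:
tracking errors are strongly autocorrelated in time, for which GCV is
known to undersmooth — on the verification sequences it selects weights
three to four orders of magnitude too small and yields nonphysical
accelerations. The weight actually used is logged in the metadata and
can be overridden. Derivatives use
second-order finite differences (central inside, one-sided at the
ends); the first and last 5 frames are flagged as edge-affected and
excluded from verification comparisons.

Mass properties assume the fish has the density of water
(1000 kg/m³) throughout. Volume, centre of mass and the inertia tensor
come from exact divergence-theorem sums over signed tetrahedra (one per
surface triangle, apex at the origin), which are exact for polynomial
integrands. The resultant force is $F = m\,a_\mathrm{CoM}$ — it
reconstructs the resultant of all external fluid forces, with added
mass implicitly included.

For a deforming body the moment of inertia is not constant, so torque
cannot be $I\dot\omega$. Instead the package evaluates the total
angular momentum
$L = \rho \iiint_V r^*(x) \times v^*(x)\, \mathrm{d}V$ (positions and
velocities relative to the CoM) and differentiates it in time. The
volume integral is reduced to the same signed-tetrahedra sum with the
apex at the CoM, where $r^* = 0$: within each tetrahedron the vertex
velocity field is interpolated linearly, making the integrand quadratic
and the integral available in closed form
($\iint \lambda_i \lambda_j = V/20\,(1 + \delta_{ij})$ over a
tetrahedron). For rigid motion the true velocity field *is* linear in
position, so the rigid-body limit $L = I\omega$ is exact up to the
surface tessellation — the package's validation exploits this, plus a
Monte-Carlo volume-sampling oracle for a genuinely deforming
two-segment body. Per-vertex velocities come from central differences
of the matched vertex trajectories (the mesh topology is identical
across frames). Torque is the second-order finite difference of $L$.

Forces and torques are also expressed in a fish-aligned frame:
$x_\mathrm{fish}$ along the moment-of-inertia-weighted mean body angle
in the deformation plane (section area × squared CoM distance as
weights), $z_\mathrm{fish}$ normal to that plane, $y_\mathrm{fish}$
completing the right-handed frame, and a "forward" force component
along the CoM velocity direction.

# The synthetic verification experiments

**Swimming fish.** The default motion script emulates a 5 mm larva at
2000 fps: a C-start-like bend of 20 ms whose head–tail angle peaks near
170°, blending smoothly into continuous swimming with a 35 Hz
travelling body wave (wavelength one body length, tail-biased
amplitude envelope), a 50° net turn, a speed ramp to 80 mm/s, small
roll/pitch/yaw oscillations and a slight dive. All time courses are at
least C², so reference forces and torques are well defined; positions
integrate an analytic speed along an analytic heading with a 64×
oversampled trapezoidal rule. The sequence is rendered through the
three-camera rig at 1024² over a 15 × 15 mm field of view
(≈340 px along the fish; 512² and 2048² variants give ≈170 and
≈680 px) and degraded exactly as the emulated imaging chain:
Gaussian blur σ = 1 px, contrast reduced 45% about the light
background, and additive Gaussian noise (σ = 5% of full scale)
generated at 10× lower resolution, oversampled nearest-neighbour and
blurred with σ = 5 px. With a fixed seed the sequences are
bit-reproducible.

What the generator does *not* emulate: occlusions by other fish,
refraction, lens distortion, motion blur within the exposure, and any
true fluid–structure interaction (the kinematics are prescribed, not
simulated). Passing the verification bounds therefore demonstrates the
internal consistency and numerical fidelity of the chain, not
robustness to every artefact of real video.

**Rigid cylinder.** A 1.25 mm × 5 mm cylinder receives prescribed
multi-frequency force and torque profiles at the µN / µN·mm scale.
Translation integrates trapezoidally; rotation uses the midpoint rule
(axis-angle increments from the midpoint angular velocity). The
resulting mesh sequence feeds straight into the inverse-dynamics chain,
and the recovered profiles match the prescribed ones to a fraction of a
percent RMS away from the trimmed edges.

# Problem sizes and numerical choices

The shipped verification runs use a 110-frame sequence at 1024² for
the motion and dynamics checks (the test suite uses 90 frames, and a
16-frame slice per resolution for the resolution-ordering check);
these lengths cover the C-start, the blend and over one full tail-beat
cycle of continuous swimming while keeping a desk-scale runtime.
Other defaults: P = 40 / M = 51 sections for rendering and dynamics,
P = 28 / M = 35 for tracking; 6-point Gauss–Legendre quadrature per
spline piece for the regulariser; simplex tolerances 10⁻³ (coarse) and
10⁻⁴ (fine), the ten-fold ratio being structural; GCV grid
λ ∈ 10⁻²…10¹⁰ (quarter-decade steps, then refined). Degenerate inputs
are handled explicitly: empty masks raise "no fish found", non-watertight
meshes are rejected by the volume integrals, nearly parallel camera rays
make triangulation fail loudly, and series shorter than 9 samples cannot
be smoothed with the fourth-order penalty.

# Known limitations

- Per-frame head orientation has a shallow trade-off against anterior
  curvature (the regulariser suppresses head-side curvature gradients,
  and yaw compensates), and the curvature at the collapsing tail tip is
  nearly unobservable in the silhouettes: its misfit footprint is a few
  pixels, so the integrated head-tail angle is the weakest tracked
  quantity. Orientation errors of several degrees and substantial
  head-tail angle errors during the fastest phases are intrinsic to the
  silhouette information at this resolution with this model; snout and
  centre-of-mass positions (the quantities that drive the resultant
  force) are recovered one to two orders of magnitude more precisely.
- Resultant force and torque errors inherit the orientation/curvature
  uncertainty of the tracked states; the inverse-dynamics chain itself
  is verified to fractions of a percent on the rigid-cylinder round
  trip, so those errors are tracking-limited, not dynamics-limited.
- The tracker is causal (no global refinement over all frames); a
  smoothing re-pass could reduce mid-sequence excursions but is
  deliberately out of scope.
- Torsion, out-of-plane bending, pectoral fins and independent fin-fold
  deformation are excluded by the pure-bending parameterisation.
- Constant density is assumed throughout the volume; a swim bladder or
  tissue-density differences would require a volumetric mesh with a
  density field.
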