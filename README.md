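# fishtrack3d

Automated 3D tracking and inverse dynamics of swimming fish from
multi-camera silhouette video.

Larval fish manoeuvre in three dimensions: they yaw, pitch and roll while
bending their body into escape bends and travelling waves. `fishtrack3d`
reconstructs that motion from synchronised high-speed video and converts
it into resultant forces and torques. It is aimed at experimental
biomechanics work on undulatory swimmers (larval zebrafish being the
reference case), where silhouette video from two or more calibrated
cameras is the standard recording modality.

## The method

A parameterised body model — a longitudinal series of merged
cross-section contours (trunk spline, eye superellipses, fin-fold
ellipse) lofted into a watertight triangulated surface — is deformed by
pure bending: curvature κ(s) is prescribed at 7 midline control points,
interpolated by a natural cubic spline, pinned to zero over the stiff
anterior 10%, and integrated analytically into the local tangent angle
θ(s) = ℓ∫κ ds. The posed surface (intrinsic yaw–pitch–roll rotation plus
snout translation) is rendered through calibrated virtual cameras
(orthographic by default, matching collimated-light shadow imaging), and
the 13-parameter state Ω is found per frame by minimising

    f_tot(Ω) = f_GoF(Ω) + f_reg(Ω)

where `f_GoF` counts the pixels in the symmetric difference between
rendered and segmented silhouettes over all cameras, and
`f_reg = ∫ w(s) (dκ/ds)² ds`, `w(s) = c₀e^{−c₁s}`, penalises unsmooth
curvature most strongly near the head. Minimisation is two-stage
Nelder–Mead (coarse, then ten-fold reduced tolerance) with prediction
from previous frames and randomised restarts.

The tracked parameters are smoothed with a Whittaker penalised
least-squares smoother (4th-order difference penalty, GCV-selected
weight), and post-processed by exact polyhedral volume integrals into
centre-of-mass motion, mass, resultant force `F = m a_CoM`, the angular
momentum of the deforming body `L = ρ∭ r* × v* dV` (reduced to closed-form
sums over signed tetrahedra with linearly interpolated vertex
velocities), and the resultant torque `τ = dL/dt`.

Everything is validated against two built-in, fully synthetic
verification experiments: a simulated swimming larva with exactly known
motion rendered to degraded three-camera images, and a rigid cylinder
driven by prescribed forces and torques.

## Worked example

Recover prescribed forces and torques from a moving rigid cylinder
(1.25 mm × 5 mm, density of water):

```r
library(fishtrack3d)
pf  <- cylinderProfiles()                    # µN / µN·mm sinusoids
sim <- simulateCylinder(pf$forceFun, pf$torqueFun, fps = 2000, nFrames = 100)
dyn <- meshDynamics(sim$Varr, sim$tri, fps = 2000)
keep <- 6:95                                 # trim 5 edge frames per side
fErr <- sqrt(rowSums((dyn$force  - sim$refForce)^2))[keep]
tErr <- sqrt(rowSums((dyn$torque - sim$refTorque)^2))[keep]
round(c(mass_kg     = dyn$mass,
        rmsF_rel    = sqrt(mean(fErr^2)) / max(sqrt(rowSums(sim$refForce^2))),
        rmsTau_rel  = sqrt(mean(tErr^2)) / max(sqrt(rowSums(sim$refTorque^2)))), 6)
#>    mass_kg   rmsF_rel rmsTau_rel
#>   0.000006   0.001461   0.004293
```

The cylinder has a mass of 6.1 mg; the recovered force and torque series
match the prescribed profiles to 0.15% and 0.43% RMS of their peaks —
the inverse-dynamics chain (polyhedral CoM/inertia, finite-difference
derivatives, angular-momentum surface integrals) is numerically faithful
away from the smoothing edge frames.

A complete tracked experiment (generate → render → degrade → segment →
track → inverse dynamics) runs through one call pair:

```r
exp <- verificationExperiment(nFrames = 110, resolution = 1024, seed = 1)
me  <- motionErrors(exp)      # per-frame snout/CoM/orientation/bend errors
de  <- dynamicsErrors(exp)    # force/torque error vs the prescribed shapes
```

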