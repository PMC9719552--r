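---
title: "Defocus-based 3D bead tracking and hopping transport over stripe domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defocus-based 3D bead tracking and hopping transport over stripe domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magbead3d)
```

## The measurement problem

Superparamagnetic microbeads transported over a magnetically striped substrate
move *close to the surface*: their height above the substrate is set by a
balance of magnetic, electrostatic, van der Waals and gravitational forces,
and it changes when anything binds to either surface. That makes the
bead-substrate separation a label-free observable for chip-based diagnostics -
provided it can actually be measured through an ordinary bright-field
microscope, frame by frame, while the bead is moving.

`magbead3d` implements the two halves of that measurement:

1. **Defocus-based axial localization.** A bead imaged away from the focal
   plane is blurred; a sharpness metric evaluated on a region of interest
   (ROI) around the bead encodes its axial position. The metric is calibrated
   per particle against a piezo-stage focus sweep, after which every video
   frame yields a z coordinate with an uncertainty.
2. **A quasi-static transport model.** The stray-field landscape of a
   head-to-head / tail-to-tail (hh/tt) stripe-domain pattern, superposed with
   trapezoidal external field pulses, predicts where the bead sits laterally
   and at which height it rides during a field-driven "hopping" step. The
   model is the reference the measured 3D trajectories are compared against.

A third component, a seeded synthetic microscopy generator, renders focus
sweeps and transport videos with known 3D ground truth so that the whole chain
is testable without experimental data.

## Sharpness metric and axial calibration

The sharpness measure is the Tenenbaum (Tenengrad) gradient,

$$f_\mathrm{TBG} = \sum_{i,j} G_x(i,j)^2 + G_y(i,j)^2,$$

with $G_x, G_y$ the responses of the unnormalized 3x3 Sobel kernels. Two
conventions are fixed in `tenenbaum_gradient()`: the kernels are applied as
correlations (the sign cancels under squaring), and the one-pixel border is
excluded from the sum so the value does not depend on a padding convention.
The metric is quadratic in intensity and invariant under constant offsets;
both properties are asserted in the test suite against a brute-force
convolution oracle.

The depth of field of the assumed optics, $\mathrm{DOF} = \lambda / (2\,
\mathrm{NA}^2)$, is about `r round(compute_dof(optics_model()), 1)` nm for
white light at NA 1.4 (`compute_dof()`), i.e. the focal plane is far thinner
than the bead, which is what makes the sharpness response steep.

A focus sweep steps the sample axially (25 or 50 nm piezo steps), records a
reference image per step, and `sweep_to_curve()` evaluates the TBG on a
background-subtracted ROI per frame. The curve has a single maximum at best
focus, saturates far from focus (the ROI content sinks below the noise
floor), and is asymmetric: the rising flank below focus is steeper than the
falling flank. `fit_calibration()` selects that rising flank - the most
sensitive branch - as the calibration region. Because no linearity criterion
beyond "almost linear over 2-4 um" is canonical, the flank is trimmed to the
longest contiguous window whose ordinary least-squares fit reaches
$R^2 \ge 0.98$ (configurable); windows shorter than 4 samples are rejected.

`tbg_to_z()` inverts the fitted line, reporting z relative to the flank start
(larger piezo z = closer to the objective = higher elevation). The
uncertainty combines first-order propagation of the (intercept, slope)
covariance with the observation scatter `residual_sd/slope` in quadrature; a
Monte-Carlo test verifies that the resulting 1.96-sigma intervals cover the
truth 90-99% of the time. TBG values outside the fitted flank's range are
converted but flagged `extrapolated`.

Calibrations are strictly per particle and per position: optical responses
differ between beads, and the illumination varies across the field of view.
A calibration is trusted for a trajectory only if the TBG before and after
the lateral movement agrees within 10% (`calibration_stable()`); beads that
fail are excluded with a logged reason.

## Preprocessing

`enhance_frame()` applies global 256-level histogram equalization and an
isotropic hard circular low-pass in the 2D Fourier domain (default cutoff:
0.3 of Nyquist - neither the filter shape nor the cutoff is canonical, both
are configuration-exposed). `estimate_background()` is the pixel-wise mean
over all transport-video frames and is subtracted (re-centred at mid-range,
clipped) from video and sweep frames alike; this removes the inhomogeneous
illumination that would otherwise leak position-dependent changes into the
TBG. In the full pipeline the equalization is off by default: the synthetic
frames already span the full intensity range, and per-frame equalization
rescales the TBG frame-dependently. For low-contrast camera data it should be
enabled.

One consequence of a mean-frame background deserves emphasis: every position
where a bead dwells leaves a "ghost" (the time-averaged bead image) in the
background, and subtracting it attenuates the TBG by a factor that depends on
the local dwell fraction. The stability criterion above is exactly the guard
against this: it passes when the dwell fractions - and hence the attenuations
- at the start and end of the trajectory match, as they do for a transport
step recorded with symmetric pre- and post-step intervals.

## Detection and linking

The 2D tracker is a documented stand-in for the machine-learning tracker used
with the original experiments (out of scope here). `detect_particles()`
computes an absolute difference-of-Gaussians contrast (default scales 6 and
24 px), which suppresses the smooth illumination within each frame and
responds to bead-scale blobs of either polarity - defocused beads appear dark
or bright depending on the side of focus. Local maxima above threshold are
merged under a minimum separation (which should be at least a bead diameter:
a defocused core-shell bead is a ring, and the ring must collapse to one
candidate), then refined by an iterated median-thresholded centroid over a
circular window; the iteration matters because the initial peak may sit on
the rim of the ring. On clean synthetic frames the localization error is
below 0.02 um; the detector is exactly translation-equivariant by
construction (FFT-based smoothing).

`link_trajectories()` performs greedy mutual-nearest-neighbour linking under
a maximum displacement (default 0.5 um per frame at 1000 fps). Ambiguous
ties terminate a track rather than guess: a false join would silently attach
the wrong calibration to the rest of a trajectory, which is worse than a
shorter track. There is no gap closing.

`crop_roi()` cuts the exactly sized square ROI (50 px = 5.5 um for beads up
to 3 um, 60 px = 6.6 um for 4 um beads at 0.11 um/px) symmetrically around
the tracked centre; ROIs that would cross the frame edge raise an error and
the affected particle is excluded from the axial analysis.

## The field landscape

The stripe pattern's stray field is modelled by straight domain-wall lines
with alternating magnetic line charge (hh walls positive, at x = 0 mod one
period; tt walls negative, at one domain width), buried 0.16 um below the
substrate top surface (150 nm polymer spacer + 10 nm capping). Three
interchangeable evaluations are provided and cross-validated:

- `line_charge`: the direct truncated sum of 2D line-charge fields
  $H_r = q_\ell / (2\pi r)$ - the reference oracle. The wall window is
  centred on the evaluation point and the outermost walls carry half weight
  (alternating-series end averaging), which keeps the truncated sum exactly
  periodic and suppresses the truncation tail by two orders of magnitude.
- `harmonic`: the odd-harmonic Fourier series
  $H_z = \sum_{n\ \mathrm{odd}} (2 q_\ell / P) \cos(k_n x)\, e^{-k_n z}$
  (and $\sin$ for $H_x$), $k_n = 2\pi n / P$. For heights above a fraction
  of a period this is numerically exact with 25 terms, and it matches the
  closed form $(q_\ell/P) / \sin(2\pi (x + i z)/P)$ to machine precision.
- `fitted`: separable closed forms - an exponential decay in z and a
  sixth-degree polynomial in x per half-period, extended by the hh/tt
  antisymmetry - produced by `fit_mfl_forms()` from the line-charge field.
  For fit windows above `period/(2*pi)` the recovered decay constant is the
  first-harmonic value within a few percent. This reproduces the functional
  structure used when the landscape is derived from micromagnetic
  simulations; a full micromagnetic computation is out of scope.

The absolute wall charge (default 0.03 A, giving stray fields of a few mT
near the bead) is a configuration fixture: the experimental value depends on
the film stack and is not available here.

`pulse_sequence()` describes the external drive: a constant in-plane field
(default 1 mT) and a z-field alternating between +8 mT and -8 mT plateaus
with 20 ms linear ramps. All fields are A/m internally; mT inputs convert by
$B = \mu_0 H$. `effective_field()` superposes stray and external fields.

## Force balance and hopping

The bead magnetizes linearly ($U_p = -\tfrac{\mu_0}{2} V \chi
|\vec H_\mathrm{eff}|^2$, evaluated at the bead centre; saturation and
volume averaging are out of scope). Because $|\vec H_\mathrm{eff}|^2$
contains the cross term $2 \vec H_\mathrm{ext} \cdot \vec H_\mathrm{MFL}$,
reversing the external z-field converts the magnetic force above a wall from
attractive to repulsive and moves the lateral potential minimum to the
adjacent (opposite-polarity) wall - the elementary transport step.

`net_vertical_force()` balances four terms on the gap coordinate $z'$
(surface-to-surface separation; the field is evaluated at
gap + radius + source depth): the magnetic force $-\partial U_p / \partial z$
(central difference, 1 nm step - the difference from the analytic derivative
of the exponential modes is ~1e-8 and one code path serves all three field
modes), the linearized double-layer repulsion
$P_\mathrm{el}\, e^{-z'/\lambda_D}$, the sphere-plane van der Waals
attraction $-A_H R / (6 z'^2)$, and effective gravity
$-(\rho_p - \rho_f) V g$. `equilibrium_gap()` scans 2000 log-spaced gaps
between 1 nm and 50 um, takes the smallest sign change where the force
decreases through zero (the stable root on the approach side), and bisects to
0.1 nm; an unbracketed root returns the scan cap with a flag rather than an
error.

The interaction constants (Hamaker 1e-20 J, Debye length 150 nm,
electrostatic prefactor 1.1e-10 N - computable from +/-30 mV surface
potentials via `electrostatic_prefactor()` - bead susceptibility 0.15,
density 1350 kg/m^3) are plausible values for polymer beads in water over a
polymer-coated substrate. No measured parameter set for a specific film
stack and bead lot is bundled with the package, so all of them are
configuration fixtures, stated here once and not tuned; users with
characterized systems should supply their own values.

`lateral_minimum()` locates the occupied potential minimum (coarse grid plus
golden-section refinement to nm resolution). `hop_step_width()` tracks it
through a full pulse cycle. One subtlety: with the constant x-bias field the
minima sit slightly (~0.14 um) off the wall centres, displaced towards +x
under +Hz, so the two reversals of a cycle displace the occupied minimum by
5 - 2delta and 5 + 2delta alternately; by strict periodicity they sum to one
period exactly. The *transport step width* is therefore defined as the mean
displacement per reversal over a cycle, which equals the domain width (5 um)
exactly; the individual displacements are exposed as `steps_um`.

`transport_elevation_profile()` evaluates the equilibrium gap along an
observed or synthetic lateral trajectory x(t) at 1 ms steps - quasi-static by
construction: the model contains no inertia or hydrodynamic drag, so the
elevation jumps discontinuously at a field reversal where a real bead rises
over tens of milliseconds. Profiles are normalized so the smallest bracketed
separation is zero. Under the default conditions one transport step rises
from 0 to a peak of about 9 um at an interior x between the walls and
returns to 0 at the step's end; the peak height scales with the wall charge,
susceptibility and density contrast and should be read as
order-of-magnitude, not calibrated, physics.

## The synthetic benchmark

The generator emulates what the pipeline needs, not the full image physics:

- **Templates.** `core_shell` (bright rim, dark core - beads with a
  superparamagnetic shell) and `homogeneous` (dark disk - uniformly filled
  beads), anti-aliased over one pixel.
- **Defocus.** A Gaussian blur whose sigma grows linearly with |defocus|,
  with different rates below (0.8 px/um) and above (0.5 px/um) focus. The
  base blur (2 px) and growth rates were chosen once so the resulting
  sharpness curve reproduces the canonical shape: single peak, saturating
  tails, steeper rising flank, and a quasi-linear rising flank of about
  2.5 um under the default optics (0.11 um/px, 800x600 frames).
- **Illumination and noise.** A low-order polynomial surface (~10%
  inhomogeneity), Gaussian read noise (sd 0.01) plus Poisson-equivalent shot
  noise (gain 2e-4).
- **Trajectories.** `ground_truth_trajectory()` uses a sigmoid lateral
  transit (60 ms per hop, a plausible transit time for these drive fields)
  after each field reversal and takes z from the force balance, so the
  rendered videos are exactly consistent with the model the pipeline is
  later compared against.

`default_benchmark()` renders five 4-um core-shell beads on successive hh
walls, a 50-nm-step focus sweep over 8 um, and a 260-frame, 1000-fps video
of one hopping step with the video window centred on the step. The centring
is deliberate: it equalizes the dwell time at the start and end walls so the
mean-background ghost attenuation matches and the stability criterion is
satisfiable at all (see above). The resting defocus is -1.5 um, i.e. on the
rising flank, as the measurement strategy prescribes. With these conditions
the full pipeline recovers x(t) with RMSE below 0.02 um and z(t) on the
calibrated flank with MAE around 0.2 um - comfortably inside the package's
acceptance bands of 0.05 um and 0.5 um (the latter mirroring the ~500 nm
uncertainty expected of the experimental method).

What the passing benchmark does *not* show: robustness to aggregating or
touching beads, Brownian lateral jitter, camera-specific artifacts,
diffraction rings, or drift - real data carry all of these, and the
generator deliberately models none of them.

## Numerical choices and degenerate inputs

- Sweep curves that are constant are flagged "no focus found"; curves with
  several comparable maxima warn "multiple peaks".
- Flank fitting requires at least 4 samples below the peak and a positive
  slope; ties between equally long candidate windows go to the higher $R^2$.
- Linking ties (distance difference below 1e-6 um) terminate tracks.
- The equilibrium scan brackets roots on a log grid; monotonicity of the gap
  in the electrostatic prefactor (increasing) and Hamaker constant
  (decreasing) is asserted in tests.
- A flat lateral potential (zero fields) is reported as degenerate rather
  than returning an arbitrary argmin.
- All generators are deterministic given a seed; the RNG state of the caller
  is restored afterwards.

## Problem sizes

The shipped tests run the full pipeline twice: on a scaled-down benchmark
(two beads, 320x240 px, 130 frames) for the fast checks, and once on the
default benchmark (five beads, 800x600 px, 260 frames plus a 161-frame
sweep) for the end-to-end recovery check. The field and force-balance checks
use 100 randomized parameter draws against a 1e5-point dense-scan oracle.
These sizes were chosen so the entire suite completes in minutes on a single
CPU while still exercising every stage at full frame size.
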