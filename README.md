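# magbead3d

Three-dimensional tracking of superparamagnetic microbeads from bright-field
microscopy videos, and a quasi-static model of their "hopping" transport over
a stripe-domain magnetic field landscape.

## The problem

Micron-sized superparamagnetic beads can be shuttled across a magnetically
striped chip by superposing the stripes' stray field with weak external field
pulses. The beads travel *close to the substrate*, and their flying height is
set by a force balance that shifts when analytes bind to either surface —
which makes the bead–substrate separation a label-free diagnostic observable.
The catch: an ordinary microscope only measures x and y. `magbead3d`
implements the missing piece — frame-by-frame axial localization from image
*defocus* — together with the transport model needed to interpret the
resulting 3D trajectories. It is aimed at lab-on-a-chip researchers who want
to quantify vertical bead motion with nothing but a bright-field microscope
and a piezo stage.

## The method

**Axial localization.** The sharpness of a bead image is measured by the
Tenenbaum (Tenengrad) gradient over a region of interest (ROI) around the
tracked bead centre,

    f_TBG = Σ_ij  Gx(i,j)² + Gy(i,j)²,

where `Gx`, `Gy` are 3×3 Sobel responses. During a focus sweep (25–50 nm
piezo steps) `f_TBG(z)` traces a single-peaked curve whose steep, nearly
linear *rising flank* below focus is fitted by least squares; inverting the
fit turns the per-frame TBG of a 1000-fps video into a z coordinate with a
propagated uncertainty. Calibrations are per particle and per position, and
are only trusted if the TBG before and after the lateral motion agrees
within 10%.

**Transport model.** The stripe pattern's field is that of alternating
magnetically charged domain-wall lines (head-to-head/tail-to-tail), available
as a truncated line-charge sum, an odd-harmonic series
`H_z = Σ_n (2q/P) cos(k_n x) e^(−k_n z)`, or fitted separable closed forms
(exponential in z, sixth-degree polynomial in x). A bead with linear
magnetization has potential `U_p = −(µ0/2) V χ |H_ext + H_MFL|²`; reversing
the external z-field flips the attraction above a wall into repulsion and
moves the potential minimum one domain width onward. The vertical force
balance (magnetic, electrostatic double-layer, van der Waals, effective
gravity) yields the quasi-static equilibrium separation along the hop.

A seeded synthetic-microscopy generator (`default_benchmark()`) renders focus
sweeps and transport videos with known 3D ground truth, so the complete
pipeline is testable without experimental data.

## Worked example

```r
library(magbead3d)

# optics: white light, NA 1.4 -> a ~130 nm depth of field
om <- optics_model(wavelength_nm = 500, numerical_aperture = 1.4)
compute_dof(om)
#> [1] 127.551

# synthetic benchmark: 5 beads, focus sweep + one hopping step at 1000 fps
bm  <- default_benchmark(seed = 1)
res <- track3d_pipeline(bm$video, bm$sweep)
print(res)
#> <track3d_result> 260 frames, 6 2D tracks, 5 with z (excluded: 1)
#>   - p001: sweep curve unusable
#>   flank 1.75-1.85 um, inverse slope 0.01356-0.01523 um/TBG

# per-bead z trace (um, relative to the calibration reference)
head(res$tracks$p002[, c("frame", "x_um", "y_um", "z_um", "z_sigma_um")], 3)
#>   frame      x_um     y_um      z_um z_sigma_um
#> 1     0 10.006207 16.46414 0.3934587 0.08108491
#> 2     1  9.987649 16.45202 0.3912588 0.08109282
#> 3     2  9.986769 16.47256 0.3949449 0.08107958
write_tracks_csv(res, "tracks_out")

# transport model: step width and elevation profile of one hop
hop_step_width()$step_um
#> [1] 5
traj <- ground_truth_trajectory(stripe_pattern(),
                                pulse_sequence(plateau_ms = 150),
                                micromer_bead(), interaction_params())
max(traj$z_um)      # peak quasi-static elevation during the hop, um
#> [1] 9.082726
```

The pipeline report says one "track" was dropped (a frame-corner artifact
with no focus response) and five beads were calibrated, each with a ~1.8 µm
linear flank. On this benchmark the recovered lateral positions are accurate
to ~0.015 µm RMSE and the axial positions on the calibrated flank to
~0.2 µm MAE — the axial figure mirrors the ~0.5 µm uncertainty expected of
the defocus method. `hop_step_width()` confirms that one field reversal
moves the occupied potential minimum by one domain width (5 µm), and the
elevation profile predicts the bead rising ~9 µm while crossing to the
adjacent wall before settling back.

A command-line front end with `synth`, `calibrate`, `track3d`, `simulate`
and `fieldmap` subcommands is installed under `inst/scripts/magbead3d`.

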