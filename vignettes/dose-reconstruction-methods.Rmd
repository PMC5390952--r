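---
title: "Methods: simulating and reconstructing MLC-tracked deliveries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reconstructing MLC-tracked deliveries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During a hypofractionated prostate fraction the target drifts by several
millimetres while the linac delivers a step-and-shoot IMRT plan. Dynamic MLC
tracking reshapes the field in the beam's-eye-view (BEV) to follow the
measured target translations; the clinically relevant question is what dose
the moving target and the static organs at risk *actually* received.
`trackdose` answers this with a per-aperture dose reconstruction: the
delivery is observed as two asynchronous streams — MLC aperture reports
(every 40 ms) and machine states (every 20 ms: cumulative monitor units,
dose rate, gantry angle, beam-on flag) — and every aperture report triggers
one incremental dose calculation from pre-computed dose influence matrices.

The per-aperture loop is, for each report:

1. find the target position closest in time (ties to the earlier sample);
2. select the beam's pre-calculated beamlet set by gantry angle;
3. weight each beamlet by its geometric overlap with the aperture,
   linearly interpolated between closed (0) and open (1) for beamlets
   partially covered by leaves or Y jaws;
4. form the beamlet dose superposition;
5. scale by the incremental MU since the previous report (beam-off
   apertures are processed identically with zero MU);
6. accumulate onto the planning grid, mapping the target volume of
   interest at its displaced position.

Three delivery modes are simulated: *static* (no motion, no tracking — the
reconstruction must reproduce the planned dose), *conventional* (motion,
no tracking) and *tracked* (translational MLC tracking of the
latency-delayed target position).

## The phantom and the synthetic dose kernel

There is no planning CT here: the phantom is a voxelized set of analytic
solids (water-equivalent body, ellipsoidal prostate CTV of about 44 cm³, a
rectum posterior and a bladder anterior/superior of it) on a configurable
grid, 50×50×50 voxels at 3 mm by default. The pelvis is treated as
homogeneous water, which is also the assumption that justifies rigid dose
mapping for the moving target.

The treatment-planning-system pencil beam is replaced by a documented
synthetic kernel. A beamlet of width $w_u \times w_v$ deposits

$$D(\mathbf{x}) = C\, e^{-\mu d(\mathbf{x})}\,
  F_{w_u,\sigma}(u - u_b)\, F_{w_v,\sigma}(v - v_b),$$

where $d$ is the radiological depth along the (parallel, non-divergent)
beam, $F_{w,\sigma}$ is a top-hat of width $w$ convolved with a Gaussian of
width $\sigma$, and $(u, v)$ are BEV coordinates (leaf travel, leaf width).
Defaults: $\mu = 0.005\,\mathrm{mm}^{-1}$, $\sigma = 3$ mm, and $C$
calibrated so that a single beamlet at unit weight deposits 0.25 cGy/MU on
its central axis at 100 mm depth. The kernel is deliberately
shift-invariant on a homogeneous phantom: translating a beamlet by one
beamlet pitch translates its dose column by the corresponding voxel offset
*exactly*, which turns "perfect tracking recovers the static dose" into an
exact oracle rather than a tolerance judgement. Radiological depth is
ray-marched in 1 mm steps with nearest-neighbour density lookup; on a
box-shaped body whose spacing is a multiple of the step this sampling is
exact, elsewhere it quantizes depth by at most half a step (±0.25% dose).

Dose influence matrices $D_{ij}$ (cGy/MU per beamlet at unit weight) are
computed per beam for the CTV expanded by 2.5 cm — the anticipated motion
range — and stored sparse; voxels outside this region receive no dose and
target samples escaping it contribute zero and increment a warning counter.

## Plans

Inverse optimization is out of scope. The plan generator is a heuristic:
evenly spaced gantry angles (7 beams by default), a first segment conformal
to the PTV projection per leaf row, and seeded shrunken/offset sub-apertures
for subsequent segments, all respecting a minimum open area of 4 cm²
(avoiding very small segments). MU are split across segments with a
decaying ~63/26/11% pattern and can be rescaled exactly to a prescription
(default: PTV D95 = 725 cGy for a single fraction) since dose is linear in
MU. The CTV-to-PTV margin is configurable: isotropic 1/3/5 mm or the
clinical 5 mm reduced to 3 mm posteriorly.

Margins expand the CTV by a per-octant ellipsoid test on voxel centers.
On a coarse grid a margin smaller than the voxel pitch adds no voxel
centers; the margin tests therefore run on a 1 mm grid, and expansion
volumes are asserted within the half-voxel surface band of the analytic
value.

## Motion, latency, offsets, rotations

Four trajectory archetypes emulate recorded prostate motion qualitatively
(the original electromagnetic-transponder recordings are not available):
*continuous drift* (posterior + inferior linear drift, −0.6/−0.4 mm/min),
*erratic* (the same drift plus ~1.5 anterior transients per minute of 2–5 mm
decaying over ~10 s), *high frequency* (slow anterior + superior drift with
~6 short transients per minute) and *stable* (correlated noise bounded at
1 mm). All values are declared package defaults, chosen to be of the order
seen in published prostate-motion studies; drifts of a few millimetres over
minutes and transients of a few millimetres over seconds. Trajectories are
sampled at 25 Hz and are bit-reproducible per (archetype, seed, duration,
rate).

The tracker does not see the true position: a Gaussian latency of
100 ± 15 ms (clipped at 0) is drawn once per aperture query, seeded by
(seed, query index) so that "online" runs replay identically. Because the
reconstruction itself uses the *true* trajectory, latency is exactly the
residual tracking error source.

Interfractional motion is a constant offset vector added to the trajectory
during reconstruction of conventional deliveries, swept over the full
−3…+3 mm grid in 1 mm steps (343 reconstructions). Rotations (pitch about
LR, then roll about SI, both right-handed, pivoting on the target centre of
volume) are applied to the whole fraction in the target mapping only —
tracking remains translational — and swept over ±20° (41 pitch-only steps
of 1°, or 121 pitch×roll combinations in 4° steps). The source material
does not define rotation sign conventions; this package fixes right-handed
rotations about the +LR and +SI axes and attaches no clinical meaning to
the sign.

## Reconstruction methods

Two target-mapping methods are implemented:

* **MLC+VOI** (`mlc_voi`, default): the reported aperture is used as
  delivered; the static-anatomy dose grid accumulates every increment, and
  the target VOI additionally samples each increment at its displaced (and
  rotated) voxel centers by trilinear interpolation, mapping target dose
  back into the planning-time target. OAR dose is read from the static
  grid.
* **MLC-only** (`mlc_only`): the rigid-shift alternative — anatomy stays
  static and the *residual* BEV shift (tracked MLC motion minus target
  motion) is applied to the planned aperture. Motion is not grouped into
  discrete intervals; every aperture gets its own residual.

For a posterior drift under tracking the two methods agree on the target
but split on the rectum: `mlc_voi` sees the aperture chase the target
toward the rectum and reports the dose increase; `mlc_only` reconstructs a
nearly planned dose and misses it. The package asserts exactly this sign.

## Numerical choices

* Nearest-in-time searches (target samples, machine states) break ties
  toward the earlier event — determinism over elegance.
* Incremental MU comes from the machine state nearest each aperture report;
  the sum telescopes to the final cumulative MU exactly, which is what the
  MU-conservation test asserts at 1e-9. The alternative (interpolating MU
  to the report timestamp) converges to the same dose as the state cadence
  shrinks.
* Streams are generated with events at phase boundaries in addition to the
  fixed cadences, so that MU accrued up to a segment boundary is attributed
  to the aperture that delivered it; this is what makes the static
  reconstruction reproduce the planned dose to ~1e-14 instead of ~0.03%.
* Target-dose mapping uses trilinear sampling (nearest-neighbour available
  as an option); for a rigid shift the interpolation weights are constant
  across voxels, and integer-voxel shifts reduce to exact gathers.
* Leaf dynamics are idealized (infinite leaf speed): the tracked aperture
  equals the ideal shifted aperture at every report, so residual error
  enters only through latency. MLC transmission and tongue-and-groove are
  ignored (sub-0.2% effects for the modelled MLC).
* Beamlet weights are exact interval-overlap fractions; the test oracle
  sub-samples areas on a 0.01 mm lattice, the reporting precision of the
  aperture stream, on which the exact and sampled fractions coincide.

## What the synthetic world does and does not establish

The generator reproduces the *structure* of the problem: asynchronous
streams, beam-off apertures, latency, margins, motion archetypes, offset
and rotation grids, and the non-exclusive-VOI DVH analytics (Dx points,
V95% overlap, non-tumour integral dose $I_j = \rho_j (V_j/N_j) \sum_i D_i$
in litre·Gy). A green test suite establishes the reconstruction machinery:
MU conservation, static identity, exact perfect-tracking recovery,
cold-spot generation and removal, and the qualitative OAR trade-offs.

It does *not* reproduce patient-specific dosimetry: there is no CT
heterogeneity, no beam divergence, no scatter modelling, no optimizer, and
the motion traces are parametric emulations. Published per-patient dose
numbers are therefore out of reach by construction, and the package makes
no claim about them.

## Known limitations

* VMAT/dynamic-arc deliveries, couch or gantry tracking, DICOM-RT I/O and
  re-planning are not modelled.
* Rotation handling exists only in the dose mapping; aperture-morphing
  rotation tracking is not implemented.
* OARs are static by assumption; only the target moves.
* The event-clock contract replaces real-time transport: streams are
  generated and processed in timestamp order, never read ahead.
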