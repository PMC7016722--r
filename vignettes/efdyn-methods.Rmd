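---
title: "Methods: EF-hand calcium-binding dynamics with efdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EF-hand calcium-binding dynamics with efdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efdyn)
```

efdyn analyses molecular-dynamics trajectories of EF-hand calcium-binding
proteins — the S100A1 homodimer is the motivating system — around one
physical narrative: Ca²⁺ binding at the second EF loop opens the angle
between helices H3 and H4, exposing the hydrophobic patch that enables
protein–protein interaction, while free ions find the acidic EF-site
residues, shed part of their hydration shell, and reside there. This
vignette documents the models, parameters and numerical choices behind each
stage, what the synthetic generator does and does not emulate, and the
design decisions that were genuinely open.

Internal units are nanometres and picoseconds throughout; every cutoff
below is quoted in those units. Residue numbers are used exactly as printed
in input files (1-based, no renumbering), and subunits are chain
identifiers.

## Structures, trajectories and selections

`read_structure`/`read_trajectory` accept PDB (including multi-MODEL) and
GRO files. PDB parsing is delegated to bio3d and wrapped with a pre-scan
that reports malformed ATOM/HETATM records and inter-MODEL atom-count
mismatches by line or frame number; GRO parsing is done natively
(fixed-column, one frame per title/count/body/box block), reading `t=`
stamps from title lines when present. PDB coordinates are converted from Å
to nm; GRO is already nm. When no per-frame times exist, frames are spaced
uniformly at `dt_ps` (default 10 ps, a typical trajectory output
granularity; the original saving interval of the motivating study is not
stated anywhere, so it is a free parameter here).

Waters are recognised by residue name (HOH/SOL/WAT/TIP/SPC families),
monatomic ions likewise (CA/NA/CL/MG/K/ZN and charged variants). The
selection language (`select_atoms`) supports `chain`, `resid` (values and
`a:b` ranges), `resname`, `name`, `backbone` (N/CA/C/O heavy atoms of
non-water, non-ion residues), `water`, `ion`, `all`, and `and`/`or`/`not`
with parentheses. Selections resolve to sorted unique indices; empty
selections are legal so that absence is distinguishable from error.

## Superposition, RMSD, RMSF

Superposition uses the Kabsch algorithm (SVD of the 3×3 cross-covariance,
with the determinant correction that enforces a proper rotation). Fits
require at least three non-collinear atoms; collinearity is detected from
the singular-value spectrum of the centred reference. `rmsd_series`
superposes every frame on the same selection before measuring, so rigid
translation and rotation contribute nothing. `rmsf_per_residue` superposes
on the running mean structure (two passes, which is where the iteration has
converged for the near-rigid cases the package targets), computes per-atom
RMS deviations from the mean position, and averages within residues.

## The interhelical opening angle

The opening metric is a three-point angle: for each subunit, take the Cα
atoms of the H3 anchor, the EF-site anchor and the H4 anchor (Lys56, Glu73,
Trp90 in S100A1 numbering; configurable), and measure the angle at the
EF-site anchor between the vectors to the two helix anchors. The middle
residue is the vertex because the quantity of interest is the opening of H3
relative to H4 about the EF-loop hinge; this matches the geometric
construction drawn through those three residues in the motivating
structures. Angles are reported in degrees in [0, 180].

Windowed summaries (`block_average_angles`) partition time into
`(previous_end, end_i]` ns windows — e.g. ends at 10, 40 and 80 or 100 ns —
and report the mean, sample SD (n−1 denominator) and frame count per
window. A published phrase suggesting five sub-levels per window is
ambiguous and deliberately not implemented; the three-window scheme is what
the printed tables actually contain.

## SASA

`sasa_frame` implements Shrake–Rupley: each selected atom's van der Waals
sphere is inflated by the probe radius (default 0.14 nm, water-sized) and
covered with a deterministic Fibonacci spiral lattice (default 960 points;
minimum 32). A point is buried if it falls inside any other selected atom's
inflated sphere; the exposed fraction times `4π(r+probe)²` sums to the
area. The spiral lattice makes results bit-reproducible — there is no
Monte-Carlo scatter — with a systematic discretisation error below 0.5% at
960 points for an isolated sphere and about 1% for strongly overlapping
pairs (both bounds are asserted against closed-form sphere/cap areas in the
test suite). Radii come from a small GROMOS-like united-atom table
(`default_vdw_radii`; C 0.172, N 0.155, O 0.150, S 0.180, H 0.120 nm,
plus common ions); unknown elements are an error rather than a silent
default. `sasa_series` adds a frequency histogram at a configurable bin
width (default 0.5 nm²) whose counts sum to the number of frames.

## Contacts and hydrogen bonds

`min_distance_trace` is the per-frame minimum Euclidean distance over all
cross pairs of two selections. `contact_map` applies this per residue pair
across two subunits using heavy atoms only (hydrogens are excluded from all
distance criteria, since hydrogen treatment varies across force fields and
deposited models), averages the per-frame minima over a time window, and
classifies each cell:

* cells whose overall minimum never drops below 0.4 nm are non-contacts;
* otherwise the time-averaged minimum is binned red < 0.15, orange
  [0.15, 0.25), yellow [0.25, 0.30), green [0.30, 0.35), blue ≥ 0.35 nm.

The red/orange boundaries are midpoints around the nominal 0.1 and 0.2 nm
class centres, chosen to make the five classes exhaustive and disjoint; the
0.4 nm existence filter is applied to the minimum (not mean) distance, the
more permissive reading, so transient contacts remain visible. "Average
distance" is the arithmetic mean of per-frame minima; a geometric-mean
variant is available behind `mean_type = "geometric"`.

H-bond counting is a distance-only criterion by default: cross pairs of N/O
heavy atoms within 0.35 nm, each atom free to participate in several pairs.
This is deliberate — the convention the package follows specifies only a
distance cutoff — but an optional donor–H–acceptor angle term
(≥ 150°, hydrogens assigned by a 0.12 nm covalent search) is available via
`use_angle = TRUE` for systems with explicit hydrogens.

## Ion encounters, residence time, occupancy, hydration

`ion_residue_distance_trace` measures, per frame, the minimum distance
between any selected ion atom and any heavy atom of a residue (optionally
carboxylate/oxygen-only). Selecting several ions pools them, matching the
"collective" distance convention for a binding site.

`detect_encounters` scans the trace at a 0.5 nm cutoff. An encounter begins
at the first frame below the cutoff; the trajectory start counts as
"outside". Because the published convention never defines what separates a
first from a second encounter, sub-cutoff episodes separated by excursions
shorter than `gap_tol_ps` (default 50 ps) are merged — otherwise every
thermal re-crossing would count as a new encounter. At most two encounters
are recorded (FET, SET), the published bookkeeping. A reported second
encounter time of 0 is read as "no second encounter", since t = 0 cannot
follow a first encounter.

`total_residence_time` implements the published arithmetic exactly as
printed: `T − FET` with only a first encounter, `T − SET` with only a
second, `(SET − FET) + (T − SET)` with both (algebraically `T − FET`; the
two-term form is kept and the identity is pinned by a regression test), and
0 with none. The vectorised `trt_from_times` drives the bundled table
audit, where several printed rows are arithmetically inconsistent with
these formulas; `residence_time_report()` flags them rather than matching
them, because the equations, not the typeset numbers, are authoritative.

Occupancy (`binding_site_occupancy`) is the fraction of frames with any ion
within the 0.3 nm solvation shell of a residue. Hydration
(`hydration_count_series`) counts distinct water molecules whose oxygen
lies within an explicit cutoff of the ion — deliberately mandatory, because
two shells are in play: 0.3 nm (first shell, the coordination criterion)
and 0.5 nm (extended shell, the regime in which a bulk divalent ion is
surrounded by 15–18 waters). A centred running mean (default 500 ps) is
attached. The water-bridged H-bond between an EF carboxylate and the ion is
detectable by composing `hbond_count_series` with hydration membership, but
no quantitative criterion for it is established, so it remains a documented
recipe rather than an operation.

## Conformational clustering

`pairwise_rmsd_matrix` computes all-pair RMSD after pairwise Kabsch
superposition, in compiled code via the Gram identity
`rmsd²(i,j) = (|Xi|² + |Xj|² − 2(σ₁+σ₂±σ₃))/n` on centred frames (σ the
singular values of `XiᵀXj`, sign enforcing a proper rotation). Cancellation
limits "zero" entries to ~1e−7 nm, far below any clustering cutoff. An
optional frame stride documents itself on the result; it is an
approximation for long trajectories.

`gromos_cluster` is the GROMOS neighbor-counting algorithm: repeatedly take
the frame with the most neighbors within the cutoff (default 0.2 nm) as a
centroid, assign it and its neighbors to a cluster, remove them, repeat.
Ties in neighbor count break to the lowest frame index, making the result
deterministic; extraction order is non-increasing in size, so cluster 1 is
always the largest. `temporal_distribution` converts labels to contiguous
time spans (a run's span extends to the start of the next run; the last
ends at the final frame time, so spans partition the sampled interval), and
`running_mean_trace` provides the 100-ps running mean of the cluster-id
series — meaningful because ids are size-ordered, so low values mean
dominant conformations.

## The synthetic generator

The generator stands in for the study's undeposited trajectories; it
emulates the *statistical structure the analyses assume*, not physics.
There are no forces or integrator, trajectories are non-periodic (the
cutoff analyses are local and the toy box is large relative to every
cutoff), and noise is isotropic per-atom Gaussian added after the scripted
geometry is realised, so ground truth stays exact.

* **Toy dimer** (`build_toy_dimer`): two chains of N/CA/C/O pseudo-backbone
  on a coarse helix (defaults: 100 residues per subunit, 0.23 nm radius,
  0.15 nm rise, 100° twist), anchors at residues 56/73/90, and acidic
  EF-site residues {24, 32, 63, 66, 68, 73} — mirroring the binding
  residues of the motivating system — each carrying a side-chain oxygen
  pseudo-atom so carboxylate-focused analyses have a target.
* **Hinge motion**: per frame, the H4 arm (residues beyond the vertex) is
  rotated about the vertex Cα, about the axis normal to the anchor plane,
  by exactly the angle the schedule demands. The realised interhelical
  angle therefore equals the scripted value to machine precision before
  noise.
* **Ion schedules**: an ion is placed along the outward radial direction
  through its target residue's side-chain oxygen at the scripted distance;
  since every other residue atom lies further inward, the measured minimum
  distance equals the schedule exactly. Segments are hold, linear or
  exponential; scripted FET/SET, 0.3-nm occupancy and per-frame distances
  are recorded as ground truth. Approach windows in the seeded test suite
  fall in the ~5–25 ns range in which free ions reached the protein surface
  in the motivating study, with a fast (~100–200 ps) final capture.
* **Waters**: rigid 3-site molecules whose oxygens are resampled uniformly
  each frame outside a 0.2 nm exclusion around ions — an ideal bath, with
  no water–water structure. Only oxygens participate in hydration counts.
  A desolvation script thins the shell population of one ion with a
  Gaussian time profile, recording the scripted minimum time.
* **Bulk preset** (`bulk_ion_preset`): one ion in an ambient-density bath
  (33.4 waters/nm³, 2 nm cube). The expected extended-shell (0.5 nm) count
  is density × shell volume outside the exclusion radius ≈ 16.4, inside
  the published 15–18 band — the preset's defaults were fixed from that
  physical argument, not tuned to any test.

Because frames within a piecewise-hold schedule state are identical before
noise, scripted cluster labels are known exactly (states ranked by
occupancy), and the generator caches the rotated geometry per state, which
keeps 2,000-frame runs cheap.

What passing the recovery tests shows — and does not show: exact recovery
at zero noise demonstrates that the analysis operators are correct
transcriptions of their definitions, and the 0.02 nm noise suite shows the
encounter logic is robust to thermal-scale jitter; none of this validates
force fields, sampling adequacy or any property of real MD data beyond the
operators themselves.

## Reported-table audits

The printed angle-window and encounter tables of the motivating study ship
as plain-text fixtures (`reported_angle_windows`,
`reported_encounter_times`). `residence_time_report()` recomputes every TRT
from FET/SET; `angle_window_report()` recomputes across-window means and
first-to-last differences and compares them with the reported summary
figures at printed precision (0.005°). Verdicts are `pass` or
`inconsistent`; the audits never silently adopt a printed value. Notable
outcomes: the holo subunit-A mean (72.59°) and difference (14.29°) and the
free-entry subunit-B difference (14.67°) reproduce exactly, while e.g. the
apo subunit-A mean and several residence-time rows do not follow from
their own inputs and are flagged.

## Pipeline and problem sizes

`run_pipeline` executes selected stages with one validated configuration
(`run_config`; every cutoff positive, checked before any computation),
writes one CSV per stage with a provenance comment line (config hash +
seed), and emits a JSON manifest. Identical configurations produce
byte-identical outputs.

The test suite runs entirely on generated data: toy systems of 2–60 atoms
for oracle comparisons, 30-residue dimers (≈ 500 frames) for unit-level
recovery, and ten seeded 100-residue, 4-ion, ≈ 2,000-frame runs for
full-pipeline recovery — sizes chosen so the whole suite exercises every
code path in about a minute and a half on one core while keeping the
clustering problem (a 2,001² RMSD matrix) non-trivial.

## Known limitations

* No periodic-boundary handling; trajectories with wrapped coordinates must
  be unwrapped upstream.
* H-bond detection is heavy-atom geometric by default; no salt-bridge or
  per-bond lifetime analysis.
* SASA has no per-residue decomposition and no secondary-structure
  assignment.
* The GRO reader takes whole-file frames only (no velocity parsing beyond
  skipping the columns).
* The generator's waters are an ideal gas: no hydrogen-bond network, no
  exchange kinetics — hydration *counts* are meaningful, dwell times are
  not.
* Binding free energies and dissociation constants are out of scope.
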