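---
title: "fuccitrace: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fuccitrace: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuccitrace)
```

This vignette is the package's own account of its science: the reporter
and imaging model the simulator implements, the parameters that matter
and why their defaults are what they are, the phase-calling rules and
their numerical edges, and the places where the design was genuinely
open and a choice had to be made. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## 1. The measurement problem

Dual-colour cell-cycle reporters make phase boundaries visible in live
cells: a PIP-degron fusion (mVenus) is destroyed within minutes of
S-phase entry and re-accumulates in G2, while the partner channel is
either a constitutive histone fusion (H2A-mScarlet, PIP-H2A design) or a
geminin fusion (mCherry, PIP-FUCCI design) that rises through S/G2 and
collapses at cytokinesis. Given a 2-channel time-lapse of a monolayer,
the pipeline must (i) find every nucleus in every frame, (ii) link the
detections into identity-preserving tracks, (iii) select tracks that
span one full cycle between two division events, and (iv) convert each
track's fluorescence trace into three phase lengths. Each stage is a
module with a file-level contract (TIFF label movies, a CSV track-table
dialect, a phase-call CSV), so any stage can be replaced by an external
tool.

## 2. The synthetic world

`sim_config()` + `sample_lineage()` + `reporter_traces()` +
`render_movie()` generate movies with exported ground truth. The
defaults describe a freely cycling primary intestinal epithelial
monolayer imaged every 10 min for 48 h at 1 µm/px on a 512×512 field
with 12 px nuclei.

**Phase durations** are independent lognormals per phase,
`median × exp(σZ)`. Medians default to G1 = 8.3 h, S = 6.0 h,
G2/M = 2.5 h — the values reported for freely cycling cells of this
type. The dispersions σ = (0.45, 0.124, 0.23) were fitted once to the
reported quartiles ([6.2, 11.3], [5.5, 6.5], [2.2, 3.0] h): a lognormal
cannot reproduce asymmetric quartile ratios exactly, so σ is the average
of the two one-sided fits; the residual disagreement is under 3%,
within the 5% acceptance band, and is a property of the distributional
choice, not a tuning knob. Founders start at uniformly random positions
within their cycle, so the population is unsynchronised from frame 0.
A perturbation scenario (`oligomycin_scenario`) stretches phase medians
multiplicatively (e.g. G1 ×13/6.7) with no mechanistic model behind it —
it exists so the statistics surface has a realistic two-group input.

**Reporter kinetics** (noiseless, per cell):

* mVenus rises exponentially (τ = 30 min) to a plateau (20 000 units) in
  G1, decays with halftime 2.5 min from the true G1/S frame
  (`max(floor, v·2^(−t/τ½))`), sits at the floor (200) through S, then
  rises linearly (300 units/min) from the true S/G2 frame, capped at 90%
  of the plateau. The halftime default satisfies two constraints at
  once: decay to <10% of plateau within 30 min, and — at 10-min frames —
  mVenus already below 10% one frame after G1/S, which creates the
  documented 1–3-frame "dual-dim" early-S gap in the FUCCI design.
  The G2 cap means daughters (which restart at 75% of plateau) never see
  a >50% step at cytokinesis that could masquerade as a G1/S drop.
* H2A-mScarlet is constitutive (8 000) minus an inverse coupling to the
  normalised mVenus (−2 000·v̂, matching the observed anticorrelation),
  with a one-frame spike to 2.5× baseline on the mother's final frame —
  chromatid condensation at mitosis. The spike's frame-to-frame max
  intensity increment is far above the 300-unit slope filter by
  construction.
* mCherry (FUCCI) is zero in G1, ramps at 100 units/min starting
  2 frames (20 min) after the true G1/S — the onset delay producing the
  dual-dim gap — saturates at 15 000, and returns to zero on the
  daughter's first frame (a ≥90% single-step drop along a continuing
  track).

**Convention.** A cell occupies frames `[birth, division − 1]`;
daughters' `birth_frame` equals the parent's `division_frame`; the
mitotic spike sits on the mother's final frame. Every downstream
"within ±1 frame" statement traces back to this convention: the true
transition is an instant between two frames, and both the generator and
the callers resolve it to the first frame showing the new state.

**Rendering.** Nuclei are isotropic Gaussian blobs (σ = diameter/4)
whose peak is scaled so the mean over the nucleus disk equals the trace
value (the peak-to-mean factor `2/(1 − e⁻²)` ≈ 2.313 is the closed-form
disk integral, also used for the "max" trace channels). Background
(400), per-pixel multiplicative lognormal noise (σ = 0.02) and Gaussian
read noise (σ = 50) follow, clipped to 16 bits. A per-nucleus mean-
intensity CV of ~2% is typical of well-exposed confocal imaging of
nuclear reporters; it is deliberately conservative rather than
flattering. Truth labels are disks of the configured diameter, ties to
the nearer centroid.

**Motion.** Random walk (0.3 µm/frame) with soft pairwise repulsion:
overlap never exceeds 30% of a diameter (floor 0.7·d = 8.4 µm), with
boundary clamping interleaved into the repulsion iterations so a cell
pushed against the field edge cannot re-overlap its neighbour. Daughters
are placed one diameter apart along a random axis. Centroids stay one
full diameter inside the field: the scene emulates the interior of a
larger stitched monolayer, and border-truncated blobs would otherwise
dominate the segmentation error budget for reasons that have nothing to
do with the pipeline under test.

**What the generator does *not* emulate** — and therefore what a green
test does not establish: photobleaching, focus drift, stage jitter and
stitching seams; nuclear shape (real nuclei are elliptical, textured and
deform during mitosis — blobs are isotropic Gaussians); cell death,
extrusion and cycle exit; reporter silencing or heterogeneous expression
levels beyond the phase model; the fluorescence gap's interaction with a
*learned* segmenter. Recovery results on synthetic movies bound the
pipeline's algorithmic error, not its error on real microscopy.

## 3. Segmentation

`sum_channels()` saturating-adds the two channels so every nucleus is
visible at every phase. The default detector in `segment_frame()` is a
deterministic stand-in for the trained model used on real data (whose
weights are not reproducible from text); any
`function(image, diameter) → labels` can replace it.

The detector: Gaussian smoothing (σ = d/6); background = median of the
frame border; Otsu's threshold on the square-root image (nucleus
brightness spans ~3× across phases, and the variance-stabilised scale
keeps one global threshold meaningful at both ends); centre detection as
local maxima of a difference-of-Gaussians response (σ = d/6 vs 1.6·d/6);
then a matched-model residual pass: fitted blobs
`A·exp(−r²/(2σ_eff²))`, σ_eff² = (d/4)² + (d/6)², are subtracted and
leftover maxima become additional centres. Pixels are finally assigned
to the centre with the largest predicted contribution, cut at the level
a blob reaches at r = d/2, and regions outside [0.25A, 4A] are
discarded.

Why not the classical distance-transform watershed? Two failure modes
are *provable* in this world. A pair overlapping by the allowed 30% has
a convex merged mask — one distance maximum, nothing for a watershed to
split. And a dim S-phase nucleus at minimum separation from a ~3×
brighter G1 neighbour produces **no local maximum at all** in either
intensity or any DoG scale (the bright tail's gradient exceeds the dim
blob's curvature), so no marker-based method can find it; only
subtracting the bright cell's fitted blob reveals it. With the residual
pass, per-frame agreement against truth labels is 1.0 on both noiseless
and default-noise movies up to the densest, final 48-h frame (criterion
10 asserts the ≥0.95 bound). The watershed and exact-EDT primitives
remain in `src/` as utilities.

Agreement accounting (`segmentation_agreement()`) is greedy one-to-one
matching by descending IoU with a 0.5 threshold — the operational
stand-in for the "model vs human-corrected counts" bookkeeping used when
training segmenters, which never defined a spatial metric.

## 4. Tracking and selection

`link_frames()` solves the padded linear assignment problem (shortest
augmenting path, compiled) with squared displacement cost, birth/death
cost `max_dist²` and links beyond `max_dist` (10 µm) forbidden; tests
prove equality with exhaustive enumeration for up to 6 detections per
frame. No gap closing exists anywhere — a missed detection ends the
track, as the duration filter depends on unbroken identity. At a
division the mother's track continues into the nearer daughter by plain
assignment; the other daughter starts a new track.

Selection applies two per-track predicates (they commute): duration
≥ 480 min (strict "under" removal — a 480-min track stays), and at
least one |Δ red max| > 300 (strict) — the mitotic-spike signature.
`detect_cytokinesis_peaks()` finds local maxima with prominence ≥
max(3×MAD of frame differences, 0.25×(max − median)) and full width at
half prominence ≤ 3 frames. The MAD floor alone (the natural
data-adaptive choice) proved too permissive in the stated noise world:
the mScarlet inverse-coupling step at G1/S plus 2% noise makes narrow
bumps marginally above it. The added term is scaled by the trace's own
peak amplitude, which a genuine spike dominates; both parameters remain
user-settable. Consecutive peak pairs ≥ 480 min apart become cycle
segments; closer pairs are flagged `TOO_SHORT`, single peaks
`EDGE_TRUNCATED` — explicit QC flags replace the by-eye review step, and
nothing is silently dropped.

## 5. Phase calling

All calls operate on percentile-normalised traces (subtract p5, divide
by p95 − p5): monotone, so order statistics are preserved, and affine-
invariant, so raw-vs-normalised ambiguity in the original protocol is
moot (a property test asserts invariance).

* **G1/S** — 3-frame median smoothing; reference plateau = running
  maximum since cycle start (the G2 re-rise can therefore never distort
  the G1 reference); call = first frame at or below half the plateau.
  With an exact one-halving-per-frame decay the call lands on
  `g1s + 1` — "the point after" the drop — and a ≤-with-tolerance
  comparison keeps that boundary case deterministic.
* **S/G2** — over [g1s, end], L = min of the 3-frame rolling median
  ("lowest maintained level"); call = first frame after the argmin where
  the rolling median exceeds L + δ for ≥ 3 consecutive frames,
  δ = max(0.1·plateau, 3·noise). The window, margin and persistence are
  config parameters; the original rule names neither, so the defaults
  were chosen once: 3 frames (30 min) is the shortest window that kills
  single-frame spikes, and the δ floor is an order of magnitude above
  the simulated noise scale.
* **FUCCI mode** — cycle start/end are ≥50% single-frame mCherry drops
  (or a supplied division frame); cycles starting under 5 h after
  recording start are excluded `TOO_EARLY` (acclimation), under 20 h
  before recording end `TOO_LATE` (may not complete) — exclusions with
  reasons, not errors.
* **Snapshots** — a nucleus is channel-positive above the background
  median + 3 MADs (scaled MAD; k configurable). V⁺C⁻ → G1/G0, V⁻C⁺ → S,
  V⁺C⁺ → G2/M. Double-negative nuclei (the early-S gap) form an explicit
  `indeterminate` class excluded from the three-way fractions by
  default, with a `fold_indeterminate = "S"` option — the published
  three-way fractions sum to 100%, implying such nuclei were absent or
  folded, and the package refuses to make that choice silently.

Parameter recovery is the core validity argument: on ≥ 200 simulated
cycles at default noise, the median absolute error of G1/S, S/G2 and
cytokinesis frames is ≤ 1 frame, and at zero noise every call is within
±1 frame (acceptance criterion 5 computes this from scratch). A
property test also checks that error is non-decreasing in the noise
sigma over a fixed grid.

## 6. Statistics

Quartiles use the linear-interpolation convention (`quantile` type 7) —
stated because the published quartile values depend on it.
`compare_groups()` gates on Shapiro-Wilk at α = 0.05 per group: both
normal → Student's t (pooled by default, `welch = TRUE` available),
otherwise two-tailed Wilcoxon–Mann–Whitney; stars at 0.05/0.005/0.0005.
`a_priori_n()` iterates the smallest n with noncentral-t power ≥ target
(two-sided), and the rank-test branch divides by the normal-parent
asymptotic relative efficiency 3/π and takes the ceiling: with
d = 0.714, α = 0.05, power = 0.95 this gives 52 (t) and 55 (WMW) — the
latter matching the published design, which fixes which branch the
original power analysis used. The effect size d = |m₁ − m₂|/sd is
computed from summary statistics and rounded to the three decimals at
which it was originally reported before entering the iteration (the
unrounded value 0.71351 would give 56; the published computation fed
the rounded 0.714 to its power software). No multiple-testing
correction is applied across phase comparisons, matching the original
analysis; the regression screen reports per-pair slope, R² and slope
p-value, and its null behaviour is asserted per regression (the joint
"all three null" rate is 0.95³ ≈ 0.86 by construction and would be the
wrong thing to bound at 90%).

## 7. Numerical choices and degenerate inputs

Constant traces normalise to zeros with zero noise scale (no division
blow-up) and yield `NO_G1S`/`NO_SG2` flags rather than calls. Blank
frames segment to zero labels; contrast under one 16-bit unit is treated
as numerical dust. The G1/S half-crossing uses a 10⁻⁹ relative tolerance
so an exact halving is "at or below". Ordering violations in
`phase_lengths()` are errors; impossible cycles in batch mode become
flagged rows. The TIFF layer is a deliberately minimal baseline
implementation (uncompressed grayscale 8/16-bit multi-page, both byte
orders) because no TIFF-capable R package is available in the target
environment; compressed or RGB input fails with a remediation hint
rather than a misread. Configs serialise to JSON; all randomness flows
from one integer seed through fixed per-cell sub-streams, and two runs
of `run_pipeline()` with equal config and seed are byte-identical
(criterion 9).

## 8. Known limitations

The default detector is matched to the simulator's blob model; on real
microscopy it is only a baseline, and the pluggable interface is the
intended path (wrap any external segmenter). Physically coincident
nuclei with extreme brightness ratios are resolvable only because the
blob model is known exactly; real overlapping nuclei need shape cues the
model does not carry. Sister-cell pairing, lineage statistics beyond
single-track continuation, gap closing, 3-D rendering and acquisition
control are out of scope. G2 and M are never separated (the reporters
cannot distinguish them), and G0 cells are indistinguishable from G1 in
snapshots — both are reported jointly, as in the original designations.
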