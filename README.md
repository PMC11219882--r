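# fuccitrace

Quantifying cell-cycle phase lengths in live fluorescent-reporter
epithelial monolayers.

Primary (non-immortalized) intestinal epithelial cells carrying dual
cell-cycle reporters can be imaged for days, but turning those movies into
per-cell G1, S and G2/M durations requires a pipeline: segment the nuclei
in every frame, link them into gap-free tracks, pick out the tracks that
span a full cycle, and read the phase transitions off the fluorescence
traces. `fuccitrace` implements that pipeline end to end for two reporter
designs, together with a synthetic-movie generator with full lineage
ground truth, so every stage is testable without any imaging data:

* **PIP-H2A** — a PIP-degron-mVenus (bright in G1, degraded at S onset,
  re-accumulating in G2) plus a constitutive H2A-mScarlet that keeps every
  nucleus visible and spikes acutely at mitosis as chromatids condense.
* **PIP-FUCCI** — PIP-degron-mVenus plus geminin-mCherry (dark in G1,
  rising through S/G2, collapsing at cytokinesis), which also assigns a
  phase from a single snapshot: mVenus⁺ = G1/G0, mCherry⁺ = S,
  double-positive = G2/M.

## The rules at the core

For a cycle delimited by two cytokinesis events (acute, narrow peaks of
the mScarlet mean intensity, detected by prominence and width):

* **G1→S** is the first frame at which the smoothed, normalised mVenus
  trace falls to half its running-maximum plateau ("dropped over 50%"),
* **S→G2** is the first frame after the minimum of the rolling median
  ("lowest maintained level" L) at which the trace rises above
  L + δ, δ = max(0.1·plateau, 3·noise), and stays there ≥ 3 frames,
* phase lengths follow as `G1 = (g1s − start)·Δt`, `S = (sg2 − g1s)·Δt`,
  `G2M = (end − sg2)·Δt` (hours), summing exactly to the total.

Candidate tracks must be gap-free, at least 480 min long, and contain at
least one frame-to-frame change of mScarlet max intensity above 300
(16-bit units) — the mitotic-spike signature. Tracking is
linear-assignment linking with squared displacement cost, a 10 µm maximum
step and no gap closing.

Downstream statistics reproduce the study design around such data:
median/quartile summaries, Shapiro-Wilk-gated Student-t vs two-tailed
Wilcoxon–Mann–Whitney comparisons with significance stars, pairwise
phase-length regressions, Cohen's d from summary statistics, and a-priori
sample sizes via noncentral-t iteration (with the 3/π
asymptotic-relative-efficiency correction for the rank test).

## Worked example

Simulate a 30-hour movie of five founder cells, run the whole pipeline,
and summarise the recovered phase lengths:

```r
library(fuccitrace)
cfg <- sim_config(n_founders = 5, image_size = c(200L, 200L),
                  duration = 1800, seed = 11)
res <- run_pipeline(pipeline_config(sim = cfg), "demo_out")
res$phase_calls
#>   cycle_id track_id start_frame g1s_frame sg2_frame end_frame G1_h  S_h G2M_h total_h
#> 1        1        1          41        70       114       129 4.83 7.33  2.50    14.7
#> 2        2        2           8        40        76        89 5.33 6.00  2.17    13.5
#> 3        3        3          42        89       132       143 7.83 7.17  1.83    16.8
#> 4        4        5          47        96       136       148 8.17 6.67  2.00    16.8
res$group_stats
#>     phase n    q1 median    q3
#> 1    G1_h 4  5.21   6.58  7.92
#> 2     S_h 4  6.50   6.92  7.21
#> 3   G2M_h 4  1.96   2.08  2.25
#> 4 total_h 4 14.38  15.75 16.83
```

Each row of `phase_calls` is one nucleus followed from one division to
the next: the frame indices are the called cytokinesis and transition
frames (10 min/frame), and the hour columns are the derived phase
lengths. Four full cycles were captured in this short demo movie; against
the generator's ground truth the division frames are exact and the
transition calls are within one frame. The statistics surface gives the
published design numbers directly:

```r
cohens_d(8.436, 5.796, 3.7)            # 0.714 (to 3 d.p.)
a_priori_n(0.714, family = "wilcoxon") # 55 cells per group
a_priori_n(0.714, family = "t")        # 52
```

A command-line interface wraps every stage (`simulate`, `segment`,
`track`, `select`, `call`, `snapshot`, `stats`, `run`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","fuccitrace.R",package="fuccitrace"))')" \
    run --config pipeline.json --out results/
```

## Scope notes

The learned segmentation model used on real recordings is not
re-implemented; a deterministic matched-blob detector fills its role
behind a pluggable interface (`segment_frame(..., detector = )`), and the
vignette (`vignettes/fuccitrace-methods.Rmd`) documents exactly what the
synthetic benchmark does and does not establish. Real stacks are accepted
as uncompressed multi-page 16-bit grayscale TIFF plus optional label
movies and CSV track tables in the documented dialect.
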