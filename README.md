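# dyadsync

Quantifying interpersonal movement coordination in dyadic trials: how
closely does one actor's rhythmic movement entrain to a partner's?

The package implements a complete coordination-quantification and inference
pipeline for a virtual-reality paradigm in which a participant performs
paced arm curls (80 bpm ≈ 1.33 Hz, 45-s trials sampled at 50 Hz) opposite an
avatar, under a 2 (focus: self vs. other, within participant) × 2 (avatar
gaze: direct vs. averted, between participants) mixed design. It is aimed at
researchers in movement science and social cognition who need the full chain
— signal conditioning, coordination metrics, and mixed-effects inference —
reproducible from raw channels to model tables.

## What it computes

**Arm coordination — relative-phase stability (rho).** Instantaneous phases
come from the analytic signal (Hilbert transform); their difference is
wrapped to (−180, 180°] and folded to [0, 180°] (0 = in-phase, 180 =
anti-phase). Coordination stability is the mean resultant length of the
folded distribution,

    rho = | mean( exp(2i · φ) ) |,   φ = folded relative phase (radians),

with angle doubling (axial convention) so uniform dispersion maps to rho ≈ 0
and perfect locking to rho = 1; rho is Fisher-transformed
(`atanh`) for linear modelling.

**Head coordination — cross-recurrence (%REC).** Both actors'
anterior–posterior head series are time-delay embedded; the embedding delay
is the first minimum of the average mutual information and the dimension the
first minimum of the false-nearest-neighbour fractions, both estimated from
the avatar (reference) series. %REC is the percentage of cross-recurrence
matrix cells with inter-trajectory Euclidean distance within a radius
(default 12 signal units):

    %REC = 100 · #{(i, j) : ‖a_i − b_j‖ ≤ r} / (n_a · n_b).

**Gaze.** Per-trial percent dwell time on three areas of interest (avatar,
near avatar, room), over valid samples in the same 40-s analysis window.

**Inference.** Linear mixed models `outcome ~ focus * gaze +
(1 | participant)` with the study's numeric coding (focus 1 = self,
2 = other; gaze 1 = direct, 2 = averted), Satterthwaite degrees of freedom,
a Shapiro–Wilk residual-normality gate with log-transform fallback, 4-df
likelihood-ratio comparisons for each AOI predictor, and Tukey-adjusted
simple-effect contrasts.

**Synthetic experiments.** Because the paradigm's human data cannot ship
with the package, a generator with known ground truth stands in: arm
channels from unidirectionally coupled stochastic phase oscillators (the
avatar is pre-programmed and evolves uncoupled), head channels from
band-limited (0.1–1 Hz) sway with graded mixing, gaze from a semi-Markov
AOI process, all under the 2×2 design with per-cell coupling maps and a
single master seed.

## Worked example

The analysis workflow lives in `analysis/01_simulate.R` …
`analysis/05_models.R`; each script is a thin driver over package functions
and writes under `results/`. Running the five scripts in order on the
default seed prints, at the coordination stage:

```
Embedding from avatar head series: delay 22 samples, dimension 4
Arm rho: mean 0.944 (range 0.777-0.984)
Head %REC: mean 5.61% (range 4.00-7.43)
```

— the delay lands near the sway band's decorrelation scale, rho is high
because the arm task is strongly paced, and %REC sits in the low
single-digit percentages typical of cross-recurrence studies. The model
stage then prints, for arm coordination:

```
<model_fit> rho_fisher ~ focus * gaze + (1 | participant)
         term        b      se    df       t         p
1 (Intercept)  2.63039 0.17134 68.11 15.3518 8.369e-24
2       focus -0.06945 0.09351 38.00 -0.7427 4.622e-01
3        gaze -0.55990 0.10837 68.11 -5.1668 2.255e-06
4  focus:gaze  0.08220 0.05914 38.00  1.3899 1.727e-01
```

The negative `gaze` coefficient says arm coordination is lower in the
averted-gaze group (coded 2) than the direct-gaze group (coded 1) — exactly
the contrast built into the generator's arm-coupling map — while focus and
the interaction are null, as constructed. The same stage reports the 4-df
AOI likelihood-ratio comparisons and Tukey-adjusted simple effects.

Equivalently in one call:

```r
library(dyadsync)
res <- run_pipeline(pipeline_config(n_per_group = 20, seed = 20260927),
                    out_dir = "results")
res$models$rho_fisher$fit
```

## Data dialects

CSV, UTF-8, header row, times in seconds. Motion:
`participant_id, trial_id, actor, channel, t_s, x, y, z` (arm on the
vertical axis `z`, head on the anterior–posterior axis `x`). Gaze:
`participant_id, trial_id, t_s, aoi`. Design: `participant_id,
gaze_condition, trial_id, focus_condition, trial_order`. Real recordings
mapped into these dialects flow through the identical pipeline via
`read_motion_csv()` / `read_gaze_csv()`.

See `vignettes/coordination-methods.Rmd` for the generative model, estimator
choices (AMI binning, FNN tolerances, filter edge handling, the rho
convention) and known limitations.
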