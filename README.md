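# dimtrace

Time-resolved decoding of behavior-derived object dimensions from
multichannel neural recordings.

## The problem

Object vision research increasingly replaces discrete category labels with
*continuous, behavior-derived object dimensions*: every stimulus carries a
nonnegative weight on each of a set of dimensions (e.g. "colorful",
"plant-related") learned from large-scale similarity judgments. The
scientific question is *when* each of these dimensions is reflected in the
evoked neural signal: some dimensions produce a sharp early response
(~125 ms), others a slow rise to a late sustained peak (~300 ms), and some
an additional response ~100 ms after stimulus offset.

`dimtrace` implements the full analysis chain for this question, for
epoched multichannel recordings (trials × sensors × timepoints) with a
per-trial stimulus table and a stimulus × dimensions embedding:

1. **Timepoint-wise ridge decoding.** At every timepoint *t*, a
   multi-target ridge regression maps the sensor pattern
   `x_i(t) ∈ R^{sensors}` to the embedding weights `y_i ∈ R^{dims}`.
   Performance is the Pearson correlation `r_d(t) = cor(ŷ_d, y_d)` over
   held-out trials, per dimension — a timecourse of dimension information.
   The penalty is tuned per target at each timepoint by internal
   cross-validation over 100 linearly spaced values in [1e-6, 3e4].
2. **Session-wise and across-participant cross-validation.** Within a
   participant, each recording session is held out once (train on the
   rest). Across participants, the model trains on one participant's
   sessions and tests on another's held-out session, with fold sizes
   matched to the within scheme — a stringent generalization test.
3. **Sensor encoding models.** The converse fit (embedding → single sensor
   response) localizes which sensors carry dimension information when.
4. **Permutation statistics with max-statistic correction.** Test labels
   are shuffled (consistently across folds) against the unchanged model
   predictions; the threshold is the maximum, over all dimensions and
   timepoints, of the per-cell 99th null percentiles.
5. **Shape clustering by dynamic time warping.** Dimension timecourses are
   smoothed, z-scored per participant, averaged, low-SNR dimensions
   excluded (lowest 5% of significant timepoints), pairwise DTW distances
   computed (lowest-cost monotone boundary-aligned path through the
   timepoint-distance matrix), and hierarchically clustered (average
   linkage, cut at 0.5 × the maximum distance) into prototype shapes.

A forward simulator (`generator_config()`, `simulate_epochs()`) plants
dimension-specific temporal profiles, shared vs participant-specific
sensor projections, and additive noise, so every stage can be validated
end to end on data with known ground truth — no recordings needed.

## Worked example

Simulate the default desk-scale study (2 participants, 4 sessions × 200
concepts, 32 sensors, 8 dimensions — four planted "early", four "late"),
then decode participant 1 with session-wise cross-validation:

```r
library(dimtrace)
cfg <- generator_config(seed = 42)
emb <- generate_embedding(cfg$n_concepts, cfg$n_dims, seed = 43)
img <- expand_to_images(emb, exemplars_per_concept = cfg$n_sessions, seed = 44)
ds  <- simulate_epochs(cfg, img$images, seed = 45)

folds <- make_session_folds(ds$P1$trial_table)
tc <- decode_timecourse(ds["P1"], img$images, folds)
summary(tc)
#>   dimension    peak_r peak_ms     mean_r
#> 1     dim01 0.4639985     130 0.02208834
#> 2     dim02 0.4390618     130 0.03357185
#> 3     dim03 0.3432544     140 0.02129618
#> 4     dim04 0.4391962     140 0.02493294
#> 5     dim05 0.3527755     290 0.02852798
#> 6     dim06 0.3035732     290 0.02878063
#> 7     dim07 0.3302611     300 0.03868059
#> 8     dim08 0.3460704     290 0.04450338
```

The planted latencies are recovered: the four early dimensions peak within
two samples of 125 ms, the four late ones within one sample of 300 ms, at
peak correlations of 0.30–0.46. Permutation significance:

```r
nl  <- permutation_null(tc, n_permutations = 200, seed = 46)
thr <- corrected_threshold(nl)    # 0.1117
significance_mask(tc, thr)
#> significance_mask: threshold 0.1117; 8/8 dimensions significant somewhere
```

Every dimension is detected. (One onset in this run lands pre-stimulus —
dim08 at −60 ms — illustrating that this null construction is mildly
anti-conservative for fold-averaged statistics; see the methods vignette
for the analysis.) `plot(tc)` draws the timecourses;
`compare_models()` contrasts within- vs across-participant decoding at
selected latencies; `shape_analysis()` runs the DTW clustering;
`run_pipeline()` chains everything and writes TSV/JSON outputs with a
reproducibility manifest.

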