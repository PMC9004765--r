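# echoclick

Toothed whales (odontocetes) forage and navigate with echolocation
clicks — broadband impulses tens to hundreds of microseconds long whose
spectral shape and inter-click timing are often diagnostic of species.
Long-term passive acoustic monitoring with bottom-moored high-frequency
recorders produces years of such data, far more than can be labelled by
hand. `echoclick` implements, as a tested and reusable R pipeline, a
machine-learning workflow for discovering and classifying echolocation
click types in that kind of data:

1. **Detection** — an energy detector with a 10 kHz high-pass and
   100 kHz low-pass, a 115 dB<sub>pp</sub> re 1 µPa received-level floor,
   retention of impulses 30–1200 µs long, and merging of detections
   separated by less than 100 µs. Spectra are computed from 2 ms
   Hann-windowed FFTs centered on the click peak (400 points at
   fs = 200 kHz, 640 at 320 kHz) on a common 10–100 kHz grid at 0.5 kHz
   spacing.
2. **Bin features** — detections are grouped into 5-minute bins; each
   within-bin cluster is summarized by its mean min-max-normalized dB
   spectrum, its inter-click-interval (ICI) distribution truncated at
   0.6 s, its mean waveform envelope, and a Gaussian fit to the ICI
   histogram giving the modal ICI.
3. **Two-phase unsupervised clustering** — phase 1 clusters clicks
   within each bin on spectral correlation distance (floor
   120 dB<sub>pp</sub>, minimum 50 clicks, network cap 10,000 nodes);
   phase 2 clusters bin summaries across the dataset on the mean of
   spectral and envelope correlation distances (cap 20,000, minimum 25
   bins, 1% least-connected pruning). Both phases use the Chinese
   Whispers label-propagation algorithm with at most 15 iterations,
   repeated over random orders, keeping the partition with the highest
   average normalized mutual information (NMI).
4. **Classification** — a feed-forward network (input, four 512-node
   fully connected layers with 50% dropout between each, softmax output)
   trained on 341-point bin features (181 spectrum + 60 ICI + 100
   envelope), with classes balanced to 5000 examples each (random
   subsample, or Gaussian-noise / ICI-resampling augmentation) and a
   70/20/10 train/test/validation split.
5. **Evaluation** — per-class confusion matrices and the standard
   metrics

   accuracy = (TP + TN) / all, recall = TP / (TP + FN),
   precision = TP / (TP + FP),

   plus specificity and misclassification rate, a strict
   125 dB<sub>pp</sub> received-level evaluation filter, and relative
   acoustic presence (percent of recording days with presence per
   deployment, averaged across deployments at a site).

Because raw hydrophone data of this kind are not redistributable, the
package ships a **synthetic scene generator**: click-type templates
carrying the spectral peaks, −3 dB bandwidths and modal ICIs of the ten
Hawaiian click types (false killer whale, rough-toothed dolphin, two
short-finned pilot whale types, bottlenose dolphin/melon-headed whale,
Blainville's and Cuvier's beaked whales, two stenellid types, *Kogia*
spp.), audio rendering with calibrated received levels and interfering
noise, and a fast generator of labelled bin features including a ship /
echosounder "junk" class. Every stage of the pipeline is exercised
against this generator.

## A worked example

```r
library(echoclick)

tpl <- hawaii_click_templates(c("Cuvier's beaked whale", "Kogia spp."))
scene <- scene_config(
  duration_s = 30,
  trains = list(
    list(template = tpl[[1]], start_s = 1, n_clicks = 40, rl_dbpp = c(130, 135)),
    list(template = tpl[[2]], start_s = 2, n_clicks = 60, rl_dbpp = c(128, 133))
  ),
  background_rms = 0.001, seed = 11
)
audio <- render_scene(scene)
det <- detect_clicks(audio$waveform, audio$fs_hz,
                     calibration_db = audio$calibration_db)
nrow(det)
#> [1] 100
```

All 100 injected clicks are recovered in this scene (the test suite
asserts ≥ 95% recovery within 0.5 ms on high-SNR scenes in general),
and recovered peak-to-peak received levels match the injected ones to a
median error below 0.05 dB. Feeding the detections onward:

```r
bc <- cluster_bins(det, cluster_params(min_cluster_size_clicks = 20))
types <- cluster_types(bc, cluster_params(min_cluster_size_bins = 1))
match_templates(types, tpl)
#> # A tibble: 2 × 3
#>   type_id template              distance
#>     <int> <chr>                    <dbl>
#> 1       1 Cuvier's beaked whale  0.00332
#> 2       2 Kogia spp.             0.0252
```

The published evaluation tables ship with the package, so the network
metrics can be recomputed directly:

```r
cms <- hawaii_confusion_matrices()
class_metrics(cms$kona, "False killer whale")[, c("recall", "precision")]
#> # A tibble: 1 × 2
#>   recall precision
#>    <dbl>     <dbl>
#> 1  0.880     0.485
tidy(combine_matrices(cms))   # combined-site metrics for all 11 classes
```

`run_pipeline(pipeline_config(...))` chains the whole workflow —
simulate, detect, featurize, cluster, train, classify, evaluate,
presence — into a run directory with per-stage CSV/JSON outputs and a
manifest whose hash reproduces exactly under an identical configuration.

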