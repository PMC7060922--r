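# tirfdyn

Quantification of insulin-stimulated GLUT4 vesicle trafficking in TIRF
microscopy time-lapse data, built as a fully tested analysis workflow
over a synthetic-scene generator with per-vesicle ground truth.

TIRF (total internal reflection fluorescence) microscopy illuminates
only a thin evanescent layer above the coverslip — excitation decays as
`exp(−z/d)` with depth `d ≈ 110 nm` — so a GFP-tagged GLUT4 reporter
reveals exactly the vesicles near or docked at the adherent plasma
membrane. The package is for cell biologists who quantify such movies
and for method developers who need a ground-truthed testbed. It
implements:

* **Image conditioning** — rolling-ball background subtraction
  (grayscale opening with a ball-cap structuring element), exact median
  despeckling, and local-median outlier removal.
* **Mobile/static decomposition** — each 1-min bin's average projection
  is subtracted pixel-by-pixel; the clipped residual is the mobile
  stack, the remainder the static stack (`mobile + static ==
  original` exactly). Foci are defined by three criteria: a local
  maximum, ≥ 75% of integrated spot intensity within a 5-px radius
  (relative to 10 px), and a half-height support of at least a
  2-px-radius disk; counts are taken in 100 µm² ROIs.
* **Translocation kinetics** — footprint-masked intensity at discrete
  time points, fitted with
  `R(t) = 1 + (A − 1)(1 − 2^(−t/t½))` for the plateau fold `A` and
  half-time `t½`; evanescent-depth calibration from 10 µm bead images
  via the height map `z(r) = R − sqrt(R² − r²)`.
* **Screen quantification** — HA/GFP surface-to-total ratios under
  per-group and control-basal normalisation, GFP/DAPI abundance,
  Manders/Pearson colocalisation, Welch *t* and two-way ANOVA.
* **Simulation** — TIRF scenes with docked vesicles, transiently
  visiting mobile vesicles, insulin-triggered density relaxation,
  Poisson + read noise, uneven background, burst or continuous
  acquisition, and exported ground truth for every rendered vesicle.

The methods vignette (`vignettes/tirfdyn-methods.Rmd`) documents the
models, parameter choices and known limitations.

## Worked example

Simulate a movie with a known scene, condition it, and count mobile and
static vesicles per 100 µm² ROI:

```r
library(tirfdyn)

counts <- run_dynamics_study(seed = 1)   # docked 4 -> 3 per 100 um^2,
                                         # mobile visits 1 -> 2 per min
aggregate(cbind(mobile_count, static_count) ~ t_min, counts, mean)
```

Averaged over ten seeds (`analysis/03_vesicle_dynamics.R`) this prints:

```
  t_min mobile_count static_count
1  -0.5         1.13         3.64
2   0.5         1.94         3.08
3   1.5         2.09         2.99
4   2.5         2.06         2.96
5   3.5         2.15         2.97
6   4.5         2.10         2.98
7   5.5         1.95         2.97
```

Bin 1 is pre-insulin: mobile counts sit at the configured basal rate
(truth 1 per 100 µm² per min) and rise to the post-insulin plateau
(truth 2; recovered mean 2.07, +3%), while docked vesicles decline from
4 toward 3 — the insulin response the counting stage is built to
measure. Kinetics works the same way:

```r
fits <- lapply(1:10, function(s) run_kinetics_study(3.3, 12.3, seed = s))
summarize_kinetics_fits(fits)
#>   mean_A mean_t_half n_used n_flagged
#> 1   3.24        13.0     10         0
```

i.e. an adipocyte-parameterised scene (ground-truth fold 3.3, half-time
12.3 min) is recovered as fold 3.24 and 13.0 min from noisy movies, end
to end through footprint segmentation, conditioning and fitting.

## Analysis workflow

The numbered drivers under `analysis/` reproduce the full study and
write tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | generates the reference movies, ground truth and bead image |
| `02_preprocess.R` | runs the conditioning chain, reports background suppression |
| `03_vesicle_dynamics.R` | 10-seed mobile/static counting study (`roi_counts.csv`) |
| `04_kinetics.R` | 10-seed translocation-fit study + depth calibration |
| `05_screen_quantify.R` | HA/GFP conventions, colocalisation, group statistics |

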