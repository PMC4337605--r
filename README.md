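# afmhelix

Quantitative analysis of actin filament conformations in high-speed
atomic force microscopy (HS-AFM) movies — for cytoskeleton researchers
who need the helical-pitch, cluster-growth and severing statistics that
HS-AFM topographs carry at the resolution of one half helix.

## The science

An actin filament images as a periodic ridge whose height maxima mark
the crossover points of the two-start helix. Writing `P_i` for the arc
position of crossover `i` along the traced backbone, the half-helical
pitch is `p_i = P_{i+1} - P_i` (~36.8 ± 4.3 nm for bare F-actin) and the
crossover height tracks decoration (~8.6 ± 0.8 nm bare vs
~10.6 ± 1.0 nm for cofilin-decorated, supertwisted segments whose pitch
shortens to ~26.9 nm — a ratio of 1.37, i.e. 27% shortening). Because
measured pitches mix true structural variation with measurement error,
the package implements the paracrystal calibration: paracrystals
(laterally aligned filament bundles with suppressed structural
variation, pitch 36.5 ± 3.0 nm) bound the measurement error, and the
structural spread follows by quadrature subtraction,

```
sd_true = sqrt(sd_obs^2 - sd_err^2)      e.g. sqrt(4.3^2 - 3.0^2) = 3.1 nm
```

On top of the pitch/height statistics the package measures the
asymmetric supertwist propagation at cofilin cluster boundaries (first
bare neighbor on the pointed-end side ~28.8 nm vs ~37.3 nm on the
barbed side), counts cluster growth events and their directional bias
(pointed-end-dominated), and detects and classifies filament severing
sites into four boundary categories (far bare, boundary-neighboring
bare, cluster end, cluster interior).

A synthetic movie generator renders parametric filament models —
periodic crossover envelope, cylinder cross-section, spherical-tip
grayscale dilation, calibrated localization error, pixel noise — with a
complete ground-truth log (states, true pitches, growth and severing
events), so every stage of the measurement chain is validated against
known truth. See the methods vignette
(`vignettes/afm-filament-analysis.Rmd`) for the model, the error
calibration and the design decisions.

## Worked example

Simulate a 20-frame movie of a filament carrying a cofilin cluster,
write it to disk, and analyze it blind from the file:

```r
library(afmhelix)

# calibrate the injected localization jitter so the pipeline's total
# pitch-level measurement error matches the 3.0 nm paracrystal value
cfg <- calibrate_localization_jitter(afm_config(), seed = 1)

set.seed(1)
model <- build_filament_model(cfg, n_half_helices = 24,
                              cluster_spec = list(c(10, 13)))
sim <- simulate_dynamics(model, cfg, n_frames = 20, seed = 1)
write_movie(sim$movie, "movie.tif")          # + JSON calibration sidecar

movie <- read_movie("movie.tif")
ana <- afm_analyze(movie, polarity = "pointed_at_start")
summ <- afm_summarize(ana)

summ$pitch$bare
#> <afm_summary> n = 389, mean = 36.5, sd = 4.4, range [20.1, 47.0]
summ$pitch$decorated
#> <afm_summary> n = 91, mean = 27.7, sd = 3.4, range [19.9, 34.5]
summ$decomposition$bare
#> <decomposition> sd_obs 4.4 nm = sd_true 3.3 (+) sd_err 3.0 nm
summ$supertwist$ratio
#> [1] 1.32
```

Reading: 500 crossover peaks were detected and linked into 35 tracks
over 20 frames; the bare-zone pitches average 36.5 nm with a 4.4 nm
spread, of which 3.3 nm is structural after removing the calibrated
3.0 nm measurement error; the threshold-classified decorated half
helices average 27.7 nm, giving a supertwist ratio of 1.32 on this
small single-filament sample (the large-sample value is 1.37).

`ana$half_helices` is the per-frame half-helix table (pitch, height,
decoration state), `ana$clusters` the per-frame cluster spans, and
`sim$log` holds the ground truth (growth and severing events) for
validation. A thin command-line wrapper with `simulate`, `analyze` and
`summarize` subcommands is installed as `exec/afmhelix`.

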