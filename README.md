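# scnclust

Automated deconstruction of **spatial** and **temporal** organisation in
circadian bioluminescence image stacks.

Organotypic slices of the suprachiasmatic nucleus (SCN) carrying a
bioluminescent clock reporter (e.g. PER2::LUC) are imaged for days at a
fixed sampling interval. Two properties of such recordings are biologically
separable: the tissue's decomposition into stable, spatially contiguous
regions with coherent brightness profiles, and the circadian (18–30 h)
rhythmicity and orderly phase progression of those profiles. Clock mutants
dissociate them — tissue without a cell-autonomous oscillator can keep its
spatial organisation while losing rhythm; tissue without intercellular
VIP/VPAC2 coupling can keep a weak rhythm while losing spatial organisation.
`scnclust` measures both from a raw movie, for people analysing reporter
imaging of the SCN or any tissue-scale oscillator network.

## What it computes

* **Preprocessing** — quantile despiking (3×3×3 neighbourhood repair), 2×2
  superpixel averaging, Otsu tissue masking, 15-h-window peak/trough
  detection, trough-anchored frame normalisation, 3×3 cell-ROI extraction.
* **k-medoid clustering** of superpixel time series under the cosine
  distance `D(u,v) = 1 − u·v/(|u||v|)` (invariant to rescaling, so basal
  brightness cannot drive clusters), with the number of clusters chosen by
  the **gap statistic** (uniform range-box references, one-SE rule) and the
  analysis restricted to the 5–6 highest-amplitude clusters.
* **Fourier rhythm assessment** per cluster: amplitude spectra with
  white-noise significance lines at mean ± 2 SD across bins, and an
  18–30 h **notch filter** (exact band deletion + inverse transform) to test
  whether spatial organisation survives on non-circadian frequencies alone.
* **Spectral clustering and embedding**: a dense similarity network with
  correlation distance `d = sqrt((1 − r)/2)` and Gaussian kernel
  `W = exp(−d²/(2σ²))` (σ = 0.95), the symmetric normalised Laplacian
  `L = I − D^(−1/2) W D^(−1/2)` (relaxed N-cut), seeded k-means
  discretisation (k = 5, l = 2), and the **clock-face** readout: the circular
  mean direction of the nodes peaking at each frame, its monotonicity, turns
  per 24 h and phase-tracking correlation, plus the **embedding coherence**
  histogram (centre distances over half the embedding diameter; rings ≈ 1,
  filled disks ≈ 2/3).
* **A ground-truthed simulator** with `wt`, `cry_null`, `vpac2_organised`
  and `vpac2_disorganised` presets, so the whole pipeline is testable without
  the original recordings.

I/O is multi-frame TIFF (a minimal built-in baseline codec, ImageJ/tifffile
compatible) with a JSON sidecar carrying the sampling interval, and CSV/JSON
artifacts.

## Worked example

```r
library(scnclust)

# six simulated days of a wild-type slice, 64x64 px at 0.5 h per frame
cfg   <- phenotype_preset("wt", height = 64, width = 64, frame_count = 288,
                          seed = 1)
movie <- generate_movie(cfg)

report <- run_pipeline(movie$stack,
                       run_config(k_policy = "auto", gap_B = 20L,
                                  top_n = 5L, seed = 1))
report
#> <scn_report>
#>   k-medoid clusters: 5 (auto), circadian-significant fraction 1.00
#>   spatial organisation: contiguity 1.00 -> organised
#>   temporal organisation: rhythmic; clock hand 1.00 turns/24 h, monotonicity 0.98
#>   embedding coherence rho_mean = 0.944; notch re-cluster ARI = 1.00
```

Reading the numbers: the gap statistic selected **5 clusters** (the number of
planted phase regions); every top cluster has **circadian-significant**
Fourier amplitude; each spectral cluster is spatially **contiguous**
(contiguity 1.00); the clock hand completes **one turn per 24 h** almost
without reversals (monotonicity 0.98), i.e. peak expression sweeps the tissue
in phase order; the embedding is ring-like (**rho_mean 0.94**, a filled disk
would give ~0.67); and re-clustering after deleting the circadian band
reproduces the same spatial map (**notch ARI 1.00**) — the spatial
organisation is carried by non-circadian frequencies.

Running the same pipeline on `phenotype_preset("cry_null", ...)` flips only
the temporal flags (arrhythmic, reversing clock hand, spatial map intact);
`"vpac2_disorganised"` flips only the spatial ones.

A thin command-line front end over the same functions lives at
`inst/cli/scnclust.R`:

```sh
Rscript inst/cli/scnclust.R simulate-run --preset wt --size 64 --frames 288 --out out/
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on a freshly simulated wild-type
recording at the given seed — despike → superpixels → mask → gap-selected
k-medoids → amplitude trimming → spectra → notch re-cluster → spectral
clustering/embedding → clock face and coherence — prints the report, and
writes the JSON result file.

## Documentation

The methods vignette
(`vignettes/scn-spatiotemporal-methods.Rmd`) documents the model, every
tunable parameter with its default and rationale, what the simulator does and
does not emulate, numerical choices (tie-breaks, degenerate inputs,
determinism), and known limitations.
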