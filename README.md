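# ramanbiopsy

Chemometrics for intraoperative Raman optical biopsy of brain tissue.

During glioma surgery the boundary between tumor center, the
infiltration zone at the tumor edge, and normally appearing white
matter is hard to judge by eye. Raman spectroscopy probes tissue
composition directly — cholesterol, carotenoids, hemoglobin, water and
protein bands all shift in abundance as tissue turns malignant — but
raw fiber-probe spectra arrive buried under an intense fluorescence
continuum and detector noise. `ramanbiopsy` implements the full
analysis chain that turns raw spectra into a tissue call, for
spectroscopists and analysts who want a tested, reproducible, tidy
(tibble-in, tibble-out) implementation:

1. **Preprocessing** — averaged ambient-background subtraction,
   exclusion of spectra exceeding 90% of the detector dynamic range,
   Savitzky–Golay smoothing (15-point window, 3rd-order polynomial),
   fluorescence-baseline removal by a fitted sum of K Morlet wavelets

   B(ν) = Σₖ aₖ · exp(−((ν−cₖ)/sₖ)²/2) · cos(ω₀(ν−cₖ)/sₖ),

   fitted with bounded, asymmetric nonlinear least squares so the
   continuum stays under the Raman peaks; cropping to 900–1800 cm⁻¹;
   and integral-intensity normalization.
2. **Feature filtering** — a per-wavenumber Fisher criterion (one-way
   ANOVA F across the three tissue classes, df = 2, n−3): wavenumbers
   whose F statistic exceeds the critical value at level α are
   retained, and retained intensities are summed within biochemical
   bands (cholesterol, carotenoids, hemoglobin, water, amides, …)
   with significance tiers (*p<0.05, **p<0.001).
3. **Classification** — three variants, compared over paired
   train/test splits (30% training, at least 5 spectra per class):
   `pca_only` (PCA → RBF-SVM), `filtered_svm` (Fisher mask → SVM) and
   `combined` (Fisher mask → PCA → SVM).
4. **Synthetic data** — a generator that emulates the study design
   (3/3/4 samples × 5 replicates per class, background frames,
   fluorescence, saturation, noise) with full ground truth, so every
   stage is testable without access to clinical spectra.

## Worked example

```r
library(ramanbiopsy)

# simulate a study-like cohort: 3/3/4 samples x 5 replicates,
# one overexposed replicate each in normal and center
res <- run_full(generator = study_design_config(seed = 11),
                n_repeats = 50, seed = 1)
res
#> <pipeline_result>
#>   excluded spectra: center_s4_r4, normal_s2_r4
#>   retained wavenumbers: 297 of 683 (alpha=0.05)
#> <variant_comparison> 50 repeats, base_seed=1
#> # A tibble: 3 x 8
#>   variant      mean_accuracy mean_sensitivity mean_specificity sd_accuracy ...
#>   <chr>                <dbl>            <dbl>            <dbl>       <dbl>
#> 1 combined             0.881            0.921            0.78       0.0589
#> 2 filtered_svm         0.974            0.985            0.947      0.0258
#> 3 pca_only             0.847            0.906            0.696      0.0838
```

Two saturated replicates are dropped (leaving 14/15/19 spectra), 297
of 683 wavenumbers pass the Fisher filter, and over 50 paired splits
the `combined` variant buys its specificity gain over `pca_only` at
essentially unchanged accuracy — the qualitative behavior expected
when the discriminative signal is confined to sparse bands while
dense nuisance variance floods the full spectrum.

Individual stages are ordinary functions on tibbles:

```r
sim  <- generate_dataset(study_design_config(seed = 11))
meas <- dplyr::filter(sim$spectra, frame_kind == "measurement") |> raman_spectra()
bgs  <- dplyr::filter(sim$spectra, frame_kind == "background") |> raman_spectra()
pre  <- preprocess_pipeline(meas, bgs)

m    <- grouped_matrix(pre)
mask <- build_mask(m, alpha = 0.05)
glance(mask)                      # n kept, F critical value, dfs
bands <- aggregate_bands(m, mask) # per-band class means ± SE with tiers
autoplot(mask); autoplot(bands); plot_class_means(pre)
```

Spectra read and write as plain CSV/TSV (wide or long dialect) with a
JSON metadata sidecar — see `read_spectra()`, `write_spectra()`,
`read_band_library()`, `write_report()`.

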