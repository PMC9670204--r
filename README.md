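# lysoclust

Quantitative readouts for oxidative-stress-induced **perinuclear lysosomal
clustering** and its companion assays, with synthetic-data generators that
plant known ground truth for every stage.

Under oxidative stress, lysosomes are transported along microtubules
toward the microtubule-organising centre (MTOC), forming a perinuclear
cluster. This package is for cell biologists and image analysts who need
the measurements around that phenomenon to be reproducible and testable:

* **Image quantification** — the lysosomal clustering score: for each
  cell, LAMP2-channel intensity inside a circular ROI of radius 2 µm
  centred on the γ-tubulin (MTOC) spot, divided by whole-cell intensity,

  r = Σ_(ROI∩cell) I_LAMP2 / Σ_cell I_LAMP2,

  after z-projection and background thresholding; group values are
  expressed relative to the control-group mean (`quantify_field()`,
  `clustering_values()`).
* **Calcium spikes** — F340/F380 (Fura-2) ratio traces sampled every 5 s;
  spikes are baseline-relative transients with amplitude > 0.05 ratio
  units over a 40 min window, summarised as the percentage of cells per
  spike count (`detect_spikes()`, `spike_histogram()`).
* **Phosphopeptide quantification** — top-3 unmodified-peptide
  normalization of peak-area tables and per-condition fold changes with
  Tukey–Kramer testing (`normalize_peptides()`, `condition_ratios()`).
* **Group statistics** — Wilcoxon rank-sum with exact small-sample
  enumeration, Dunnett's many-to-one test via Monte Carlo on the
  equicorrelated multivariate t, Steel's rank-based many-to-one test via
  permutation, Tukey–Kramer all-pairs, plus LDH cytotoxicity and LC3-II
  flux-index arithmetic.
* **Synthetic data** — `generate_field()`, `generate_traces()`,
  `generate_peptide_table()`, `generate_groups()` plant configurable
  ground truth (perinuclear fraction, spike times/amplitudes, fold
  changes, group distributions) so each stage is validated by parameter
  recovery, not by eyeball.

See `vignettes/lysoclust-methods.Rmd` for the model, the defaults and the
design decisions.

## Worked example

Simulate a control (20 % perinuclear lysosomes) and a treated (70 %)
condition, quantify, normalise to control, and test:

```r
library(lysoclust)

sim_group <- function(fraction, n_fields, seed0) {
  vapply(seq_len(n_fields), function(i) {
    fld <- generate_field(field_sim_params(
      field_shape = c(160, 160), n_cells = 2, cell_radius_um = 3,
      n_lysosomes_per_cell = 30, perinuclear_fraction = fraction,
      perinuclear_sigma_um = 0.5, psf_sigma_um = 0.2, seed = seed0 + i))
    cfg <- quant_config(threshold = list("fixed", value = 0),
                        min_cells_per_field = 2)
    mean(quantify_field(fld, cfg)$ratio)
  }, 0)
}

quants <- data.frame(
  group = rep(c("control", "treated"), each = 8),
  ratio = c(sim_group(0.2, 8, 100), sim_group(0.7, 8, 200)))
cv <- clustering_values(quants, "control")
aggregate(clustering_value ~ group, cv, mean)
#>     group clustering_value
#> 1 control         1.000000
#> 2 treated         1.558642

wilcoxon_rank_sum(cv$clustering_value[cv$group == "treated"],
                  cv$clustering_value[cv$group == "control"])
#> <comparison_result: wilcoxon_rank_sum>
#>  comparison statistic   p_adjusted
#>      x vs y        64 0.0009391057
```

The control mean is 1 by construction; the treated group's clustering
value of ≈ 1.56 reflects the planted shift from 20 % to 70 % perinuclear
lysosomes, and the rank-sum test rejects equality at p ≈ 0.001.

Calcium traces work the same way — generate, detect, summarise:

```r
tr <- generate_traces(trace_sim_params(n_cells = 3,
                                       spike_rate_per_min = 0.1, seed = 9))
detect_spikes(tr[[2]])$spikes
#>   peak_time_s  amplitude
#> 1        1120 0.11717449
#> 2        2065 0.05818307
```

Both detected events exceed the 0.05 amplitude rule; their amplitudes are
the baseline-subtracted peak heights in ratio units.

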