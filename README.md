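# cetime

Tools for quantifying the **timing of convergence & extension (C&E)
morphogenesis** in zebrafish gastrulae and blastoderm explants, for
developmental biologists analyzing stage-resolved expression screens,
explant time-lapse shape series, and in-vivo nuclear tracking data.

C&E movements narrow the gastrula mediolaterally and elongate its
anteroposterior axis, beginning at a precise mid-gastrulation time (~8
hpf). `cetime` implements the computational workflow of a trigger-gene
timing study end to end:

* **Trigger-gene screen** — finds genes whose TPM trajectory is flat from
  sphere to 50% epiboly, rises at least 1.5-fold at shield stage
  (gastrulation onset, 6 hpf) and stays up, in *every* explant condition;
  candidates are tiered by confirmation in intact embryos and by the hard
  cutoffs Δ > 0.5 and > 5 TPM at shield. Paired-gene analysis
  (`ratio_trajectory()`) locates the peak and inversion of an antagonist
  ratio such as *sumf2*/*sumf1*.
* **Explant shape dynamics** — roundness `4·Area/(π·MajorAxis²)` from label
  masks or boundary polygons; inclusion rule (roundness < 0.5 by 12 hpf);
  Boltzmann sigmoid fits `r(t) = Bottom + (Top−Bottom)/(1+e^{(t−V50)/slope})`
  yielding V50 (timing) and slope (pace); nested-model comparison between
  genotypes by the extra sum-of-squares F test; automated extension-onset
  calls; length/width morphometry.
* **Convergence kinetics** — per-frame mean mediolateral displacement of
  tracked nuclei (convergence-positive sign), 100-µm midline exclusion and
  3-frame minimum duration, 4-point smoothing, onset as a
  piecewise-linear (hinge) changepoint gated by an F test, per-track
  persistence and speeds.
* **Quantification utilities** — 2^−ΔΔCt relative expression,
  internal-standard heparan-sulfate disaccharide amounts (pmol, % of
  total, pmol/µg protein), and pairwise protein identity/similarity under
  BLOSUM62 with an affine-gap global aligner.
* **Synthetic data** — seeded generators for all of the above, so the full
  pipeline is testable offline against planted ground truth.

## Worked example

```r
library(cetime)

## screen a synthetic panel with 8 planted trigger genes
spec <- sim_expression_spec(n_genes = 200, planted_triggers = 1:8,
                            noise_cv = 0, seed = 42)
explants <- gen_expression_panel(spec)
espec <- spec; espec$conditions <- "embryo"; espec$seed <- 43L
embryo <- gen_expression_panel(espec)
run_screen(list(explants), embryo, screen_criteria())
#> Tiered trigger-gene candidate set
#>   tier 1 (all explant conditions): 8 genes
#>   tier 2 (+ embryo-confirmed):     8 genes
#>   tier 3 (+ Delta/TPM filters):    8 genes

## explant roundness: fit one sigmoid per genotype and compare
wt  <- gen_shape_series(sim_shape_spec(n_explants = 6, v50_hpf = 8.6,
                                       noise_sd = 0.03, seed = 1))
mut <- gen_shape_series(sim_shape_spec(n_explants = 6, v50_hpf = 9.4,
                                       slope = 0.35, noise_sd = 0.03, seed = 2))
fit_boltzmann(wt)
#> Boltzmann sigmoid fit (n = 222, df = 218)
#>   bottom 0.3048  top 0.9461  V50 8.5924 hpf  slope 0.4809 hpf
#>   SSE 0.215288
compare_fits_f_test(list(control = wt, mutant = mut))
#> Extra sum-of-squares F test (shared: bottom, top, v50, slope)
#>   F(4, 436) = 522.5, p = 8.771e-165
#>   SSE pooled 2.22051, SSE separate 0.3833

## in-vivo convergence onset from nuclear tracks
tracks <- gen_tracks(sim_track_spec(n_cells = 200, onset_hpf = 8, seed = 3))
kinetics_summary(tracks)
#> kinetics_summary: 200 tracks, 54 frames
#> onset 8.000 hpf (F = 6.11e+03, p = 1.78e-60)
#> median persistence 0.266, median straight-line speed 0.138 um/min
```

The screen recovers exactly the 8 planted trigger genes through all three
tiers; the two genotypes' roundness curves differ overwhelmingly in
timing/pace (the fitted V50s are ~8.6 vs ~9.4 hpf), and the hinge
changepoint recovers the planted 8.0-hpf convergence onset to the frame.

Real data enter through `read_expression_tsv()` (genes ×
`stage|condition|replicate` columns with a YAML stage→hpf sidecar),
`read_tracks_csv()` (generic or TrackMate-style headers, pixel→µm
scaling), `read_shape_series_csv()`, `read_mask_tiff()` /
`read_polygons_csv()`, and `read_fasta_aa()`. `run_pipeline()` (or the
`inst/scripts/cet.R` command-line wrapper) chains the stages from a YAML
config and writes tidy CSV/JSON outputs plus a run manifest.

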