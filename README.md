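# txrecorder

Analysis toolkit for **transcriptomic recording** experiments: a live cell's
ground-state transcriptome is profiled from a picolitre cytoplasmic biopsy,
the same cell is then stimulated, and its phenotype is followed by
time-lapse reporter imaging. The package turns the two measurements into an
unsupervised, genome-wide ranking of ground-state genes by their ability to
predict the cell's downstream response — the analysis that lets a
before-the-fact transcriptome explain response heterogeneity that end-point
single-cell RNA-seq cannot.

It is written for analysts of biopsy-based single-cell RNA-seq (e.g.
macrophage reporter lines stimulated with LPS after sampling), but every
stage is generic: shallow plate-based count matrices in, per-cell response
parameters and gene rankings out.

## The method

Each cell's reporter time course is reduced to two parameters by ordinary
least squares inside the window where the log trace is linear (default
3–7.5 h post-stimulation):

    ln I(t) = a + b t        a = basal expression, b = extent of response

after background subtraction and calibration-bead normalization. For every
candidate gene g (union of the top-500 highly variable genes of the recorder
and reference datasets, dispersion ≥ 0.1), a simple linear model

    y_i = β0 + β1 x_gi + ε     y ∈ {slope b, intercept a}

is fit on the cell's ground-state log-normalized expression x. Genes are
ranked by R²; significance comes from the overall-model F-test
(F = R²(n−2)/(1−R²)) and from a bootstrap empirical p-value (cells resampled
with replacement B times; two-sided sign stability of β1*, with the
+1/(B+1) correction), each Benjamini–Hochberg adjusted.

Supporting modules implement the surrounding procedure: strict QC filters
(> 1,000 detected genes, < 30 % mitochondrial counts, > 30 % uniquely
mapped reads), gene filtering (spike-ins, ribosomal genes, blacklist),
log normalization (scale factor 10,000), vst-style standardized variance
for HVG selection, binned-control cell-cycle module scores, feature-matched
down-sampling of a deeper dataset (detected-feature difference < 5, exact
library match), lineage-barcode consensus + Hamming matching, and
biopsy-volume formulas (area × 0.8 µm + 90 fl; sphere volume from three
averaged diameters). A seeded synthetic-data generator with planted
gene→phenotype effects makes the whole pipeline testable end to end.

## Worked example

```r
library(txrecorder)

cfg <- recorder_config(sim = sim_config(seed = 7), seed = 7, B = 1000)
res <- run_recorder_pipeline(cfg)

res$log$cells_kept      # 17 of 40 tracked cells pass QC
res$log$n_candidates    # 384 candidate genes after the dispersion filter

head(res$ranking$slope[, c("gene_id","beta1","r2","p_f","p_boot","fdr_f","rank")], 3)
#>           gene_id beta1    r2      p_f p_boot fdr_f rank
#> 1 PredSlopeStrong -0.70 0.557 0.000582  0.002 0.082    1
#> 2       Gene00437  1.52 0.555 0.000604  0.002 0.082    2
#> 3       Gene00440  1.23 0.551 0.000641  0.004 0.082    3

head(res$ranking$intercept[, c("gene_id","beta1","r2","p_f","rank")], 1)
#>         gene_id beta1    r2      p_f rank
#> 1 PredIntercept 0.516 0.743 8.78e-06    1
```

The synthetic cohort plants a strong negative predictor of the response
slope and a positive predictor of the intercept; both are recovered at rank
1 with the correct sign. `r2 = 0.557` means that gene's ground-state
expression alone explains ~56 % of the slope variance across the 17 cells;
`fdr_f` is the BH-adjusted F-test p-value over the candidate family, and
`p_boot` the bootstrap empirical p-value (B = 1000). With only 17 cells the
second- and third-ranked background genes reach similar R² by chance — the
reason rankings at this cohort size generate hypotheses rather than proofs,
and why the recovery tests run at n = 100.

Individual stages are plain functions (`compute_cell_qc()`,
`filter_cells()`, `lognormalize()`, `vst_standardized_variance()`,
`select_hvg()`, `fit_response_profiles()`, `rank_recorder_genes()`,
`score_cell_cycle()`, `downsample_match()`, `match_sequential()`, ...), each
usable on files produced by the previous stage; `run_recorder_pipeline()`
only chains them and writes a manifest of md5-hashed artifacts.

See `vignettes/transcriptomic-recording.Rmd` for the model, the synthetic
generator's design and its limits, and every numerical choice.

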