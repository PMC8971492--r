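# cytofuse

Batch integration of single-cell cytometry data — mass cytometry (CyTOF),
conventional and spectral flow cytometry, and CITE-seq antibody counts —
via per-cluster empirical Bayes adjustment.

## The problem and the method

Cytometry datasets acquired in separate batches (days, instruments,
reagent lots, technologies) carry systematic per-marker technical
distortions that prevent direct co-analysis. Because these distortions
differ between cell types, a single global adjustment per marker is not
enough. cytofuse:

1. normalizes expression per batch (Z-score, or average-tie ranks for
   cross-platform data) purely to make cells co-clusterable;
2. overclusters all cells with a self-organizing map (default 8×8 = 64
   nodes);
3. within each SOM node, fits the location/scale batch model on the
   original ArcSinh values,

   Y_ijg = α_g + Xβ_g + γ_ig + δ_ig ε_ijg,

   shrinking the per-batch per-marker effects γ̂_ig, δ̂²_ig toward
   across-marker priors (Normal for locations, Inverse-Gamma for scales,
   moment-matched), and removes them:
   Y\* = σ̂ (Z − γ\*)/√δ²\* + α̂ + Xβ̂;
4. caps each corrected marker to its input range.

An optional condition covariate (e.g., patient vs healthy donor) is
protected from removal; the only design requirement is that at least one
condition of every batch also occurs in some other batch. Correction
quality is quantified by the **EMD reduction** (share of cross-batch
earth mover's distance removed, per node × marker × batch pair; 1 = all)
and the **MAD score** (median absolute change in within-batch MAD; 0 =
biological variance untouched). A panel-merging module imputes
non-overlapping markers across two co-corrected panels by per-node
single-donor draws with kernel-bandwidth noise, preserving co-expression
and subtype frequencies.

## Worked example

```r
library(cytofuse)

# synthetic CyTOF-like data: 4 populations, 15 markers,
# 2 batches x 5,000 cells with location/scale batch distortions
sim <- simulate_dataset(simulation_config(cells_per_batch = 5000,
                                          seed = 42))
sim$dataset
#> <cyto_dataset> 10000 cells x 15 markers
#>   batches:  batch1, batch2
#>   samples:  2
#>   conditions: A
#>   cofactor: 5  derandomized: FALSE

res <- correct(sim$dataset,
               correction_config(norm_method = "scale", seed = 42))
ev <- evaluate_correction(sim$dataset, res$dataset, seed = 43)
cat("EMD reduction:", round(ev$emd$reduction, 3),
    "over", ev$emd$n_used, "records\n")
#> EMD reduction: 0.892 over 428 records
cat("MAD score:", round(ev$mad$score, 3), "\n")
#> MAD score: 0.011
```

The correction removed 89% of the cross-batch distributional distance
(computed over the 428 node × marker × batch-pair records whose EMD was
non-trivial before or after) while changing within-batch variability by
a median of only 0.011 ArcSinh units.

Real data enter through `read_fcs()` / `assemble_dataset()` (FCS
3.0/3.1 plus a sample sheet with `sample_id`, `batch_id`, `condition`)
or `read_dataset_csv()` for flat tables such as CITE-seq antibody
counts. A command-line interface with `correct`, `merge`, `evaluate`
and `simulate` subcommands is installed at `inst/cli/cytofuse`.

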