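# cghcnv

Consensus copy-number variant (CNV) discovery and cis-eQTL mapping from
high-density tiling array-CGH data.

## What this package does

Population-scale CNV studies on tiling aCGH arrays face three coupled
problems: per-probe log2-ratios carry systematic GC-content bias and
slowly varying "wave" artifacts along chromosomes; single segmentation
algorithms each have method-specific error modes; and linking CNVs to
gene expression requires careful multiple-testing control across
variants, genes and tissues. `cghcnv` implements the full chain:

1. **Normalization** — per array, the GC bias is removed by
   residualizing the quadratic model
   `log2(R_i) = α + β₁·GC_i + β₂·GC_i² + ε_i`, then chromosomal waves
   are removed by subtracting a locally linear LOESS fit of log2-ratio
   on probe position, `log2(R_i) = g(pos_i) + ε_i`. The LOESS window
   (in probes per local fit) is chosen by maximizing the median
   improvement of the per-array signal-to-noise ratio
   `SNR_i = |log2(R_i)| / σ_Ci` over a CNV test set, where `σ_Ci` is
   the standard deviation of all probes on probe *i*'s chromosome.
2. **Consensus CNV calling** — three algorithmically independent
   callers (`call_gada_like`, `call_cbs_like`, `call_window_like`; see
   the vignette for the algorithms) are filtered by segment z-score
   (|z| > 1.5) or carrier probability (≥ 0.8), and only CNVs called by
   at least two methods with a consistent state are kept.
3. **CNVR genotyping** — consensus CNVs are merged across individuals
   into CNV regions (CNVRs); complex loci, sex-chromosome loci and loci
   near large probe gaps are removed; each individual's genotype at a
   CNVR is its **median log2-ratio** over the CNVR probes (quantitative,
   never discretized). PCA (covariance convention) and hierarchical
   clustering on 1 − Pearson correlation summarize population structure.
4. **cis-eQTL mapping** — per tissue, each gene's expression is tested
   against all CNVRs within 1 Mb of its TSS (≥ 2 carriers) with
   `E_it = α + β₁·C_i + β₂·G_it + ε_it`, where `G_it` is the
   individual's score on the first expression principal component.
   Gene-level p-values come from local permutations (min-p across the
   gene's cis CNVRs), FDR control is Storey's q-value per tissue
   (significant at q < 0.10), and significant eQTL regions get a
   Bonferroni-corrected secondary association scan of neighbouring
   genes.
5. **Synthetic data** — `make_probe_set`, `simulate_cnv_truth`,
   `simulate_acgh` and `simulate_expression` generate the whole study
   (probe geometry, shared CNV landscapes, artifact-laden arrays,
   multi-tissue expression with planted effects) with exact ground
   truth, so every stage above is testable without real arrays.

## Worked example

```r
library(cghcnv)

probes <- make_probe_set(n_chrom = 2, chrom_length_bp = 8e6, seed = 1)
truth  <- simulate_cnv_truth(probes, individuals_per_pop = 5,
                             sharing = 0.8, recurrent_dup_prob = 0,
                             seed = 7)
arrays <- simulate_acgh(probes, truth, seed = 2)

norm    <- gc_residualize(arrays, probes)
head(norm$fits, 3)
#>   individual_id       alpha     beta1       beta2 residual_sd
#> 1      POP1_i01  0.01493148 0.4905210 -0.25312578   0.1898491
#> 2      POP1_i02 -0.04672918 0.5427764 -0.22107862   0.1878024
#> 3      POP1_i03  0.10970830 0.1734648 -0.00268356   0.1885338

calls  <- call_cnvs(norm$samples, probes)     # 3 callers + filters
cons   <- consensus_per_individual(calls)
cnvrs  <- filter_cnvrs(build_cnvrs(cons), probes)
G      <- quantitative_genotypes(cnvrs, norm$samples, probes)
population_structure(G, cnvrs, subset = "deletions_only")
#> cnv_structure (subset: deletions_only )
#>   PC1/PC2 variance explained: 41%, 24%
```

The `fits` table shows each array's estimated GC intercept and
coefficients (the simulation planted β₁ = 0.5, β₂ = −0.3; per-array
estimates scatter around those values because planted CNVs and waves
add structure), and the PCA summary shows the leading axes of the
deletion-genotype matrix, which separate the simulated populations.

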