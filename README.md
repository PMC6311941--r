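# kernelMDA

Multi-kernel link prediction for miRNA-disease associations.

Experimentally verified miRNA-disease associations form a sparse binary
matrix *Y* (miRNAs × diseases). kernelMDA ranks the unverified pairs by
combining several similarity kernels per entity side and smoothing the
association signal over the resulting similarity graphs. It is aimed at
computational biologists studying non-coding RNA involvement in disease,
and at methodologists who need a fully reproducible, synthetic-data-backed
reference implementation of this family of link predictors.

## The method

Four stages, each exposed as ordinary functions:

1. **Kernels.** Per side, up to three similarity kernels:
   Gaussian interaction profile
   K(i,j) = exp(−γ̂‖IP(i) − IP(j)‖²) over rows/columns of *Y*
   (`gip_kernel`); Needleman-Wunsch sequence similarity with cosine
   normalization (`sequence_kernel`); DAG-based disease semantic
   similarity with contribution factor Δ = 0.5 (`semantic_kernel`);
   best-match-average functional similarity over a log-likelihood-scored
   gene network (`functional_kernel`) or over a disease kernel
   (`bma_functional_similarity`).
2. **Fusion.** Simplex-constrained weights μ (μ ≥ 0, Σμ = 1) minimizing
   ‖Σ<sub>j</sub> μ<sub>j</sub>K<sub>j</sub> − T‖²<sub>F</sub> + λ‖μ‖²
   against the association Gram target (T = YYᵀ or YᵀY; λ = 200),
   solved exactly as a tiny quadratic program (`fkl_fit`,
   `combine_kernels`; `average_kernel` is the unweighted baseline).
3. **Sparsification.** Top-k neighbor reweighting: each entry gets weight
   1 / 0.5 / 0 according to its rank against the k-th order statistics of
   its row and column; the denoised kernel is the elementwise product
   (`sparsify_kernel`, k = 20 by default).
4. **Scoring.** Closed-form Laplacian regularized least squares from each
   subspace, F = K(K + βLK)⁻¹Y with the normalized Laplacian
   L = D^{−1/2}(D − K)D^{−1/2} and β = 2⁻⁵, averaged across the two views:
   F\* = (F_m + F_dᵀ)/2 (`laprls_solve`, `predict_associations`).

Cross-validation (10-fold/k-fold, global and per-disease leave-one-out)
with Mann-Whitney AUC and average-precision AUPR is built in
(`make_folds`, `evaluate_cv`), along with top-N candidate ranking
(`rank_candidates`) and seeded generators for every input format
(`generate_block_associations`, `generate_dag`, `generate_sequences`,
`generate_gene_network`, `write_synthetic_bundle`) so the whole pipeline
runs without any downloads.

## Worked example

The packaged benchmark is a seeded bipartite block model: 60 miRNAs × 40
diseases in 4 aligned blocks (association probability 0.8 within, 0.05
across), giving 573 known associations.

```r
library(kernelMDA)

Y <- recovery_fixture()                      # 60 x 40, sum(Y) == 573
plan <- make_folds(Y, "kfold", seed = 1, k_folds = 5)
evaluate_cv(Y, plan)
#> evaluation (kfold): AUC = 0.8494, AUPR = 0.3073 over 5 folds

fit <- predict_associations(Y,
                            list(gip_kernel(Y, "miRNA")),
                            list(gip_kernel(Y, "disease")))
fit
#> prediction scores: 60 miRNAs x 40 diseases (range [1.644e-12, 1.001])

rank_candidates(fit$F_star, Y, "dis_001", top_n = 5)
#>   rank   miRNA        score
#> 1    1 mir_009 0.0017960642
#> 2    2 mir_013 0.0016376820
#> 3    3 mir_049 0.0005644868
#> 4    4 mir_012 0.0005369183
#> 5    5 mir_052 0.0002505933
```

The AUC of 0.85 means a held-out true association outranks a random
unverified pair 85% of the time; the ceiling on this benchmark is ≈ 0.89
even for a scorer that knows the generating probabilities, because the
cross-block background associations are unlearnable by construction (see
the methods vignette). The ranking lists the strongest novel candidates
for one disease, with known associations excluded.

The same pipeline is available from a shell via the bundled entry point:

```sh
Rscript inst/cli/kernelmda synth    --out-dir data
Rscript inst/cli/kernelmda predict  --associations data/associations.tsv --out-dir run
Rscript inst/cli/kernelmda evaluate --associations data/associations.tsv \
    --scheme kfold --k-folds 5 --seed 1 --out-dir run
```

Subcommands: `synth`, `kernels`, `fuse`, `sparsify`, `predict`,
`evaluate`, `rank`. Options come from defaults < `--config` YAML < flags,
and the effective configuration is echoed next to every output.

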