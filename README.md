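# svperf

Benchmarking and performance prediction for **somatic structural variant
(SV) detection** from matched tumour/normal whole-genome sequencing.

Detecting somatic SVs — deletions, duplications, inversions, insertions
and translocations larger than 50 bp — is hard, and how well it works
depends on design variables a study can still change before sequencing:
tumour and matched-normal depth of coverage, the variant allele fraction
(VAF, effectively tumour purity), and how precisely breakpoints must be
recovered. `svperf` is a desk-scale toolkit for quantifying and
predicting that performance. It is aimed at bioinformaticians planning a
cancer WGS experiment, and at method developers who need a reproducible
SV benchmarking harness.

The package provides four layers:

1. **Benchmarking.** A call is a true positive iff (i) its reported SV
   type is acceptable for the truth record's type and (ii) *every*
   breakend of the event lies within a breakpoint-precision threshold
   *T* bp of the assigned truth breakends. From the per-call and
   per-truth labels it computes

       sensitivity = TP / (TP + FN),   precision = TP / (TP + FP),
       F1 = 2 * sens * prec / (sens + prec)

   overall and per SV type (with insertion precision pooled as generic
   `INS`, or `DUP/INS` for callers that cannot distinguish the two), and
   breakpoint-resolution profiles (cumulative TP count versus *T*).
2. **Callset algebra.** Pairwise union and intersection callsets under
   the *dominant caller* convention: two calls are the same when their
   types match and their breakpoints are within a 5 bp window; the
   dominant caller's coordinates are kept. Five callsets yield
   2 * 5 * 4 = 40 derived callsets.
3. **Synthetic design.** A miniature masked genome, truth-set
   generation with exact per-type counts, and a caller *emulator* with a
   known logistic detection surface
   `p = plogis(b0 + b1*log(VAF*Ct) + b2*VAF + b3/Cn)`, geometric
   breakpoint jitter, false positives and germline leak-through, so the
   entire pipeline runs end-to-end with no external data and the true
   performance surface is available in closed form.
4. **Performance-surface models.** Eight candidate generalized additive
   model forms — beta regression with logit link, tensor-product
   penalized smooths on thin-plate bases, REML smoothing selection —
   fitted to evaluation tables over the VAF x coverage x threshold
   grid; leave-one-level-out cross-validation with RMSE/MAE scoring; a
   simplest-among-tied selection rule; pruning of non-significant linear
   terms; predictions with delta-method standard errors and link-scale
   confidence intervals; and minimum-requirement search ("what is the
   least tumour coverage achieving 80 % sensitivity?").

## Worked example

```r
library(svperf)

# synthetic truth on the miniature masked genome
mask  <- miniature_genome()
truth <- simulate_truth_sets(truth_set_spec(60, 100), mask, seed = 17)

# benchmark an emulated caller over a small design grid
grid <- design_grid(normal_covs = c(20, 40, 60, 100),
                    tumour_covs = c(20, 40, 60, 80, 100),
                    vafs = c(0.05, 0.1, 0.2, 0.3, 0.5, 0.8, 1),
                    t_thresholds = c(2, 10, 50, 100, 200))
tab <- build_evaluation_table(grid, truth,
                              builtin_profiles()["manta_like"],
                              mask, seed = 18)

# model selection by leave-one-level-out cross-validation
cv  <- cross_validate(tab, "sensitivity", 1:8)
as.data.frame(cv)
#>   model_id       rmse        mae n_folds
#> 1        1 0.05787141 0.04771648      21
#> 2        2 0.05883389 0.04877921      21
#> 3        3 0.05605736 0.04640740      21
#> 4        4 0.05800892 0.04808276      21
#> 5        5 0.08055650 0.06277802      21
#> 6        6 0.06753578 0.05180640      21
#> 7        7 0.06688982 0.05350003      21
#> 8        8 0.10071847 0.07955126      21
select_model(cv)
#> [1] 3

fit <- fit_perf_model(tab, perf_model_spec(select_model(cv), "sensitivity"))
predict_performance(fit, data.frame(vaf = 0.4, tumour_cov = 60,
                                    normal_cov = 60, t_threshold = 100))
#>   vaf tumour_cov normal_cov t_threshold  estimate          se    lower
#> 1 0.4         60         60         100 0.8529843 0.004804439 0.843316
#>       upper extrapolated
#> 1 0.8621534        FALSE

minimum_requirement(fit, 0.8, "tumour_cov",
                    list(vaf = 0.4, normal_cov = 60, t_threshold = 200))
#> $value
#> [1] 45
#> $achievable
#> [1] TRUE
#> $predicted
#> [1] 0.8037316
```

Reading: candidate form 3 (smooths of VAF x tumour coverage, VAF x *T*
and tumour coverage x *T*, plus a linear normal-coverage term) wins the
cross-validation; at VAF 0.4 and 60x/60x coverage the fitted surface
predicts ~85 % sensitivity at *T* = 100 bp, and ~45x tumour coverage
suffices for 80 % sensitivity at *T* = 200 bp.

Real callsets enter through `read_callset()` (VCF 4.2 with
SVTYPE/END/MATEID/BND conventions, BEDPE, or a flat TSV truth dialect),
masks through `read_mask_bed()`, and full runs through `run_pipeline()`
or the thin command-line front end in `exec/svperf`.

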