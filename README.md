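# grnstep

Stepwise gene-regulatory-network inference from targeted qPCR expression
panels.

## What it is for

When genome-scale expression data are unavailable, a regulatory network
behind a two-level phenotype contrast — here, elongated (L) versus short
(S) regions of fish fins, sampled across three fins, three regeneration
stages and three biological replicates — can still be nominated stepwise:

1. pick candidates co-expressed with a few known seed genes from a
   co-expression neighbour database (supportability score ≥ 1);
2. quantify them by qPCR and convert Cq to relative quantities,
   RQ = E^−ΔΔCq with E = 2, normalized to two reference genes and one
   calibrator sample per fin;
3. keep genes whose paired t-tests on log2 RQ are significant in the same
   direction in ≥ 2 stages of ≥ 2 fins (the consistency screen);
4. group them into direction-coherent modules and extend each module with
   genes co-expressed with *all* its members; re-test;
5. discover promoter motifs shared by ≥ half of the higher-L genes
   (4 kb upstream windows), match them against a PWM library to nominate
   upstream transcription factors, screen the TFs' own expression, and
   scan higher-S promoters for shortlisted TF sites (repressor candidates);
6. assemble a Pearson correlation network (pooled two-tailed P < 0.01,
   with per-fin significance flags) and classify TF roles by edge signs.

All inputs can be simulated from a planted ground-truth network
(`generate_planted_network()`, `simulate_expression()`,
`expression_to_cq()`, `build_coexpression_db()`, `generate_pwm_library()`,
`generate_promoters()`), so every stage is testable by recovery. See the
methods vignette (`vignettes/grnstep-methods.Rmd`) for the model, the
power analysis behind the defaults, and known limitations.

## Worked example

```r
library(grnstep)

cfg <- simulation_config(seed = 42)
net <- generate_planted_network(n_tfs = 3, n_targets = 12, n_nulls = 20,
                                effect_size = 1, seed = 42)
net
#> planted_network: 3 TFs, 12 targets, 20 decoys, 12 edges (2 repressive)

plate <- expression_to_cq(simulate_expression(net, cfg), cfg)
db    <- build_coexpression_db(net, cfg)
res   <- run_stepwise(default_seeds(net), db, plate)
head(res$final, 8)
#>   gene direction round provenance
#> 1 tf01  higher-L     1       tg01
#> 2 tf02  higher-L     1       tg05
#> 3 tf03  higher-L     1       tg09
#> 4 tg01  higher-L     1       seed
#> 5 tg02  higher-L     1       tg01
#> 6 tg03  higher-L     1       tg01
#> 7 tg04  higher-L     1       tg01
#> 8 tg05  higher-L     1       seed

sum(net$target_ids %in% res$final$gene)   # 12 of 12 targets recovered
sum(net$null_ids %in% res$final$gene)     # 0 of 20 decoys admitted

rq    <- relative_quantities(plate, c("ref1", "ref2"))
edges <- build_network(pairwise_correlations(rq, res$final$gene))
nrow(edges)                               # 104 edges at pooled P < 0.01
head(edges[, c("gene_a", "gene_b", "r", "p", "sign")], 4)
#>   gene_a gene_b         r            p sign
#> 1   tf01   tf02 0.8194918 2.199242e-16    +
#> 2   tf01   tf03 0.8106175 8.274320e-16    +
#> 3   tf01   tg01 0.7668961 2.334820e-13    +
#> 4   tf01   tg02 0.8015533 2.986624e-15    +
```

The recovered set contains every planted target with its planted direction
(the two repressed targets come back `higher-S`), the TFs join through
their own co-expression, and the pooled network is dominated by the
planted positive module. `export_network()` writes SIF/GraphML.

## Command line

Each stage (or the whole chain) runs from the shell; outputs carry a
header with version, seed and config digest, and reruns are
byte-identical:

```sh
Rscript inst/scripts/grnstep.R run-all --seed 7 --outdir out/
Rscript inst/scripts/grnstep.R motifs  --config my_settings.json
```

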