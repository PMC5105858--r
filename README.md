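# sibsam — simulation-based inference for bulk segregant analysis

`sibsam` is an R package for designing and analysing **bulk segregant
analysis (BSA)** and **introgression mapping (IM)** experiments in
*Drosophila*-like systems: organisms where hundreds to thousands of
offspring can be bred and phenotyped, but not the millions that make
yeast-style BSA trivial. It is aimed at quantitative and evolutionary
geneticists mapping trait differences between parental strains from
pooled sequencing of phenotypic-extreme pools.

The package has two halves:

1. **Forward simulators** (compiled core) that track parental-strain
   ancestry tracts through recombination, breeding, X-linkage (no male
   recombination, hemizygous males), additive phenotypes, truncation
   selection, and binomial read sampling of the selected pools — for
   both the BSA design (interbreed, phenotype once, sequence both
   tails) and the IM design (select and backcross every second
   generation).
2. **A simulation-based inference pipeline** for BSA genome scans of
   the per-window ancestry difference
   *a<sub>d</sub>* = *p̂*<sub>high</sub> − *p̂*<sub>low</sub>:
   * smooth the scan with triangular weights and call **primary peaks**
     (maxima of runs with *a<sub>d</sub>* > 0 exceeding *a<sub>dt</sub>*)
     and **secondary peaks** (local maxima judged by their deviation
     *v* above the intervening valley, with a taller-first priority
     rule);
   * assign each primary a significance estimate from matched no-QTL
     null simulations via the enrichment *e* of peaks at least that
     tall, *P* = 1/*e*;
   * estimate each significant QTL's **strength**
     *s* = *f*/(1 + *f*) (per-allele effect *f*, residual noise
     anchored at the *f* = 1 locus) and its genomic confidence interval
     by approximate-Bayesian rejection sampling against single-QTL
     simulations with *s* ~ Uniform(0, 1), accepting replicates whose
     peak height matches the data within a tolerance;
   * test whether ragged peaks hide **multiple linked QTL**: secondary
     peaks get conditional P-values from the accepted replicates, and
     significant clusters are re-estimated with joint linked-QTL
     simulations whose cluster strength is Dirichlet-apportioned among
     members.

A design-evaluation module (`run_scenario()`) scores experimental
designs by the median cM distance between true QTL and the statistic
maximum in each QTL's analysis zone, reproducing the qualitative design
guidance: BSA beats IM, and more generations, individuals, crosses and
depth all sharpen localization.

## Worked example

Simulate a BSA experiment (600 individuals, 10 generations, 20% tails,
depth 500) with one QTL of strength 0.4 at 60 cM on chromosome 3, then
run the full inference pipeline on the resulting profile:

```r
library(sibsam)
set.seed(42)

gmap <- make_synthetic_map(n_windows = 200, seed = 7)
cfg  <- experiment_config("bsa", N = 600, G = 10, q = 0.2,
                          depth = 500, n_pheno = 600)
qtl  <- qtl_model(chrom = "3", cm = 60, f = strength_to_effect(0.4))
ad   <- run_bsa_experiment(gmap, cfg, qtl)$ad

res <- sibsam_run(ad, gmap, cfg, n_null = 200, n_single = 500,
                  n_cluster = 200)
res
#> SIBSAM result: 1 primary peak(s) called, 1 significant QTL reported
#>   primary chrom 3 window 511: P=0.005 s=0.43 (0.39-0.49)

res$report[, c("kind", "cm", "height", "p_value", "s_hat", "cm_lo", "cm_hi")]
#>      kind       cm  height p_value     s_hat   cm_lo    cm_hi
#> 1 primary 60.32784 0.69928   0.005 0.4294037 59.3353 61.21554
```

The pipeline recovered the simulated QTL: a significant primary peak
(*P* = 0.005 against 200 null scans) at 60.3 cM whose strength
posterior (median 0.43, 90% interval 0.39–0.49) brackets the simulated
strength 0.4, with a ~2 cM genomic confidence interval around the true
60 cM position. With real data you would start instead from
`load_window_table("windows.tsv")`, which reads the single input file
of window coordinates, *a<sub>d</sub>* values and informative depths.

The same operations are scriptable from a shell via the bundled CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/sibsam.R", package = "sibsam"))')
Rscript $CLI make-map  --windows 400 --seed 1 -o map.tsv
Rscript $CLI simulate  --mode bsa --map map.tsv --qtl "3:60:1" --seed 5 -o profile.tsv
Rscript $CLI peaks     --input profile.tsv -o peaks.tsv
Rscript $CLI run       --input profile.tsv --null-reps 500 -o report.tsv
```

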