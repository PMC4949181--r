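# refstab

Reference-gene selection and validation for qRT-PCR normalization.

Relative quantification by qRT-PCR stands or falls with the reference
("housekeeping") genes used to normalize it: a reference whose own
expression drifts across genotypes, tissues or stress conditions biases
every fold change computed against it. Members of the classic
housekeeping families (GAPDH, actin, ubiquitin, cyclophilin) are
isogenes that can differ sharply in stability, so the choice has to be
made empirically. `refstab` implements a complete selection-and-
validation workflow for that problem, aimed at plant stress
transcriptomics but agnostic to organism:

1. **Pre-screen** (`prescreen()`, `select_candidates()`) — candidate
   isogenes are screened from public expression matrices. For each
   dataset the coefficient of variation CV = sd/mean of each gene's
   linear intensities is ranked within its gene family; ranks are
   rescaled to a within-family percentile score
   *s* = 1 − (rank − 1)/(N − 1) and summed over datasets with weights
   equal to each dataset's sample variety (distinct
   genotype × stage × tissue × water-status tuples), giving the weighted
   rank score (WRS). The top isogene of each family sits at
   WRS% = 100.
2. **Stability ranking** (`enumerate_and_rank()`) — candidates measured
   by qRT-PCR are scored with the pairwise ΔCt approach: a reference
   set's per-sample pseudo-Ct (arithmetic mean of member Cts, i.e. the
   geometric mean on the expression scale) is differenced against every
   non-member candidate, and the mean over partners of SD(ΔCt) is the
   stability score. All single genes and 2–4-gene combinations are
   enumerated exhaustively and ranked within their size class and
   overall. A single-pass geNorm M value (`genorm_m()`) is provided as
   an independent comparator.
3. **Quantification** (`ddct_quantify()`) — target genes are quantified
   against a chosen reference set by the ΔΔCt method: fold change
   = 2^(−ΔΔCt) with ΔΔCt = ΔCt − mean(ΔCt over calibrator samples).
4. **Validation** (`compare_references()`) — qRT-PCR log2 fold changes
   are paired with an independent platform's values per target gene;
   after an explicit outlier policy (flag the k largest residuals, a
   residual-SD cut, or user-supplied ids) each reference set is scored
   by the residual variance RV = Σ(y − x)²/(n − 1) around the identity
   line y = x, lower RV meaning better cross-platform concordance.

A synthetic-data module (`simulation_config()`,
`simulate_ct_table()`, `simulate_expression_matrix()`,
`simulate_validation_scenario()`) generates all three kinds of input
with known ground truth — per-sample loading offsets, gene-specific
condition effects and noise — so that every stage of the pipeline can
be exercised and checked for recovery without external data.

## Worked example

```r
library(refstab)

# ten candidates, one planted quiet gene, 12 samples, per-sample loading
cfg  <- stability_scenario_config(seed = 1)
sim  <- simulate_ct_table(cfg)
grid <- collapse_replicates(sim$ct)

rk <- enumerate_and_rank(grid, rownames(grid), max_size = 4)
summary(rk)
```

```
385 reference sets over 10 candidates; best per class:
  class             set mean_sd rank_in_total
1     1             G01   0.898            96
2     2         G05/G06   0.899            98
3     3     G07/G08/G09   0.776             4
4     4 G02/G07/G08/G09   0.721             1
```

385 reference sets are scored (10 singles + 45 pairs + 120 triples +
210 quadruples). The quiet gene `G01` — simulated with σ_ε = 0.05 and
no condition response — is the best single reference; the best mean
ΔCt SD (in cycles) shrinks as more genes are averaged into the
reference. Writing the table keeps the top 10 per class:

```r
write_ranking(rk, "ranking.tsv", top_k = 10)
m <- genorm_m(grid, rownames(grid))
names(which.min(m))        # "G01" — geNorm agrees with the delta-Ct approach
```

The same run from the shell:

```sh
Rscript inst/cli/refstab simulate --seed 1 --out-dir work
cut -f1 work/ct_truth.tsv | tail -n +2 > work/candidates.txt
Rscript inst/cli/refstab rank --ct work/ct.tsv --candidates work/candidates.txt \
    --max-size 4 --top-k 10 --out work/ranking.tsv
```

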