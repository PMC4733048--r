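# pantx

Presence/absence variation (PAV) analysis for pan-transcriptomes of
diverse inbred panels.

In a diverse panel, many genes are expressed in some lines and silent in
others (*expression* presence/absence variation, ePAV), and a subset of
those are physically missing from some genomes (*genomic* PAV).  `pantx`
implements the complete analysis pipeline around these observations:

- **ePAV calling** (`call_epav()`) — partitions genes by expression
  frequency using 5% line-count gates (19 of 368 lines; 2 of 38) and
  ternary-encodes each candidate per line with distribution-based
  trimming: nonzero values are histogrammed into 10 equal-width bins and
  values in the lowest bin, or in bins occupied fewer than 3 times, are
  masked to NA.
- **Genomic PAV prediction** (`predict_pav()`) — flags a (gene, line)
  pair as a potential deletion when every SNP-array marker in the gene
  body ± 1 kb is a missing call, and `concordance()` decomposes the
  agreement between expression-level and genomic-level calls.
- **Presence/absence GWAS** (`run_gwas()`) — ordinary least squares of
  each trait on each gene's ternary state plus principal-component
  covariates (`compute_pcs()`), with a scan-wide `1/n_markers`
  significance threshold (4.25E-4 at 2,355 markers).
- **Novel-sequence placement** (`place_novel()`) — composite LD (squared
  Pearson correlation of unphased dosages) between the SNPs of an
  off-reference sequence and positioned reference SNPs; the sequence is
  assigned to the gene containing or nearest the best SNP when r² > 0.1.
- **Pan-transcriptome size** (`rarefy()`, `fit_asymptote()`,
  `pan_summary()`) — rarefaction in 20-line steps over 10 repetitions
  and an exponential saturation fit `y = A − B·exp(−n/C)` for the
  asymptotic pan size.
- **Heterosis vs complementation** (`heterosis_correlation()`) —
  regresses mid-parent heterosis of F1 hybrids on the number of genes
  present in exactly one parent, with a permutation test.
- **Synthetic panels with ground truth** (`simulate_panel()`) — a seeded
  generator producing a structured panel (subpopulations, AR(1) LD,
  trans-regulated and deletion-driven ePAVs, anchored novel sequences,
  planted trait effects, tester-cross hybrids) against which every step
  of the pipeline can be scored.

## Worked example

```r
library(pantx)

sim <- simulate_panel(sim_config(seed = 1))
sim
#> synthetic panel: 300 lines, 530 genes ( 300 core / 200 ePAV / 30 novel ), 4000 SNPs

## 1. call ePAVs from the expression matrix
calls <- call_epav(sim$expr)
calls
#> ePAV calls over 530 genes, 300 lines
#>   rare: 0  candidates: 230  core: 300  retained ePAV: 224

## 2. predict genomic PAV from array missingness, compare the two calls
pp <- predict_pav(sim$geno, sim$map, sim$genes)
pp
#> genomic PAV prediction: 500 genes assessed, 2 candidate PAV (>= 15 potential-PAV lines)
common <- intersect(pp$candidate, calls$retained)
concordance(calls$pav[common, , drop = FALSE], pp$pav[common, , drop = FALSE])
#> concordance over 358 cells: 97.5% consistent
#>   inconsistencies: 100.0% genome-present/not-expressed, 0.0% expressed/genome-absent

## 3. presence/absence GWAS with PC structure correction
pcs <- compute_pcs(sim$geno, 3)
gw <- run_gwas(calls$pav, sim$traits, pcs)
gw
#> ePAV-GWAS: 224 markers, 1344 tests, threshold p < 0.00446
#>   significant: 24 of 1344 tests (1.79%); 0 skipped

## 4. place novel sequences by composite LD
pl <- place_novel_all(sim$novel_geno, sim$geno, sim$map, sim$genes,
                      groups = sim$novel_groups)
head(pl, 3)
#>   novel_id target_gene_id chromosome position   best_r2 n_pairs_tested placed
#> 1  novel01          g0268       chr3   539000 0.9729241          12000   TRUE
#> 2  novel02          g0171       chr2   561000 0.9811498           8000   TRUE
#> 3  novel03          g0178       chr2   619000 0.9268071           4000   TRUE

## 5. pan-transcriptome size by rarefaction
curve <- rarefy((sim$expr > 0) + 0L, seed = 1)
fit_asymptote(curve)
#> saturation fit: y = 530 - 0 exp(-n/1); asymptote A = 530 (rss 0, converged)
pan_summary(22043, 13382, 28000)     # the published composition
#> pan-transcriptome size: 22043 core + 13382 dispensable + 28000 novel = 63425 (~63000)

## 6. heterosis vs parental complementation
hc <- heterosis_correlation(sim$hybrids, sim$traits, calls$pav,
                            n_perm = 199, seed = 1)
hc
#> complementation vs mid-parent heterosis (relative):
#>  trait_name   n        r2     slope degenerate perm_p
#>         KWd 100 0.3118364 0.8223987      FALSE  0.005
#>          KT 100 0.3647484 0.8240520      FALSE  0.005
#>         RPE 100 0.3300411 0.8614876      FALSE  0.005
#>          EL 100 0.3603556 0.9065992      FALSE  0.005
#>          CW 100 0.3567136 0.8832769      FALSE  0.005
#>         KPE 100 0.3202822 0.8210605      FALSE  0.005
```

All inputs and outputs have plain TSV/BED readers and writers
(`read_expression_matrix()`, `read_genotypes()`, `read_gene_bed()`,
`read_trait_table()`, `read_hybrid_table()`, `read_ternary_matrix()` and
their `write_*` counterparts); `write_sim_panel()` dumps a full panel to
a directory of such files.

## Command line

`exec/pantx` wraps the same functions:

```sh
pantx simulate    --seed 1 --outdir panel/
pantx call-epav   --expr panel/expression.tsv --out panel/epav.tsv
pantx predict-pav --geno panel/genotypes.tsv --map panel/markers.tsv \
                  --genes panel/genes.bed --out panel/pavpred.tsv
pantx concordance --a panel/epav.tsv --b panel/pavpred.tsv
pantx gwas        --pav panel/epav.tsv --traits panel/traits.tsv \
                  --geno panel/genotypes.tsv --map panel/markers.tsv \
                  --out panel/gwas.tsv
pantx ld-map      --novel-geno panel/novel_genotypes.tsv \
                  --novel-map panel/novel_markers.tsv \
                  --ref-geno panel/genotypes.tsv --map panel/markers.tsv \
                  --genes panel/genes.bed --out panel/ld.tsv
pantx pan-curve   --presence panel/epav.tsv --seed 1 --out panel/curve.tsv
pantx heterosis   --hybrids panel/hybrids.tsv --parents panel/traits.tsv \
                  --pav panel/epav.tsv --perm 199 --seed 1 --out panel/het.tsv
```

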