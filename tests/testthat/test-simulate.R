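# Synthetic panel generator: determinism and structural invariants.

test_that("simulation is bytewise deterministic per seed", {
  s1 <- simulate_panel(sim_config(seed = 123))
  s2 <- simulate_panel(sim_config(seed = 123))
  expect_identical(s1, s2)
  s3 <- simulate_panel(sim_config(seed = 124))
  expect_false(identical(s1$expr, s3$expr))
})

test_that("sim_config validates its arguments", {
  expect_error(sim_config(n_hybrids = 300), "tester line")
  expect_error(sim_config(ld_decay = 1), "ld_decay")
})

test_that("sim_config rejects more causal genes than ePAV genes", {
  expect_error(sim_config(
    trait_specs = list(list(trait_name = "T", n_causal_epav = 999L,
                            effect_size = 1, noise_sd = 1))),
    "more causal genes")
})

test_that("the default panel satisfies its structural invariants", {
  sim <- default_panel(1L)
  cf <- sim$config
  tr <- sim$truth

  # dimensions and identifiers
  expect_identical(dim(sim$expr),
                   c(cf$n_core_genes + cf$n_epav_genes + cf$n_novel_genes,
                     cf$n_lines))
  expect_identical(dim(sim$geno), c(cf$n_snps, cf$n_lines))
  expect_identical(colnames(sim$expr), colnames(sim$geno))
  expect_identical(nrow(sim$hybrids),
                   cf$n_hybrids * length(unique(sim$traits$trait_name)))

  # expression is nonnegative with no missing values
  expect_false(anyNA(sim$expr))
  expect_true(all(sim$expr >= 0))

  # genotype dosages are in {0, 1, 2, NA}
  expect_true(all(sim$geno %in% c(0L, 1L, 2L, NA)))

  # truth states cover exactly the non-core genes
  noncore <- names(tr$gene_class)[tr$gene_class != "core"]
  expect_setequal(rownames(tr$states_true), noncore)

  # truth expression respects the planted states: absent -> exactly zero
  for (g in setdiff(noncore, names(tr$genomic_absent))) {
    absent <- colnames(sim$expr)[tr$states_true[g, ] == 0L]
    expect_true(all(sim$expr[g, absent] == 0))
  }

  # core genes stay above the upper presence gate
  gates <- presence_gates(cf$n_lines)
  core <- names(tr$gene_class)[tr$gene_class == "core"]
  expect_true(all(rowSums(sim$expr[core, ] > 0) > gates[["upper"]]))

  # pan size is the number of genes expressed anywhere
  expect_identical(tr$pan_size, sum(rowSums(sim$expr > 0) >= 1L))
})

test_that("genomic-PAV deletions zero expression and blank the SNP window", {
  sim <- default_panel(1L)
  tr <- sim$truth
  expect_gt(length(tr$genomic_absent), 0)
  for (g in names(tr$genomic_absent)) {
    absent <- tr$genomic_absent[[g]]
    expect_true(all(sim$expr[g, absent] == 0))
    gi <- match(g, sim$genes$gene_id)
    w <- sim$map$chromosome == sim$genes$chromosome[gi] &
      sim$map$position >= sim$genes$start[gi] - 1000L &
      sim$map$position <= sim$genes$end[gi] + 1000L
    expect_gte(sum(w), 2L)
    expect_true(all(is.na(sim$geno[w, absent])))
  }
})

test_that("regulator SNPs live on another chromosome than their gene", {
  sim <- default_panel(1L)
  tr <- sim$truth
  gene_chr <- setNames(sim$genes$chromosome, sim$genes$gene_id)
  reg_chr <- sim$map$chromosome[match(tr$regulators, sim$map$marker_id)]
  expect_true(all(reg_chr != gene_chr[names(tr$regulators)]))
})

test_that("hybrid heterosis tracks the planted complementation when noiseless", {
  cf <- sim_config(
    seed = 9L, n_lines = 60L, n_core_genes = 40L, n_epav_genes = 60L,
    n_novel_genes = 5L, n_snps = 1500L, n_hybrids = 30L,
    trait_specs = list(list(trait_name = "Y", n_causal_epav = 2L,
                            effect_size = 1, noise_sd = 1e-9)),
    heterosis_effect = 0.5)
  sim <- simulate_panel(cf)
  h <- sim$hybrids
  tv <- setNames(sim$traits$value,
                 paste(sim$traits$line_id, sim$traits$trait_name))
  mp <- (tv[paste(h$parent1_id, h$trait_name)] +
           tv[paste(h$parent2_id, h$trait_name)]) / 2
  mph <- h$f1_value - mp
  expect_equal(unname(mph), 0.5 * unname(sim$truth$complementary_true),
               tolerance = 1e-6)
})

test_that("with heterosis_effect = 0 the measured slope is null", {
  cf <- sim_config(seed = 31L, heterosis_effect = 0)
  sim <- simulate_panel(cf)
  calls <- call_epav(sim$expr)
  hc <- heterosis_correlation(sim$hybrids, sim$traits, calls$pav,
                              n_perm = 199L, seed = 31L)
  expect_true(all(hc$per_trait$perm_p > 0.05))
  expect_lt(max(hc$per_trait$r2), 0.1)
})

test_that("write_sim_panel round-trips through the package readers", {
  sim <- simulate_panel(sim_config(
    seed = 2L, n_lines = 40L, n_core_genes = 30L, n_epav_genes = 30L,
    n_novel_genes = 4L, n_snps = 800L, n_hybrids = 10L))
  d <- withr::local_tempdir()
  write_sim_panel(sim, d)
  expect_identical(read_expression_matrix(file.path(d, "expression.tsv")),
                   sim$expr)
  rt <- read_genotypes(file.path(d, "genotypes.tsv"),
                       file.path(d, "markers.tsv"))
  expect_identical(rt$geno, sim$geno)
  expect_identical(rt$map$marker_id, sim$map$marker_id)
  genes <- read_gene_bed(file.path(d, "genes.bed"))
  expect_identical(genes$start, sim$genes$start)
  expect_identical(genes$end, sim$genes$end)
  expect_identical(read_trait_table(file.path(d, "traits.tsv")), sim$traits)
  expect_identical(read_hybrid_table(file.path(d, "hybrids.tsv")),
                   sim$hybrids)
})
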