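# Complementation counts and mid-parent heterosis regression.

test_that("complementary_count matches hand-enumerated toys", {
  pav <- rbind(g1 = c(1L, 0L), g2 = c(0L, 1L), g3 = c(1L, 1L),
               g4 = c(0L, 0L), g5 = c(NA_integer_, 1L))
  colnames(pav) <- c("A", "B")
  r <- complementary_count(pav, "A", "B")
  expect_identical(r$count, 2L)        # g1, g2; g5 excluded via NA
  expect_identical(r$n_compared, 4L)
  # symmetric in the parents
  expect_identical(complementary_count(pav, "B", "A")$count, r$count)
  expect_error(complementary_count(pav, "A", "C"), "'C' absent")
})

test_that("complementary_count matches exhaustive enumeration", {
  for (s in 1:20) {
    pav <- toy_ternary(15, 6, seed = 40 + s, na_frac = 0.2)
    for (pair in list(c(1, 2), c(3, 6))) {
      p1 <- colnames(pav)[pair[1]]; p2 <- colnames(pav)[pair[2]]
      cnt <- 0L; nc <- 0L
      for (i in seq_len(nrow(pav))) {
        a <- pav[i, p1]; b <- pav[i, p2]
        if (is.na(a) || is.na(b)) next
        nc <- nc + 1L
        if (a != b) cnt <- cnt + 1L
      }
      r <- complementary_count(pav, p1, p2)
      expect_identical(r$count, cnt)
      expect_identical(r$n_compared, nc)
    }
  }
})

test_that("mid_parent_heterosis matches hand arithmetic", {
  r <- mid_parent_heterosis(12, 8, 12)
  expect_equal(r$mph_abs, 2)
  expect_equal(r$mph_rel, 20)
  expect_true(is.na(mid_parent_heterosis(3, 1, -1)$mph_rel))  # mid-parent 0
  expect_equal(mid_parent_heterosis(3, 1, -1)$mph_abs, 3)
  expect_error(mid_parent_heterosis(NA, 1, 2), "must be present")
})

het_fixture <- function(slope_per_gene = 2, noise = 0, seed = 50,
                        n_hyb = 30, n_genes = 40) {
  set.seed(seed)
  lines <- c(sprintf("P%02d", seq_len(n_hyb)), "T")
  pav <- matrix(rbinom(n_genes * (n_hyb + 1), 1, 0.5), n_genes, n_hyb + 1,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)), lines))
  cc <- vapply(seq_len(n_hyb), function(i)
    sum(pav[, i] != pav[, "T"]), numeric(1))
  parents <- data.frame(line_id = lines, trait_name = "Y",
                        value = 10, stringsAsFactors = FALSE)
  hybrids <- data.frame(
    hybrid_id = paste0("h", seq_len(n_hyb)),
    parent1_id = lines[seq_len(n_hyb)], parent2_id = "T", trait_name = "Y",
    f1_value = 10 + slope_per_gene * cc + rnorm(n_hyb, 0, noise),
    stringsAsFactors = FALSE)
  list(pav = pav, parents = parents, hybrids = hybrids, cc = cc)
}

test_that("a noiseless linear complementation effect gives r2 = 1 and the exact slope", {
  fx <- het_fixture(slope_per_gene = 2, noise = 0)
  hc <- heterosis_correlation(fx$hybrids, fx$parents, fx$pav,
                              measure = "absolute")
  expect_equal(hc$per_trait$r2, 1, tolerance = 1e-12)
  expect_equal(hc$per_trait$slope, 2, tolerance = 1e-10)
  # relative measure rescales by the constant mid-parent 10: slope x 10
  hr <- heterosis_correlation(fx$hybrids, fx$parents, fx$pav)
  expect_equal(hr$per_trait$slope, 20, tolerance = 1e-10)
  expect_equal(hr$per_trait$r2, 1, tolerance = 1e-12)
})

test_that("heterosis_correlation matches a direct computation with noise", {
  fx <- het_fixture(slope_per_gene = 0.5, noise = 3, seed = 51)
  hc <- heterosis_correlation(fx$hybrids, fx$parents, fx$pav,
                              measure = "absolute")
  mph <- fx$hybrids$f1_value - 10
  expect_equal(hc$per_trait$r2, cor(fx$cc, mph)^2, tolerance = 1e-12)
  expect_equal(hc$per_trait$slope, cov(fx$cc, mph) / var(fx$cc),
               tolerance = 1e-12)
  expect_identical(hc$per_trait$n, length(fx$cc))
  # binned means stay ordered in x and cover all hybrids
  b <- hc$bins[["Y"]]
  expect_true(all(diff(b$mean_count) > 0))
  expect_identical(sum(b$n), length(fx$cc))
})

test_that("permutation p-values are small for real effects and honest under the null", {
  fx <- het_fixture(slope_per_gene = 1, noise = 1, seed = 52)
  hc <- heterosis_correlation(fx$hybrids, fx$parents, fx$pav,
                              measure = "absolute", n_perm = 199, seed = 1)
  expect_lte(hc$per_trait$perm_p, 0.01)
  null <- fx
  null$hybrids$f1_value <- 10 + rnorm(nrow(null$hybrids), 0, 1)
  hn <- heterosis_correlation(null$hybrids, null$parents, null$pav,
                              measure = "absolute", n_perm = 199, seed = 1)
  expect_gt(hn$per_trait$perm_p, 0.05)
})

test_that("degenerate and underpowered traits are handled explicitly", {
  fx <- het_fixture()
  # constant complementary counts: degenerate, r2 0
  pav1 <- fx$pav; pav1[] <- 1L
  hc <- heterosis_correlation(fx$hybrids, fx$parents, pav1,
                              measure = "absolute")
  expect_true(hc$per_trait$degenerate)
  expect_equal(hc$per_trait$r2, 0)
  # too few hybrids: the trait is skipped with a reason, the call errors
  few <- fx$hybrids[1:4, ]
  expect_error(heterosis_correlation(few, fx$parents, fx$pav),
               "no trait with enough usable hybrids")
})

test_that("gene_set restricts the complementation universe", {
  fx <- het_fixture(seed = 53)
  sub <- rownames(fx$pav)[1:10]
  hc <- heterosis_correlation(fx$hybrids, fx$parents, fx$pav,
                              gene_set = sub, measure = "absolute")
  cc_sub <- vapply(seq_len(ncol(fx$pav) - 1), function(i)
    sum(fx$pav[sub, i] != fx$pav[sub, "T"]), numeric(1))
  expect_equal(sort(unique(hc$hybrid_data[["Y"]]$complementary_count)),
               sort(unique(cc_sub)))
})
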