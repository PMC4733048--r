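# Genomic PAV prediction from array missingness, and concordance.

toy_genome <- function() {
  # two genes on chr1 (3 markers each in body +/- 1kb), one 1-marker gene
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chromosome = c("chr1", "chr1", "chr2"),
    start = c(2000L, 20000L, 1000L), end = c(4000L, 22000L, 2000L),
    stringsAsFactors = FALSE)
  map <- data.frame(
    marker_id = paste0("s", 1:7),
    chromosome = c(rep("chr1", 6), "chr2"),
    position = c(1500L, 3000L, 4500L, 19500L, 21000L, 22500L, 1500L),
    stringsAsFactors = FALSE)
  list(genes = genes, map = map)
}

test_that("predict_pav flags lines whose whole gene window is missing", {
  tg <- toy_genome()
  n <- 40
  geno <- matrix(1L, nrow = 7, ncol = n,
                 dimnames = list(tg$map$marker_id, sprintf("L%02d", 1:n)))
  # gene gA (markers s1-s3) fully missing in lines 1-3; partial miss in line 4
  geno[1:3, 1:3] <- NA_integer_
  geno[1, 4] <- NA_integer_
  pp <- predict_pav(geno, tg$map, tg$genes)
  expect_identical(pp$threshold, 2L)          # ceiling(0.05 * 40)
  expect_identical(pp$candidate, "gA")
  expect_identical(unname(pp$pav["gA", 1:4]), c(0L, 0L, 0L, 1L))
  # the single-marker gene gC is below min_snps and never assessed
  expect_identical(unname(pp$marker_counts["gC"]), 1L)
  expect_false("gC" %in% pp$candidate)
})

test_that("predict_pav threshold reproduces both array regimes", {
  tg <- toy_genome()
  for (n in c(368L, 38L)) {
    geno <- matrix(1L, nrow = 7, ncol = n,
                   dimnames = list(tg$map$marker_id, sprintf("L%03d", 1:n)))
    pp <- predict_pav(geno, tg$map, tg$genes)
    expect_identical(pp$threshold, as.integer(ceiling(0.05 * n)))
  }
})

test_that("predict_pav warns about genes on chromosomes absent from the map", {
  tg <- toy_genome()
  tg$genes$chromosome[3] <- "chrX"
  geno <- matrix(1L, nrow = 7, ncol = 40,
                 dimnames = list(tg$map$marker_id, sprintf("L%02d", 1:40)))
  expect_warning(pp <- predict_pav(geno, tg$map, tg$genes), "gC")
  expect_false("gC" %in% names(pp$marker_counts))
})

test_that("window marker counts are non-decreasing in the flank", {
  tg <- toy_genome()
  geno <- matrix(1L, nrow = 7, ncol = 40,
                 dimnames = list(tg$map$marker_id, sprintf("L%02d", 1:40)))
  c1 <- predict_pav(geno, tg$map, tg$genes, pav_params(flank = 0L))$marker_counts
  c2 <- predict_pav(geno, tg$map, tg$genes, pav_params(flank = 1000L))$marker_counts
  c3 <- predict_pav(geno, tg$map, tg$genes, pav_params(flank = 5000L))$marker_counts
  expect_true(all(c2 >= c1) && all(c3 >= c2))
})

test_that("concordance matches a hand-computed 2x2 example", {
  e <- matrix(c(1L, 0L, 0L, 1L), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  g <- matrix(c(1L, 1L, 0L, 0L), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  r <- concordance(e, g)
  expect_identical(r$n_compared, 4L)
  expect_equal(r$consistency, 0.5)
  # the two inconsistent cells split evenly between the two directions
  expect_equal(r$inconsistent_present_genome_absent_expr, 0.5)
  expect_equal(r$inconsistent_expr_without_genome, 0.5)
})

test_that("concordance matches exhaustive enumeration on random ternary matrices", {
  for (s in 1:20) {
    e <- toy_ternary(8, 12, seed = s)
    g <- toy_ternary(8, 12, seed = s + 100)
    r <- concordance(e, g)
    n <- 0L; eq <- 0L; gp <- 0L; ep <- 0L
    for (i in 1:8) for (j in 1:12) {
      if (is.na(e[i, j]) || is.na(g[i, j])) next
      n <- n + 1L
      if (e[i, j] == g[i, j]) eq <- eq + 1L
      else if (g[i, j] == 1L) gp <- gp + 1L
      else ep <- ep + 1L
    }
    expect_identical(r$n_compared, n)
    expect_equal(r$consistency, eq / n)
    if (gp + ep > 0) {
      expect_equal(r$inconsistent_present_genome_absent_expr, gp / (gp + ep))
      expect_equal(r$inconsistent_expr_without_genome, ep / (gp + ep))
    }
  }
})

test_that("concordance aligns matrices by shared dimnames", {
  e <- toy_ternary(6, 8, seed = 2)
  g <- toy_ternary(6, 8, seed = 3)
  r <- concordance(e, g)
  perm <- concordance(e[sample(6), sample(8)], g)
  expect_equal(perm$consistency, r$consistency)
  expect_error(concordance(e, toy_ternary(3, 3, seed = 1,
                                          genes = paste0("x", 1:3),
                                          lines = paste0("y", 1:3))),
               "share no")
})
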