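# Parental presence/absence complementation versus mid-parent heterosis.

#' Count genes complementary between two parents
#'
#' A gene is complementary when it is present in exactly one of the two
#' parents.  Genes with an NA state in either parent are excluded from
#' both the count and the comparison denominator.
#'
#' @param pav Ternary matrix (genes x lines).
#' @param p1,p2 Parent line ids (columns of `pav`).
#' @return A list `count`, `n_compared`.
#' @export
complementary_count <- function(pav, p1, p2) {
  for (p in c(p1, p2))
    if (!p %in% colnames(pav))
      stop("parent '", p, "' absent from the presence/absence matrix")
  a <- pav[, p1]; b <- pav[, p2]
  use <- !is.na(a) & !is.na(b)
  list(count = sum(a[use] != b[use]), n_compared = sum(use))
}

#' Mid-parent heterosis of one hybrid
#'
#' @param f1 F1 trait value.
#' @param p1,p2 Parental trait values.
#' @return A list `mph_abs` (F1 minus mid-parent, trait units) and
#'   `mph_rel` (percent of mid-parent; NA when the mid-parent value is 0).
#' @export
mid_parent_heterosis <- function(f1, p1, p2) {
  if (anyNA(c(f1, p1, p2))) stop("all three trait values must be present")
  mp <- (p1 + p2) / 2
  mph_abs <- f1 - mp
  list(mph_abs = mph_abs,
       mph_rel = if (mp == 0) NA_real_ else 100 * mph_abs / mp)
}

#' Correlate complementation with mid-parent heterosis
#'
#' Per trait, regresses mid-parent heterosis (relative by default) on the
#' number of complementary genes across hybrids, reporting Pearson r2,
#' the regression slope, and mean heterosis within quantile bins of the
#' complementary count.  An optional permutation test shuffles heterosis
#' values across hybrids.
#'
#' @param hybrids Hybrid table (`hybrid_id`, `parent1_id`, `parent2_id`,
#'   `trait_name`, `f1_value`).
#' @param parents Trait table for the parental lines.
#' @param pav Ternary matrix of the gene set used for complementation
#'   (e.g. novel genes or called ePAVs).
#' @param gene_set Optional gene ids restricting `pav`.
#' @param measure `"relative"` (percent mid-parent heterosis, default) or
#'   `"absolute"`.
#' @param n_bins Quantile bins for the trend means (default 5).
#' @param min_hybrids Minimum usable hybrids per trait (default 10);
#'   traits below it are skipped with a reason.
#' @param n_perm Permutations for the null distribution of r2 (default 0
#'   = none).
#' @param seed Optional RNG seed for the permutations.
#' @return A list of class `heterosis_cor`: `per_trait` (data.frame
#'   `trait_name`, `n`, `r2`, `slope`, `degenerate`, `perm_p`), `bins`
#'   (per-trait data.frames of binned means), `hybrid_data` (per-trait
#'   hybrid-level values), `skipped`.
#' @export
heterosis_correlation <- function(hybrids, parents, pav, gene_set = NULL,
                                  measure = c("relative", "absolute"),
                                  n_bins = 5L, min_hybrids = 10L,
                                  n_perm = 0L, seed = NULL) {
  measure <- match.arg(measure)
  if (!is.null(gene_set))
    pav <- pav[intersect(gene_set, rownames(pav)), , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)

  # complementary counts are a property of the parent pair, not the trait
  pairs <- unique(hybrids[, c("parent1_id", "parent2_id")])
  pair_key <- paste(pairs$parent1_id, pairs$parent2_id, sep = "\r")
  cc <- vapply(seq_len(nrow(pairs)), function(i)
    complementary_count(pav, pairs$parent1_id[i], pairs$parent2_id[i])$count,
    numeric(1L))
  names(cc) <- pair_key

  pt_key <- paste(parents$line_id, parents$trait_name, sep = "\r")
  pval <- stats::setNames(parents$value, pt_key)

  res <- list(); bins <- list(); hdata <- list(); skipped <- list()
  for (tn in unique(hybrids$trait_name)) {
    h <- hybrids[hybrids$trait_name == tn, , drop = FALSE]
    p1v <- pval[paste(h$parent1_id, tn, sep = "\r")]
    p2v <- pval[paste(h$parent2_id, tn, sep = "\r")]
    cnt <- cc[paste(h$parent1_id, h$parent2_id, sep = "\r")]
    mp <- (p1v + p2v) / 2
    mph <- h$f1_value - mp
    if (measure == "relative")
      mph <- ifelse(mp == 0, NA_real_, 100 * mph / mp)
    use <- !is.na(mph) & !is.na(cnt)
    if (sum(use) < min_hybrids) {
      skipped[[tn]] <- sprintf("only %d usable hybrids (< %d)",
                               sum(use), min_hybrids)
      next
    }
    x <- cnt[use]; yy <- mph[use]
    degenerate <- stats::sd(x) == 0 || stats::sd(yy) == 0
    if (degenerate) {
      r2 <- 0; slope <- NA_real_
    } else {
      r2 <- stats::cor(x, yy)^2
      slope <- stats::cov(x, yy) / stats::var(x)
    }
    perm_p <- NA_real_
    if (n_perm > 0L && !degenerate) {
      obs <- r2
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        rp <- stats::cor(x, sample(yy))^2
        if (rp >= obs) exceed <- exceed + 1L
      }
      perm_p <- (exceed + 1L) / (n_perm + 1L)
    }
    qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
    if (length(qs) < 2L) {     # constant counts: a single all-inclusive bin
      bins[[tn]] <- data.frame(
        trait_name = tn, bin = sprintf("[%g,%g]", qs, qs),
        mean_count = mean(x), mean_mph = mean(yy), n = length(x),
        stringsAsFactors = FALSE)
    } else {
      bin <- cut(x, breaks = qs, include.lowest = TRUE)
      bins[[tn]] <- data.frame(
        trait_name = tn, bin = levels(bin),
        mean_count = as.numeric(tapply(x, bin, mean)),
        mean_mph = as.numeric(tapply(yy, bin, mean)),
        n = as.integer(table(bin)), stringsAsFactors = FALSE)
    }
    hdata[[tn]] <- data.frame(hybrid_id = h$hybrid_id[use],
                              trait_name = tn, complementary_count = x,
                              mph = yy, stringsAsFactors = FALSE)
    res[[tn]] <- data.frame(trait_name = tn, n = length(x), r2 = r2,
                            slope = slope, degenerate = degenerate,
                            perm_p = perm_p, stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no trait with enough usable hybrids")
  per_trait <- do.call(rbind, res)
  rownames(per_trait) <- NULL
  structure(list(per_trait = per_trait, bins = bins, hybrid_data = hdata,
                 measure = measure,
                 skipped = unlist(skipped)),
            class = "heterosis_cor")
}

#' @export
print.heterosis_cor <- function(x, ...) {
  cat("complementation vs mid-parent heterosis (", x$measure, "):\n", sep = "")
  print(x$per_trait, row.names = FALSE)
  if (length(x$skipped))
    cat("skipped:", paste(names(x$skipped), x$skipped, sep = ": ",
                          collapse = "; "), "\n")
  invisible(x)
}
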