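# Binary-marker association scan.
#
# Presence/absence states are used directly as the genotype: for each
# (marker, trait) pair an ordinary least-squares fit of trait on
# [intercept, state, PC covariates] yields the effect (mean-difference
# estimate) and a two-sided t-test p-value.  The scan-wide significance
# threshold is 1/n_markers unless an explicit alpha is given; for a scan
# of 2,355 markers that is 4.25e-4.

#' GWAS parameters
#'
#' @param n_pcs Number of principal-component covariates (default 3);
#'   informational here, the covariates themselves are passed to
#'   [run_gwas()].
#' @param threshold_rule `"one_over_n"` (significance at p < 1/n_markers)
#'   or a numeric alpha.
#' @param min_group Minimum line count required in each marker class
#'   (default 5); markers below it are skipped.
#' @return A list of class `gwas_params`.
#' @export
gwas_params <- function(n_pcs = 3L, threshold_rule = "one_over_n",
                        min_group = 5L) {
  stopifnot(n_pcs >= 0L, min_group >= 1L)
  if (is.numeric(threshold_rule))
    stopifnot(threshold_rule > 0, threshold_rule <= 1)
  else stopifnot(identical(threshold_rule, "one_over_n"))
  structure(list(n_pcs = as.integer(n_pcs), threshold_rule = threshold_rule,
                 min_group = as.integer(min_group)), class = "gwas_params")
}

#' Principal-component covariates from genotypes
#'
#' Missing dosages are mean-imputed per marker, the matrix is centered,
#' and the top `k` principal components of the lines are returned.  Sign
#' convention: within each component the largest-magnitude marker loading
#' is positive.
#'
#' @param geno Dosage matrix (markers x lines).
#' @param k Number of components; must be smaller than the line count.
#' @return A lines x k numeric matrix of PC scores (columns `PC1`...).
#' @export
compute_pcs <- function(geno, k = 3L) {
  stopifnot(is.matrix(geno))
  n <- ncol(geno)
  if (k >= n)
    stop("k must be smaller than the number of lines (", n, ")")
  if (k == 0L)
    return(matrix(numeric(0), nrow = n, ncol = 0L,
                  dimnames = list(colnames(geno), NULL)))
  x <- t(geno)                                # lines x markers
  mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  na <- is.na(x)
  x[na] <- mu[col(x)[na]]
  x <- sweep(x, 2L, colMeans(x))
  sv <- svd(x, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(colnames(geno), paste0("PC", seq_len(k)))
  scores
}

.gwas_skip <- function(reason)
  structure(list(reason = reason), class = "gwas_skip")

#' Test one presence/absence marker against a trait
#'
#' @param y Named trait vector (per line), NAs allowed.
#' @param x Named ternary marker vector in \{0, 1, NA\}.
#' @param covariates Optional lines x p covariate matrix (row names =
#'   line ids).
#' @param min_group Minimum count required in each marker class.
#' @return A one-row data.frame (`n_used`, `effect`, `se`, `p_value`), or
#'   an object of class `gwas_skip` carrying the skip `reason` when a
#'   marker class is below `min_group` or the state is aliased with the
#'   covariates.
#' @export
test_marker <- function(y, x, covariates = NULL, min_group = 5L) {
  lines <- names(x)
  if (is.null(lines) || is.null(names(y)))
    stop("y and x must be named by line id")
  y <- y[lines]
  use <- !is.na(x) & !is.na(y)
  x1 <- x[use]; y1 <- y[use]
  n0 <- sum(x1 == 0L); n1 <- sum(x1 == 1L)
  if (min(n0, n1) < min_group)
    return(.gwas_skip(sprintf("marker class below min_group (%d/%d)",
                              n0, n1)))
  X <- cbind(`(Intercept)` = 1, state = as.numeric(x1))
  if (!is.null(covariates) && ncol(covariates) > 0L) {
    cv <- covariates[lines[use], , drop = FALSE]
    if (anyNA(cv)) stop("missing covariate values for tested lines")
    X <- cbind(X, cv)
  }
  fit <- stats::lm.fit(X, y1)
  df <- length(y1) - fit$rank
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                               drop = FALSE])
  # column order after pivoting
  se_all <- sqrt(diag(XtXinv) * rss / df)
  pos <- match("state", colnames(X)[fit$qr$pivot[seq_len(fit$rank)]])
  if (is.na(pos))
    return(.gwas_skip("marker state aliased with covariates"))
  effect <- fit$coefficients[["state"]]
  se <- se_all[pos]
  tval <- effect / se
  data.frame(n_used = length(y1), effect = effect, se = se,
             p_value = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

#' Presence/absence GWAS scan
#'
#' Tests every (marker, trait) combination with [test_marker()].  The
#' significance threshold is `1 / n_markers` under the default
#' `"one_over_n"` rule, with `n_markers` the number of markers entering
#' the scan (rows of `pav`, counted before any per-trait skips).
#'
#' @param pav Ternary marker matrix (markers/genes x lines).
#' @param traits Trait table (`line_id`, `trait_name`, `value`).
#' @param covariates Optional lines x p covariate matrix, e.g. from
#'   [compute_pcs()].
#' @param params [gwas_params()].
#' @return A list of class `gwas_scan`: `records` (data.frame
#'   `marker_id`, `trait_name`, `n_used`, `effect`, `se`, `p_value`,
#'   `significant`), `threshold`, `n_markers` and `skipped` (data.frame of
#'   skipped tests with reasons).
#' @export
run_gwas <- function(pav, traits, covariates = NULL, params = gwas_params()) {
  stopifnot(is.matrix(pav))
  n_markers <- nrow(pav)
  if (n_markers == 0L) stop("no markers to test")
  thr <- if (identical(params$threshold_rule, "one_over_n"))
    1 / n_markers else params$threshold_rule
  trait_names <- unique(traits$trait_name)
  recs <- vector("list", length(trait_names) * n_markers)
  skip <- list()
  k <- 0L
  for (tn in trait_names) {
    tt <- traits[traits$trait_name == tn, ]
    y <- stats::setNames(tt$value, tt$line_id)[colnames(pav)]
    names(y) <- colnames(pav)
    for (m in rownames(pav)) {
      r <- test_marker(y, pav[m, ], covariates, params$min_group)
      if (inherits(r, "gwas_skip")) {
        skip[[length(skip) + 1L]] <-
          data.frame(marker_id = m, trait_name = tn,
                     reason = r$reason, stringsAsFactors = FALSE)
        next
      }
      k <- k + 1L
      recs[[k]] <- cbind(data.frame(marker_id = m, trait_name = tn,
                                    stringsAsFactors = FALSE), r)
    }
  }
  if (k == 0L) stop("no testable marker for any trait")
  records <- do.call(rbind, recs[seq_len(k)])
  rownames(records) <- NULL
  records$significant <- records$p_value < thr
  structure(list(records = records, threshold = thr, n_markers = n_markers,
                 skipped = if (length(skip)) do.call(rbind, skip) else
                   data.frame(marker_id = character(), trait_name = character(),
                              reason = character())),
            class = "gwas_scan")
}

#' @export
print.gwas_scan <- function(x, ...) {
  ns <- sum(x$records$significant)
  cat(sprintf("ePAV-GWAS: %d markers, %d tests, threshold p < %.3g\n",
              x$n_markers, nrow(x$records), x$threshold))
  cat(sprintf("  significant: %d of %d tests (%s%%); %d skipped\n",
              ns, nrow(x$records), fraction_pct(ns, nrow(x$records)),
              nrow(x$skipped)))
  invisible(x)
}

#' @export
summary.gwas_scan <- function(object, ...) {
  agg <- stats::aggregate(significant ~ trait_name, data = object$records, sum)
  names(agg)[2L] <- "n_significant"
  agg
}

#' Percentage of a count, rounded to two decimals
#'
#' Formatting used by the scan summaries, e.g. 56 of 13,382 markers is
#' 0.42 (percent).
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @param digits Decimal places (default 2).
#' @return Numeric percentage rounded to `digits`.
#' @export
fraction_pct <- function(k, n, digits = 2L) round(100 * k / n, digits)
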