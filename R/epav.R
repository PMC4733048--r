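# Distribution-based ePAV detection.
#
# A gene is scored by how many lines express it (value > 0).  With
# L = ceiling(min_frac * n_lines) and U = n_lines - L - 1, genes expressed
# in fewer than L lines are too rare to call, genes expressed in more than
# U lines are core, and the remainder are ePAV candidates.  At n = 368 and
# min_frac = 0.05 this gives the (19, 348) line-count gates; at n = 38 the
# lower gate is 2.  Candidate genes are then ternary-encoded per line with
# histogram trimming of outlying nonzero values.

#' ePAV calling parameters
#'
#' @param min_frac Lower presence fraction; genes expressed in fewer than
#'   `ceiling(min_frac * n_lines)` lines are "rare", in more than
#'   `n_lines - ceiling(min_frac * n_lines) - 1` lines "core".  Default 0.05.
#' @param n_bins Number of equal-width histogram bins used to trim a
#'   candidate gene's nonzero values.  Default 10.
#' @param min_bin_count Bins occupied by fewer than this many values are
#'   masked to NA (bin 1 is masked regardless).  Default 3.
#' @param recheck_maf After masking, keep a gene only if its presence
#'   fraction among non-NA states lies in `[min_frac, 1 - min_frac]`.
#'   Default TRUE.
#' @param log_bins Bin on the log scale instead of the raw scale.
#'   Default FALSE (raw equal-width bins).
#' @return A list of class `epav_params`.
#' @export
epav_params <- function(min_frac = 0.05, n_bins = 10L, min_bin_count = 3L,
                        recheck_maf = TRUE, log_bins = FALSE) {
  stopifnot(min_frac > 0, min_frac < 0.5, n_bins >= 2L, min_bin_count >= 1L)
  structure(list(min_frac = min_frac, n_bins = as.integer(n_bins),
                 min_bin_count = as.integer(min_bin_count),
                 recheck_maf = isTRUE(recheck_maf),
                 log_bins = isTRUE(log_bins)),
            class = "epav_params")
}

#' Presence-count gates for a panel size
#'
#' @param n_lines Panel size.
#' @param min_frac Lower presence fraction (default 0.05).
#' @return Named vector `c(lower = L, upper = U)`: a gene expressed in
#'   fewer than `L` lines is rare, in more than `U` lines core.
#' @export
presence_gates <- function(n_lines, min_frac = 0.05) {
  L <- as.integer(ceiling(min_frac * n_lines))
  c(lower = L, upper = as.integer(n_lines) - L - 1L)
}

#' Partition genes by expression frequency
#'
#' @param expr Expression matrix (genes x lines), nonnegative.
#' @param params [epav_params()].
#' @return A data.frame with columns `gene_id`, `n_expressed`, `class`
#'   (`rare`, `epav_candidate` or `core`); the partition is exhaustive and
#'   disjoint.
#' @export
classify_genes <- function(expr, params = epav_params()) {
  stopifnot(is.matrix(expr))
  if (nrow(expr) == 0L || ncol(expr) == 0L)
    stop("empty expression matrix")
  n <- ncol(expr)
  if (n < 20L)
    stop("need at least 20 lines to classify expression frequency (got ",
         n, ")")
  gates <- presence_gates(n, params$min_frac)
  cnt <- rowSums(expr > 0)
  cls <- ifelse(cnt < gates[["lower"]], "rare",
                ifelse(cnt > gates[["upper"]], "core", "epav_candidate"))
  data.frame(gene_id = rownames(expr), n_expressed = as.integer(cnt),
             class = cls, stringsAsFactors = FALSE)
}

#' Ternary-encode one candidate gene
#'
#' The gene's nonzero values are histogrammed into `n_bins` equal-width
#' bins spanning their range (last bin right-closed).  A nonzero value is
#' masked to NA if it falls in bin 1 or in any bin occupied by fewer than
#' `min_bin_count` values; other nonzero values become 1; zeros become 0.
#' Both masking rules are evaluated against the single initial histogram.
#' If all nonzero values are equal no trimming occurs.
#'
#' @param values Per-line nonnegative expression vector for one gene.
#' @param params [epav_params()].
#' @return Integer vector of the same length with values in \{0, 1, NA\}.
#' @export
binarize_gene <- function(values, params = epav_params()) {
  if (any(is.na(values)) || any(values < 0))
    stop("expression values must be nonnegative and non-missing")
  nz <- values > 0
  if (!any(nz))
    stop("all-zero expression vector: gene should have been classified rare")
  out <- integer(length(values))
  v <- values[nz]
  if (params$log_bins) v <- log(v)
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    out[nz] <- 1L
    names(out) <- names(values)
    return(out)
  }
  width <- (hi - lo) / params$n_bins
  bin <- pmin(floor((v - lo) / width), params$n_bins - 1L) + 1L
  occ <- tabulate(bin, nbins = params$n_bins)
  masked <- bin == 1L | occ[bin] < params$min_bin_count
  state <- ifelse(masked, NA_integer_, 1L)
  out[nz] <- state
  names(out) <- names(values)
  out
}

#' Call ePAV over an expression matrix
#'
#' Applies [classify_genes()], ternary-encodes each ePAV candidate with
#' [binarize_gene()], and (by default) re-checks the presence fraction
#' among non-NA states, dropping genes outside
#' `[min_frac, 1 - min_frac]`.
#'
#' @param expr Expression matrix (genes x lines).
#' @param params [epav_params()].
#' @return A list of class `epav_calls` with elements `pav` (ternary
#'   matrix over retained genes), `retained` (gene ids), and
#'   `classification` (the [classify_genes()] table).
#' @export
call_epav <- function(expr, params = epav_params()) {
  cls <- classify_genes(expr, params)
  cand <- cls$gene_id[cls$class == "epav_candidate"]
  states <- matrix(NA_integer_, nrow = length(cand), ncol = ncol(expr),
                   dimnames = list(cand, colnames(expr)))
  for (g in cand)
    states[g, ] <- binarize_gene(expr[g, ], params)
  keep <- rep(TRUE, length(cand))
  if (params$recheck_maf && length(cand)) {
    pres <- rowSums(states == 1L, na.rm = TRUE)
    nn <- rowSums(!is.na(states))
    frac <- ifelse(nn > 0, pres / nn, 0)
    keep <- frac >= params$min_frac & frac <= 1 - params$min_frac
  }
  structure(list(pav = states[keep, , drop = FALSE],
                 retained = cand[keep], classification = cls,
                 params = params),
            class = "epav_calls")
}

#' @export
print.epav_calls <- function(x, ...) {
  tab <- table(factor(x$classification$class,
                      levels = c("rare", "epav_candidate", "core")))
  cat("ePAV calls over", nrow(x$classification), "genes,",
      ncol(x$pav), "lines\n")
  cat(sprintf("  rare: %d  candidates: %d  core: %d  retained ePAV: %d\n",
              tab[["rare"]], tab[["epav_candidate"]], tab[["core"]],
              length(x$retained)))
  invisible(x)
}
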