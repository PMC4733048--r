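# Genomic PAV prediction from SNP-array missingness.
#
# A gene (body plus symmetric flank) is scanned for array markers; a line
# is a potential PAV for the gene when every window marker is missing in
# that line.  Genes where potential PAV occurs in at least
# ceiling(min_frac * n_lines) lines are candidate PAVs: at n = 368 the
# threshold is 19 lines (sparse-array regime), at n = 38 it is 2
# (dense-array regime).

#' PAV prediction parameters
#'
#' @param flank Window extension in bp on each side of the gene body
#'   (default 1000).
#' @param min_snps Minimum markers in the window for a gene to be
#'   assessable (default 2).
#' @param min_frac Minimum fraction of potential-PAV lines for a gene to
#'   be a candidate PAV (default 0.05); the count threshold is
#'   `ceiling(min_frac * n_lines)`.
#' @return A list of class `pav_params`.
#' @export
pav_params <- function(flank = 1000L, min_snps = 2L, min_frac = 0.05) {
  stopifnot(flank >= 0, min_snps >= 1L, min_frac > 0, min_frac < 1)
  structure(list(flank = as.integer(flank), min_snps = as.integer(min_snps),
                 min_frac = min_frac), class = "pav_params")
}

#' Predict genomic PAV from array missingness
#'
#' @param geno Dosage matrix (markers x lines) with values \{0, 1, 2, NA\}.
#' @param map Marker map data.frame (`marker_id`, `chromosome`,
#'   `position`), covering every matrix marker.
#' @param genes Gene annotation data.frame (`gene_id`, `chromosome`,
#'   `start`, `end`), 1-based inclusive.
#' @param params [pav_params()].
#' @return A list of class `pav_prediction` with elements `pav` (ternary
#'   matrix restricted to candidate PAV genes: 0 = potential PAV in that
#'   line, 1 = at least one genotyped window marker), `marker_counts`
#'   (named integer vector of window marker counts per annotated gene),
#'   and `candidate` (candidate gene ids).  Genes whose chromosome is
#'   absent from the map are excluded with a warning; genes with fewer
#'   than `min_snps` window markers are not assessed.
#' @export
predict_pav <- function(geno, map, genes, params = pav_params()) {
  stopifnot(is.matrix(geno))
  if (!all(rownames(geno) %in% map$marker_id))
    stop("genotype matrix contains markers missing from the map")
  map <- map[match(rownames(geno), map$marker_id), ]
  n_lines <- ncol(geno)
  thr <- as.integer(ceiling(params$min_frac * n_lines))

  off_map <- !(genes$chromosome %in% unique(map$chromosome))
  if (any(off_map)) {
    warning("excluding ", sum(off_map),
            " gene(s) on chromosomes absent from the marker map: ",
            paste(utils::head(genes$gene_id[off_map], 3L), collapse = ", "),
            if (sum(off_map) > 3L) ", ..." else "")
    genes <- genes[!off_map, , drop = FALSE]
  }

  counts <- integer(nrow(genes))
  names(counts) <- genes$gene_id
  states <- matrix(NA_integer_, nrow = nrow(genes), ncol = n_lines,
                   dimnames = list(genes$gene_id, colnames(geno)))
  miss <- is.na(geno)
  for (i in seq_len(nrow(genes))) {
    w <- map$chromosome == genes$chromosome[i] &
      map$position >= genes$start[i] - params$flank &
      map$position <= genes$end[i] + params$flank
    counts[i] <- sum(w)
    if (counts[i] < params$min_snps) next
    all_na <- colSums(!miss[w, , drop = FALSE]) == 0L
    states[i, ] <- ifelse(all_na, 0L, 1L)
  }
  absent_counts <- rowSums(states == 0L, na.rm = TRUE)
  assessed <- counts >= params$min_snps
  cand <- genes$gene_id[assessed & absent_counts >= thr]
  structure(list(pav = states[cand, , drop = FALSE], marker_counts = counts,
                 candidate = cand, threshold = thr, params = params),
            class = "pav_prediction")
}

#' @export
print.pav_prediction <- function(x, ...) {
  cat("genomic PAV prediction:", length(x$marker_counts), "genes assessed,",
      length(x$candidate), "candidate PAV (>=", x$threshold,
      "potential-PAV lines)\n")
  invisible(x)
}

#' Concordance between two presence/absence matrices
#'
#' Compares matching (gene, line) cells of an expression-level call and a
#' genomic-level call, ignoring cells NA in either, and decomposes the
#' inconsistencies into "present in the genome but not expressed" versus
#' "expressed without genomic support".
#'
#' @param epav Ternary matrix of expression presence/absence.
#' @param genomic Ternary matrix of genomic presence/absence.
#' @return A list of class `concordance_report`: `n_compared`,
#'   `consistency`, `inconsistent_present_genome_absent_expr` and
#'   `inconsistent_expr_without_genome` (the latter two are fractions of
#'   the inconsistent cells and sum to 1 when any exist).
#' @export
concordance <- function(epav, genomic) {
  genes <- intersect(rownames(epav), rownames(genomic))
  lines <- intersect(colnames(epav), colnames(genomic))
  if (!length(genes) || !length(lines))
    stop("matrices share no (gene, line) index")
  e <- epav[genes, lines, drop = FALSE]
  g <- genomic[genes, lines, drop = FALSE]
  use <- !is.na(e) & !is.na(g)
  n <- sum(use)
  if (n == 0L)
    stop("no overlapping non-NA cells to compare")
  match_n <- sum(e[use] == g[use])
  gp_ea <- sum(g[use] == 1L & e[use] == 0L)  # genome present, not expressed
  ep_ga <- sum(g[use] == 0L & e[use] == 1L)  # expressed, genome absent
  inc <- gp_ea + ep_ga
  structure(list(
    n_compared = n,
    consistency = match_n / n,
    inconsistent_present_genome_absent_expr = if (inc) gp_ea / inc else NA_real_,
    inconsistent_expr_without_genome = if (inc) ep_ga / inc else NA_real_),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance over %d cells: %.1f%% consistent\n",
              x$n_compared, 100 * x$consistency))
  if (!is.na(x$inconsistent_present_genome_absent_expr))
    cat(sprintf("  inconsistencies: %.1f%% genome-present/not-expressed, %.1f%% expressed/genome-absent\n",
                100 * x$inconsistent_present_genome_absent_expr,
                100 * x$inconsistent_expr_without_genome))
  invisible(x)
}
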