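# Composite-LD placement of novel (off-reference) sequences.
#
# LD between unphased dosage vectors is the squared Pearson correlation
# over pairwise-complete entries ("composite" LD: both phase relationships
# equally likely, so no haplotype inference).  A novel sequence is placed
# at the reference gene containing (or nearest to) the positioned SNP with
# the highest r2 to any of the sequence's own SNPs, provided that r2
# exceeds 0.1.

#' Filter markers by minor allele frequency
#'
#' @param geno Dosage matrix (markers x lines).
#' @param min_maf Retain markers with minor-allele frequency strictly
#'   greater than this, computed over non-NA calls (default 0.05).
#' @return The filtered dosage matrix.
#' @export
maf_filter <- function(geno, min_maf = 0.05) {
  stopifnot(is.matrix(geno))
  n_called <- rowSums(!is.na(geno))
  p <- rowSums(geno, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf > min_maf
  if (!any(keep))
    stop("all markers removed by the MAF filter (min_maf = ", min_maf, ")")
  geno[keep, , drop = FALSE]
}

#' Composite LD between two dosage vectors
#'
#' @param g1,g2 Dosage vectors in \{0, 1, 2, NA\} over the same lines.
#' @param min_complete Minimum pairwise-complete entries (default 10).
#' @return Squared Pearson correlation of dosages over pairwise-complete
#'   entries, or `NA` when fewer than `min_complete` entries remain or
#'   either vector is monomorphic on the complete subset.
#' @export
composite_r2 <- function(g1, g2, min_complete = 10L) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length")
  use <- !is.na(g1) & !is.na(g2)
  if (sum(use) < min_complete) return(NA_real_)
  a <- as.numeric(g1[use]); b <- as.numeric(g2[use])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

# r2 matrix between the rows of two dosage matrices, with the same
# semantics as composite_r2 (pairwise-complete, min count, polymorphism)
.composite_r2_matrix <- function(a, b, min_complete = 10L) {
  r <- suppressWarnings(stats::cor(t(a), t(b),
                                   use = "pairwise.complete.obs"))
  n_complete <- (!is.na(a)) %*% t(!is.na(b))
  r[n_complete < min_complete] <- NA_real_
  r^2
}

#' Place a novel sequence by composite LD
#'
#' Computes composite r2 between every SNP of the novel sequence and every
#' positioned reference SNP; the best pair determines the placement.  If
#' the best r2 exceeds `r2_min` the target is the gene containing the best
#' reference SNP, falling back to the nearest gene on that chromosome;
#' otherwise the sequence is unplaced.  Exact r2 ties are broken by
#' (chromosome label, position) ascending.
#'
#' @param novel_geno Dosage matrix of the novel sequence's SNPs
#'   (markers x lines).
#' @param ref_geno Reference dosage matrix over the same lines.
#' @param ref_map Marker map for `ref_geno`.
#' @param genes Gene annotation data.frame.
#' @param r2_min Placement threshold (default 0.1, exceeded strictly).
#' @param novel_id Identifier recorded in the result.
#' @return A one-row data.frame of class `placement`: `novel_id`,
#'   `target_gene_id` (NA when unplaced), `chromosome`, `position`,
#'   `best_r2`, `n_pairs_tested`, `placed`.
#' @export
place_novel <- function(novel_geno, ref_geno, ref_map, genes, r2_min = 0.1,
                        novel_id = "novel") {
  stopifnot(is.matrix(novel_geno), is.matrix(ref_geno))
  shared <- intersect(colnames(novel_geno), colnames(ref_geno))
  if (length(shared) < ncol(novel_geno) || length(shared) < ncol(ref_geno))
    stop("novel and reference matrices must share their line ids")
  nv <- novel_geno[, shared, drop = FALSE]
  rf <- ref_geno[, shared, drop = FALSE]
  r2 <- .composite_r2_matrix(nv, rf)
  n_tested <- sum(!is.na(r2))
  unplaced <- data.frame(novel_id = novel_id, target_gene_id = NA_character_,
                         chromosome = NA_character_, position = NA_integer_,
                         best_r2 = NA_real_, n_pairs_tested = n_tested,
                         placed = FALSE, stringsAsFactors = FALSE)
  class(unplaced) <- c("placement", "data.frame")
  if (n_tested == 0L) return(unplaced)
  best <- max(r2, na.rm = TRUE)
  unplaced$best_r2 <- best
  if (best <= r2_min) return(unplaced)
  # candidate reference SNPs achieving the maximum; deterministic tie-break
  hit_cols <- unique(which(r2 == best, arr.ind = TRUE)[, "col"])
  m <- ref_map[match(rownames(rf)[hit_cols], ref_map$marker_id), ]
  ord <- order(m$chromosome, m$position)
  chrom <- m$chromosome[ord[1L]]
  pos <- m$position[ord[1L]]
  gene <- .snp_gene(chrom, pos, genes)
  out <- data.frame(novel_id = novel_id, target_gene_id = gene,
                    chromosome = chrom, position = as.integer(pos),
                    best_r2 = best, n_pairs_tested = n_tested,
                    placed = !is.na(gene), stringsAsFactors = FALSE)
  class(out) <- c("placement", "data.frame")
  out
}

# gene containing (chrom, pos), else nearest gene on chrom; NA if none
.snp_gene <- function(chrom, pos, genes) {
  g <- genes[genes$chromosome == chrom, , drop = FALSE]
  if (!nrow(g)) return(NA_character_)
  inside <- g$start <= pos & g$end >= pos
  if (any(inside)) {
    g <- g[inside, , drop = FALSE]
    return(g$gene_id[order(g$start)][1L])
  }
  d <- pmax(g$start - pos, pos - g$end, 0L)
  g$gene_id[order(d, g$start)][1L]
}

#' Place many novel sequences
#'
#' @param novel_genos Named list of dosage matrices, one per novel
#'   sequence, or a single matrix plus `groups` naming each row's novel
#'   sequence.
#' @param groups When `novel_genos` is one matrix: character vector, per
#'   row, of novel-sequence ids.
#' @inheritParams place_novel
#' @return A data.frame with one [place_novel()] row per novel sequence.
#' @export
place_novel_all <- function(novel_genos, ref_geno, ref_map, genes,
                            r2_min = 0.1, groups = NULL) {
  if (is.matrix(novel_genos)) {
    stopifnot(!is.null(groups), length(groups) == nrow(novel_genos))
    novel_genos <- split.data.frame(novel_genos, groups)
    novel_genos <- lapply(novel_genos, as.matrix)
  }
  out <- lapply(names(novel_genos), function(id)
    place_novel(novel_genos[[id]], ref_geno, ref_map, genes, r2_min, id))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
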