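# Synthetic diverse-inbred-panel generator with ground truth.
#
# Emulates the data a kernel pan-transcriptome analysis consumes: a
# structured panel of inbred lines; SNP dosages with subpopulation-
# specific allele frequencies and first-order autoregressive LD along
# each chromosome; core genes expressed everywhere; ePAV genes switched
# on/off mostly by trans regulator SNPs on other chromosomes and rarely
# (~1% by default) by genomic PAV, the latter leaving runs of missing
# array calls over the deleted gene; novel sequences carrying SNPs in
# high LD with positioned reference SNPs; traits with planted ePAV
# effects and a subpopulation shift; and F1 hybrids whose heterosis grows
# with parental presence/absence complementation.  All randomness comes
# from one seeded stream with a fixed draw order, so a seed pins every
# output byte.

#' Simulation configuration
#'
#' Defaults describe a panel of 300 diverse inbreds in 3 subpopulations,
#' 5 chromosomes with 4,000 SNPs, 300 core genes, 200 ePAV genes of which
#' 1% are genomic PAVs, 30 novel sequences, six planted yield-like
#' traits and 100 tester-cross F1 hybrids.
#'
#' @param n_lines Panel size (default 300).
#' @param n_core_genes,n_epav_genes,n_novel_genes Gene counts
#'   (defaults 300/200/30).
#' @param frac_epav_genomic Fraction of ePAV genes driven by genomic PAV
#'   (default 0.01).
#' @param n_subpops Subpopulations (default 3).
#' @param n_snps Reference SNPs (default 4000).
#' @param ld_decay AR(1) correlation of adjacent latent haplotype
#'   variables, in (0, 1) (default 0.8).
#' @param regulator_min_gap Minimum marker-index separation between the
#'   regulator SNPs of different trans-ePAV genes on the same chromosome
#'   (default 8), so distinct regulators are distinct loci rather than
#'   one haplotype.
#' @param trait_specs List of lists `trait_name`, `n_causal_epav`,
#'   `effect_size` (trait units per present state), `noise_sd`.  The
#'   default plants six yield-like traits (kernel width/thickness, rows
#'   per ear, ear length, cob weight, kernels per ear), three causal
#'   ePAV genes each.
#' @param heterosis_effect Trait increment per complementary gene in an
#'   F1 (default 0.2; with ~85 complementary genes per tester cross this
#'   yields mid-parent heterosis around 85% of the mid-parent value,
#'   typical of yield components).
#' @param outlier_rate Probability an expressed value is inflated 10-50x,
#'   emulating rare quantification artifacts (default 5e-4).
#' @param dropout_rate Probability an expressed value is zeroed
#'   (default 0.02); capped for core genes so they stay above 95%
#'   presence.
#' @param seed RNG seed (default 1).
#' @param n_chromosomes,snp_spacing,gene_length,gene_spacing Genome
#'   layout, bp.
#' @param subpop_freq_sd SD of subpopulation allele-frequency deviations
#'   (default 0.15).
#' @param flip_error Per-(gene, line) probability a regulator-driven
#'   state is flipped (default 0.02).
#' @param geno_missing_rate Background array missing-call rate
#'   (default 0.02).
#' @param subpop_trait_sd SD of per-subpopulation trait mean shifts
#'   (default 0.3).
#' @param trait_baseline Trait grand mean, keeps mid-parent values away
#'   from zero so relative heterosis is defined (default 20).
#' @param novel_snp_noise Per-line probability a novel SNP's dosage
#'   deviates from its anchor reference SNP (default 0.03; keeps
#'   anchor-novel r2 around 0.9).
#' @param n_hybrids Tester-cross F1s (default 100).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 300L, n_core_genes = 300L,
                       n_epav_genes = 200L, n_novel_genes = 30L,
                       frac_epav_genomic = 0.01, n_subpops = 3L,
                       n_snps = 4000L, ld_decay = 0.8,
                       regulator_min_gap = 8L,
                       trait_specs = lapply(
                         c("KWd", "KT", "RPE", "EL", "CW", "KPE"),
                         function(tn) list(trait_name = tn,
                                           n_causal_epav = 3L,
                                           effect_size = 1.0,
                                           noise_sd = 0.5)),
                       heterosis_effect = 0.2, outlier_rate = 5e-4,
                       dropout_rate = 0.02, seed = 1L,
                       n_chromosomes = 5L, snp_spacing = 2000L,
                       gene_length = 4000L, gene_spacing = 8000L,
                       subpop_freq_sd = 0.15, flip_error = 0.02,
                       geno_missing_rate = 0.02, subpop_trait_sd = 0.3,
                       trait_baseline = 20, novel_snp_noise = 0.03,
                       n_hybrids = 100L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_lines > 0, n_core_genes > 0, n_epav_genes > 0,
              n_novel_genes > 0, n_subpops > 0, n_snps > 0,
              n_chromosomes > 0, n_hybrids > 0,
              frac_epav_genomic >= 0, frac_epav_genomic <= 1,
              ld_decay > 0, ld_decay < 1,
              outlier_rate >= 0, outlier_rate <= 1,
              dropout_rate >= 0, dropout_rate <= 1,
              flip_error >= 0, flip_error <= 1,
              geno_missing_rate >= 0, geno_missing_rate <= 1,
              novel_snp_noise >= 0, novel_snp_noise <= 1)
  })
  for (ts in cfg$trait_specs)
    if (ts$n_causal_epav > cfg$n_epav_genes)
      stop("trait '", ts$trait_name, "' requests more causal genes (",
           ts$n_causal_epav, ") than there are ePAV genes (",
           cfg$n_epav_genes, ")")
  if (cfg$n_hybrids > cfg$n_lines - 1L)
    stop("n_hybrids must leave at least the tester line uncrossed")
  structure(cfg, class = "sim_config")
}

# lognormal expression values for 'present' cells of one gene
.expr_values <- function(n, meanlog, sdlog = 0.8) stats::rlnorm(n, meanlog, sdlog)

#' Simulate a full panel with ground truth
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_panel` with elements `expr` (expression
#'   matrix over core + ePAV + novel genes), `geno` + `map` (reference
#'   SNPs; genomic-PAV windows are NA in deleted lines), `genes`
#'   (reference gene annotation, 1-based), `traits`, `hybrids`,
#'   `novel_geno` + `novel_groups` (novel-sequence SNPs and their
#'   sequence assignment), `subpop` (per-line labels), and `truth`
#'   (class `sim_truth`): `gene_class`, `states_true` (truth presence of
#'   every non-core gene per line), `genomic_absent` (per genomic-PAV
#'   gene, absent line ids), `regulators`, `causal`, `novel_truth`
#'   (anchor chromosome/position and target gene per novel sequence) and
#'   `pan_size` (genes expressed in at least one line).
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)

  line_ids <- sprintf("L%03d", seq_len(cf$n_lines))
  subpop <- stats::setNames(
    sort(rep_len(seq_len(cf$n_subpops), cf$n_lines)), line_ids)

  ## --- genome layout -----------------------------------------------------
  n_ref <- cf$n_core_genes + cf$n_epav_genes
  chroms <- sprintf("chr%d", seq_len(cf$n_chromosomes))
  genes_per_chrom <- as.integer(ceiling(n_ref / cf$n_chromosomes))
  gidx <- seq_len(n_ref) - 1L
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_ref)),
    chromosome = chroms[gidx %/% genes_per_chrom + 1L],
    start = as.integer(500L + (gidx %% genes_per_chrom) * cf$gene_spacing),
    end = as.integer(500L + (gidx %% genes_per_chrom) * cf$gene_spacing +
                       cf$gene_length - 1L),
    stringsAsFactors = FALSE)

  snps_per_chrom <- as.integer(ceiling(cf$n_snps / cf$n_chromosomes))
  sidx <- seq_len(cf$n_snps) - 1L
  map <- data.frame(
    marker_id = sprintf("s%05d", seq_len(cf$n_snps)),
    chromosome = chroms[sidx %/% snps_per_chrom + 1L],
    position = as.integer(1000L + (sidx %% snps_per_chrom) * cf$snp_spacing),
    stringsAsFactors = FALSE)

  ## --- dosages: AR(1) latent haplotypes, subpop-specific frequencies -----
  base_p <- stats::runif(cf$n_snps, 0.1, 0.9)
  sub_p <- matrix(pmin(pmax(
    rep(base_p, each = cf$n_subpops) +
      stats::rnorm(cf$n_subpops * cf$n_snps, 0, cf$subpop_freq_sd),
    0.05), 0.95), nrow = cf$n_subpops)
  thr <- stats::qnorm(1 - sub_p)             # subpops x snps

  dos_true <- matrix(0L, nrow = cf$n_snps, ncol = cf$n_lines,
                     dimnames = list(map$marker_id, line_ids))
  for (ch in chroms) {
    mi <- which(map$chromosome == ch)
    M <- length(mi)
    for (hap in 1:2) {
      z <- matrix(stats::rnorm(cf$n_lines * M), nrow = cf$n_lines)
      for (m in seq_len(M)[-1L])
        z[, m] <- cf$ld_decay * z[, m - 1L] +
          sqrt(1 - cf$ld_decay^2) * z[, m]
      allele <- z > thr[subpop, mi, drop = FALSE]
      dos_true[mi, ] <- dos_true[mi, ] + t(allele)
    }
  }

  ## --- gene classes ------------------------------------------------------
  n_genomic <- round(cf$frac_epav_genomic * cf$n_epav_genes)
  epav_ids <- sample(genes$gene_id, cf$n_epav_genes)
  genomic_ids <- if (n_genomic > 0) sample(epav_ids, n_genomic) else character()
  trans_ids <- setdiff(epav_ids, genomic_ids)
  core_ids <- setdiff(genes$gene_id, epav_ids)
  novel_ids <- sprintf("novel%02d", seq_len(cf$n_novel_genes))
  gene_class <- stats::setNames(
    rep("core", n_ref + cf$n_novel_genes), c(genes$gene_id, novel_ids))
  gene_class[trans_ids] <- "epav_trans"
  gene_class[genomic_ids] <- "epav_genomic"
  gene_class[novel_ids] <- "novel"

  carrier_freq <- rowMeans(dos_true >= 1L)
  gene_chrom <- stats::setNames(genes$chromosome, genes$gene_id)

  ## --- trans ePAV: regulator SNP on another chromosome -------------------
  usable <- carrier_freq >= 0.15 & carrier_freq <= 0.85
  available <- usable                # regulators are distinct, spaced loci
  regulators <- stats::setNames(character(length(trans_ids)), trans_ids)
  states_true <- matrix(NA_integer_, nrow = cf$n_epav_genes + cf$n_novel_genes,
                        ncol = cf$n_lines,
                        dimnames = list(c(epav_ids, novel_ids), line_ids))
  for (g in trans_ids) {
    cand <- which(available & map$chromosome != gene_chrom[[g]])
    if (!length(cand))
      stop("ran out of usable regulator SNPs; increase n_snps or lower ",
           "regulator_min_gap")
    reg <- cand[sample.int(length(cand), 1L)]
    regulators[g] <- map$marker_id[reg]
    same_chr <- map$chromosome == map$chromosome[reg]
    available[same_chr &
                abs(seq_len(cf$n_snps) - reg) < cf$regulator_min_gap] <- FALSE
    on <- dos_true[reg, ] >= 1L
    flip <- stats::runif(cf$n_lines) < cf$flip_error
    states_true[g, ] <- as.integer(xor(on, flip))
  }

  ## --- genomic-PAV ePAV: subpopulation-correlated deletions --------------
  lo <- ceiling(0.05 * cf$n_lines); hi <- floor(0.95 * cf$n_lines)
  genomic_absent <- list()
  for (g in genomic_ids) {
    repeat {
      home <- sample.int(cf$n_subpops, 1L)
      absent <- ifelse(subpop == home,
                       stats::runif(cf$n_lines) < 0.6,
                       stats::runif(cf$n_lines) < 0.02)
      if (sum(absent) >= lo && sum(absent) <= hi) break
    }
    genomic_absent[[g]] <- line_ids[absent]
    states_true[g, ] <- as.integer(!absent)
  }

  ## --- novel sequences: SNPs in high LD with an anchored reference SNP ---
  body_gene <- rep(NA_character_, cf$n_snps)   # gene body containing each SNP
  for (i in seq_len(n_ref)) {
    w <- map$chromosome == genes$chromosome[i] &
      map$position >= genes$start[i] & map$position <= genes$end[i]
    body_gene[w] <- genes$gene_id[i]
  }
  anchor_ok <- which(usable & !is.na(body_gene))
  novel_truth <- data.frame(novel_id = novel_ids,
                            chromosome = NA_character_,
                            position = NA_integer_,
                            target_gene_id = NA_character_,
                            anchor_marker = NA_character_,
                            stringsAsFactors = FALSE)
  novel_snp_rows <- list()
  novel_groups <- character()
  for (i in seq_len(cf$n_novel_genes)) {
    a <- anchor_ok[sample.int(length(anchor_ok), 1L)]
    novel_truth$chromosome[i] <- map$chromosome[a]
    novel_truth$position[i] <- map$position[a]
    novel_truth$target_gene_id[i] <- body_gene[a]
    novel_truth$anchor_marker[i] <- map$marker_id[a]
    k <- sample.int(5L, 1L)
    for (s in seq_len(k)) {
      d <- dos_true[a, ]
      noisy <- stats::runif(cf$n_lines) < cf$novel_snp_noise
      d[noisy] <- stats::rbinom(sum(noisy), 2L, base_p[a])
      novel_snp_rows[[length(novel_snp_rows) + 1L]] <- d
      novel_groups <- c(novel_groups, novel_ids[i])
    }
    on <- dos_true[a, ] >= 1L
    flip <- stats::runif(cf$n_lines) < cf$flip_error
    states_true[novel_ids[i], ] <- as.integer(xor(on, flip))
  }
  novel_geno <- do.call(rbind, novel_snp_rows)
  dimnames(novel_geno) <- list(
    sprintf("nsnp%04d", seq_len(nrow(novel_geno))), line_ids)
  names(novel_groups) <- rownames(novel_geno)

  ## --- expression matrix -------------------------------------------------
  all_genes <- c(genes$gene_id, novel_ids)
  expr <- matrix(0, nrow = length(all_genes), ncol = cf$n_lines,
                 dimnames = list(all_genes, line_ids))
  meanlog <- stats::setNames(stats::rnorm(length(all_genes), log(10), 0.5),
                             all_genes)
  core_cap <- ceiling(0.05 * cf$n_lines) - 1L   # zeros a core gene may carry
  gene_has_outlier <- stats::setNames(logical(length(all_genes)), all_genes)
  for (g in all_genes) {
    present <- if (gene_class[[g]] == "core") rep(TRUE, cf$n_lines) else
      states_true[g, ] == 1L
    vals <- numeric(cf$n_lines)
    vals[present] <- .expr_values(sum(present), meanlog[[g]])
    drop <- present & stats::runif(cf$n_lines) < cf$dropout_rate
    if (gene_class[[g]] == "core" && sum(drop) > core_cap)
      drop[which(drop)[-seq_len(core_cap)]] <- FALSE
    vals[drop] <- 0
    burst <- vals > 0 & stats::runif(cf$n_lines) < cf$outlier_rate
    vals[burst] <- vals[burst] * stats::runif(sum(burst), 10, 50)
    gene_has_outlier[g] <- any(burst)
    expr[g, ] <- vals
  }

  ## --- array output: background missingness + deletion masking -----------
  geno <- dos_true
  geno[stats::runif(length(geno)) < cf$geno_missing_rate] <- NA_integer_
  for (g in genomic_ids) {
    i <- match(g, genes$gene_id)
    w <- map$chromosome == genes$chromosome[i] &
      map$position >= genes$start[i] - 1000L &
      map$position <= genes$end[i] + 1000L
    geno[w, genomic_absent[[g]]] <- NA_integer_
  }
  novel_geno[stats::runif(length(novel_geno)) < cf$geno_missing_rate] <-
    NA_integer_

  ## --- traits with planted ePAV effects ----------------------------------
  causal <- list()
  traits <- list()
  trait_noise <- numeric()
  # plant effects on genes with mid-range presence, clean quantification
  # (no inflated outlier cells) and a state not collinear with population
  # structure: a state whose variance is mostly between subpopulations is
  # absorbed by the structure correction and carries no recoverable
  # within-population signal
  eta2 <- apply(states_true[trans_ids, , drop = FALSE], 1L, function(st) {
    if (stats::var(st) == 0) return(1)
    stats::var(stats::ave(st, subpop)) / stats::var(st)
  })
  usable_trans <- trans_ids[
    rowMeans(states_true[trans_ids, , drop = FALSE]) >= 0.25 &
      rowMeans(states_true[trans_ids, , drop = FALSE]) <= 0.80 &
      !gene_has_outlier[trans_ids] & eta2 < 0.3]
  for (ts in cf$trait_specs) {
    pool <- if (length(usable_trans) >= ts$n_causal_epav) usable_trans
            else trans_ids
    cg <- sample(pool, ts$n_causal_epav)
    shift <- stats::rnorm(cf$n_subpops, 0, cf$subpop_trait_sd)
    y <- cf$trait_baseline + shift[subpop] +
      colSums(states_true[cg, , drop = FALSE] * ts$effect_size) +
      stats::rnorm(cf$n_lines, 0, ts$noise_sd)
    causal[[ts$trait_name]] <- data.frame(
      trait_name = ts$trait_name, gene_id = cg, effect = ts$effect_size,
      stringsAsFactors = FALSE)
    traits[[ts$trait_name]] <- data.frame(
      line_id = line_ids, trait_name = ts$trait_name, value = y,
      stringsAsFactors = FALSE)
    trait_noise[ts$trait_name] <- ts$noise_sd
  }
  traits <- do.call(rbind, traits); rownames(traits) <- NULL
  causal <- do.call(rbind, causal); rownames(causal) <- NULL

  ## --- tester-cross hybrids: MPH rises with complementation --------------
  tester <- line_ids[cf$n_lines]
  cross_parents <- line_ids[seq_len(cf$n_hybrids)]
  disp <- states_true   # every non-core gene, truth states
  comp <- vapply(cross_parents, function(p)
    sum(disp[, p] != disp[, tester]), numeric(1L))
  tv <- stats::setNames(traits$value,
                        paste(traits$line_id, traits$trait_name, sep = "\r"))
  hyb <- list()
  for (tn in names(trait_noise)) {
    mp <- (tv[paste(cross_parents, tn, sep = "\r")] +
             tv[paste(tester, tn, sep = "\r")]) / 2
    f1 <- mp + cf$heterosis_effect * comp +
      stats::rnorm(cf$n_hybrids, 0, trait_noise[[tn]])
    hyb[[tn]] <- data.frame(
      hybrid_id = sprintf("%s_x_%s", cross_parents, tester),
      parent1_id = cross_parents, parent2_id = tester, trait_name = tn,
      f1_value = as.numeric(f1), stringsAsFactors = FALSE)
  }
  hybrids <- do.call(rbind, hyb); rownames(hybrids) <- NULL

  truth <- structure(list(
    gene_class = gene_class, states_true = states_true,
    genomic_absent = genomic_absent, regulators = regulators,
    causal = causal, novel_truth = novel_truth,
    complementary_true = comp,
    pan_size = sum(rowSums(expr > 0) >= 1L)), class = "sim_truth")

  structure(list(expr = expr, geno = geno, map = map, genes = genes,
                 traits = traits, hybrids = hybrids,
                 novel_geno = novel_geno, novel_groups = novel_groups,
                 subpop = subpop, truth = truth, config = cf),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("synthetic panel:", x$config$n_lines, "lines,",
      nrow(x$expr), "genes (", sum(x$truth$gene_class == "core"), "core /",
      sum(x$truth$gene_class %in% c("epav_trans", "epav_genomic")), "ePAV /",
      sum(x$truth$gene_class == "novel"), "novel ),",
      nrow(x$geno), "SNPs\n")
  invisible(x)
}

#' Write every panel artifact to a directory
#'
#' Writes the expression matrix, genotypes + map, gene BED, trait and
#' hybrid tables, novel-sequence genotypes, and the truth record as plain
#' TSV/BED files.
#'
#' @param panel A [simulate_panel()] result.
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_sim_panel <- function(panel, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_expression_matrix(panel$expr, p("expression.tsv"))
  write_genotypes(panel$geno, panel$map, p("genotypes.tsv"), p("markers.tsv"))
  write_gene_bed(panel$genes, p("genes.bed"))
  write_trait_table(panel$traits, p("traits.tsv"))
  write_hybrid_table(panel$hybrids, p("hybrids.tsv"))
  write_genotypes(panel$novel_geno,
                  data.frame(marker_id = rownames(panel$novel_geno),
                             chromosome = unname(panel$novel_groups),
                             position = seq_len(nrow(panel$novel_geno)),
                             stringsAsFactors = FALSE),
                  p("novel_genotypes.tsv"), p("novel_markers.tsv"))
  utils::write.table(
    data.frame(gene_id = names(panel$truth$gene_class),
               class = unname(panel$truth$gene_class)),
    p("truth_gene_class.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$truth$causal, p("truth_causal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$truth$novel_truth, p("truth_novel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
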