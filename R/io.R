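# Readers/writers for the pipeline's on-disk artifacts.
#
# One TSV dialect throughout: tab separator, "NA" missing token, no quoting,
# header row of line ids, first column the row (gene/marker) identifier.
# Genomic coordinates are 1-based inclusive internally; BED (0-based,
# half-open) is converted at the file boundary only.  Strand is ignored.

NA_TOKEN <- "NA"

# shortest decimal representation that round-trips the double exactly
# (falls back to %.17g, which always does)
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  todo <- !is.na(x)
  for (d in 1:16) {
    if (!any(todo)) break
    cand <- sprintf(paste0("%.", d, "g"), x[todo])
    hit <- as.numeric(cand) == x[todo]
    out[todo][hit] <- cand[hit]
    todo[todo] <- !hit
  }
  out[is.na(x)] <- NA_TOKEN
  out
}

.read_tsv_matrix <- function(path, id_label) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          na.strings = character(0))
  if (ncol(df) < 2L)
    stop("'", path, "': expected an id column plus at least one data column")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("'", path, "': duplicate ", id_label, " identifier '",
         ids[duplicated(ids)][1L], "'")
  cols <- colnames(df)[-1L]
  if (anyDuplicated(cols))
    stop("'", path, "': duplicate line identifier '",
         cols[duplicated(cols)][1L], "'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(ids, cols)
  m
}

.write_tsv_matrix <- function(m, path, id_label) {
  header <- paste(c(id_label, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

.first_bad_cell <- function(bad, m) {
  idx <- which(bad, arr.ind = TRUE)[1L, ]
  sprintf("gene/row '%s', line '%s'", rownames(m)[idx[1L]], colnames(m)[idx[2L]])
}

#' Read an expression matrix
#'
#' Reads a genes x lines TSV of nonnegative, RPKM-like expression values.
#' The first column holds gene identifiers, the header row line identifiers.
#' Missing values are not permitted: an unexpressed gene is an explicit 0.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix (genes in rows, lines in columns) with unique
#'   dimnames.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  chr <- .read_tsv_matrix(path, "gene_id")
  suppressWarnings(vals <- array(as.numeric(chr), dim = dim(chr),
                                 dimnames = dimnames(chr)))
  bad <- is.na(vals)
  if (any(bad))
    stop("'", path, "': non-numeric or missing expression value at ",
         .first_bad_cell(bad, chr), " (value '", chr[which(bad)[1L]], "')")
  neg <- vals < 0
  if (any(neg))
    stop("'", path, "': negative expression value at ",
         .first_bad_cell(neg, vals))
  vals
}

#' Write an expression matrix
#'
#' @param m Numeric matrix as returned by [read_expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(is.na(m)) || any(m < 0))
    stop("expression matrix must be nonnegative with no missing values")
  chr <- array(.fmt_num(m), dim = dim(m), dimnames = dimnames(m))
  .write_tsv_matrix(chr, path, "gene_id")
}

.validate_ternary <- function(chr, where) {
  ok <- chr %in% c("0", "1", NA_TOKEN)
  if (!all(ok))
    stop(where, ": invalid presence/absence token '", chr[!ok][1L], "' at ",
         .first_bad_cell(array(!ok, dim(chr)), chr),
         " (expected 0, 1 or NA)")
  states <- array(NA_integer_, dim = dim(chr), dimnames = dimnames(chr))
  states[chr == "0"] <- 0L
  states[chr == "1"] <- 1L
  states
}

#' Read a ternary presence/absence matrix
#'
#' Cells must be the literal tokens `0`, `1` or `NA` (present, absent,
#' masked).  Used for ePAV calls, predicted genomic PAV and novel-sequence
#' presence patterns alike.
#'
#' @param path Path to a tab-separated file.
#' @return An integer matrix with values in \{0, 1, NA\}.
#' @export
read_ternary_matrix <- function(path) {
  chr <- .read_tsv_matrix(path, "gene_id")
  .validate_ternary(chr, paste0("'", path, "'"))
}

#' Write a ternary presence/absence matrix
#'
#' @param m Integer/numeric matrix with values in \{0, 1, NA\}.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ternary_matrix <- function(m, path) {
  stopifnot(is.matrix(m))
  if (!all(m %in% c(0L, 1L, NA)))
    stop("ternary matrix cells must be 0, 1 or NA")
  chr <- array(as.character(m), dim = dim(m), dimnames = dimnames(m))
  chr[is.na(m)] <- NA_TOKEN
  .write_tsv_matrix(chr, path, "gene_id")
}

#' Read a genotype matrix with its marker map
#'
#' The dosage file is a markers x lines TSV with cells in \{0, 1, 2, NA\};
#' the map file has columns `marker_id`, `chromosome`, `position`
#' (1-based bp).  Every marker in the dosage matrix must have exactly one
#' map row.
#'
#' @param geno_path Path to the dosage TSV.
#' @param map_path Path to the 3-column map TSV.
#' @return A list with elements `geno` (integer matrix, markers x lines)
#'   and `map` (data.frame `marker_id`, `chromosome`, `position`), the map
#'   ordered as the matrix rows.
#' @export
read_genotypes <- function(geno_path, map_path) {
  chr <- .read_tsv_matrix(geno_path, "marker_id")
  ok <- chr %in% c("0", "1", "2", NA_TOKEN)
  if (!all(ok))
    stop("'", geno_path, "': invalid dosage '", chr[!ok][1L], "' at ",
         .first_bad_cell(array(!ok, dim(chr)), chr),
         " (expected 0, 1, 2 or NA)")
  geno <- array(NA_integer_, dim = dim(chr), dimnames = dimnames(chr))
  for (tok in c("0", "1", "2")) geno[chr == tok] <- as.integer(tok)

  map <- utils::read.table(map_path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "integer"))
  need <- c("marker_id", "chromosome", "position")
  if (!identical(colnames(map), need))
    stop("'", map_path, "': expected columns ", paste(need, collapse = ", "))
  if (anyDuplicated(map$marker_id))
    stop("'", map_path, "': duplicate marker '",
         map$marker_id[duplicated(map$marker_id)][1L], "'")
  if (any(is.na(map$position)) || any(map$position < 1L))
    stop("'", map_path, "': positions must be positive 1-based integers")
  missing <- setdiff(rownames(geno), map$marker_id)
  if (length(missing))
    stop("'", map_path, "': marker '", missing[1L],
         "' present in the genotype matrix but absent from the map")
  map <- map[match(rownames(geno), map$marker_id), , drop = FALSE]
  rownames(map) <- NULL
  list(geno = geno, map = map)
}

#' Write a genotype matrix and marker map
#'
#' @param geno Integer matrix with values in \{0, 1, 2, NA\}.
#' @param map Data frame with `marker_id`, `chromosome`, `position`.
#' @param geno_path,map_path Output paths.
#' @return `geno_path`, invisibly.
#' @export
write_genotypes <- function(geno, map, geno_path, map_path) {
  stopifnot(is.matrix(geno), all(geno %in% c(0L, 1L, 2L, NA)))
  chr <- array(as.character(geno), dim = dim(geno), dimnames = dimnames(geno))
  chr[is.na(geno)] <- NA_TOKEN
  .write_tsv_matrix(chr, geno_path, "marker_id")
  lines <- c("marker_id\tchromosome\tposition",
             sprintf("%s\t%s\t%d", map$marker_id, map$chromosome,
                     as.integer(map$position)))
  writeLines(lines, map_path)
  invisible(geno_path)
}

#' Read gene annotation from BED
#'
#' BED3+name input (0-based, half-open).  Coordinates are converted to the
#' internal 1-based inclusive convention: internal start = BED start + 1,
#' internal end = BED end.
#'
#' @param path Path to a 4-column BED file (chrom, start, end, name),
#'   tab-separated, no header.
#' @return A data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end` (1-based inclusive).
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    stop("'", path, "': expected BED3+name (chrom, start, end, name)")
  df <- df[, 1:4]
  colnames(df) <- c("chromosome", "start0", "end", "gene_id")
  bad <- df$end <= df$start0
  if (any(bad))
    stop("'", path, "': BED interval with end <= start for gene '",
         df$gene_id[bad][1L], "'")
  if (anyDuplicated(df$gene_id))
    stop("'", path, "': duplicate gene '",
         df$gene_id[duplicated(df$gene_id)][1L], "'")
  out <- data.frame(gene_id = df$gene_id, chromosome = df$chromosome,
                    start = as.integer(df$start0) + 1L,
                    end = as.integer(df$end), stringsAsFactors = FALSE)
  out
}

#' Write gene annotation as BED
#'
#' Converts internal 1-based inclusive intervals back to BED (0-based,
#' half-open); exact inverse of [read_gene_bed()].
#'
#' @param genes Data frame with `gene_id`, `chromosome`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% colnames(genes)))
  if (any(genes$start > genes$end))
    stop("gene annotation with start > end")
  writeLines(sprintf("%s\t%d\t%d\t%s", genes$chromosome,
                     as.integer(genes$start) - 1L, as.integer(genes$end),
                     genes$gene_id), path)
  invisible(path)
}

#' Read a line x trait table
#'
#' Long-format TSV with columns `line_id`, `trait_name`, `value`; at most
#' one value per (line, trait), missing values by omission.
#'
#' @param path Path to the TSV.
#' @return A data.frame with those three columns.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("line_id", "trait_name", "value")
  if (!all(need %in% colnames(df)))
    stop("'", path, "': expected columns ", paste(need, collapse = ", "))
  df <- df[, need]
  key <- paste(df$line_id, df$trait_name, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1L, ]
    stop("'", path, "': duplicate trait value for line '", d$line_id,
         "', trait '", d$trait_name, "'")
  }
  df$value <- as.numeric(df$value)
  df
}

#' Write a line x trait table
#' @param traits Data frame with `line_id`, `trait_name`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  writeLines(c("line_id\ttrait_name\tvalue",
               sprintf("%s\t%s\t%s", traits$line_id, traits$trait_name,
                       .fmt_num(traits$value))), path)
  invisible(path)
}

#' Read an F1 hybrid table
#'
#' Columns `hybrid_id`, `parent1_id`, `parent2_id`, `trait_name`,
#' `f1_value`; the two parents of a hybrid must differ.
#'
#' @param path Path to the TSV.
#' @return A data.frame with those five columns.
#' @export
read_hybrid_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("hybrid_id", "parent1_id", "parent2_id", "trait_name", "f1_value")
  if (!all(need %in% colnames(df)))
    stop("'", path, "': expected columns ", paste(need, collapse = ", "))
  df <- df[, need]
  bad <- df$parent1_id == df$parent2_id
  if (any(bad))
    stop("'", path, "': hybrid '", df$hybrid_id[bad][1L],
         "' has identical parents")
  df$f1_value <- as.numeric(df$f1_value)
  df
}

#' Write an F1 hybrid table
#' @param hybrids Data frame as returned by [read_hybrid_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hybrid_table <- function(hybrids, path) {
  writeLines(c("hybrid_id\tparent1_id\tparent2_id\ttrait_name\tf1_value",
               sprintf("%s\t%s\t%s\t%s\t%s", hybrids$hybrid_id,
                       hybrids$parent1_id, hybrids$parent2_id,
                       hybrids$trait_name, .fmt_num(hybrids$f1_value))), path)
  invisible(path)
}
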