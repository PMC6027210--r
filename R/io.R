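#' @importFrom utils read.delim write.table head modifyList packageVersion
#' @importFrom stats median quantile sd var setNames
NULL

## Stage/tissue vocabulary used throughout: five developmental stages
## (Gosner 23 .. Gosner 46) and three adult tissues.
CLASS_LEVELS <- c("G23", "G27", "G31", "G43", "G46", "brain", "liver", "gonad")
SEX_LEVELS <- c("XX", "XY")

#' Construct a counts matrix container
#'
#' Bundles a gene x sample matrix of non-negative integer read counts with
#' per-gene transcript lengths (bp), validating identifiers and invariants.
#'
#' @param counts integer matrix, genes in rows and samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param lengths positive integer vector of transcript lengths, one per gene,
#'   named by gene id (or unnamed in row order).
#' @return An object of class \code{counts_matrix}: a list with elements
#'   \code{counts} and \code{lengths}.
#' @export
counts_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ", rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample id: ", colnames(counts)[duplicated(colnames(counts))][1L])
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"  # keeps totals safe above .Machine$integer.max
  if (is.null(names(lengths))) {
    if (length(lengths) != nrow(counts)) stop("lengths must have one entry per gene")
    names(lengths) <- rownames(counts)
  }
  if (!all(rownames(counts) %in% names(lengths)))
    stop("lengths missing for some genes")
  lengths <- lengths[rownames(counts)]
  if (any(!is.finite(lengths)) || any(lengths < 3) || any(lengths != round(lengths)))
    stop("transcript lengths must be integers >= 3 bp")
  structure(list(counts = counts, lengths = as.numeric(lengths)),
            class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("counts_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Read a counts matrix from TSV
#'
#' Expects a header row of sample ids, gene ids in the first column, and an
#' optional \code{length} column giving transcript length in bp (1000 bp is
#' assumed for every gene when absent). Malformed input is rejected, never
#' coerced.
#'
#' @param path path to a tab-separated file.
#' @return A \code{\link{counts_matrix}}.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("counts file needs a gene id column plus >=1 sample")
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  df <- df[, -1L, drop = FALSE]
  len_col <- which(colnames(df) == "length")
  if (length(len_col)) {
    lengths <- df[[len_col]]
    df <- df[, -len_col, drop = FALSE]
  } else {
    lengths <- rep(1000, length(gene_ids))
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1L]
    stop("non-numeric counts in column '", colnames(df)[bad], "'")
  }
  bad <- which(m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  rownames(m) <- gene_ids
  counts_matrix(m, setNames(as.numeric(lengths), gene_ids))
}

#' Write a counts matrix to TSV
#'
#' Canonical form: gene ids in a \code{gene_id} first column, then a
#' \code{length} column, then samples in stored order. \code{write_counts}
#' followed by \code{\link{read_counts}} is the identity.
#'
#' @param x a \code{\link{counts_matrix}}.
#' @param path output path.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "counts_matrix"))
  df <- data.frame(gene_id = rownames(x$counts),
                   length = format(x$lengths, scientific = FALSE, trim = TRUE),
                   format(x$counts, scientific = FALSE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects tab-separated columns \code{sample_id}, \code{class}, \code{sex},
#' \code{replicate}. Class must be one of the five developmental stages
#' (G23, G27, G31, G43, G46) or adult tissues (brain, liver, gonad); sex is
#' the genetic sex (XX or XY).
#'
#' @param path path to the TSV.
#' @param counts optional \code{\link{counts_matrix}} to cross-check sample ids
#'   against (every counts sample must appear exactly once).
#' @return data.frame with validated columns.
#' @export
read_sample_table <- function(path, counts = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  validate_sample_table(df, counts)
}

#' Validate a sample metadata table
#'
#' @param df data.frame with columns sample_id, class, sex, replicate.
#' @param counts optional \code{\link{counts_matrix}} for cross-checking.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validate_sample_table <- function(df, counts = NULL) {
  need <- c("sample_id", "class", "sex", "replicate")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample table missing columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$replicate <- as.character(df$replicate)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1L])
  bad <- setdiff(unique(df$class), CLASS_LEVELS)
  if (length(bad))
    stop("unknown class '", bad[1L], "'; allowed: ", paste(CLASS_LEVELS, collapse = ", "))
  bad <- setdiff(unique(df$sex), SEX_LEVELS)
  if (length(bad))
    stop("unknown sex '", bad[1L], "'; allowed: ", paste(SEX_LEVELS, collapse = ", "))
  if (!is.null(counts)) {
    missing_samples <- setdiff(colnames(counts$counts), df$sample_id)
    if (length(missing_samples))
      stop("sample in counts but absent from sample table: ", missing_samples[1L])
  }
  df
}

#' Write a sample table to TSV
#' @param df validated sample table.
#' @param path output path.
#' @export
write_sample_table <- function(df, path) {
  write.table(df[, c("sample_id", "class", "sex", "replicate")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

BLAST_COLS <- c("query_id", "subject_id", "pident", "aln_len", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore", "qlen", "slen")

#' Read tabular homology hits
#'
#' Parses BLAST tabular output in the extended 14-column form
#' \code{-outfmt "6 std qlen slen"}: the 12 standard columns plus query and
#' subject lengths, which the reciprocal-best-hit overlap criterion requires.
#'
#' @param path path to the tab-separated hit table (no header).
#' @return data.frame with one row per hit, columns named
#'   \code{query_id, subject_id, pident, aln_len, mismatch, gapopen, qstart,
#'   qend, sstart, send, evalue, bitscore, qlen, slen}.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(setNames(as.data.frame(lapply(BLAST_COLS, function(i) character(0))), BLAST_COLS))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 14L)) {
    i <- which(nf != 14L)[1L]
    stop(sprintf("line %d: expected 14 columns (outfmt '6 std qlen slen'), got %d",
                 i, nf[i]))
  }
  m <- do.call(rbind, parts)
  df <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                   stringsAsFactors = FALSE)
  num_cols <- 3:14
  for (j in num_cols) df[[BLAST_COLS[j]]] <- as.numeric(m[, j])
  if (anyNA(df[num_cols]))
    stop("non-numeric value in a numeric hit column")
  if (any(df$evalue < 0)) stop("negative e-value")
  if (any(df$pident < 0 | df$pident > 100)) stop("pident outside [0,100]")
  df
}

#' Write tabular homology hits
#' @param hits data.frame as returned by \code{\link{read_blast_tab}}.
#' @param path output path.
#' @export
write_blast_tab <- function(hits, path) {
  df <- hits[, BLAST_COLS]
  df$evalue <- format(df$evalue, scientific = TRUE, digits = 3, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read paired codon sequences from FASTA
#'
#' Pairs are encoded as consecutive records \code{<id>|a} and \code{<id>|b}.
#'
#' @param path FASTA path.
#' @return named list of pairs; each element is \code{list(id, seq_a, seq_b)}.
#' @export
read_codon_pairs <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  base <- sub("\\|[ab]$", "", nm)
  tag <- sub("^.*\\|", "", nm)
  if (!all(tag %in% c("a", "b")))
    stop("codon-pair FASTA records must be named <id>|a and <id>|b")
  ids <- unique(base)
  lapply(setNames(ids, ids), function(id) {
    a <- as.character(ss[[which(base == id & tag == "a")[1L]]])
    b <- as.character(ss[[which(base == id & tag == "b")[1L]]])
    list(id = id, seq_a = a, seq_b = b)
  })
}

#' Write paired codon sequences to FASTA
#' @param pairs list as returned by \code{\link{read_codon_pairs}}.
#' @param path output path.
#' @export
write_codon_pairs <- function(pairs, path) {
  seqs <- do.call(c, unname(lapply(pairs, function(p) {
    setNames(c(p$seq_a, p$seq_b), paste0(p$id, c("|a", "|b")))
  })))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a result table with a provenance header
#'
#' Emits TSV with one leading comment line recording a config hash and seed,
#' so result files are traceable to the run that produced them.
#'
#' @param df result data.frame.
#' @param path output path.
#' @param seed integer seed used for the producing stage (NA if none).
#' @param config list; hashed (md5 of its deparsed form) into the header.
#' @export
write_result_tsv <- function(df, path, seed = NA_integer_, config = list()) {
  hash <- substr(digest_config(config), 1, 12)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ranabias config_hash=%s seed=%s", hash, seed), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config, control = "all"), tmp)
  unname(tools::md5sum(tmp))
}
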