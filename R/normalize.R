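#' Counts per million
#'
#' @param counts numeric gene x sample matrix.
#' @param lib_sizes library sizes; defaults to column sums. Pass effective
#'   (TMM-adjusted) sizes for normalized CPM.
#' @return gene x sample CPM matrix.
#' @export
cpm_matrix <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' Reads per kilobase per million
#'
#' @inheritParams cpm_matrix
#' @param lengths transcript lengths in bp, one per gene.
#' @return gene x sample RPKM matrix.
#' @export
rpkm_matrix <- function(counts, lengths, lib_sizes = colSums(counts)) {
  cpm_matrix(counts, lib_sizes) / (lengths / 1e3)
}

#' Transcripts per million
#'
#' Length-normalized rates rescaled so each sample sums to one million.
#'
#' @inheritParams rpkm_matrix
#' @return gene x sample TPM matrix.
#' @export
tpm_matrix <- function(counts, lengths) {
  rate <- counts / lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Trimmed mean of M-values scaling factors
#'
#' Between-sample scaling factors that minimize log-fold changes between
#' libraries: for each sample versus a reference, gene-wise log-ratios (M) and
#' mean abundances (A) are computed on library-size-normalized counts, the most
#' extreme 30\% of M and 5\% of A are trimmed (two-sided), and the factor is
#' the weighted mean of the surviving M-values with inverse asymptotic
#' (binomial) variance weights. Factors are rescaled to geometric mean 1. The
#' reference is the sample whose CPM upper quartile is closest to the mean
#' upper quartile.
#'
#' @param counts numeric gene x sample matrix (>= 2 samples).
#' @param ref_sample reference column name or index, or \code{"auto"}.
#' @param logratio_trim,abundance_trim two-sided trim fractions for M and A.
#' @return named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = "auto",
                        logratio_trim = 0.3, abundance_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  if (any(colSums(counts > 0) < 2L))
    stop("degenerate sample with <2 expressed genes")
  lib <- colSums(counts)
  uq <- apply(cpm_matrix(counts), 2, quantile, probs = 0.75)
  r <- if (identical(ref_sample, "auto")) which.min(abs(uq - mean(uq))) else ref_sample
  if (is.character(r)) r <- match(r, colnames(counts))
  yr <- counts[, r]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == r) return(1)
    y <- counts[, j]
    keep <- y > 0 & yr > 0
    if (!any(keep)) stop("no genes shared with the reference sample")
    y1 <- y[keep]; y2 <- yr[keep]
    m <- log2((y1 / lib[j]) / (y2 / lib[r]))
    a <- 0.5 * log2((y1 / lib[j]) * (y2 / lib[r]))
    w <- (lib[j] - y1) / (lib[j] * y1) + (lib[r] - y2) / (lib[r] * y2)
    n <- length(m)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
    rm_ <- rank(m, ties.method = "first"); ra <- rank(a, ties.method = "first")
    use <- rm_ >= loM & rm_ <= hiM & ra >= loA & ra <= hiA
    if (!any(use)) return(1)
    2 ^ (sum(m[use] / w[use]) / sum(1 / w[use]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Filter to expressed genes within a stage or tissue
#'
#' A gene is kept when its mean log2(CPM) across the class's samples exceeds 0
#' and its CPM exceeds 1 in at least half of the samples of each genetic sex.
#' CPM here is computed before TMM scaling (filtering precedes normalization).
#'
#' @param x a \code{\link{counts_matrix}}.
#' @param samples validated sample table.
#' @param class one of the stage/tissue classes.
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(x, samples, class) {
  sel <- samples[samples$class == class, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no samples in class '", class, "'")
  for (s in SEX_LEVELS)
    if (sum(sel$sex == s) < 2L)
      stop("class '", class, "' needs >=2 replicates of sex ", s)
  cm <- x$counts[, sel$sample_id, drop = FALSE]
  cpm <- cpm_matrix(cm)
  mean_logcpm <- rowMeans(log2(cpm))          # -Inf when any sample is zero
  keep <- is.finite(mean_logcpm) & mean_logcpm > 0
  for (s in SEX_LEVELS) {
    cols <- sel$sample_id[sel$sex == s]
    frac <- rowMeans(cpm[, cols, drop = FALSE] > 1)
    keep <- keep & frac >= 0.5
  }
  rownames(cm)[keep]
}
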