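#' Chi-square test for an excess of one bias direction
#'
#' One-degree-of-freedom goodness-of-fit of the female/male biased gene counts
#' against a 50:50 expectation, without continuity correction.
#'
#' @param n_female,n_male non-negative integer counts.
#' @return list with \code{chi2} and \code{pvalue}.
#' @export
chi_square_excess <- function(n_female, n_male) {
  if (n_female < 0 || n_male < 0) stop("counts must be non-negative")
  n <- n_female + n_male
  if (n == 0) stop("both counts are zero")
  e <- n / 2
  chi2 <- (n_female - e)^2 / e + (n_male - e)^2 / e
  list(chi2 = chi2, pvalue = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Excess-direction tests across fold-change thresholds
#'
#' Tabulates female- and male-biased gene counts at the FDR-only threshold and
#' at cumulative fold-change cut-offs (FC >= 2, 4, 8 on the sex-bias calls),
#' with a chi-square test of directional excess at each.
#'
#' @param sexbias per-gene records from \code{\link{call_sex_bias}}.
#' @return data.frame \code{class, threshold, n_female, n_male, chi2, pvalue};
#'   rows with zero biased genes carry NA statistics.
#' @export
excess_table <- function(sexbias) {
  cls <- sexbias$class[1]
  ## FDR_only relaxes the fold-change gate, keeping the FDR criterion
  sets <- list(FDR_only = sexbias$qvalue < 0.05,
               FC2 = sexbias$biased & abs(sexbias$log2fc) >= 1,
               FC4 = sexbias$biased & abs(sexbias$log2fc) >= 2,
               FC8 = sexbias$biased & abs(sexbias$log2fc) >= 3)
  rows <- lapply(names(sets), function(th) {
    sel <- sets[[th]]
    nf <- sum(sel & sexbias$log2fc < 0)
    nm <- sum(sel & sexbias$log2fc > 0)
    if (nf + nm == 0)
      return(data.frame(class = cls, threshold = th, n_female = 0L, n_male = 0L,
                        chi2 = NA_real_, pvalue = NA_real_))
    ct <- chi_square_excess(nf, nm)
    data.frame(class = cls, threshold = th, n_female = nf, n_male = nm,
               chi2 = ct$chi2, pvalue = ct$pvalue)
  })
  do.call(rbind, rows)
}

#' Pseudo-count for sex-specific genes
#'
#' Replaces zero RPKM entries by one tenth of the minimum positive RPKM found
#' anywhere in the matrix, so genes expressed in only one sex enter the
#' fold-change analysis as extreme sex-biased genes instead of being dropped.
#' The operation is idempotent.
#'
#' @param rpkm gene x sample RPKM matrix with at least one positive entry.
#' @return adjusted matrix.
#' @export
apply_sexspecific_pseudocount <- function(rpkm) {
  pos <- rpkm[rpkm > 0]
  if (!length(pos)) stop("all-zero RPKM matrix")
  rpkm[rpkm == 0] <- min(pos) / 10
  rpkm
}

#' Expression-driver analysis across fold-change bins
#'
#' Collects sex-biased genes beyond each signed log2FC threshold
#' (1, 3, 5, 7 for male-biased; -1, -3, -5, -7 for female-biased; bins nest)
#' and reports the mean log2(RPKM) per sex in each bin, with two-sided
#' Wilcoxon rank-sum tests between successive bins within each sex and
#' between sexes within each bin. Distributions compared are the per-gene
#' per-sex mean log2 RPKM. Comparisons are flagged interpretable only when
#' both bin means are positive (negative mean log2 RPKM corresponds to raw
#' RPKM below 1).
#'
#' @param sexbias per-gene records from \code{\link{call_sex_bias}}.
#' @param rpkm gene x sample RPKM matrix (zeros already pseudo-counted),
#'   rows covering the biased genes.
#' @param samples validated sample table for the rpkm columns.
#' @param class stage/tissue analysed.
#' @param min_biased minimum biased genes for the class to qualify.
#' @return list with \code{bins} (data.frame: direction, threshold, n_genes,
#'   mean_log2rpkm_male, mean_log2rpkm_female, interpretable) and
#'   \code{tests} (data.frame of Wilcoxon comparisons), or NULL if skipped.
#' @export
driver_bins <- function(sexbias, rpkm, samples, class, min_biased = 100) {
  if (sum(sexbias$biased) < min_biased) {
    message(sprintf("class '%s': <%d sex-biased genes, skipping driver analysis",
                    class, min_biased))
    return(NULL)
  }
  sel <- samples[samples$class == class, , drop = FALSE]
  lr <- log2(rpkm[, sel$sample_id, drop = FALSE])
  gm <- rowMeans(lr[, sel$sex == "XY", drop = FALSE])
  gf <- rowMeans(lr[, sel$sex == "XX", drop = FALSE])
  thresholds <- c(1, 3, 5, 7)
  members <- list(); bins <- NULL
  for (dir in c("male", "female")) {
    sgn <- if (dir == "male") 1 else -1
    for (th in thresholds) {
      ids <- sexbias$gene_id[sexbias$biased & sgn * sexbias$log2fc >= th]
      ids <- intersect(ids, rownames(rpkm))
      key <- paste(dir, th, sep = ":")
      members[[key]] <- ids
      bins <- rbind(bins, data.frame(
        direction = dir, threshold = sgn * th, n_genes = length(ids),
        mean_log2rpkm_male = if (length(ids)) mean(gm[ids]) else NA_real_,
        mean_log2rpkm_female = if (length(ids)) mean(gf[ids]) else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  bins$interpretable <- !is.na(bins$mean_log2rpkm_male) &
    bins$mean_log2rpkm_male > 0 & bins$mean_log2rpkm_female > 0
  tests <- NULL
  wtest <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    if (all(c(a, b) == c(a, b)[1])) return(1)
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
  for (dir in c("male", "female")) {
    for (i in seq_len(length(thresholds) - 1L)) {
      a <- members[[paste(dir, thresholds[i], sep = ":")]]
      b <- members[[paste(dir, thresholds[i + 1L], sep = ":")]]
      for (sex in c("male", "female")) {
        v <- if (sex == "male") gm else gf
        tests <- rbind(tests, data.frame(
          comparison = "successive_bins", direction = dir, sex = sex,
          bin_a = thresholds[i], bin_b = thresholds[i + 1L],
          pvalue = wtest(v[a], v[b]), stringsAsFactors = FALSE))
      }
    }
    for (th in thresholds) {
      ids <- members[[paste(dir, th, sep = ":")]]
      tests <- rbind(tests, data.frame(
        comparison = "between_sexes", direction = dir, sex = NA_character_,
        bin_a = th, bin_b = th,
        pvalue = wtest(gm[ids], gf[ids]), stringsAsFactors = FALSE))
    }
  }
  list(bins = bins, tests = tests)
}
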