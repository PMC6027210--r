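## The 11 pooled stage/tissue expression classes used for specificity:
## gonadal differentiation begins around stage G31, so earlier stages and the
## two somatic adult tissues pool both sexes; later stages and the gonad are
## kept sex-limited (testis = XY gonad, ovary = XX gonad).
PROFILE_CLASSES <- c("G23", "G27", "G31", "brain", "liver",
                     "G43_female", "G43_male", "G46_female", "G46_male",
                     "testis", "ovary")

profile_class_of <- function(class, sex) {
  pooled <- c("G23", "G27", "G31", "brain", "liver")
  ifelse(class %in% pooled, class,
         ifelse(class == "gonad", ifelse(sex == "XY", "testis", "ovary"),
                paste0(class, ifelse(sex == "XY", "_male", "_female"))))
}

#' Pool per-sample TPM into the 11 stage/tissue expression classes
#'
#' Class value = mean TPM across the class's samples: both sexes for the five
#' sex-pooled classes (G23, G27, G31, brain, liver), a single genetic sex for
#' the six sex-limited ones (female/male G43, female/male G46, testis, ovary).
#'
#' @param tpm gene x sample TPM matrix.
#' @param samples validated sample table covering the columns of \code{tpm}.
#' @return gene x 11 matrix with columns in the fixed order
#'   \code{G23, G27, G31, brain, liver, G43_female, G43_male, G46_female,
#'   G46_male, testis, ovary}.
#' @export
pool_profiles <- function(tpm, samples) {
  samples <- samples[match(colnames(tpm), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stop("samples table does not cover all tpm columns")
  pc <- profile_class_of(samples$class, samples$sex)
  absent <- setdiff(PROFILE_CLASSES, unique(pc))
  if (length(absent))
    stop("missing stage/tissue classes: ", paste(absent, collapse = ", "))
  out <- vapply(PROFILE_CLASSES, function(k) {
    rowMeans(tpm[, pc == k, drop = FALSE])
  }, numeric(nrow(tpm)))
  dimnames(out) <- list(rownames(tpm), PROFILE_CLASSES)
  out
}

#' Tau tissue-specificity index
#'
#' \deqn{\tau = \sum_i [1 - \log(TPM_i)/\log(TPM_{max})] / (N - 1)}
#' over the N stage/tissue classes of a gene's pooled expression profile.
#' Values below 1 TPM are floored to 1 before taking logs (the index is
#' otherwise undefined for sub-1 TPM); the log base cancels. Tau is 0 for
#' perfectly uniform expression and 1 for expression confined to one class.
#' Genes with no class above 1 TPM have undefined Tau and return \code{NA}.
#'
#' @param profile numeric vector of class TPM values (length >= 2), or a
#'   gene x class matrix (one Tau per row).
#' @return numeric Tau in [0,1], or NA where undefined.
#' @export
tau <- function(profile) {
  if (is.matrix(profile)) return(apply(profile, 1, tau))
  if (any(profile < 0)) stop("TPM values must be non-negative")
  x <- pmax(profile, 1)
  mx <- max(x)
  if (mx <= 1) return(NA_real_)
  sum(1 - log(x) / log(mx)) / (length(x) - 1)
}

#' Tau with specificity calls
#'
#' @param profiles gene x class TPM matrix from \code{\link{pool_profiles}}.
#' @return data.frame with \code{gene_id, tau, specific_080, specific_090,
#'   max_class}; Tau is NA (and flags FALSE) for genes never above 1 TPM.
#' @export
tau_table <- function(profiles) {
  tv <- tau(profiles)
  data.frame(gene_id = rownames(profiles), tau = tv,
             specific_080 = !is.na(tv) & tv > 0.8,
             specific_090 = !is.na(tv) & tv > 0.9,
             max_class = colnames(profiles)[max.col(profiles, ties.method = "first")],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean Tau of the most expressed genes per class
#'
#' For each expression class, genes are ranked by that class's TPM (ties
#' broken by gene id for determinism) and the mean Tau of the top fraction is
#' reported, one row per class x fraction.
#'
#' @param profiles gene x class TPM matrix.
#' @param taus numeric Tau per gene (same order as profile rows); NAs excluded.
#' @param fractions numeric fractions in (0, 1].
#' @return data.frame \code{class, fraction, n_genes, mean_tau}.
#' @export
top_fraction_summary <- function(profiles, taus,
                                 fractions = c(0.10, 0.30, 0.70, 0.90)) {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0,1]")
  ok <- !is.na(taus)
  profiles <- profiles[ok, , drop = FALSE]
  taus <- taus[ok]
  out <- expand.grid(class = colnames(profiles), fraction = fractions,
                     stringsAsFactors = FALSE)
  out$n_genes <- 0L; out$mean_tau <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- profiles[, out$class[i]]
    ord <- order(-v, rownames(profiles))
    k <- max(1L, floor(out$fraction[i] * length(v)))
    idx <- ord[seq_len(k)]
    out$n_genes[i] <- k
    out$mean_tau[i] <- mean(taus[idx])
  }
  out
}

#' Spearman correlation between sex bias and tissue specificity
#'
#' Rank correlation between the magnitude of the log2 male/female ratio (or
#' the signed ratio with \code{signed = TRUE}) and Tau over genes expressed in
#' one class. Skipped (returns NULL with a message) when the class has fewer
#' than \code{min_biased} sex-biased genes.
#'
#' @param sexbias per-gene records from \code{\link{call_sex_bias}}.
#' @param taus data.frame from \code{\link{tau_table}}.
#' @param signed use signed log2FC instead of |log2FC|.
#' @param min_biased minimum number of biased genes for the class to qualify.
#' @return list with \code{rho}, \code{pvalue}, \code{n}, or NULL if skipped.
#' @export
spearman_bias_tau <- function(sexbias, taus, signed = FALSE, min_biased = 100) {
  if (sum(sexbias$biased) < min_biased) {
    message(sprintf("class '%s': %d sex-biased genes (<%d), skipping correlation",
                    sexbias$class[1], sum(sexbias$biased), min_biased))
    return(NULL)
  }
  m <- merge(sexbias, taus, by = "gene_id")
  m <- m[!is.na(m$tau), , drop = FALSE]
  v <- if (signed) m$log2fc else abs(m$log2fc)
  if (length(unique(v)) < 2L || length(unique(m$tau)) < 2L)
    stop("constant vector: Spearman correlation undefined")
  ct <- suppressWarnings(stats::cor.test(v, m$tau, method = "spearman"))
  list(rho = unname(ct$estimate), pvalue = ct$p.value, n = nrow(m))
}
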