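#' Moment estimate of a common negative-binomial dispersion
#'
#' Counts are first scaled to a common effective depth, then per-gene
#' within-group means and pooled variances feed the ratio estimator
#' \eqn{\hat\phi = \sum_g (v_g - m_g) / \sum_g m_g^2}, floored at 1e-4.
#'
#' @param counts gene x sample matrix of depth-equalized counts.
#' @param groups list of two integer/character vectors of columns.
#' @return scalar dispersion estimate (>= 1e-4).
#' @export
estimate_common_dispersion <- function(counts, groups) {
  num <- den <- 0
  for (g in groups) {
    cg <- counts[, g, drop = FALSE]
    if (ncol(cg) < 2L) next
    m <- rowMeans(cg)
    v <- apply(cg, 1, var)
    num <- num + sum((v - m) * (ncol(cg) - 1))
    den <- den + sum(m^2 * (ncol(cg) - 1))
  }
  if (den <= 0) return(1e-4)
  max(num / den, 1e-4)
}

#' Conditional exact-style negative-binomial test
#'
#' Two-sided per-gene test of equal NB means between two groups. Counts are
#' scaled to a common effective depth (geometric mean of effective library
#' sizes) and rounded; conditional on a gene's total, the group-A sum follows
#' a negative hypergeometric (Dirichlet-multinomial) law with shape
#' \eqn{n_A/\phi, n_B/\phi} under the null, free of the gene mean. The
#' two-sided p-value sums the probabilities of all outcomes no more likely
#' than the observed one. Genes with zero total get p = 1.
#'
#' @param counts gene x sample matrix (filtered genes).
#' @param group_a,group_b column names or indices of the two groups.
#' @param dispersion common NB dispersion, or \code{"auto"} for the moment
#'   estimate from the data.
#' @param eff_lib effective library sizes for all involved columns (library
#'   size times TMM factor); defaults to column sums of \code{counts}.
#' @return list with \code{pvalue} (per-gene vector), \code{dispersion} used,
#'   and \code{pseudo} depth-equalized counts.
#' @export
nb_exact_test <- function(counts, group_a, group_b, dispersion = "auto",
                          eff_lib = NULL) {
  counts <- as.matrix(counts)
  if (is.character(group_a)) group_a <- match(group_a, colnames(counts))
  if (is.character(group_b)) group_b <- match(group_b, colnames(counts))
  if (!length(group_a) || !length(group_b)) stop("both groups must be nonempty")
  cols <- c(group_a, group_b)
  if (is.null(eff_lib)) eff_lib <- colSums(counts)[cols] else eff_lib <- eff_lib[cols]
  if (any(eff_lib <= 0)) stop("effective library sizes must be positive")
  common <- exp(mean(log(eff_lib)))
  pseudo <- round(sweep(counts[, cols, drop = FALSE], 2, common / eff_lib, "*"))
  ia <- seq_along(group_a); ib <- length(group_a) + seq_along(group_b)
  if (identical(dispersion, "auto"))
    dispersion <- estimate_common_dispersion(pseudo, list(ia, ib))
  phi <- max(dispersion, 1e-4)
  sa <- rowSums(pseudo[, ia, drop = FALSE])
  sb <- rowSums(pseudo[, ib, drop = FALSE])
  na <- length(ia); nb <- length(ib)
  p <- vapply(seq_along(sa), function(i) {
    nb_exact_pvalue(sa[i], sb[i], na, nb, phi)
  }, numeric(1))
  list(pvalue = p, dispersion = phi, pseudo = pseudo)
}

## P(S_A = s | S_A + S_B = t) for iid NB samples with common dispersion phi:
## beta-binomial-type mass with shapes (na/phi, nb/phi); the NB success
## probability cancels under the null.
nb_cond_logpmf <- function(s, t, na, nb, phi) {
  a <- na / phi; b <- nb / phi
  (lgamma(a + s) - lgamma(s + 1) - lgamma(a)) +
    (lgamma(b + t - s) - lgamma(t - s + 1) - lgamma(b)) -
    (lgamma(a + b + t) - lgamma(t + 1) - lgamma(a + b))
}

nb_exact_pvalue <- function(sa, sb, na, nb, phi, max_exact = 2e5) {
  t <- sa + sb
  if (t == 0) return(1)
  if (t <= max_exact) {
    lp <- nb_cond_logpmf(0:t, t, na, nb, phi)
    obs <- lp[sa + 1]
    min(1, sum(exp(lp[lp <= obs + 1e-10])))
  } else {
    ## large totals: normal approximation to the conditional law
    a <- na / phi; b <- nb / phi
    mu <- t * a / (a + b)
    v <- t * a * b * (a + b + t) / ((a + b)^2 * (a + b + 1))
    z <- (abs(sa - mu) - 0.5) / sqrt(v)
    min(1, 2 * stats::pnorm(-max(z, 0)))
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment.
#'
#' @param p numeric vector of p-values in [0,1].
#' @return vector of q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Call sex-biased genes within one stage or tissue
#'
#' Filters to expressed genes, computes TMM-scaled effective library sizes,
#' tests XY versus XX samples with the conditional NB exact-style test,
#' adjusts p-values by Benjamini-Hochberg, and classifies bias. A gene is
#' sex-biased when q < \code{fdr} and |log2FC| >= \code{lfc}; log2FC is
#' log2 of (mean male CPM + prior) over (mean female CPM + prior), so
#' negative values are female-biased. Fold-change categories follow the
#' labels low (|FC| exactly 2), mild (2-4), high (4-8), very high (>= 8).
#'
#' @param x a \code{\link{counts_matrix}}.
#' @param samples validated sample table.
#' @param class stage/tissue to analyse.
#' @param fdr,lfc calling thresholds (defaults 0.05 and 1).
#' @param prior prior count added to each group mean CPM before the ratio.
#' @param dispersion passed to \code{\link{nb_exact_test}}.
#' @return data.frame of per-gene records: \code{gene_id, class, log2fc,
#'   pvalue, qvalue, biased, direction, category}.
#' @export
call_sex_bias <- function(x, samples, class, fdr = 0.05, lfc = 1,
                          prior = 0.5, dispersion = "auto") {
  keep <- filter_expressed(x, samples, class)
  sel <- samples[samples$class == class, , drop = FALSE]
  cm <- x$counts[keep, sel$sample_id, drop = FALSE]
  f <- tmm_factors(cm)
  eff <- colSums(cm) * f
  males <- sel$sample_id[sel$sex == "XY"]
  females <- sel$sample_id[sel$sex == "XX"]
  res <- nb_exact_test(cm, males, females, dispersion = dispersion, eff_lib = eff)
  cpm <- cpm_matrix(cm, eff)
  mu_m <- rowMeans(cpm[, males, drop = FALSE])
  mu_f <- rowMeans(cpm[, females, drop = FALSE])
  log2fc <- log2((mu_m + prior) / (mu_f + prior))
  q <- bh_adjust(res$pvalue)
  biased <- q < fdr & abs(log2fc) >= lfc
  direction <- ifelse(!biased, "none", ifelse(log2fc > 0, "male", "female"))
  category <- fold_change_category(log2fc, biased)
  data.frame(gene_id = keep, class = class, log2fc = log2fc,
             pvalue = res$pvalue, qvalue = q, biased = biased,
             direction = direction, category = category,
             row.names = NULL, stringsAsFactors = FALSE)
}

fold_change_category <- function(log2fc, biased) {
  fc <- 2^abs(log2fc)
  out <- rep("none", length(log2fc))
  out[biased & fc == 2] <- "low"
  out[biased & fc > 2 & fc < 4] <- "mild"
  out[biased & fc >= 4 & fc < 8] <- "high"
  out[biased & fc >= 8] <- "very_high"
  out
}
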