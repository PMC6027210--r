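## Standard genetic code, codons ordered T,C,A,G by position.
GC_BASES <- c("T", "C", "A", "G")
GC_AA <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1L]]
STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  e <- expand.grid(b3 = GC_BASES, b2 = GC_BASES, b1 = GC_BASES,
                   stringsAsFactors = FALSE)
  paste0(e$b1, e$b2, e$b3)
}

CODON_TABLE <- local({
  cods <- all_codons()
  setNames(GC_AA, cods)
})

codon_aa <- function(codon) unname(CODON_TABLE[codon])

## Synonymous site count per codon: per position, the fraction of the three
## single-nucleotide changes that preserve the amino acid (changes to stop
## codons count as nonsynonymous).
SYN_SITES <- local({
  cods <- setdiff(all_codons(), STOP_CODONS)
  vapply(setNames(cods, cods), function(cod) {
    aa <- codon_aa(cod)
    chars <- strsplit(cod, "")[[1L]]
    s <- 0
    for (pos in 1:3) for (nt in setdiff(GC_BASES, chars[pos])) {
      cand <- chars; cand[pos] <- nt
      cand <- paste(cand, collapse = "")
      if (!(cand %in% STOP_CODONS) && codon_aa(cand) == aa) s <- s + 1 / 3
    }
    s
  }, numeric(1))
})

## All orderings of the differing positions between two codons; paths through
## stop codons are dropped; syn/nonsyn step counts averaged over valid paths.
codon_path_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1L]]; b <- strsplit(c2, "")[[1L]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- list(1L)
  if (k == 2L) perms <- list(c(1L, 2L), c(2L, 1L))
  if (k == 3L) perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                             c(3,1,2), c(3,2,1))
  sds <- nds <- numeric(0)
  for (pm in perms) {
    cur <- a; sd <- nd <- 0; ok <- TRUE
    for (p in pos[pm]) {
      nxt <- cur; nxt[p] <- b[p]
      cod_cur <- paste(cur, collapse = ""); cod_nxt <- paste(nxt, collapse = "")
      if (cod_nxt %in% STOP_CODONS) { ok <- FALSE; break }
      if (codon_aa(cod_nxt) == codon_aa(cod_cur)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { sds <- c(sds, sd); nds <- c(nds, nd) }
  }
  if (!length(sds)) return(NULL)  # every pathway crosses a stop codon
  c(sd = mean(sds), nd = mean(nds))
}

#' Validate a pair of aligned codon sequences
#'
#' Upper-cases, checks equal length divisible by 3, restricts the alphabet to
#' A/C/G/T, strips a shared terminal stop codon, and rejects internal stops.
#'
#' @param seq_a,seq_b gap-free DNA strings.
#' @return list \code{seq_a, seq_b} of validated sequences.
#' @export
validate_codon_alignment <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences differ in length")
  if (nchar(seq_a) %% 3 != 0) stop("length not a multiple of 3")
  if (grepl("[^ACGT]", seq_a) || grepl("[^ACGT]", seq_b))
    stop("sequences must contain only A, C, G, T (no gaps or ambiguity codes)")
  split_codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  L <- length(ca)
  if (ca[L] %in% STOP_CODONS && cb[L] %in% STOP_CODONS) {
    ca <- ca[-L]; cb <- cb[-L]
  }
  if (any(ca %in% STOP_CODONS) || any(cb %in% STOP_CODONS))
    stop("internal stop codon")
  list(seq_a = paste(ca, collapse = ""), seq_b = paste(cb, collapse = ""))
}

#' Pairwise dN/dS by Nei-Gojobori (1986) counting
#'
#' Synonymous/nonsynonymous site fractions are computed per codon from the
#' universal code and averaged over the two sequences; observed differences
#' at multi-hit codons are averaged over all equally weighted substitution
#' pathways that avoid stop codons (codon pairs whose every pathway crosses a
#' stop are skipped and counted). Proportions are Jukes-Cantor corrected,
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}; the correction is undefined at
#' p >= 3/4 and the record is then flagged invalid. Omega = dN/dS is NA when
#' dS = 0.
#'
#' @param seq_a,seq_b aligned gap-free codon sequences (see
#'   \code{\link{validate_codon_alignment}}).
#' @param id identifier carried into the record.
#' @return one-row data.frame: \code{id, n_codons, skipped_codons, S_sites,
#'   N_sites, Sd, Nd, pS, pN, dS, dN, omega, valid}.
#' @export
ng86_dnds <- function(seq_a, seq_b, id = NA_character_) {
  v <- validate_codon_alignment(seq_a, seq_b)
  ca <- substring(v$seq_a, seq(1, nchar(v$seq_a), 3), seq(3, nchar(v$seq_a), 3))
  cb <- substring(v$seq_b, seq(1, nchar(v$seq_b), 3), seq(3, nchar(v$seq_b), 3))
  S <- N <- Sd <- Nd <- 0
  skipped <- 0L; used <- 0L
  for (i in seq_along(ca)) {
    d <- codon_path_diffs(ca[i], cb[i])
    if (is.null(d)) { skipped <- skipped + 1L; next }
    used <- used + 1L
    s_i <- (SYN_SITES[ca[i]] + SYN_SITES[cb[i]]) / 2
    S <- S + s_i; N <- N + (3 - s_i)
    Sd <- Sd + d["sd"]; Nd <- Nd + d["nd"]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  valid <- !is.na(dS) && !is.na(dN)
  omega <- if (valid && dS > 0) dN / dS else NA_real_
  data.frame(id = id, n_codons = used, skipped_codons = skipped,
             S_sites = S, N_sites = N, Sd = unname(Sd), Nd = unname(Nd),
             pS = unname(pS), pN = unname(pN), dS = dS, dN = dN,
             omega = omega, valid = valid,
             row.names = NULL, stringsAsFactors = FALSE)
}

jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' dN/dS for a list of codon pairs
#'
#' @param pairs list of \code{list(id, seq_a, seq_b)} as produced by
#'   \code{\link{read_codon_pairs}} or \code{\link{simulate_orthologs}}.
#' @return data.frame of \code{\link{ng86_dnds}} records.
#' @export
dnds_table <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) ng86_dnds(p$seq_a, p$seq_b, p$id)))
}

#' Linear model of evolutionary rate on sex bias and tissue specificity
#'
#' Ordinary least squares of sqrt(dN/dS) on a 3-level sex-bias factor
#' (unbiased/male/female, or the continuous log2FC with
#' \code{continuous = TRUE}), Tau, and their interaction, followed by F-type
#' drop-term tests: the interaction against the full model, then each main
#' effect against the additive model.
#'
#' @param omega non-negative dN/dS values (NA excluded).
#' @param bias character vector in \code{male, female, unbiased} (or numeric
#'   log2FC when \code{continuous}).
#' @param tau_values Tau per observation.
#' @param continuous treat \code{bias} as a continuous covariate.
#' @param min_per_class minimum observations per bias class.
#' @return list with \code{fit} (the full \code{lm}), \code{coefficients},
#'   and \code{drop_tests} (data.frame \code{term, df, F, pvalue}).
#' @export
sqrt_lm <- function(omega, bias, tau_values, continuous = FALSE,
                    min_per_class = 10) {
  ok <- !is.na(omega) & !is.na(tau_values) & !is.na(bias)
  d <- data.frame(y = sqrt(omega[ok]), tau = tau_values[ok])
  if (continuous) {
    d$bias <- as.numeric(bias[ok])
  } else {
    b <- as.character(bias[ok])
    bad <- setdiff(unique(b), c("male", "female", "unbiased", "none"))
    if (length(bad)) stop("unknown bias class '", bad[1], "'")
    b[b == "none"] <- "unbiased"
    cnt <- table(b)
    if (any(cnt < min_per_class))
      stop("need >= ", min_per_class, " observations per bias class; ",
           names(cnt)[which.min(cnt)], " has ", min(cnt))
    fb <- factor(b)
    if ("unbiased" %in% levels(fb)) fb <- stats::relevel(fb, ref = "unbiased")
    d$bias <- fb
  }
  if (any(d$y < 0) || any(!is.finite(d$y))) stop("omega must be finite and >= 0")
  full <- stats::lm(y ~ bias * tau, data = d)
  if (anyNA(stats::coef(full))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))][1]
    stop("rank-deficient design; collinear term: ", bad)
  }
  additive <- stats::lm(y ~ bias + tau, data = d)
  only_tau <- stats::lm(y ~ tau, data = d)
  only_bias <- stats::lm(y ~ bias, data = d)
  ftest <- function(reduced, larger, term) {
    a <- stats::anova(reduced, larger)
    data.frame(term = term, df = a$Df[2], F = a$F[2], pvalue = a$`Pr(>F)`[2],
               stringsAsFactors = FALSE)
  }
  drops <- rbind(ftest(additive, full, "bias:tau"),
                 ftest(only_tau, additive, "bias"),
                 ftest(only_bias, additive, "tau"))
  list(fit = full, coefficients = summary(full)$coefficients,
       drop_tests = drops)
}

#' Pairwise Wilcoxon comparison of dN/dS between gene groups
#'
#' Two-sided rank-sum tests for each pair of groups (e.g. male-biased /
#' female-biased / unbiased, or sex-linked / autosomal). Invalid or NA omega
#' values are excluded with a message; single-member groups are skipped.
#'
#' @param omega numeric dN/dS values.
#' @param groups parallel character vector of group labels.
#' @return data.frame \code{group_a, group_b, n_a, n_b, median_a, median_b,
#'   pvalue}.
#' @export
dnds_group_compare <- function(omega, groups) {
  ok <- !is.na(omega)
  if (sum(!ok)) message(sum(!ok), " NA/invalid omega values excluded")
  for (g in unique(groups))
    if (!any(ok & groups == g)) stop("group '", g, "' has no valid omega values")
  omega <- omega[ok]; groups <- as.character(groups[ok])
  gl <- split(omega, groups)
  nm <- names(gl)
  out <- NULL
  for (i in seq_len(length(nm) - 1L)) for (j in seq((i + 1L), length(nm))) {
    a <- gl[[i]]; b <- gl[[j]]
    if (length(a) < 2L || length(b) < 2L) {
      message("group with a single member, skipping ", nm[i], " vs ", nm[j])
      next
    }
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    out <- rbind(out, data.frame(group_a = nm[i], group_b = nm[j],
                                 n_a = length(a), n_b = length(b),
                                 median_a = median(a), median_b = median(b),
                                 pvalue = p, stringsAsFactors = FALSE))
  }
  out
}
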