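#' Reciprocal-best-hit ortholog assignment
#'
#' The best hit per query is the lowest e-value (ties broken by highest
#' bitscore, then lexicographic subject id). A pair is accepted when the two
#' tables name each other as best hits and the forward hit satisfies
#' e-value < \code{max_evalue}, alignment covering at least \code{min_overlap}
#' of both query and subject lengths, and percent identity of at least
#' \code{min_pident}.
#'
#' @param hits_ab,hits_ba hit tables from \code{\link{read_blast_tab}} for the
#'   two blast directions.
#' @param subject_info optional data.frame \code{ortholog_id, chromosome,
#'   position} placing subjects on a genome; unknown subjects get NA.
#' @param max_evalue,min_overlap,min_pident acceptance thresholds
#'   (defaults 1e-10, 0.5, 40).
#' @return data.frame \code{gene_id, ortholog_id, chromosome, position,
#'   pident, evalue, overlap_q, overlap_s}; a one-to-one matching.
#' @export
rbh_orthologs <- function(hits_ab, hits_ba, subject_info = NULL,
                          max_evalue = 1e-10, min_overlap = 0.5,
                          min_pident = 40) {
  if (is.null(hits_ab) || is.null(hits_ba)) stop("both hit tables are required")
  best_ab <- best_hits(hits_ab)
  best_ba <- best_hits(hits_ba)
  back <- setNames(best_ba$subject_id, best_ba$query_id)
  reciprocal <- !is.na(back[best_ab$subject_id]) &
    back[best_ab$subject_id] == best_ab$query_id
  h <- best_ab[reciprocal, , drop = FALSE]
  ovq <- h$aln_len / h$qlen
  ovs <- h$aln_len / h$slen
  pass <- h$evalue < max_evalue & ovq >= min_overlap & ovs >= min_overlap &
    h$pident >= min_pident
  h <- h[pass, , drop = FALSE]
  out <- data.frame(gene_id = h$query_id, ortholog_id = h$subject_id,
                    chromosome = rep(NA_integer_, nrow(h)),
                    position = rep(NA_integer_, nrow(h)),
                    pident = h$pident, evalue = h$evalue,
                    overlap_q = ovq[pass], overlap_s = ovs[pass],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(subject_info)) {
    i <- match(out$ortholog_id, subject_info$ortholog_id)
    out$chromosome <- subject_info$chromosome[i]
    out$position <- subject_info$position[i]
  }
  out[order(out$gene_id), , drop = FALSE]
}

best_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  ord <- order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Permutation test for per-chromosome enrichment of sex-biased genes
#'
#' For each chromosome, the number of assigned genes on it is drawn without
#' replacement from all assigned genes \code{n_perm} times, giving a null
#' distribution of biased-gene counts per direction. The one-sided p-value is
#' \code{(1 + draws >= observed) / (1 + n_perm)}; Bonferroni adjusts within
#' the family chromosomes x directions.
#'
#' @param sexbias per-gene records from \code{\link{call_sex_bias}}.
#' @param assignments data.frame from \code{\link{rbh_orthologs}} with
#'   non-NA chromosomes; only genes present in both tables are used.
#' @param n_perm number of permutations (>= 1000).
#' @param seed integer seed for the draws.
#' @param keep_null also return the per-chromosome null count draws (for
#'   calibration diagnostics).
#' @return data.frame \code{chromosome, direction, n_assigned, n_observed,
#'   p_perm, p_bonf}; with \code{keep_null}, a list \code{result, null} where
#'   \code{null[[chr]]} is an n_perm x 2 matrix of male/female null counts.
#' @export
enrichment_permutation <- function(sexbias, assignments, n_perm = 10000,
                                   seed = 1L, keep_null = FALSE) {
  if (n_perm < 1000) stop("n_perm must be at least 1000")
  a <- assignments[!is.na(assignments$chromosome), , drop = FALSE]
  m <- merge(sexbias[, c("gene_id", "direction")], a[, c("gene_id", "chromosome")],
             by = "gene_id")
  if (!nrow(m)) stop("no tested gene has a chromosome assignment")
  is_m <- m$direction == "male"
  is_f <- m$direction == "female"
  chroms <- sort(unique(m$chromosome))
  G <- nrow(m)
  set.seed(seed)
  rows <- list(); nulls <- list()
  for (ch in chroms) {
    on_ch <- m$chromosome == ch
    nc <- sum(on_ch)
    if (nc == 0L) { message("chromosome ", ch, " has no assigned genes, skipped"); next }
    obs_m <- sum(is_m & on_ch); obs_f <- sum(is_f & on_ch)
    null_m <- integer(n_perm); null_f <- integer(n_perm)
    for (i in seq_len(n_perm)) {
      draw <- sample.int(G, nc)
      null_m[i] <- sum(is_m[draw]); null_f[i] <- sum(is_f[draw])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = ch, direction = c("male", "female"),
      n_assigned = nc, n_observed = c(obs_m, obs_f),
      p_perm = c((1 + sum(null_m >= obs_m)) / (1 + n_perm),
                 (1 + sum(null_f >= obs_f)) / (1 + n_perm)))
    if (keep_null)
      nulls[[as.character(ch)]] <- cbind(male = null_m, female = null_f)
  }
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, out$p_perm * nrow(out))
  if (keep_null) list(result = out, null = nulls) else out
}

#' Wilcoxon comparison of expression sex-ratio between strata
#'
#' Two-sided rank-sum tests of per-gene log2 male/female ratios on the sex
#' chromosomes (1 and 2: jointly and each separately) against all autosomes.
#'
#' @param sexbias per-gene records with \code{log2fc}.
#' @param assignments chromosome assignments (\code{gene_id, chromosome}).
#' @param sex_chromosomes integer ids of the sex-linked chromosomes.
#' @return data.frame \code{stratum, n_sex, n_auto, pvalue}.
#' @export
ratio_wilcoxon <- function(sexbias, assignments, sex_chromosomes = c(1L, 2L)) {
  m <- merge(sexbias[, c("gene_id", "log2fc")],
             assignments[, c("gene_id", "chromosome")], by = "gene_id")
  m <- m[!is.na(m$chromosome), , drop = FALSE]
  auto <- m$log2fc[!(m$chromosome %in% sex_chromosomes)]
  strata <- c(list(joint = sex_chromosomes), as.list(setNames(sex_chromosomes,
              paste0("chr", sex_chromosomes))))
  rows <- lapply(names(strata), function(nm) {
    sx <- m$log2fc[m$chromosome %in% strata[[nm]]]
    if (!length(sx) || !length(auto)) stop("empty stratum in ratio comparison")
    data.frame(stratum = nm, n_sex = length(sx), n_auto = length(auto),
               pvalue = suppressWarnings(stats::wilcox.test(sx, auto)$p.value))
  })
  do.call(rbind, rows)
}

#' Sliding-window means along chromosomes
#'
#' Step-1 rolling means over exactly \code{window} genes ordered by position;
#' windows never span chromosomes. Chromosomes with fewer genes than the
#' window produce no output.
#'
#' @param values named numeric vector (names = gene ids).
#' @param assignments data.frame \code{gene_id, chromosome, position}.
#' @param window window size in genes (default 40).
#' @return data.frame \code{chromosome, window_start_index, center_position,
#'   mean_value}.
#' @export
sliding_window <- function(values, assignments, window = 40) {
  a <- assignments[!is.na(assignments$chromosome) &
                     assignments$gene_id %in% names(values), , drop = FALSE]
  a <- a[order(a$chromosome, a$position, a$gene_id), , drop = FALSE]
  rows <- lapply(sort(unique(a$chromosome)), function(ch) {
    sub <- a[a$chromosome == ch, , drop = FALSE]
    if (nrow(sub) < window) {
      message("chromosome ", ch, ": ", nrow(sub), " genes < window ", window,
              ", no windows")
      return(NULL)
    }
    mv <- zoo::rollmean(values[sub$gene_id], k = window, align = "left")
    cp <- zoo::rollmean(as.numeric(sub$position), k = window, align = "left")
    data.frame(chromosome = ch, window_start_index = seq_along(mv),
               center_position = cp, mean_value = as.numeric(mv),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chromosome = integer(0), window_start_index = integer(0),
                      center_position = numeric(0), mean_value = numeric(0))
  out
}
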