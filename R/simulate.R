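#' Simulation configuration
#'
#' Defaults emulate the multi-stage, multi-tissue study design: eight
#' stage/tissue classes sampled in both genetic sexes, log-normal gene
#' abundances, negative-binomial counts with a common dispersion, a fraction
#' of genes sex-biased in exactly one class with symmetric half-effects per
#' sex, a 10-chromosome map with optional enrichment of biased genes on the
#' sex chromosomes (1 and 2), and codon-pair sequences with known omega.
#'
#' @param n_genes number of genes.
#' @param n_rep replicates per (class, sex) cell (>= 2).
#' @param baseline_log_mean,baseline_log_sd natural-log mean/sd of gene
#'   baseline expression (log-normal).
#' @param nb_dispersion common NB dispersion (variance = mu + phi mu^2).
#' @param depth_log_sd log-sd of per-library depth multipliers.
#' @param biased_fraction named per-class fractions of genes sex-biased in
#'   that class; must sum to <= 1 across classes.
#' @param lfc_range range of |log2FC| effect sizes (uniform).
#' @param sexspecific_fraction fraction of biased genes expressed in one sex
#'   only (mean 0 in the other).
#' @param n_chromosomes number of chromosomes (sex chromosomes are 1 and 2).
#' @param chrom_size chromosome length in bp (equal sizes; uniform positions).
#' @param sexchrom_enrichment relative odds (>= 1) that a biased gene lands on
#'   chromosome 1 or 2.
#' @param p_mappable probability a gene has a reciprocal-best ortholog pair.
#' @param decoy_fraction fraction of genes receiving decoy homology hits.
#' @param omega_grid true dN/dS values for simulated codon pairs.
#' @param n_pairs_per_omega codon pairs per omega value.
#' @param n_codons codons per simulated sequence.
#' @param divergence expected proposed mutations per nucleotide site per
#'   branch.
#' @param seed integer seed; fully determines all outputs.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000,
                       n_rep = 4,
                       baseline_log_mean = log(100),
                       baseline_log_sd = 1.2,
                       nb_dispersion = 0.1,
                       depth_log_sd = 0.15,
                       biased_fraction = c(G23 = 0.005, G27 = 0.005,
                                           G31 = 0.005, G43 = 0.02,
                                           G46 = 0.15, brain = 0.02,
                                           liver = 0.02, gonad = 0.25),
                       lfc_range = c(1, 4),
                       sexspecific_fraction = 0.05,
                       n_chromosomes = 10,
                       chrom_size = 1e8,
                       sexchrom_enrichment = 1,
                       p_mappable = 0.9,
                       decoy_fraction = 0.2,
                       omega_grid = c(0.1, 0.2, 0.5),
                       n_pairs_per_omega = 5,
                       n_codons = 300,
                       divergence = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (any(cfg$biased_fraction < 0) || sum(cfg$biased_fraction) > 1)
    stop("biased fractions must be in [0,1] and sum to <= 1")
  if (cfg$sexspecific_fraction < 0 || cfg$sexspecific_fraction > 1)
    stop("sexspecific_fraction must be in [0,1]")
  if (cfg$nb_dispersion <= 0) stop("dispersion must be positive")
  if (cfg$n_rep < 2) stop("need >= 2 replicates per (class, sex) cell")
  if (cfg$sexchrom_enrichment < 1) stop("sexchrom_enrichment must be >= 1")
  bad <- setdiff(names(cfg$biased_fraction), CLASS_LEVELS)
  if (length(bad)) stop("unknown class in biased_fraction: ", bad[1])
  structure(cfg, class = "sim_config")
}

#' Simulate a counts matrix with implanted sex bias
#'
#' Counts are NB(mean = depth x gene mean x sex effect, common dispersion).
#' A gene biased in a class has its male/female means multiplied by
#' \eqn{2^{\pm lfc/2}} in that class only, so the unbiased mean is the
#' geometric midpoint; sex-specific genes have mean 0 in the disfavored sex.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{counts} (a \code{\link{counts_matrix}}),
#'   \code{samples} (sample table), and \code{truth} (per-gene data.frame:
#'   \code{gene_id, bias_class, true_direction, true_lfc, sex_specific,
#'   chromosome, position}).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  gene_mean <- stats::rlnorm(n, cfg$baseline_log_mean, cfg$baseline_log_sd)
  lengths <- pmax(300, round(stats::rlnorm(n, log(1500), 0.4)))

  frac <- cfg$biased_fraction
  probs <- c(frac, none = 1 - sum(frac))
  bias_class <- sample(names(probs), n, replace = TRUE, prob = probs)
  biased <- bias_class != "none"
  direction <- rep("none", n)
  direction[biased] <- sample(c("male", "female"), sum(biased), replace = TRUE)
  true_lfc <- numeric(n)
  true_lfc[biased] <- stats::runif(sum(biased), cfg$lfc_range[1], cfg$lfc_range[2])
  sex_specific <- rep(FALSE, n)
  sex_specific[biased] <- stats::runif(sum(biased)) < cfg$sexspecific_fraction

  w <- rep(1, cfg$n_chromosomes)
  wb <- w; wb[1:2] <- cfg$sexchrom_enrichment
  chromosome <- integer(n)
  chromosome[!biased] <- sample.int(cfg$n_chromosomes, sum(!biased),
                                    replace = TRUE, prob = w)
  chromosome[biased] <- sample.int(cfg$n_chromosomes, sum(biased),
                                   replace = TRUE, prob = wb)
  position <- sample.int(cfg$chrom_size, n, replace = TRUE)

  samples <- expand.grid(replicate = sprintf("r%d", seq_len(cfg$n_rep)),
                         sex = SEX_LEVELS, class = CLASS_LEVELS,
                         stringsAsFactors = FALSE)[, 3:1]
  samples$sample_id <- sprintf("%s_%s_%s", samples$class, samples$sex,
                               samples$replicate)
  depth <- stats::rlnorm(nrow(samples), 0, cfg$depth_log_sd)

  counts <- matrix(0, n, nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    eff <- rep(1, n)
    hit <- biased & bias_class == samples$class[j]
    if (any(hit)) {
      up_male <- direction == "male"
      is_male <- samples$sex[j] == "XY"
      favored <- hit & (up_male == is_male)
      disfavored <- hit & (up_male != is_male)
      eff[favored] <- 2^(true_lfc[favored] / 2)
      eff[disfavored] <- 2^(-true_lfc[disfavored] / 2)
      eff[disfavored & sex_specific] <- 0
    }
    mu <- depth[j] * gene_mean * eff
    counts[, j] <- stats::rnbinom(n, size = 1 / cfg$nb_dispersion, mu = mu)
  }
  truth <- data.frame(gene_id = gene_ids, bias_class = bias_class,
                      true_direction = direction, true_lfc = true_lfc,
                      sex_specific = sex_specific, chromosome = chromosome,
                      position = position, stringsAsFactors = FALSE)
  list(counts = counts_matrix(counts, setNames(lengths, gene_ids)),
       samples = validate_sample_table(samples), truth = truth)
}

#' Simulate diverged codon-sequence pairs with known omega
#'
#' An ancestral stop-free codon sequence is mutated independently along two
#' branches: point substitutions are proposed uniformly over sites, accepted
#' with probability 1 when synonymous and \code{omega} when nonsynonymous,
#' and never allowed to create a stop codon.
#'
#' @param cfg a \code{\link{sim_config}} (uses \code{omega_grid,
#'   n_pairs_per_omega, n_codons, divergence, seed}).
#' @return list with \code{pairs} (list of \code{id, seq_a, seq_b}) and
#'   \code{truth} (data.frame \code{id, true_omega}).
#' @export
simulate_orthologs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!length(cfg$omega_grid)) stop("omega_grid must be nonempty")
  exp_ps <- 0.75 * (1 - exp(-8 * cfg$divergence / 3))
  if (exp_ps >= 0.7499)
    stop("requested divergence implies pS >= 0.75; Jukes-Cantor correction undefined")
  set.seed(cfg$seed + 1L)
  sense <- setdiff(all_codons(), STOP_CODONS)
  pairs <- list(); truth <- NULL
  for (w in cfg$omega_grid) {
    for (k in seq_len(cfg$n_pairs_per_omega)) {
      anc <- sample(sense, cfg$n_codons, replace = TRUE)
      id <- sprintf("pair_w%s_%02d", format(w), k)
      pairs[[id]] <- list(id = id,
                          seq_a = paste(evolve_branch(anc, w, cfg$divergence),
                                        collapse = ""),
                          seq_b = paste(evolve_branch(anc, w, cfg$divergence),
                                        collapse = ""))
      truth <- rbind(truth, data.frame(id = id, true_omega = w,
                                       stringsAsFactors = FALSE))
    }
  }
  list(pairs = pairs, truth = truth)
}

evolve_branch <- function(codons, omega, divergence) {
  nsite <- 3L * length(codons)
  n_prop <- stats::rpois(1, divergence * nsite)
  nts <- c("A", "C", "G", "T")
  for (i in seq_len(n_prop)) {
    site <- sample.int(nsite, 1L)
    ci <- (site - 1L) %/% 3L + 1L
    pos <- (site - 1L) %% 3L + 1L
    cod <- strsplit(codons[ci], "")[[1L]]
    new_nt <- sample(setdiff(nts, cod[pos]), 1L)
    cand <- cod; cand[pos] <- new_nt
    cand <- paste(cand, collapse = "")
    if (cand %in% STOP_CODONS) next
    if (codon_aa(cand) == codon_aa(codons[ci]) || stats::runif(1) < omega)
      codons[ci] <- cand
  }
  codons
}

#' Simulate reciprocal homology hit tables with known truth
#'
#' Each gene receives, with probability \code{p_mappable}, a reciprocal best
#' pair meeting the ortholog-acceptance thresholds; decoy hits (sub-threshold
#' reciprocal pairs for unmappable genes, and strictly worse secondary hits
#' for a fraction of mappable genes) are layered on top. The constructed
#' reciprocal-best-hit truth set is returned.
#'
#' @param truth per-gene truth from \code{\link{simulate_expression}}
#'   (uses gene ids, chromosomes and positions for the subject side).
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{hits_ab}, \code{hits_ba} (hit data.frames),
#'   \code{subject_info} (\code{ortholog_id, chromosome, position}) and
#'   \code{truth_pairs} (data.frame \code{gene_id, ortholog_id}).
#' @export
simulate_hits <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n <- nrow(truth)
  mappable <- stats::runif(n) < cfg$p_mappable
  ort <- paste0("xt_", truth$gene_id)
  qlen <- sample(600:3000, n, replace = TRUE)
  slen <- pmax(150, round(qlen / 3))  # peptide-style subject lengths
  mk <- function(q, s, pident, alen, qlen, slen, evalue, bits) {
    data.frame(query_id = q, subject_id = s, pident = pident, aln_len = alen,
               mismatch = round(alen * (100 - pident) / 100), gapopen = 0L,
               qstart = 1L, qend = alen, sstart = 1L, send = alen,
               evalue = evalue, bitscore = bits, qlen = qlen, slen = slen,
               stringsAsFactors = FALSE)
  }
  ab <- list(); ba <- list()
  i_map <- which(mappable)
  if (length(i_map)) {
    alen <- pmax(ceiling(0.5 * qlen[i_map]), slen[i_map])  # covers both
    pid <- stats::runif(length(i_map), 60, 98)
    ev <- 10^(-stats::runif(length(i_map), 30, 180))
    bits <- stats::runif(length(i_map), 200, 2000)
    ab[["true"]] <- mk(truth$gene_id[i_map], ort[i_map], pid, alen,
                       qlen[i_map], slen[i_map], ev, bits)
    ba[["true"]] <- mk(ort[i_map], truth$gene_id[i_map], pid, alen,
                       slen[i_map], qlen[i_map], ev, bits)
  }
  ## worse secondary hits for some mappable genes (never best; RBH unaffected)
  i_dec <- i_map[stats::runif(length(i_map)) < cfg$decoy_fraction]
  if (length(i_dec)) {
    other <- ort[sample.int(n, length(i_dec), replace = TRUE)]
    keep <- other != ort[i_dec]
    i_dec <- i_dec[keep]; other <- other[keep]
    if (length(i_dec)) {
      alen <- ceiling(0.4 * qlen[i_dec])
      ab[["decoy2"]] <- mk(truth$gene_id[i_dec], other,
                           stats::runif(length(i_dec), 35, 60), alen,
                           qlen[i_dec], slen[match(other, ort)],
                           10^(-stats::runif(length(i_dec), 3, 9)),
                           stats::runif(length(i_dec), 40, 90))
    }
  }
  ## sub-threshold reciprocal pairs for unmappable genes (evalue too weak)
  i_un <- which(!mappable)
  if (length(i_un)) {
    alen <- pmax(ceiling(0.5 * qlen[i_un]), slen[i_un])
    ev <- 10^(-stats::runif(length(i_un), 3, 9))  # fails evalue < 1e-10
    pid <- stats::runif(length(i_un), 45, 90)
    bits <- stats::runif(length(i_un), 40, 90)
    ab[["weak"]] <- mk(truth$gene_id[i_un], ort[i_un], pid, alen,
                       qlen[i_un], slen[i_un], ev, bits)
    ba[["weak"]] <- mk(ort[i_un], truth$gene_id[i_un], pid, alen,
                       slen[i_un], qlen[i_un], ev, bits)
  }
  hits_ab <- do.call(rbind, ab); rownames(hits_ab) <- NULL
  hits_ba <- do.call(rbind, ba); rownames(hits_ba) <- NULL
  ## shuffle row order: RBH must be invariant to it
  hits_ab <- hits_ab[sample.int(nrow(hits_ab)), , drop = FALSE]
  hits_ba <- hits_ba[sample.int(nrow(hits_ba)), , drop = FALSE]
  list(hits_ab = hits_ab, hits_ba = hits_ba,
       subject_info = data.frame(ortholog_id = ort,
                                 chromosome = truth$chromosome,
                                 position = truth$position,
                                 stringsAsFactors = FALSE),
       truth_pairs = data.frame(gene_id = truth$gene_id[i_map],
                                ortholog_id = ort[i_map],
                                stringsAsFactors = FALSE))
}
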