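#' Run the full analysis pipeline
#'
#' Orchestrates simulation (or loading of real inputs), per-class sex-bias
#' calling, directional-excess tables, Tau specificity, bias-specificity
#' correlations, turnover accounting, ortholog assignment with enrichment and
#' sliding-window scans, dN/dS estimation and the rate model, writing one TSV
#' per stage plus a JSON run manifest. Fully deterministic given the seed:
#' stage k uses seed \code{seed * 100 + k}.
#'
#' @param config either a path to a YAML file or a list. Recognized fields:
#'   \code{out_dir}; \code{seed}; \code{thresholds} (\code{fdr, lfc,
#'   tau_specific, window, n_perm, shared_min}); and either \code{sim} (a list
#'   of \code{\link{sim_config}} arguments) or \code{inputs} (paths
#'   \code{counts, samples, hits_ab, hits_ba, subject_info, orthologs_fasta}).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  if (is.null(config$sim) && is.null(config$inputs))
    stop("config must provide either a 'sim' block or real 'inputs'")
  th <- modifyList(list(fdr = 0.05, lfc = 1, tau_specific = 0.8, window = 40,
                        n_perm = 10000, shared_min = 35),
                   if (is.null(config$thresholds)) list() else config$thresholds)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  manifest <- list(config_hash = digest_config(config), seed = seed,
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("ranabias")),
                   thresholds = th, stages = list())
  note <- function(stage, rows) {
    manifest$stages[[stage]] <<- list(rows = rows)
    message("stage ", stage, ": ", rows, " rows")
  }

  ## 1. inputs
  if (!is.null(config$sim)) {
    cfg <- do.call(sim_config, modifyList(config$sim, list(seed = seed * 100 + 1)))
    sim <- simulate_expression(cfg)
    counts <- sim$counts; samples <- sim$samples
    hits <- simulate_hits(sim$truth, cfg)
    orth <- simulate_orthologs(cfg)
    write_counts(counts, outp("counts.tsv"))
    write_sample_table(samples, outp("samples.tsv"))
    write_result_tsv(sim$truth, outp("truth.tsv"), seed, config)
    write_blast_tab(hits$hits_ab, outp("hits_AB.tsv"))
    write_blast_tab(hits$hits_ba, outp("hits_BA.tsv"))
    write_result_tsv(hits$subject_info, outp("subject_info.tsv"), seed, config)
    write_codon_pairs(orth$pairs, outp("orthologs.fasta"))
    subject_info <- hits$subject_info
    pairs <- orth$pairs
  } else {
    counts <- read_counts(config$inputs$counts)
    samples <- read_sample_table(config$inputs$samples, counts)
    hits <- list(hits_ab = read_blast_tab(config$inputs$hits_ab),
                 hits_ba = read_blast_tab(config$inputs$hits_ba))
    subject_info <- if (!is.null(config$inputs$subject_info))
      read.delim(config$inputs$subject_info, comment.char = "#") else NULL
    pairs <- if (!is.null(config$inputs$orthologs_fasta))
      read_codon_pairs(config$inputs$orthologs_fasta) else NULL
  }
  note("inputs", ncol(counts$counts))

  ## 2. per-class sex-bias calls
  bias <- list()
  for (cl in intersect(CLASS_LEVELS, unique(samples$class))) {
    bias[[cl]] <- call_sex_bias(counts, samples, cl, fdr = th$fdr, lfc = th$lfc)
    write_result_tsv(bias[[cl]], outp(sprintf("sexbias_%s.tsv", cl)), seed, config)
  }
  note("sexbias", sum(vapply(bias, nrow, integer(1))))

  ## 3. directional excess tables
  excess <- do.call(rbind, lapply(bias, excess_table))
  write_result_tsv(excess, outp("excess.tsv"), seed, config)
  note("excess", nrow(excess))

  ## 4. Tau specificity
  tpm <- tpm_matrix(counts$counts, counts$lengths)
  profiles <- pool_profiles(tpm, samples)
  taus <- tau_table(profiles)
  write_result_tsv(taus, outp("tau.tsv"), seed, config)
  topfrac <- top_fraction_summary(profiles, taus$tau)
  write_result_tsv(topfrac, outp("tau_top_fractions.tsv"), seed, config)
  note("tau", nrow(taus))

  ## 5. bias-specificity correlations
  cors <- NULL
  for (cl in names(bias)) {
    r <- spearman_bias_tau(bias[[cl]], taus)
    if (!is.null(r))
      cors <- rbind(cors, data.frame(class = cl, rho = r$rho,
                                     pvalue = r$pvalue, n = r$n))
  }
  if (!is.null(cors)) write_result_tsv(cors, outp("bias_tau_spearman.tsv"), seed, config)
  note("spearman", if (is.null(cors)) 0L else nrow(cors))

  ## 6. turnover between qualifying class pairs
  turn <- NULL
  cls <- names(bias)
  for (i in seq_len(length(cls) - 1L)) for (j in seq((i + 1L), length(cls))) {
    ts <- suppressWarnings(turnover_summary(bias[[cls[i]]], bias[[cls[j]]],
                                            th$shared_min))
    if (isTRUE(ts$reportable))
      turn <- rbind(turn, data.frame(class_a = cls[i], class_b = cls[j],
                                     n_shared = ts$n_shared, n_f2m = ts$n_f2m,
                                     n_m2f = ts$n_m2f, percent = ts$percent))
  }
  if (!is.null(turn)) write_result_tsv(turn, outp("turnover.tsv"), seed, config)
  note("turnover", if (is.null(turn)) 0L else nrow(turn))

  ## 7. orthologs, enrichment, ratio tests, windows
  assign <- rbh_orthologs(hits$hits_ab, hits$hits_ba, subject_info)
  write_result_tsv(assign, outp("orthologs.tsv"), seed, config)
  enrich <- windows <- NULL
  focal <- names(bias)[which.max(vapply(bias, function(b) sum(b$biased), numeric(1)))]
  if (nrow(assign) && any(!is.na(assign$chromosome))) {
    enrich <- enrichment_permutation(bias[[focal]], assign,
                                     n_perm = th$n_perm, seed = seed * 100 + 7)
    enrich$class <- focal
    write_result_tsv(enrich, outp("enrichment.tsv"), seed, config)
    ratio <- ratio_wilcoxon(bias[[focal]], assign)
    write_result_tsv(ratio, outp("ratio_wilcoxon.tsv"), seed, config)
    lfcv <- setNames(bias[[focal]]$log2fc, bias[[focal]]$gene_id)
    windows <- sliding_window(lfcv, assign, window = th$window)
    write_result_tsv(windows, outp("windows.tsv"), seed, config)
  }
  note("chromomap", nrow(assign))

  ## 8. dN/dS and the rate model
  dnds <- NULL
  if (!is.null(pairs)) {
    dnds <- dnds_table(pairs)
    write_result_tsv(dnds, outp("dnds.tsv"), seed, config)
  }
  note("dnds", if (is.null(dnds)) 0L else nrow(dnds))

  manifest$focal_class <- focal
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
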