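# Independent oracles and small fixture builders shared across tests.

# Brute-force Benjamini-Hochberg step-up, written from the definition:
# q_(i) = min over j >= i of p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    qs[i] <- min(sorted[i:m] * m / (i:m), 1)
  }
  q <- numeric(m)
  q[o] <- qs
  q
}

# Brute-force windowed mean.
rollmean_oracle <- function(v, k) {
  n <- length(v) - k + 1
  vapply(seq_len(n), function(i) mean(v[i:(i + k - 1)]), numeric(1))
}

# Independent Nei-Gojobori counting oracle built on Biostrings' genetic code,
# recursing explicitly over substitution orderings.
ng86_oracle <- function(seq_a, seq_b) {
  gc <- Biostrings::GENETIC_CODE
  translate1 <- function(cod) unname(gc[[cod]])
  bases <- c("A", "C", "G", "T")
  syn_sites1 <- function(cod) {
    aa <- translate1(cod)
    ch <- strsplit(cod, "")[[1]]
    s <- 0
    for (p in 1:3) for (b in bases[bases != ch[p]]) {
      mut <- ch; mut[p] <- b
      mut <- paste(mut, collapse = "")
      if (translate1(mut) != "*" && translate1(mut) == aa) s <- s + 1 / 3
    }
    s
  }
  paths <- function(cur, target) {
    pos <- which(cur != target)
    if (!length(pos)) return(list(c(sd = 0, nd = 0)))
    out <- list()
    for (p in pos) {
      nxt <- cur; nxt[p] <- target[p]
      cod_c <- paste(cur, collapse = ""); cod_n <- paste(nxt, collapse = "")
      if (translate1(cod_n) == "*") next
      step <- if (translate1(cod_n) == translate1(cod_c)) c(1, 0) else c(0, 1)
      for (rest in paths(nxt, target))
        out[[length(out) + 1]] <- c(sd = step[1] + rest[["sd"]],
                                    nd = step[2] + rest[["nd"]])
    }
    out
  }
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(seq_a); cb <- split3(seq_b)
  S <- N <- Sd <- Nd <- 0
  for (i in seq_along(ca)) {
    pw <- paths(strsplit(ca[i], "")[[1]], strsplit(cb[i], "")[[1]])
    if (!length(pw)) next
    sd_avg <- mean(vapply(pw, `[`, numeric(1), "sd"))
    nd_avg <- mean(vapply(pw, `[`, numeric(1), "nd"))
    s_i <- (syn_sites1(ca[i]) + syn_sites1(cb[i])) / 2
    S <- S + s_i; N <- N + 3 - s_i
    Sd <- Sd + sd_avg; Nd <- Nd + nd_avg
  }
  c(S = S, N = N, Sd = Sd, Nd = Nd)
}

# Random stop-free codon sequence pair differing by random point edits.
random_codon_pair <- function(n_codons, n_edits) {
  sense <- setdiff(ranabias:::all_codons(), c("TAA", "TAG", "TGA"))
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  bases <- c("A", "C", "G", "T")
  tries <- 0
  while (n_edits > 0 && tries < 50 * n_edits) {
    tries <- tries + 1
    ci <- sample.int(n_codons, 1); p <- sample.int(3, 1)
    ch <- strsplit(b[ci], "")[[1]]
    ch[p] <- sample(bases[bases != ch[p]], 1)
    cand <- paste(ch, collapse = "")
    if (cand %in% c("TAA", "TAG", "TGA")) next
    b[ci] <- cand
    n_edits <- n_edits - 1
  }
  list(seq_a = paste(a, collapse = ""), seq_b = paste(b, collapse = ""))
}

# Minimal sex-bias record table with prescribed shared/turnover structure.
make_bias_pair <- function(n_shared, n_f2m, n_m2f, prefix = "g") {
  ids <- sprintf("%s%04d", prefix, seq_len(n_shared))
  dir_a <- rep("male", n_shared)
  dir_a[seq_len(n_f2m)] <- "female"
  dir_b <- dir_a
  dir_b[seq_len(n_f2m)] <- "male"                       # female -> male
  if (n_m2f > 0) {
    i <- n_f2m + seq_len(n_m2f)
    dir_a[i] <- "male"; dir_b[i] <- "female"            # male -> female
  }
  mk <- function(dirs, class) data.frame(
    gene_id = ids, class = class,
    log2fc = ifelse(dirs == "male", 2, -2),
    pvalue = 1e-4, qvalue = 1e-3, biased = TRUE, direction = dirs,
    category = "mild", stringsAsFactors = FALSE)
  list(a = mk(dir_a, "A"), b = mk(dir_b, "B"))
}

# Tiny counts fixture with controllable CPM per sample.
toy_counts <- function(target_counts, lib_sizes, lengths = NULL) {
  ng <- nrow(target_counts)
  filler <- lib_sizes - colSums(target_counts)
  m <- rbind(target_counts, filler)
  rownames(m) <- c(sprintf("g%02d", seq_len(ng)), "filler")
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(lengths)) lengths <- rep(1000, nrow(m))
  counts_matrix(m, stats::setNames(lengths, rownames(m)))
}
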