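mk_hit <- function(q, s, evalue = 1e-50, pident = 90, alen = 500,
                   qlen = 600, slen = 510, bits = 900) {
  data.frame(query_id = q, subject_id = s, pident = pident, aln_len = alen,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = alen,
             sstart = 1L, send = alen, evalue = evalue, bitscore = bits,
             qlen = qlen, slen = slen, stringsAsFactors = FALSE)
}

test_that("reciprocal-best-hit assignment enforces every acceptance threshold", {
  ab <- mk_hit("g1", "p1")
  ba <- mk_hit("p1", "g1", qlen = 510, slen = 600)
  expect_equal(rbh_orthologs(ab, ba)$gene_id, "g1")
  # e-value 1e-9 fails the 1e-10 cut-off
  expect_equal(nrow(rbh_orthologs(mk_hit("g1", "p1", evalue = 1e-9), ba)), 0L)
  # identity below 40 fails
  expect_equal(nrow(rbh_orthologs(mk_hit("g1", "p1", pident = 39), ba)), 0L)
  # overlap below half of either sequence fails
  expect_equal(nrow(rbh_orthologs(mk_hit("g1", "p1", alen = 250), ba)), 0L)
  # non-reciprocal: p1's best points elsewhere
  ba2 <- rbind(mk_hit("p1", "g2", evalue = 1e-80), ba)
  expect_equal(nrow(rbh_orthologs(ab, ba2)), 0L)
  expect_error(rbh_orthologs(ab, NULL), "required")
})

test_that("RBH output is a one-to-one matching, invariant to row order", {
  cfg <- sim_config(n_genes = 300, seed = 13)
  s <- simulate_expression(cfg)
  h <- simulate_hits(s$truth, cfg)
  rb <- rbh_orthologs(h$hits_ab, h$hits_ba, h$subject_info)
  expect_false(anyDuplicated(rb$gene_id) > 0)
  expect_false(anyDuplicated(rb$ortholog_id) > 0)
  sh <- function(d) d[rev(seq_len(nrow(d))), ]
  rb2 <- rbh_orthologs(sh(h$hits_ab), sh(h$hits_ba), h$subject_info)
  rownames(rb) <- rownames(rb2) <- NULL
  expect_equal(rb2, rb)
  # chromosome/position transferred from the subject side
  i <- match(rb$gene_id, s$truth$gene_id)
  expect_equal(rb$chromosome, s$truth$chromosome[i])
  expect_equal(rb$position, s$truth$position[i])
})

test_that("permutation enrichment p-values agree with the hypergeometric tail", {
  # 20 genes, 5 male-biased; one chromosome of 4 genes holding 4 of them
  sb <- data.frame(gene_id = sprintf("g%02d", 1:20), class = "gonad",
                   log2fc = c(rep(2, 5), rep(0, 15)), pvalue = 1e-4,
                   qvalue = 1e-3, biased = c(rep(TRUE, 5), rep(FALSE, 15)),
                   direction = c(rep("male", 5), rep("none", 15)),
                   category = "mild")
  asn <- data.frame(gene_id = sb$gene_id,
                    chromosome = c(rep(1L, 4), rep(2L, 16)),
                    position = 1:20)
  en <- enrichment_permutation(sb, asn, n_perm = 10000, seed = 99)
  obs <- en[en$chromosome == 1 & en$direction == "male", ]
  expect_equal(obs$n_observed, 4)
  p_hyper <- stats::phyper(3, 5, 15, 4, lower.tail = FALSE)
  expect_lt(abs(obs$p_perm - p_hyper),
            3 * sqrt(p_hyper * (1 - p_hyper) / 10000) + 2 / 10000)
  expect_gte(obs$p_perm, 1 / 10001)  # plus-one correction floor
  # no biased genes anywhere: p = 1 on every chromosome
  sb0 <- sb; sb0$biased <- FALSE; sb0$direction <- "none"
  en0 <- enrichment_permutation(sb0, asn, n_perm = 1000, seed = 1)
  expect_true(all(en0$p_perm == 1))
  # Bonferroni family = chromosomes x directions
  expect_equal(en$p_bonf, pmin(1, en$p_perm * nrow(en)))
})

test_that("expression-ratio strata tests are deterministic and powered", {
  set.seed(17)
  n <- 2200
  sb <- data.frame(gene_id = sprintf("g%04d", 1:n), class = "gonad",
                   log2fc = rnorm(n), pvalue = 1, qvalue = 1, biased = FALSE,
                   direction = "none", category = "none")
  asn <- data.frame(gene_id = sb$gene_id,
                    chromosome = c(rep(1L, 100), rep(2L, 100),
                                   sample(3:10, n - 200, TRUE)),
                    position = seq_len(n))
  r1 <- ratio_wilcoxon(sb, asn)
  expect_equal(r1$stratum, c("joint", "chr1", "chr2"))
  expect_identical(ratio_wilcoxon(sb, asn)$pvalue, r1$pvalue)  # deterministic
  expect_gt(min(r1$pvalue), 1e-4)  # null: no tiny p expected
  # shift all sex-chromosome genes by +1: detected at p < 0.001
  sb2 <- sb
  sb2$log2fc[asn$chromosome %in% 1:2] <- sb2$log2fc[asn$chromosome %in% 1:2] + 1
  expect_lt(ratio_wilcoxon(sb2, asn)$pvalue[1], 0.001)
})

test_that("sliding windows equal the brute-force mean and never span chromosomes", {
  v <- setNames(rep(2, 80), sprintf("g%02d", 1:80))
  asn <- data.frame(gene_id = names(v), chromosome = rep(1:2, each = 40),
                    position = rep(seq_len(40) * 100, 2))
  w <- sliding_window(v, asn, window = 40)
  expect_equal(nrow(w), 2L)  # exactly one window per 40-gene chromosome
  expect_true(all(w$mean_value == 2))
  # 39 genes < window 40: no windows
  asn39 <- asn[1:39, ]
  expect_message(w39 <- sliding_window(v[1:39], asn39, 40), "no windows")
  expect_equal(nrow(w39), 0L)
  # arithmetic series 1..50: first mean 20.5, last 30.5
  v2 <- setNames(as.numeric(1:50), sprintf("h%02d", 1:50))
  asn2 <- data.frame(gene_id = names(v2), chromosome = 1L,
                     position = seq_len(50) * 10)
  w2 <- sliding_window(v2, asn2, 40)
  expect_equal(w2$mean_value[1], 20.5)
  expect_equal(w2$mean_value[nrow(w2)], 30.5)
  # random inputs against the brute-force oracle
  set.seed(23)
  v3 <- setNames(rnorm(120), sprintf("r%03d", 1:120))
  asn3 <- data.frame(gene_id = names(v3), chromosome = 1L,
                     position = sample.int(1e6, 120))
  w3 <- sliding_window(v3, asn3, window = 15)
  ord <- v3[asn3$gene_id[order(asn3$position)]]
  expect_equal(w3$mean_value, rollmean_oracle(ord, 15))
})
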