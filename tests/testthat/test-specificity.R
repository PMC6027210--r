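test_that("profile pooling averages the right samples into 11 fixed classes", {
  cfg <- sim_config(n_genes = 40, seed = 3)
  s <- simulate_expression(cfg)
  tpm <- tpm_matrix(s$counts$counts, s$counts$lengths)
  prof <- pool_profiles(tpm, s$samples)
  expect_equal(colnames(prof),
               c("G23", "G27", "G31", "brain", "liver", "G43_female",
                 "G43_male", "G46_female", "G46_male", "testis", "ovary"))
  # pooled class = mean over both sexes; sex-limited class = one sex only
  g23_cols <- s$samples$sample_id[s$samples$class == "G23"]
  expect_equal(prof[, "G23"], rowMeans(tpm[, g23_cols]))
  tes_cols <- s$samples$sample_id[s$samples$class == "gonad" & s$samples$sex == "XY"]
  expect_equal(prof[, "testis"], rowMeans(tpm[, tes_cols]))
  # two replicates 10 and 20 -> 15
  m <- matrix(c(10, 20), 1, dimnames = list("g", c("a", "b")))
  st <- data.frame(sample_id = c("a", "b"), class = "G23", sex = c("XX", "XY"),
                   replicate = c("r1", "r2"))
  expect_error(pool_profiles(m, st), "missing stage/tissue classes")
})

test_that("Tau evaluates its defining formula and stays within [0,1]", {
  expect_equal(tau(rep(50, 11)), 0)
  expect_equal(tau(c(1000, rep(1, 10))), 1)
  expect_equal(tau(c(1000, rep(0.2, 10))), 1)   # sub-1 TPM floored
  # hand evaluation, 3 classes (100, 10, 1), log10: (0 + 0.5 + 1)/2
  expect_equal(tau(c(100, 10, 1)), 0.75)
  expect_true(is.na(tau(rep(0.5, 11))))         # undefined below the floor
  expect_error(tau(c(-1, 5)), "non-negative")
})

test_that("Tau is reorder-invariant and rises as expression concentrates", {
  set.seed(11)
  for (i in 1:50) {
    v <- rlnorm(11, log(20), 1.5)
    t0 <- tau(v)
    expect_true(t0 >= 0 && t0 <= 1)
    expect_equal(tau(sample(v)), t0)
    # move mass from a non-max class into the max class
    w <- v
    imax <- which.max(w); other <- which(w == sort(w, decreasing = TRUE)[2])[1]
    shift <- w[other] * 0.5
    w[other] <- w[other] - shift; w[imax] <- w[imax] + shift
    expect_gte(tau(w) + 1e-12, t0)
  }
  # tau = 0 iff all floored values equal
  expect_equal(tau(c(5, 5, 5, 5)), 0)
  expect_gt(tau(c(5, 5, 5, 6)), 0)
})

test_that("top-fraction summaries rank within class and handle ties deterministically", {
  prof <- rbind(g1 = c(1000, 1, 1), g2 = c(500, 500, 500), g3 = c(2, 2, 2),
                g4 = c(900, 1, 1))
  colnames(prof) <- c("c1", "c2", "c3")
  tv <- tau(prof)
  s <- top_fraction_summary(prof, tv, fractions = c(0.5, 1.0))
  # full fraction: identical mean over every class ordering
  full <- s[s$fraction == 1, "mean_tau"]
  expect_true(all(abs(full - mean(tv)) < 1e-12))
  # top half of c1 are the single-class-specific genes g1, g4 -> mean tau 1
  expect_equal(s[s$class == "c1" & s$fraction == 0.5, "mean_tau"], 1)
  expect_error(top_fraction_summary(prof, tv, fractions = 0), "\\(0,1\\]")
})

test_that("bias-specificity correlation detects monotone links and respects the gate", {
  n <- 150
  sb <- data.frame(gene_id = sprintf("g%03d", 1:n), class = "gonad",
                   log2fc = seq(0.1, 5, length.out = n), pvalue = 1e-4,
                   qvalue = 1e-3, biased = TRUE, direction = "male",
                   category = "mild")
  taus <- data.frame(gene_id = sb$gene_id, tau = seq(0.01, 0.99, length.out = n))
  r <- spearman_bias_tau(sb, taus)
  expect_equal(r$rho, 1)
  # independent bias and tau: |rho| below the 3/sqrt(n) null bound
  set.seed(5)
  n2 <- 2000
  sb2 <- sb[rep(1, n2), ]; sb2$gene_id <- sprintf("h%04d", 1:n2)
  sb2$log2fc <- rnorm(n2)
  taus2 <- data.frame(gene_id = sb2$gene_id, tau = runif(n2))
  r2 <- spearman_bias_tau(sb2, taus2)
  expect_lt(abs(r2$rho), 0.08)
  # below the 100-biased-gene gate: skipped with a message
  sb$biased[1:60] <- FALSE
  expect_message(r3 <- spearman_bias_tau(sb, taus), "skipping")
  expect_null(r3)
})
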