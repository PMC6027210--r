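test_that("expression filter applies both the mean-logCPM and per-sex rules", {
  # 4-sample toy: CPMs 3,3,0.5,0.5 with sexes XX,XX,XY,XY -> removed
  tc <- matrix(c(3, 3, 1, 1), nrow = 1)
  cm <- toy_counts(tc, lib_sizes = c(1e6, 1e6, 2e6, 2e6))
  st <- data.frame(sample_id = paste0("s", 1:4), class = "gonad",
                   sex = c("XX", "XX", "XY", "XY"), replicate = c("r1", "r2", "r1", "r2"))
  colnames(cm$counts) <- st$sample_id
  expect_false("g01" %in% filter_expressed(cm, st, "gonad"))

  # CPM 2 everywhere -> retained; all-zero gene -> removed
  tc2 <- rbind(rep(2, 4), rep(0, 4))
  cm2 <- toy_counts(tc2, lib_sizes = rep(1e6, 4))
  colnames(cm2$counts) <- st$sample_id
  keep <- filter_expressed(cm2, st, "gonad")
  expect_true("g01" %in% keep)
  expect_false("g02" %in% keep)
  expect_error(filter_expressed(cm2, st, "liver"), "no samples")
})

test_that("TMM factors are scale-invariant, order-invariant and match edgeR", {
  set.seed(1)
  n <- 2000
  mu <- rlnorm(n, log(80), 1)
  a <- rnbinom(n, size = 10, mu = mu)
  m <- cbind(s1 = a, s2 = 2L * a, s3 = rnbinom(n, size = 10, mu = mu))
  rownames(m) <- sprintf("g%04d", 1:n)
  f <- tmm_factors(m)
  # doubling all counts is pure depth: factors stay at 1
  expect_lt(abs(f[["s1"]] - f[["s2"]]), 1e-6)
  # identical libraries
  f_id <- tmm_factors(cbind(x = a + 1L, y = a + 1L))
  expect_equal(unname(f_id), c(1, 1), tolerance = 1e-12)
  # permutation of gene order changes nothing
  perm <- sample(n)
  expect_equal(unname(tmm_factors(m[perm, ])), unname(f), tolerance = 1e-12)
  # geometric mean 1
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  # independent implementation agreement
  skip_if_not_installed("edgeR")
  f_e <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
  expect_equal(unname(f), f_e, tolerance = 1e-3)
})

test_that("NB exact-style test is calibrated on a seeded null simulation", {
  set.seed(42)
  n <- 5000; phi <- 0.1
  mu <- rlnorm(n, log(100), 1.2)
  depth <- rlnorm(8, 0, 0.15)
  m <- sapply(depth, function(d) rnbinom(n, size = 1 / phi, mu = mu * d))
  dimnames(m) <- list(sprintf("g%04d", 1:n), paste0("s", 1:8))
  res <- nb_exact_test(m, 1:4, 5:8)
  expect_lt(abs(res$dispersion - phi), 0.03)
  band <- 3 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(res$pvalue < 0.05) - 0.05), band)
})

test_that("NB exact-style test behaves at the extremes", {
  # identical groups with equal counts -> p = 1
  m <- matrix(5, nrow = 2, ncol = 6,
              dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  res <- nb_exact_test(m, 1:3, 4:6, dispersion = 0.1)
  expect_equal(res$pvalue, c(1, 1))
  # zero total -> p = 1 by definition
  m0 <- matrix(0, 1, 6, dimnames = list("g", paste0("s", 1:6)))
  expect_equal(nb_exact_test(m0, 1:3, 4:6, dispersion = 0.1,
                             eff_lib = rep(1e6, 6))$pvalue, 1)
  # all-zero versus very large counts -> overwhelming evidence
  mx <- matrix(c(0, 0, 0, 5000, 5000, 5000), 1,
               dimnames = list("g", paste0("s", 1:6)))
  p <- nb_exact_test(mx, 1:3, 4:6, dispersion = 0.1,
                     eff_lib = rep(1e6, 6))$pvalue
  expect_lt(p, 1e-6)
  # agreement with edgeR's exact test on a small fixture
  skip_if_not_installed("edgeR")
  set.seed(3)
  f <- matrix(rnbinom(400 * 6, size = 10, mu = 60), 400,
              dimnames = list(sprintf("g%03d", 1:400), paste0("s", 1:6)))
  mine <- nb_exact_test(f, 1:3, 4:6, dispersion = 0.1)
  d <- edgeR::DGEList(f, group = rep(c("a", "b"), each = 3))
  d$common.dispersion <- 0.1
  pe <- edgeR::exactTest(d)$table$PValue
  expect_gt(cor(log(mine$pvalue), log(pe)), 0.98)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0,1\\]")
})

test_that("sex-bias calling enforces both the FDR and fold-change gates", {
  cat1 <- ranabias:::fold_change_category
  expect_equal(cat1(log2fc = c(1, 1.5, 2.5, 3.5), biased = rep(TRUE, 4)),
               c("low", "mild", "high", "very_high"))
  expect_equal(cat1(0.8, FALSE), "none")
  # a strong implant is called with the right direction; a null gene is not
  cfg <- sim_config(n_genes = 400, seed = 21)
  s <- simulate_expression(cfg)
  sb <- call_sex_bias(s$counts, s$samples, "gonad")
  expect_true(all(sb$biased == (sb$qvalue < 0.05 & abs(sb$log2fc) >= 1)))
  expect_true(all(sb$direction[sb$biased & sb$log2fc > 0] == "male"))
  m <- merge(sb, s$truth, by = "gene_id")
  strong <- m$bias_class == "gonad" & m$true_lfc >= 2 & m$biased
  expect_true(all(m$true_direction[strong] == m$direction[strong]))
})
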