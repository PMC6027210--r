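test_that("directional chi-square matches the textbook statistic and is symmetric", {
  r <- chi_square_excess(3, 16)
  expect_equal(r$chi2, 8.894737, tolerance = 1e-6)
  expect_equal(r$pvalue, 0.002859938, tolerance = 1e-6)
  expect_equal(chi_square_excess(10, 10)$chi2, 0)
  expect_equal(chi_square_excess(10, 10)$pvalue, 1)
  expect_error(chi_square_excess(0, 0), "zero")
  # exhaustive check against stats::chisq.test for all totals <= 60,
  # plus symmetry and monotonicity in imbalance at fixed total
  for (tot in c(1:10, 20, 40, 60)) {
    for (a in tot:ceiling(tot / 2)) {
      b <- tot - a
      mine <- chi_square_excess(b, a)
      ref <- suppressWarnings(stats::chisq.test(c(a, b), p = c(0.5, 0.5),
                                                correct = FALSE))
      expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$pvalue, ref$p.value, tolerance = 1e-12)
      expect_equal(chi_square_excess(a, b)$pvalue, mine$pvalue)
    }
  }
  # monotone in imbalance, explicit
  tot <- 40
  chis <- sapply(20:40, function(a) chi_square_excess(tot - a, a)$chi2)
  expect_true(all(diff(chis) > 0))
})

test_that("sex-specific pseudo-count substitutes a tenth of the minimum and is idempotent", {
  m <- matrix(c(0.5, 0, 2, 4), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  adj <- apply_sexspecific_pseudocount(m)
  expect_equal(adj["g2", "a"], 0.05)
  expect_equal(adj[m > 0], m[m > 0])
  expect_equal(apply_sexspecific_pseudocount(adj), adj)
  # no zeros: unchanged
  expect_equal(apply_sexspecific_pseudocount(m + 1), m + 1)
  expect_error(apply_sexspecific_pseudocount(matrix(0, 2, 2)), "all-zero")
})

test_that("driver bins nest, track the upregulated sex, and keep sex-specific genes", {
  # 240 female-biased genes driven by female upregulation
  set.seed(2)
  n <- 240
  ids <- sprintf("g%03d", 1:n)
  lfc <- -runif(n, 1, 9)
  sb <- data.frame(gene_id = ids, class = "liver", log2fc = lfc, pvalue = 1e-5,
                   qvalue = 1e-4, biased = TRUE, direction = "female",
                   category = "mild", stringsAsFactors = FALSE)
  st <- data.frame(sample_id = paste0("s", 1:8), class = "liver",
                   sex = rep(c("XX", "XY"), each = 4),
                   replicate = paste0("r", rep(1:4, 2)))
  base <- 4  # male RPKM flat at 4; female raised by the fold change
  rpkm <- cbind(matrix(rep(base * 2^(-lfc), 4), n), matrix(base, n, 4)) *
    matrix(exp(rnorm(n * 8, 0, 0.05)), n)
  dimnames(rpkm) <- list(ids, st$sample_id)
  db <- driver_bins(sb, rpkm, st, "liver")
  fb <- db$bins[db$bins$direction == "female", ]
  expect_equal(fb$threshold, -c(1, 3, 5, 7))
  expect_true(all(diff(fb$mean_log2rpkm_female) > 0))   # rises across bins
  expect_lt(abs(fb$mean_log2rpkm_male[4] - fb$mean_log2rpkm_male[1]), 0.3)
  succ <- db$tests[db$tests$comparison == "successive_bins" &
                     db$tests$direction == "female" & db$tests$sex == "female", ]
  expect_true(all(succ$pvalue < 0.05))
  # nesting property
  memb <- lapply(c(1, 3, 5, 7), function(th) sb$gene_id[-sb$log2fc >= th])
  for (i in 1:3) expect_true(all(memb[[i + 1]] %in% memb[[i]]))
  # identical expression: between-sex comparisons are ties at p = 1
  rpkm_flat <- matrix(4, n, 8, dimnames = dimnames(rpkm))
  db2 <- driver_bins(sb, rpkm_flat, st, "liver")
  bt <- db2$tests[db2$tests$comparison == "between_sexes" &
                    db2$tests$direction == "female", ]
  expect_true(all(bt$pvalue == 1, na.rm = TRUE))
  # a sex-specific gene (zero male RPKM) enters the extreme bin after the
  # pseudo-count instead of being dropped
  rpkm3 <- rpkm; rpkm3[1, 5:8] <- 0
  sb3 <- sb; sb3$log2fc[1] <- -12
  adj <- apply_sexspecific_pseudocount(rpkm3)
  db3 <- driver_bins(sb3, adj, st, "liver")
  expect_true(ids[1] %in% sb3$gene_id[sb3$biased & -sb3$log2fc >= 7])
  expect_gt(db3$bins$n_genes[db3$bins$direction == "female" &
                               db3$bins$threshold == -7], 0)
})

test_that("excess tables count directions at nested fold-change thresholds", {
  sb <- data.frame(gene_id = sprintf("g%02d", 1:10), class = "gonad",
                   log2fc = c(1.2, 2.5, 3.5, -1.5, -2.2, -3.8, 0.5, -0.4, 1.1, -9),
                   pvalue = 1e-4, qvalue = c(rep(1e-3, 9), 0.5),
                   biased = c(rep(TRUE, 6), FALSE, FALSE, TRUE, FALSE),
                   direction = "x", category = "x")
  et <- excess_table(sb)
  expect_equal(et$n_male[et$threshold == "FC2"], 4)   # 1.2, 2.5, 3.5, 1.1
  expect_equal(et$n_female[et$threshold == "FC2"], 3)
  expect_equal(et$n_male[et$threshold == "FC4"], 2)
  expect_equal(et$n_female[et$threshold == "FC8"], 1)
})
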