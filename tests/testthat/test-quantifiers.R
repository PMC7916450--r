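test_that("AVE pools spot means over redundant spots", {
  # one gene, one spot, replicas 1..4 -> AVE 2.5; two spots with spot
  # means 2 and 4 -> AVE 3
  f1 <- replica_fabric(matrix(1:4, 1, dimnames = list("g1", NULL)))
  expect_equal(quantifiers(f1, "P")$AVE, 2.5)
  vals <- rbind(c(1, 2, 3, 2), c(3, 4, 5, 4))   # spot means 2 and 4
  f2 <- manual_fabric(vals, gene = c("g1", "g1"),
                      spot_id = c("g1_1", "g1_2"),
                      samples = paste0("P.", 1:4))
  expect_equal(quantifiers(f2, "P")$AVE, 3)
})

test_that("REV is the chi-square mid-interval corrected pooled CV", {
  # frozen oracle: {1,2,3,4} has CV 0.5163978; at r = 3 the mid-interval
  # correction is 0.5 * (3/0.2157953 + 3/9.348404) = 7.1114876
  f <- replica_fabric(matrix(1:4, 1, dimnames = list("g1", NULL)))
  q <- quantifiers(f, "P")
  expect_equal(q$df, 3L)
  expect_equal(q$correction, 7.1114876, tolerance = 1e-6)
  expect_equal(q$REV, 367.23564, tolerance = 1e-6)
  # zero within-spot variance -> REV exactly 0
  f0 <- replica_fabric(matrix(2, 2, 4,
                              dimnames = list(c("a", "b"), NULL)))
  expect_equal(quantifiers(f0, "P")$REV, c(0, 0))
})

test_that("the correction exceeds 1, decreases, and vanishes at large df", {
  dfs <- c(3, 7, 15, 51, 399)
  corr <- rev_correction(dfs)
  expect_true(all(corr > 1))
  expect_true(all(diff(corr) < 0))
  expect_equal(corr[dfs == 399], 1, tolerance = 0.02)
})

test_that("self- and antiphase correlations hit the exact bounds", {
  f <- replica_fabric(rbind(g1 = 1:4, g2 = 4:1, g3 = c(2, 2, 2, 2)))
  expect_equal(compute_cor(f$tensors$P, "g1", "g1")$COR, 1)
  expect_equal(compute_cor(f$tensors$P, "g1", "g2")$COR, -1)
  expect_true(is.na(compute_cor(f$tensors$P, "g1", "g3")$COR))
})

test_that("pooled and spot-averaged correlation paths agree with direct
           arithmetic", {
  set.seed(7)
  # gene a: 2 spots, gene b: 2 spots (pooled path), gene c: 1 spot
  vals <- matrix(exp(rnorm(20, 0, 0.3)) + 1, 5, 4)
  gene <- c("a", "a", "b", "b", "c")
  f <- manual_fabric(vals, gene = gene, samples = paste0("P.", 1:4))
  t <- f$tensors$P
  dev <- vals - rowMeans(vals)
  # pooled, spots paired by index
  da <- as.vector(dev[1:2, ]); db <- as.vector(dev[3:4, ])
  expect_equal(compute_cor(t, "a", "b")$COR,
               sum(da * db) / sqrt(sum(da^2) * sum(db^2)))
  expect_equal(compute_cor(t, "a", "b")$n_eff, 8L)
  # unequal redundancy: per-replica spot-averaged deviations
  ea <- colMeans(dev[1:2, ]); ec <- dev[5, ]
  expect_equal(compute_cor(t, "a", "c")$COR,
               sum(ea * ec) / sqrt(sum(ea^2) * sum(ec^2)))
  expect_equal(compute_cor(t, "a", "c")$n_eff, 4L)
  # the dense pair table agrees with the scalar path
  cc <- coordination(f, "P")
  for (i in seq_len(nrow(cc)))
    expect_equal(cc$COR[i],
                 compute_cor(t, cc$gene_a[i], cc$gene_b[i])$COR)
})

test_that("coordination cutoffs reproduce the printed thresholds", {
  expect_equal(round(cor_cutoff(1), 2), 0.95)
  expect_equal(round(cor_cutoff(2), 3), 0.707)
  expect_equal(round(cor_cutoff(13), 3), 0.273)
  expect_error(cor_cutoff(1, n_replicas = 2), "df")
})

test_that("cutoffs decrease with redundancy and match a t-CDF inversion", {
  cuts <- cor_cutoff(1:13)
  expect_true(all(diff(cuts) < 0))
  # independent oracle: invert the two-tailed t tail probability by
  # bisection rather than through the quantile function
  crit_r <- function(df, alpha = 0.05) {
    f <- function(r) {
      t <- r * sqrt(df) / sqrt(1 - r^2)
      2 * stats::pt(-t, df) - alpha
    }
    stats::uniroot(f, c(1e-9, 1 - 1e-12), tol = 1e-12)$root
  }
  for (R in c(1, 2, 5, 13))
    expect_equal(cor_cutoff(R), crit_r(4 * R - 2), tolerance = 1e-9)
  expect_equal(cor_cutoff(3, alpha = 0.01),
               crit_r(10, alpha = 0.01), tolerance = 1e-9)
  # unequal redundancy is governed by the smaller R
  expect_equal(cor_cutoff(13, 1), cor_cutoff(1))
})

test_that("classification follows the cutoff and independence band", {
  expect_equal(classify_coordination(0.99, cor_cutoff(1)), "synergistic")
  expect_equal(classify_coordination(-0.99, cor_cutoff(1)), "antagonistic")
  expect_equal(classify_coordination(0, cor_cutoff(1)), "independent")
  expect_equal(classify_coordination(0.5, cor_cutoff(1)),
               "not_significant")
  expect_equal(classify_coordination(c(0.8, -0.8), cor_cutoff(2)),
               c("synergistic", "antagonistic"))
  expect_equal(classify_coordination(0.024, cor_cutoff(1), 0.025),
               "independent")
})

test_that("negating one gene's deviations swaps synergism and antagonism", {
  sim <- simulate_experiment(null_design(40, seed = 14,
                                         bio_cv_range = c(0.02, 0.10)))
  fit <- fabric(sim$tables)
  t <- fit$tensors$MRLp
  mirrored <- t$values
  rows <- which(t$spot_gene == 1L)
  mirrored[rows, ] <- 2 * t$mu[rows] - mirrored[rows, ]
  f2 <- manual_fabric(mirrored, gene = t$genes[t$spot_gene],
                      spot_id = t$spot_id,
                      samples = paste0("MRLp.", 1:4))
  g1 <- t$genes[1L]
  for (g in t$genes[2:10]) {
    a <- compute_cor(t, g1, g)$COR
    b <- compute_cor(f2$tensors$MRLp, g1, g)$COR
    expect_equal(b, -a, tolerance = 1e-12)
  }
})

test_that("the COR matrix is symmetric with unit diagonal", {
  sim <- simulate_experiment(default_design("tiny", n_genes = 30,
                                            seed = 16))
  fit <- fabric(sim$tables)
  st <- genofabric:::cor_structures(fit$tensors$MRLlpr)
  C <- genofabric:::cor_matrix_from_structures(st)
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, nrow(C)))
  expect_true(all(abs(C) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("AVE, REV and coordination are statistically independent on null
           data", {
  sim <- simulate_experiment(null_design(1000, seed = 27))
  fit <- fabric(sim$tables)
  q <- quantifiers(fit, "MRLp")
  st <- genofabric:::cor_structures(fit$tensors$MRLp)
  C <- genofabric:::cor_matrix_from_structures(st)
  mean_abs_cor <- (rowSums(abs(C)) - 1) / (nrow(C) - 1)
  expect_lt(abs(stats::cor(q$AVE, q$REV)), 0.1)
  expect_lt(abs(stats::cor(q$AVE, mean_abs_cor)), 0.1)
})
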