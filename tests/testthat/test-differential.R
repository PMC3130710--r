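test_that("group statistics match the textbook pooled-variance formulas", {
  em <- toy_matrix(rbind(c(1, 1, 3, 3), c(0, 2, 0, 2)), 2)
  st <- group_stats(em)
  expect_equal(st$mean_ko, c(1, 1))
  expect_equal(st$mean_wt, c(3, 1))
  expect_equal(st$s2, c(0, 2))
  expect_equal(st$df, c(2, 2))

  set.seed(12)
  vals <- matrix(rnorm(10 * 1), nrow = 1)
  em2 <- toy_matrix(vals, 5)
  st2 <- group_stats(em2)
  ko <- vals[1, 1:5]; wt <- vals[1, 6:10]
  pooled <- ((5 - 1) * var(ko) + (5 - 1) * var(wt)) / (5 + 5 - 2)
  expect_equal(st2$mean_ko, mean(ko))
  expect_equal(st2$s2, pooled)

  expect_error(group_stats(toy_matrix(matrix(1:2, 1), 1)), "at least 2")
})

test_that("linear-positive matrices are log2-transformed with a floor", {
  vals <- matrix(c(4, 4, 8, 8, 1, 2, 1, 2), nrow = 2, byrow = TRUE)
  rownames(vals) <- c("m1", "m2")
  colnames(vals) <- c("KO1", "KO2", "WT1", "WT2")
  em <- expression_matrix(vals, c("KO", "KO", "WT", "WT"), "linear-positive")
  st <- group_stats(em)
  expect_equal(st$mean_ko[1], 2)   # log2(4)
  expect_equal(st$mean_wt[1], 3)   # log2(8)
  expect_error(expression_matrix(vals - 5, c("KO", "KO", "WT", "WT"),
                                 "linear-positive"), "strictly positive")
})

test_that("EB prior estimation recovers generating parameters and edge cases", {
  # recovery from scaled inverse-chi-square draws (d0 = 4, s0^2 = 1)
  set.seed(71)
  df <- 8
  d0 <- 4; s0 <- 1
  s2_true <- d0 * s0 / rchisq(10000, d0)
  s2 <- s2_true * rchisq(10000, df) / df
  pr <- estimate_eb_prior(s2, df)
  expect_equal(pr$d0, d0, tolerance = 0.10)
  expect_equal(pr$s0_sq, s0, tolerance = 0.05)

  # identical variances: infinite prior df, s0^2 equals the common value
  pr2 <- estimate_eb_prior(rep(0.25, 100), df = 8)
  expect_identical(pr2$d0, Inf)
  expect_equal(pr2$s0_sq, 0.25)

  expect_error(estimate_eb_prior(c(0.1, 0.2), df = 4), "at least 50")
  expect_error(estimate_eb_prior(rep(0, 100), df = 4), "degenerate")
})

test_that("EB prior agrees with an independent empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(72)
  s2 <- (4 * 0.05 / rchisq(5000, 4)) * rchisq(5000, 8) / 8
  pr <- estimate_eb_prior(s2, 8)
  ref <- limma::fitFDist(s2, df1 = 8)
  expect_equal(pr$d0, ref$df2, tolerance = 1e-6)
  expect_equal(pr$s0_sq, ref$scale, tolerance = 1e-6)

  # posterior variances match limma::squeezeVar
  sq <- limma::squeezeVar(s2, df = 8)
  st <- data.frame(mean_ko = 0, mean_wt = 0, s2 = s2, df = 8,
                   n_ko = 5, n_wt = 5)
  tt <- moderated_t_test(st, pr)
  s2_post <- (pr$d0 * pr$s0_sq + 8 * s2) / (pr$d0 + 8)
  expect_equal(s2_post, sq$var.post, tolerance = 1e-6)
})

test_that("moderated t follows the shrunken-variance formula", {
  # zero mean difference
  st0 <- data.frame(mean_ko = 1, mean_wt = 1, s2 = 0.5, df = 8,
                    n_ko = 5, n_wt = 5)
  t0 <- moderated_t_test(st0, list(d0 = 4, s0_sq = 0.1))
  expect_equal(t0$t_mod, 0)
  expect_equal(t0$p_value, 1)

  # 3v3 toy with a hand-set prior, against step-by-step arithmetic
  ko <- c(2.1, 2.4, 2.0); wt <- c(1.1, 1.0, 1.3)
  s2 <- (2 * var(ko) + 2 * var(wt)) / 4
  st <- data.frame(mean_ko = mean(ko), mean_wt = mean(wt), s2 = s2, df = 4,
                   n_ko = 3, n_wt = 3)
  tt <- moderated_t_test(st, list(d0 = 4, s0_sq = 0.1))
  s2_post <- (4 * 0.1 + 4 * s2) / (4 + 4)
  t_hand <- (mean(ko) - mean(wt)) / sqrt(s2_post * (1 / 3 + 1 / 3))
  expect_equal(tt$t_mod, t_hand)
  expect_equal(tt$df_total, 8)
  expect_equal(tt$p_value, 2 * pt(-abs(t_hand), 8))

  # d0 = Inf with s0^2 = s2: the known-variance z statistic
  tinf <- moderated_t_test(st, list(d0 = Inf, s0_sq = s2))
  z <- (mean(ko) - mean(wt)) / sqrt(s2 * (2 / 3))
  expect_equal(tinf$t_mod, z)
  expect_equal(tinf$p_value, 2 * pnorm(-abs(z)))
})

test_that("moderated t interpolates between ordinary t and z limits", {
  st <- data.frame(mean_ko = 1.5, mean_wt = 1.0, s2 = 0.3, df = 8,
                   n_ko = 5, n_wt = 5)
  t_ord <- (0.5) / sqrt(0.3 * (2 / 5))
  lo <- moderated_t_test(st, list(d0 = 1e-6, s0_sq = 10))
  expect_equal(lo$t_mod, t_ord, tolerance = 1e-5)
  expect_equal(lo$p_value, 2 * pt(-t_ord, 8), tolerance = 1e-4)
  hi <- moderated_t_test(st, list(d0 = 1e6, s0_sq = 0.3))
  z <- 0.5 / sqrt(0.3 * (2 / 5))
  expect_equal(hi$t_mod, z, tolerance = 1e-4)
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(40)
  for (i in 1:1000) {
    n <- sample(1:60, 1)
    p <- round(runif(n), sample(c(1, 2, 3, 6), 1))  # induce ties
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-15 & adj <= 1))
  }
})

test_that("signed fold change uses the negative-reciprocal convention", {
  expect_equal(signed_fold_change(0, 0), 1)
  expect_equal(signed_fold_change(log2(2.4), 0), 2.4)
  # 10.2-fold down in the knockout reports as -10.2
  expect_equal(signed_fold_change(0, log2(10.2)), -10.2)
  # involution under ratio inversion
  set.seed(41)
  d <- runif(50, -4, 4); d <- d[abs(d) > 1e-6]
  expect_equal(signed_fold_change(d, 0), -signed_fold_change(-d, 0))
  expect_true(all(abs(signed_fold_change(d, 0)) >= 1))
  # round trip back to the ratio scale
  expect_equal(-1 / -10.2, 2^(log2(1 / 10.2) - 0) * 1, tolerance = 1e-12)
})

test_that("null simulations keep type-I error and realized FDR in check", {
  cfg <- sim_config(frac_de = 0, seed = 1)
  rates <- vapply(1:5, function(s) {
    sim <- simulate_expression_matrix(cfg, n_features = 4000,
                                      n_per_group = 5, seed = s)
    d <- run_de(sim$matrix)
    c(mean(d$table$p_value < 0.05), d$n_significant)
  }, c(0, 0))
  expect_gt(mean(rates[1, ]), 0.04)
  expect_lt(mean(rates[1, ]), 0.06)
  # with no true effects, FDR < 0.02 calls are (nearly) absent
  expect_lt(mean(rates[2, ]), 1.5)
})

test_that("run_de is well-powered on planted effects and honors the threshold", {
  cfg <- sim_config(frac_de = 0.1, effect_min = 1, effect_max = 1,
                    var_prior_df = 1e8, var_prior_scale = 0.09, seed = 2)
  sim <- simulate_expression_matrix(cfg, n_features = 2000, n_per_group = 5,
                                    seed = 2)
  d <- run_de(sim$matrix, fdr_threshold = 0.02)
  de <- sim$truth$de_flags
  expect_gt(mean(d$table$significant[de]), 0.8)           # power
  called <- d$table$significant
  expect_lt(mean(!de[called]), 0.05)                      # empirical FDR
  expect_true(all(d$table$adj_p >= d$table$p_value - 1e-15))
  expect_equal(significant_features(d)$feature_id,
               d$table$feature_id[d$table$adj_p < 0.02])
  # empty matrix passes through
  e <- run_de(expression_matrix(matrix(numeric(), 0, 4,
                                       dimnames = list(NULL, paste0("s", 1:4))),
                                c("KO", "KO", "WT", "WT")))
  expect_equal(nrow(e$table), 0)
})

test_that("PCA flags displaced samples but not homogeneous cohorts", {
  set.seed(50)
  vals <- matrix(rnorm(400 * 10), 400)
  em <- toy_matrix(vals, 5)
  expect_false(any(pca_outlier_flags(em, k = 2)))
  vals2 <- vals; vals2[, 3] <- vals2[, 3] + 4   # global 4-SD shift
  em2 <- toy_matrix(vals2, 5)
  flags <- pca_outlier_flags(em2, k = 2)
  expect_true(flags[["KO3"]])
  expect_equal(sum(flags), 1)
  expect_error(pca_outlier_flags(toy_matrix(matrix(rnorm(40), 10), 2), k = 5),
               "fewer samples")
})

test_that("contamination screen flags marker-elevated samples", {
  set.seed(51)
  vals <- matrix(rnorm(100 * 8), 100)
  rownames(vals) <- sprintf("P%03d", 1:100)
  em <- toy_matrix(vals, 4)
  markers <- c("P001", "P002", "P003")
  expect_false(any(contamination_screen(em, markers)))
  vals[markers, 2] <- vals[markers, 2] + 5
  em2 <- toy_matrix(vals, 4)
  expect_true(contamination_screen(em2, markers, z_threshold = 2)[["KO2"]])
  expect_warning(contamination_screen(em2, c(markers, "HBB_MISSING")),
                 "absent")
})
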