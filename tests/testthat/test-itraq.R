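make_design <- function(channels = c("113", "114", "115"),
                        samples = c("KO1", "WT1")) {
  list(run_id = "r1", replicate_id = "rep1",
       channel_to_sample = stats::setNames(samples, channels[-1]),
       reference_channel = channels[1],
       bias = stats::setNames(rep(1, length(channels)), channels),
       correction_matrix = diag(length(channels)))
}

test_that("isotope correction solves the impurity linear system", {
  d <- make_design(channels = c("114", "115"), samples = "KO1")
  rows <- data.frame(run_id = "r1", protein_id = "P1", peptide_key = "p1",
                     "114" = 100, "115" = 100, check.names = FALSE)
  # identity matrix: unchanged
  expect_equal(apply_isotope_correction(rows, d)[, c("114", "115")],
               rows[, c("114", "115")])

  d$correction_matrix <- matrix(c(0.9, 0.1, 0.1, 0.9), 2,
                                dimnames = list(c("114", "115"), c("114", "115")))
  got <- apply_isotope_correction(rows, d)
  expect_equal(unlist(got[, c("114", "115")]), c("114" = 100, "115" = 100))

  # pure channel-114 signal plus spill: corrected by explicit 2x2 inversion
  rows2 <- rows; rows2[["114"]] <- 90; rows2[["115"]] <- 10
  got2 <- apply_isotope_correction(rows2, d)
  inv <- solve(matrix(c(0.9, 0.1, 0.1, 0.9), 2))
  expect_equal(unlist(got2[, c("114", "115")], use.names = FALSE),
               pmax(as.vector(inv %*% c(90, 10)), 0))

  # zero in, zero out; singular matrix refused; negatives floored
  rows3 <- rows; rows3[["114"]] <- 0; rows3[["115"]] <- 0
  expect_equal(unlist(apply_isotope_correction(rows3, d)[, c("114", "115")],
                      use.names = FALSE), c(0, 0))
  d$correction_matrix <- matrix(1, 2, 2,
                                dimnames = list(c("114", "115"), c("114", "115")))
  expect_error(apply_isotope_correction(rows, d), "singular")
})

test_that("ratio pairs take x from the reference and drop zero pairs", {
  d <- make_design()
  rows <- data.frame(run_id = "r1", protein_id = rep("P1", 3),
                     peptide_key = c("a", "b", "c"),
                     "113" = c(100, 0, 200), "114" = c(200, 50, 400),
                     "115" = c(90, 60, 180), check.names = FALSE)
  pr <- build_ratio_pairs(rows, d, "P1", "KO1")
  expect_equal(nrow(pr$pairs), 2)
  expect_equal(pr$n_dropped, 1)
  expect_equal(pr$pairs$x, c(100, 200))
  expect_equal(pr$pairs$y, c(200, 400))
  expect_error(build_ratio_pairs(rows, d, "P1", "NOPE"), "unknown sample_id")
})

test_that("through-origin slope and R^2 follow the closed form", {
  # exact proportionality
  f <- fit_protein_ratio(data.frame(x = c(100, 200, 400), y = c(200, 400, 800)))
  expect_equal(f$slope, 2)
  expect_equal(f$r_squared, 1)
  # single identity point
  expect_equal(fit_protein_ratio(data.frame(x = 100, y = 100))$slope, 1)
  # noisy triple matches sum(xy)/sum(x^2) computed independently
  x <- c(100, 200, 400); y <- c(210, 390, 820)
  f2 <- fit_protein_ratio(data.frame(x = x, y = y))
  expect_equal(f2$slope, oracle_slope(x, y))
  expect_equal(f2$slope, 427000 / 210000)
  # empty input yields a no-estimate result
  expect_null(fit_protein_ratio(data.frame(x = numeric(), y = numeric())))
})

test_that("slope estimator equals the brute-force oracle on random pair sets", {
  set.seed(20)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    x <- stats::rlnorm(n, 5, 1)
    y <- stats::rlnorm(n, 5, 1)
    f <- fit_protein_ratio(data.frame(x = x, y = y))
    expect_equal(f$slope, oracle_slope(x, y))
    r2 <- 1 - sum((y - f$slope * x)^2) / sum(y^2)
    expect_equal(f$r_squared, min(max(r2, 0), 1))
  }
})

test_that("slope is scale-equivariant in y with unchanged R^2", {
  set.seed(21)
  x <- stats::rlnorm(8, 5, 1); y <- 2 * x * stats::rlnorm(8, 0, 0.1)
  f <- fit_protein_ratio(data.frame(x = x, y = y))
  for (c in c(0.1, 3, 50)) {
    fc <- fit_protein_ratio(data.frame(x = x, y = c * y))
    expect_equal(fc$slope, c * f$slope)
    expect_equal(fc$r_squared, f$r_squared)
  }
})

test_that("regression outlier removal drops gross outliers but respects guards", {
  # perfectly proportional: nothing to remove
  clean <- data.frame(x = 1:11 * 50, y = 1:11 * 100,
                      peptide_key = letters[1:11])
  expect_equal(remove_regression_outliers(clean)$removed_count, 0)

  # 11 on-line pairs + 1 pair at 8x the line: that pair removed (with a
  # single outlier the standardized residual is bounded by ~sqrt(n - 1),
  # so the strict > 3 rule needs n >= 11 clean points to be able to fire)
  out <- rbind(clean, data.frame(x = 300, y = 8 * 600, peptide_key = "z"))
  res <- remove_regression_outliers(out)
  expect_equal(res$removed_count, 1)
  expect_false("z" %in% res$pairs$peptide_key)

  # 3 pairs with one outlier: below the minimum, untouched
  small <- data.frame(x = c(10, 20, 30), y = c(20, 40, 600),
                      peptide_key = c("a", "b", "c"))
  expect_equal(remove_regression_outliers(small)$removed_count, 0)
  # never removes below 3 remaining pairs
  four <- data.frame(x = c(10, 20, 30, 40), y = c(20, 40, 900, 1000),
                     peptide_key = letters[1:4])
  expect_gte(nrow(remove_regression_outliers(four)$pairs), 3)
})

test_that("channel bias adjustment centers high-confidence ratios at 1", {
  est <- data.frame(run_id = "r1", replicate_id = "rep1",
                    channel = rep(c("114", "115"), each = 3),
                    sample_id = rep(c("KO1", "WT1"), each = 3),
                    protein_id = rep(c("P1", "P2", "P3"), 2),
                    slope = c(2, 2, 2, 1, 1, 1),
                    r_squared = 0.95, n_unique_peptides = 3L,
                    n_observations = 5L, max_intensity = 1e4,
                    outliers_removed = 0L, n_zero_dropped = 0L,
                    stringsAsFactors = FALSE)
  adj <- adjust_channel_bias(est)
  expect_equal(adj$bias_factors$bias[adj$bias_factors$channel == "114"], 2)
  expect_equal(adj$estimates$slope, rep(1, 6))
  # already centered input is unchanged and the operation is idempotent
  again <- adjust_channel_bias(adj$estimates)
  expect_equal(again$estimates$slope, adj$estimates$slope)
  expect_equal(again$bias_factors$bias, rep(1, 2))
  # a channel with no high-confidence proteins keeps factor 1, with warning
  lo <- est[1:3, ]; lo$r_squared <- 0.5
  expect_warning(adj2 <- adjust_channel_bias(lo), "no high-confidence")
  expect_equal(adj2$estimates$slope, lo$slope)
})

test_that("bias factors planted in the simulation are recovered", {
  cfg <- sim_config(n_proteins = 250, peptides_min = 5, peptides_mean = 6,
                    noise_cv = 0.1, outlier_fraction = 0, bias_range = 1.5,
                    frac_de = 0.02, n_per_group = 4, seed = 31)
  ex <- simulate_itraq_experiment(cfg, n_replicates = 1)
  est <- quantify_run(ex$runs[[1]], ex$designs[[1]])
  adj <- adjust_channel_bias(est)
  bf <- adj$bias_factors
  planted <- ex$designs[[1]]$bias[bf$channel]
  expect_true(all(abs(bf$bias / planted - 1) < 0.05))
})

test_that("estimate filtering applies the strict R^2 and depth rules", {
  mk <- function(r2, pep, obs)
    data.frame(r_squared = r2, n_unique_peptides = pep, n_observations = obs,
               slope = 1)
  expect_equal(nrow(filter_estimates(mk(0.70, 3, 6))), 0)  # boundary rejected
  expect_equal(nrow(filter_estimates(mk(0.95, 1, 5))), 0)  # peptide rule
  expect_equal(nrow(filter_estimates(mk(0.80, 2, 4))), 1)  # boundary kept
  expect_equal(nrow(filter_estimates(mk(0.80, 2, 3))), 0)  # observation rule
})

test_that("replicate compositing averages, falls back and flags mismatches", {
  mk <- function(prot, samp, slope, run = "rA")
    data.frame(run_id = run, protein_id = prot, sample_id = samp,
               slope = slope, stringsAsFactors = FALSE)
  a <- rbind(mk("P1", "KO1", 2), mk("P2", "KO1", 1.5), mk("P3", "KO1", 4))
  b <- rbind(mk("P1", "KO1", 2, "rB"), mk("P3", "KO1", 1, "rB"))
  comp <- composite_ratios(a, b, mismatch_log2_threshold = 1)
  comp <- comp[order(comp$protein_id), ]
  expect_equal(comp$ratio[comp$protein_id == "P1"], 2)
  expect_identical(comp$source[comp$protein_id == "P1"], "both-replicates")
  expect_equal(comp$ratio[comp$protein_id == "P2"], 1.5)
  expect_identical(comp$source[comp$protein_id == "P2"], "single-replicate")
  # |log2(4/1)| = 2 > 1: flagged
  expect_true(comp$mismatch_flag[comp$protein_id == "P3"])
  # geometric-mean compositing
  comp2 <- composite_ratios(mk("P1", "KO1", 2), mk("P1", "KO1", 1.9, "rB"))
  expect_equal(comp2$ratio, sqrt(2 * 1.9))
  # duplicated estimates must have been aggregated upstream
  expect_error(composite_ratios(rbind(a, a[1, ]), b), "duplicate")
})

test_that("noiseless quantification recovers the planted log2 matrix exactly", {
  ne <- noiseless_experiment()
  q <- quantify_run_set(ne$experiment$runs, ne$experiment$designs,
                        quant_params(adjust_bias = FALSE))
  m <- coef(q)
  truth <- ne$experiment$truth$protein_log2_ratio[rownames(m), colnames(m)]
  expect_equal(dim(m), dim(truth))
  expect_lt(max(abs(m - truth)), 1e-10)
  expect_equal(q$qc$n_mismatch_excluded, 0)
})

test_that("noisy quantification recovers truth with bounded error", {
  cfg <- sim_config(n_proteins = 150, peptides_min = 6, peptides_mean = 6,
                    noise_cv = 0.2, outlier_fraction = 0.01,
                    bias_range = 1.5, n_per_group = 4, seed = 8)
  ex <- simulate_itraq_experiment(cfg)
  q <- quantify_run_set(ex$runs, ex$designs)
  m <- coef(q)
  truth <- ex$truth$protein_log2_ratio[rownames(m), colnames(m)]
  rmse <- sqrt(mean((m - truth)^2, na.rm = TRUE))
  expect_lt(rmse, 0.25)
})

test_that("ratio recovery improves with peptide depth", {
  rmse_at <- function(n_pep, seed) {
    cfg <- sim_config(n_proteins = 40, peptides_min = n_pep,
                      peptides_mean = n_pep, noise_cv = 0.2,
                      outlier_fraction = 0, bias_range = 1, frac_de = 0.1,
                      n_per_group = 3, seed = seed)
    ex <- simulate_itraq_experiment(cfg, n_replicates = 1)
    q <- quantify_run_set(ex$runs, ex$designs,
                          quant_params(adjust_bias = FALSE,
                                       filter_min_peptides = 1L,
                                       filter_min_obs = 2L))
    m <- coef(q)
    truth <- ex$truth$protein_log2_ratio[rownames(m), colnames(m)]
    sqrt(mean((m - truth)^2, na.rm = TRUE))
  }
  seeds <- 1:20
  r2 <- mean(vapply(seeds, function(s) rmse_at(2, s), 0))
  r4 <- mean(vapply(seeds, function(s) rmse_at(4, s), 0))
  r8 <- mean(vapply(seeds, function(s) rmse_at(8, s), 0))
  expect_gt(r2, r4)
  expect_gt(r4, r8)
})

test_that("empty input produces an empty matrix with a warning", {
  expect_warning(q <- quantify_run_set(list(), list()), "empty")
  expect_equal(dim(q$log2_matrix), c(0, 0))
})
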