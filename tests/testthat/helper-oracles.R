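# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# through-origin least-squares slope, computed by explicit accumulation
oracle_slope <- function(x, y) {
  sxy <- 0; sxx <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + x[i] * y[i]
    sxx <- sxx + x[i]^2
  }
  sxy / sxx
}

# Benjamini-Hochberg step-up, literal textbook enumeration
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running_min <- 1
  for (i in n:1) {
    running_min <- min(running_min, p[o[i]] * n / i)
    adj[o[i]] <- running_min
  }
  pmin(adj, 1)
}

# hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# C(N, n) draws of the sample list from the universe
oracle_hyper_tail <- function(k, n, K, N) {
  if (k == 0) return(1)
  universe <- seq_len(N)
  hits <- universe <= K          # first K elements are set members
  draws <- utils::combn(N, n)
  mean(colSums(matrix(hits[draws], nrow = n)) >= k)
}

# Pearson correlation from the raw definition
oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# small noiseless iTRAQ experiment used by several end-to-end tests
noiseless_experiment <- function(n_proteins = 30, frac_de = 0.2,
                                 n_per_group = 4, seed = 42) {
  cfg <- sim_config(n_proteins = n_proteins, peptides_min = 4,
                    peptides_mean = 5, noise_cv = 0, outlier_fraction = 0,
                    bias_range = 1, frac_de = frac_de,
                    n_per_group = n_per_group, seed = seed)
  list(config = cfg, experiment = simulate_itraq_experiment(cfg))
}

# tiny two-group expression matrix built by hand
toy_matrix <- function(values, n_per_group) {
  groups <- rep(c("KO", "WT"), each = n_per_group)
  colnames(values) <- paste0(groups, seq_len(n_per_group))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%03d", seq_len(nrow(values)))
  expression_matrix(values, groups, scale_tag = "log2")
}
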