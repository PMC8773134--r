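# Independent oracles and small fixture builders used across tests.

# One-factor PERMANOVA pseudo-F computed straight from the distance-based
# sum-of-squares identities (independent of vegan):
#   SST = sum_{i<j} d_ij^2 / n,  SSW = sum_g sum_{i<j in g} d_ij^2 / n_g
permanova_F_oracle <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  a <- length(unique(groups))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# exact permutation p-value by full enumeration of label orders
permanova_p_exact <- function(d, groups) {
  n <- length(groups)
  perms <- gtools_permutations(n)
  f_obs <- permanova_F_oracle(d, groups)
  f_all <- apply(perms, 1, function(ix) permanova_F_oracle(d, groups[ix]))
  mean(f_all >= f_obs - 1e-12)
}

# all n! permutations of 1..n (tiny n only), no external dependency
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# toy learner that predicts the mean of its training labels (OOF oracle)
mean_learner <- function() {
  custom_learner("foldmean",
                 fit = function(X, y) mean(y),
                 predict = function(m, X) rep(m, nrow(X)))
}

# small deterministic two-view cohort shared by several test files
tiny_cohort <- function(n = 120, seed = 11, ...) {
  simulate_cohort(n_samples = n, n_species = 25, n_pathways = 15,
                  signal_effect = 0.05, seed = seed, ...)
}

clr_of <- function(view) clr_transform(multiplicative_replacement(view))
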