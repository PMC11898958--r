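# Independent oracles and small fixture builders shared across tests.

# Normal-equations OLS: solve X'X b = X'y directly (intercept prepended).
oracle_ols <- function(X, y) {
  D <- cbind(1, as.matrix(X))
  drop(solve(crossprod(D), crossprod(D, y)))
}

# Brute-force leave-one-out: n separate refits via the normal equations.
oracle_loo <- function(X, y) {
  X <- as.matrix(X)
  vapply(seq_len(nrow(X)), function(i) {
    b <- oracle_ols(X[-i, , drop = FALSE], y[-i])
    drop(c(1, X[i, ]) %*% b)
  }, numeric(1))
}

# Pearson r from raw sums, independent of stats::cor.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Random full-rank regression design with a linear signal.
random_design <- function(n, p, noise = 0.5) {
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("V", seq_len(p))))
  beta <- rnorm(p)
  list(X = X, y = drop(X %*% beta) + rnorm(n, sd = noise), beta = beta)
}

# Random inclusion mask with exactly k selected genes.
repair_mask_for_test <- function(len, k) {
  m <- rep(FALSE, len)
  m[sample(len, k)] <- TRUE
  m
}

# A small descriptor CSV on disk; returns its path.
write_descriptor_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "descriptors.csv")
  write.csv(df, path, row.names = FALSE)
  path
}
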