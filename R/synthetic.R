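# Synthetic data with the statistical structure the GA-MLR analysis
# assumes: correlated descriptor blocks, near-duplicate columns for the
# pruning stage, and a sparse linear response with Gaussian noise.

#' Generate a synthetic compound-by-descriptor matrix
#'
#' Base descriptors are standard normal. When `block_correlation > 0`,
#' consecutive base columns are organized into blocks of `block_size` that
#' share a latent factor (`X = sqrt(rho) F + sqrt(1 - rho) E`), giving
#' within-block correlation `rho`. `n_redundant` additional columns are
#' near-duplicates of randomly chosen base columns (base + Normal(0, 0.01)
#' perturbation, pairwise r > 0.99), planted so the pruning stage has
#' something to find. Column provenance records the role of each column.
#'
#' @param n_compounds number of rows (>= 4)
#' @param n_descriptors total number of columns, including redundant ones
#' @param block_correlation within-block correlation in \[0, 1)
#' @param n_redundant number of planted near-duplicate columns
#' @param block_size columns per correlated block (default 5)
#' @param seed integer seed
#' @return A `descriptor_matrix` with provenance `"base"`, `"block <b>"` or
#'   `"duplicate of <name>"`.
#' @export
generate_descriptors <- function(n_compounds, n_descriptors,
                                 block_correlation = 0, n_redundant = 0,
                                 block_size = 5L, seed = 1L) {
  if (n_compounds < 4L) stop("need at least 4 compounds")
  if (n_redundant >= n_descriptors) {
    stop("n_redundant must be smaller than n_descriptors")
  }
  stopifnot(block_correlation >= 0, block_correlation < 1)
  set.seed(seed)
  n_base <- n_descriptors - n_redundant
  E <- matrix(rnorm(n_compounds * n_base), n_compounds, n_base)
  prov <- rep("base", n_base)
  if (block_correlation > 0) {
    blocks <- ceiling(seq_len(n_base) / block_size)
    F_ <- matrix(rnorm(n_compounds * max(blocks)), n_compounds)
    X <- sqrt(block_correlation) * F_[, blocks] +
      sqrt(1 - block_correlation) * E
    prov <- paste("block", blocks)
  } else {
    X <- E
  }
  names_base <- sprintf("D%03d", seq_len(n_base))
  if (n_redundant > 0) {
    src <- sample(n_base, n_redundant, replace = n_redundant > n_base)
    dup <- X[, src, drop = FALSE] +
      matrix(rnorm(n_compounds * n_redundant, sd = 0.01), n_compounds)
    X <- cbind(X, dup)
    prov <- c(prov, paste("duplicate of", names_base[src]))
  }
  descriptor_matrix(
    X, compound_names = sprintf("SynOP-%02d", seq_len(n_compounds)),
    descriptor_names = c(names_base,
                         if (n_redundant > 0)
                           sprintf("R%03d", seq_len(n_redundant))),
    provenance = prov)
}

#' Plant a sparse linear response on a descriptor matrix
#'
#' Chooses `support_size` descriptors at random (excluding planted
#' duplicates), draws coefficients of magnitude about `effect_scale` with
#' random signs, and generates `y = intercept + X beta + Normal(0, sd)`
#' noise. With `relative_noise = TRUE` the noise standard deviation is
#' `noise_sd` times the standard deviation of the noiseless signal.
#'
#' @param X a `descriptor_matrix` (e.g. from [generate_descriptors()])
#' @param support_size number of truly predictive descriptors
#' @param effect_scale coefficient magnitude scale
#' @param noise_sd Gaussian noise standard deviation (absolute, or a
#'   fraction of the signal sd when `relative_noise = TRUE`)
#' @param intercept true intercept
#' @param relative_noise interpret `noise_sd` relative to the signal sd
#' @param seed integer seed
#' @return A `synthetic_dataset`: list with `X`, `y`, `true_support`,
#'   `true_coefficients`, `intercept`, `noise_sd` (the absolute value
#'   used) and `seed`.
#' @export
generate_response <- function(X, support_size, effect_scale = 1,
                              noise_sd = 0.1, intercept = 0,
                              relative_noise = FALSE, seed = 1L) {
  prov <- attr(X, "provenance") %||% rep("", ncol(X))
  eligible <- colnames(X)[!startsWith(prov, "duplicate")]
  if (support_size > length(eligible)) {
    stop("support_size exceeds the non-redundant descriptor count")
  }
  set.seed(seed)
  support <- sort(sample(eligible, support_size))
  beta <- effect_scale * runif(support_size, 0.8, 1.2) *
    sample(c(-1, 1), support_size, replace = TRUE)
  names(beta) <- support
  signal <- intercept + drop(unclass(X)[, support, drop = FALSE] %*% beta)
  sd_used <- if (relative_noise) noise_sd * sd(signal) else noise_sd
  y <- signal + rnorm(nrow(X), sd = sd_used)
  out <- list(X = X, y = setNames(y, rownames(X)), true_support = support,
              true_coefficients = beta, intercept = intercept,
              noise_sd = sd_used, seed = as.integer(seed))
  class(out) <- "synthetic_dataset"
  out
}

#' Generate a synthetic chromatographic endpoint table
#'
#' Emulates the structure of a biomimetic-chromatography endpoint table:
#' `chi_c18` in \[20, 110\] and `chi_iam` in \[15, 45\] correlated at about
#' `cor_chi` (lipophilicity drives phospholipid affinity), `logk_hsa` in
#' \[-0.5, 1.3\] correlated with `chi_iam` at about `cor_hsa` (protein
#' binding is only partly lipophilicity-driven), and `pct_hsa` computed
#' exactly from `logk_hsa` via [percent_hsa_from_logk()]. Values are
#' Gaussian-copula draws, so target correlations are approached with mild
#' attenuation (within about 0.05 at these levels).
#'
#' @param n_compounds number of compounds (>= 4)
#' @param cor_chi latent correlation between the two CHI indices
#' @param cor_hsa latent correlation between `chi_iam` and `logk_hsa`
#' @param seed integer seed
#' @return A `retention_table`.
#' @export
generate_endpoint_table <- function(n_compounds, cor_chi = 0.9,
                                    cor_hsa = 0.7, seed = 1L) {
  if (n_compounds < 4L) stop("need at least 4 compounds")
  stopifnot(abs(cor_chi) < 1, abs(cor_hsa) < 1)
  set.seed(seed)
  z1 <- rnorm(n_compounds)
  z2 <- cor_chi * z1 + sqrt(1 - cor_chi^2) * rnorm(n_compounds)
  z3 <- cor_hsa * z2 + sqrt(1 - cor_hsa^2) * rnorm(n_compounds)
  logk <- -0.5 + 1.8 * pnorm(z3)
  out <- data.frame(
    id = seq_len(n_compounds),
    name = sprintf("SynOP-%02d", seq_len(n_compounds)),
    chi_c18 = 20 + 90 * pnorm(z1),
    chi_iam = 15 + 30 * pnorm(z2),
    logk_hsa = logk,
    pct_hsa = percent_hsa_from_logk(logk),
    stringsAsFactors = FALSE)
  class(out) <- c("retention_table", "data.frame")
  out
}
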