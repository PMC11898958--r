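# Descriptor-matrix pruning and auto-scaling, applied before model building.

#' Prune constant, near-constant and highly correlated descriptors
#'
#' Removes, in order: constant columns; near-constant columns (modal value
#' occupying more than `near_constant_freq` of entries, or sample standard
#' deviation below `1e-8` times the value range); and, from every pair with
#' absolute Pearson correlation at or above `corr_threshold`, one column.
#' The absolute value is used so that strong negative correlation also
#' triggers removal. The correlated-pair tie-break keeps the earlier column
#' in input order (`tie_break = "first"`) or the higher-variance column
#' (`tie_break = "variance"`); both are deterministic.
#'
#' @param X a `descriptor_matrix` (or plain numeric matrix) with >= 2 rows
#' @param corr_threshold prune one of each pair with `|r| >=` this value
#'   (default 0.95)
#' @param near_constant_freq modal-frequency fraction above which a column
#'   is near-constant (default 0.95)
#' @param tie_break which column of a correlated pair to keep
#' @return List with `matrix` (the pruned `descriptor_matrix`) and `report`
#'   (a `pruning_report`: `removed_constant`, `removed_near_constant`,
#'   `removed_correlated` as a kept/dropped data frame, and the thresholds).
#' @export
prune_descriptors <- function(X, corr_threshold = 0.95,
                              near_constant_freq = 0.95,
                              tie_break = c("first", "variance")) {
  tie_break <- match.arg(tie_break)
  if (nrow(X) < 2L) stop("need at least 2 compounds to prune")
  stopifnot(corr_threshold > 0, corr_threshold <= 1)
  if (!inherits(X, "descriptor_matrix")) X <- descriptor_matrix(X)
  cols <- colnames(X)

  sds <- apply(X, 2L, sd)
  ranges <- apply(X, 2L, function(x) diff(range(x)))
  constant <- cols[ranges == 0]

  modal_freq <- apply(X, 2L, function(x) max(table(x)) / length(x))
  near <- cols[!(cols %in% constant) &
                 (modal_freq > near_constant_freq | sds < 1e-8 * ranges)]

  keep <- setdiff(cols, c(constant, near))
  dropped_pairs <- data.frame(kept = character(0), dropped = character(0),
                              r = numeric(0), stringsAsFactors = FALSE)
  if (length(keep) >= 2L) {
    R <- abs(cor(unclass(X)[, keep, drop = FALSE]))
    diag(R) <- 0
    # Greedy scan in input order: the first member of each offending pair
    # wins unless tie_break = "variance" prefers the spread-out column.
    alive <- rep(TRUE, length(keep))
    for (i in seq_along(keep)) {
      if (!alive[i]) next
      for (j in seq_along(keep)) {
        if (j <= i || !alive[j]) next
        if (R[i, j] >= corr_threshold) {
          drop_j <- tie_break == "first" || sds[keep[j]] <= sds[keep[i]]
          d <- if (drop_j) j else i
          k <- if (drop_j) i else j
          alive[d] <- FALSE
          dropped_pairs <- rbind(dropped_pairs, data.frame(
            kept = keep[k], dropped = keep[d], r = R[i, j],
            stringsAsFactors = FALSE))
          if (!drop_j) break
        }
      }
    }
    keep <- keep[alive]
  }
  if (length(keep) == 0L) {
    stop("pruning removed every descriptor; relax the thresholds")
  }
  report <- list(removed_constant = constant,
                 removed_near_constant = near,
                 removed_correlated = dropped_pairs,
                 corr_threshold = corr_threshold,
                 near_constant_freq = near_constant_freq,
                 n_in = length(cols), n_out = length(keep))
  class(report) <- "pruning_report"
  list(matrix = subset_descriptors(X, keep), report = report)
}

#' @export
print.pruning_report <- function(x, ...) {
  cat(sprintf("Descriptor pruning: %d -> %d columns\n", x$n_in, x$n_out))
  cat(sprintf("  constant: %d, near-constant: %d, correlated (|r| >= %.2f): %d\n",
              length(x$removed_constant), length(x$removed_near_constant),
              x$corr_threshold, nrow(x$removed_correlated)))
  invisible(x)
}

#' Auto-scale a numeric matrix
#'
#' Standardizes every column to zero mean and unit sample standard
#' deviation, the scaling applied before clustering and heat-map display so
#' that indices on different scales contribute equally.
#'
#' @param X numeric matrix with no constant column
#' @return Matrix of the same shape; attributes `center` and `scale` hold
#'   the column means and standard deviations.
#' @export
autoscale <- function(X) {
  X <- as.matrix(unclass(X))
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
         "; prune before auto-scaling")
  }
  ctr <- colMeans(X)
  out <- sweep(sweep(X, 2L, ctr), 2L, sds, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sds
  out
}
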