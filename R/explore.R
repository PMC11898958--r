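# Exploratory analysis of the endpoint table: correlations, auto-scaled
# hierarchical clustering, bioaccumulation grouping.

default_endpoint_columns <- c("chi_c18", "chi_iam", "logk_hsa")

#' Pearson correlation matrix of endpoint columns
#'
#' @param table a `retention_table` (>= 3 compounds)
#' @param columns endpoint columns to correlate; the default uses the three
#'   independent measurements (`%HSA` is a deterministic transform of
#'   `logk_hsa` and is excluded to avoid double-weighting)
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, columns = default_endpoint_columns) {
  M <- endpoint_matrix(table, columns)
  if (nrow(M) < 3L) stop("need at least 3 compounds")
  cor(M)
}

endpoint_matrix <- function(table, columns) {
  missing <- setdiff(columns, names(table))
  if (length(missing) > 0L) {
    stop("column(s) not in table: ", paste(missing, collapse = ", "))
  }
  M <- as.matrix(as.data.frame(table)[, columns, drop = FALSE])
  rownames(M) <- table$name
  if (any(apply(M, 2L, sd) == 0)) stop("constant endpoint column")
  M
}

#' Hierarchical clustering of auto-scaled endpoints
#'
#' Agglomerative clustering of the compounds on the selected endpoint
#' columns, auto-scaled so each index contributes equally. Default linkage
#' is Ward (on squared Euclidean distances, `hclust` method `ward.D2`).
#'
#' @inheritParams correlation_matrix
#' @param linkage `"ward"`, `"single"`, `"complete"` or `"average"`
#' @param distance currently `"euclidean"`
#' @return A `qsrr_hclust`: list with the `hclust` tree, the auto-scaled
#'   `data` matrix, `leaf_order` (compound names in dendrogram order) and
#'   the settings used.
#' @export
hierarchical_cluster <- function(table, columns = default_endpoint_columns,
                                 linkage = c("ward", "single", "complete",
                                             "average"),
                                 distance = "euclidean") {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance, "euclidean")
  M <- endpoint_matrix(table, columns)
  if (nrow(M) < 2L) stop("need at least 2 compounds to cluster")
  S <- autoscale(M)
  hc <- hclust(dist(S, method = distance),
               method = if (linkage == "ward") "ward.D2" else linkage)
  out <- list(tree = hc, data = S, columns = columns, linkage = linkage,
              distance = distance,
              leaf_order = rownames(S)[hc$order])
  class(out) <- "qsrr_hclust"
  out
}

#' Cut a clustering tree into groups
#'
#' Rule `"k"` cuts into exactly `k` groups. Rule `"gap"` cuts where the gap
#' between successive merge heights is largest, a simple heuristic for the
#' natural number of groups.
#'
#' @param clustering a `qsrr_hclust`
#' @param rule `"k"` or `"gap"`
#' @param k group count for rule `"k"`
#' @return Named integer group labels (1..k), with attribute `k`.
#' @export
cut_tree <- function(clustering, rule = c("k", "gap"), k = NULL) {
  rule <- match.arg(rule)
  hc <- clustering$tree
  n <- length(hc$labels %||% hc$order)
  if (rule == "k") {
    if (is.null(k)) stop("rule 'k' needs k")
    if (k > n) stop("k exceeds the number of compounds")
    labels <- cutree(hc, k = k)
  } else {
    h <- hc$height  # non-decreasing for monotone linkages
    k <- if (length(h) < 2L) 2L else n - which.max(diff(h))
    labels <- cutree(hc, k = k)
  }
  attr(labels, "k") <- as.integer(k)
  labels
}

#' Name clusters by bioaccumulation potential
#'
#' Orders clusters by their mean `chi_c18` (lipophilicity, the main driver
#' of bioaccumulation) and names them `low` < `medium` < `high` for three
#' groups, or `group1` (lowest) upward otherwise.
#'
#' @param table the `retention_table` that was clustered
#' @param labels integer group labels from [cut_tree()]
#' @param by endpoint column used to rank the groups
#' @return Factor of group names, ordered low to high.
#' @export
label_bioaccumulation <- function(table, labels, by = "chi_c18") {
  k <- length(unique(labels))
  means <- tapply(table[[by]], labels, mean)
  lvl <- if (k == 3L) c("low", "medium", "high") else paste0("group", seq_len(k))
  name_of <- setNames(lvl[rank(means)], names(means))
  factor(name_of[as.character(labels)], levels = lvl)
}
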