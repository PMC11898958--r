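# Domain containers, packaged fixtures, readers/writers and configuration.

#' Load a chromatographic endpoint table
#'
#' Reads a table of compounds with their measured biomimetic-chromatography
#' indices: `chi_c18` (reversed-phase chromatographic hydrophobicity index),
#' `chi_iam` (immobilized-artificial-membrane index, phospholipid affinity),
#' `logk_hsa` (log retention-derived affinity to human serum albumin) and
#' `pct_hsa` (percent plasma-protein binding). The built-in source
#' `"builtin:op18"` returns the packaged 18-compound organophosphate
#' pesticide dataset.
#'
#' @param source either `"builtin:op18"` or the path to a CSV file with a
#'   header row and at least the columns `name`, `chi_c18`, `chi_iam`,
#'   `logk_hsa`, `pct_hsa`. An `id` column and a `smiles` column are
#'   optional; `id` defaults to the row number.
#' @return A `retention_table`: a data frame with one row per compound,
#'   columns `id`, `name`, `chi_c18`, `chi_iam`, `logk_hsa`, `pct_hsa` and
#'   optionally `smiles`, in file order.
#' @examples
#' tab <- load_retention_table("builtin:op18")
#' tab[tab$name == "Dichlorvos", "chi_c18"]
#' @export
load_retention_table <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  path <- if (identical(source, "builtin:op18")) {
    system.file("extdata", "op_chromatographic_indices.csv",
                package = "qsrrop", mustWork = TRUE)
  } else {
    source
  }
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    read.csv(path, check.names = FALSE, colClasses = "character",
             fileEncoding = "UTF-8"),
    error = function(e) stop("schema error: unreadable table in ", path))
  if (nrow(raw) == 0L || ncol(raw) == 0L) {
    stop("schema error: empty table in ", path)
  }
  required <- c("name", "chi_c18", "chi_iam", "logk_hsa", "pct_hsa")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  num_cols <- c("chi_c18", "chi_iam", "logk_hsa", "pct_hsa")
  out <- data.frame(
    id = if ("id" %in% names(raw)) as.integer(raw$id) else seq_len(nrow(raw)),
    name = raw$name,
    stringsAsFactors = FALSE
  )
  for (col in num_cols) out[[col]] <- parse_numeric_column(raw[[col]], col)
  if ("smiles" %in% names(raw)) out$smiles <- raw$smiles
  validate_retention_table(out)
  class(out) <- c("retention_table", "data.frame")
  out
}

# Numeric parsing with Unicode-minus normalization (printed tables often use
# U+2212) and a row/column-addressed error for anything non-numeric.
parse_numeric_column <- function(x, col) {
  x <- gsub("−", "-", trimws(x))
  bad <- which(is.na(suppressWarnings(as.numeric(x))) | x == "")
  if (length(bad) > 0L) {
    stop("parse error: non-numeric cell at row ", bad[1L],
         ", column '", col, "'")
  }
  as.numeric(x)
}

validate_retention_table <- function(tab) {
  if (anyDuplicated(tab$name)) {
    stop("compound names must be unique; duplicated: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  }
  if (any(tab$pct_hsa <= 0 | tab$pct_hsa >= 100)) {
    stop("pct_hsa must lie in (0, 100)")
  }
  invisible(tab)
}

#' Write a retention table to CSV
#'
#' @param tab a `retention_table`
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
save_retention_table <- function(tab, path) {
  stopifnot(inherits(tab, "retention_table"))
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Load a compound-by-descriptor matrix
#'
#' Reads a delimited table whose first column holds compound names and whose
#' remaining columns are numeric molecular descriptors (from any descriptor
#' software). Missing values are rejected: descriptor imputation is out of
#' scope and upstream software should be consulted instead.
#'
#' @param path CSV path: header row, first column compound name, remaining
#'   columns numeric.
#' @return A `descriptor_matrix`: a numeric matrix (rows = compounds in file
#'   order, rownames = compound names) with a `provenance` attribute holding
#'   one free-text string per descriptor.
#' @export
load_descriptor_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("schema error: need a compound-name column plus >= 1 descriptor")
  }
  cmp <- raw[[1L]]
  if (anyDuplicated(cmp)) {
    stop("duplicate compound names: ",
         paste(unique(cmp[duplicated(cmp)]), collapse = ", "))
  }
  vals <- vapply(names(raw)[-1L], function(col) {
    x <- gsub("−", "-", trimws(raw[[col]]))
    bad <- which(is.na(suppressWarnings(as.numeric(x))) | x == "")
    if (length(bad) > 0L) {
      stop("missing or non-numeric value at row ", bad[1L],
           " ('", cmp[bad[1L]], "'), descriptor '", col, "'")
    }
    as.numeric(x)
  }, numeric(nrow(raw)))
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L,
                                      dimnames = list(NULL, names(raw)[-1L]))
  descriptor_matrix(vals, compound_names = cmp)
}

#' Construct a descriptor matrix
#'
#' @param values numeric matrix, rows = compounds, columns = descriptors
#' @param compound_names character vector of row labels (unique)
#' @param descriptor_names optional column labels (default: existing
#'   colnames)
#' @param provenance optional per-descriptor free-text provenance (software,
#'   descriptor block)
#' @return A `descriptor_matrix` object.
#' @export
descriptor_matrix <- function(values, compound_names = rownames(values),
                              descriptor_names = colnames(values),
                              provenance = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(compound_names)) compound_names <- as.character(seq_len(nrow(values)))
  if (is.null(descriptor_names)) descriptor_names <- paste0("D", seq_len(ncol(values)))
  stopifnot(length(compound_names) == nrow(values),
            length(descriptor_names) == ncol(values))
  if (anyDuplicated(compound_names)) stop("duplicate compound names")
  if (anyNA(values)) stop("descriptor matrix contains missing values")
  dimnames(values) <- list(compound_names, descriptor_names)
  if (is.null(provenance)) provenance <- rep("", ncol(values))
  stopifnot(length(provenance) == ncol(values))
  attr(values, "provenance") <- setNames(provenance, descriptor_names)
  class(values) <- c("descriptor_matrix", class(values))
  values
}

# Keep provenance/class when subsetting columns of a descriptor matrix.
subset_descriptors <- function(X, keep) {
  prov <- attr(X, "provenance")
  Y <- unclass(X)[, keep, drop = FALSE]
  descriptor_matrix(Y, compound_names = rownames(Y),
                    descriptor_names = colnames(Y),
                    provenance = unname(prov[colnames(Y)]))
}

#' Reference QSRR models for the organophosphate endpoint set
#'
#' Returns the three published two-descriptor model equations for the
#' 18-compound organophosphate set as fitted-form [qsrr_model] objects:
#' CHI_C18 from `SpMax_Dz(i)` and `R3s`, CHI_IAM from `LogP` and `PJI3`,
#' and LogK_HSA from `LogS` and `TDB05i`. Coefficients are the printed
#' values; the underlying descriptor values are not published, so these
#' models serve as prediction-equation fixtures, not refittable fits.
#'
#' @return Named list of three `qsrr_model` objects
#'   (`chi_c18`, `chi_iam`, `logk_hsa`).
#' @export
reference_qsrr_models <- function() {
  list(
    chi_c18 = qsrr_model(
      endpoint = "chi_c18", intercept = 82.496,
      coefficients = c("SpMax_Dz(i)" = 17.488, "R3s" = -17.080)),
    chi_iam = qsrr_model(
      endpoint = "chi_iam", intercept = 34.273,
      coefficients = c("LogP" = 4.836, "PJI3" = 3.392)),
    logk_hsa = qsrr_model(
      endpoint = "logk_hsa", intercept = 0.600,
      coefficients = c("LogS" = -0.423, "TDB05i" = -0.284))
  )
}

#' Save / load a validation report
#'
#' Writes the report as structured JSON (machine-readable, full precision)
#' plus a human-readable plain-text summary alongside (same path with a
#' `.txt` extension).
#'
#' @param report a `validation_report` from [validate_qsrr()]
#' @param path output path for the JSON file
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("I/O error: directory does not exist: ", dir)
  payload <- unclass(report)
  payload$metrics <- as.list(payload$metrics)  # keep metric names in JSON
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  writeLines(format_report(report), txt)
  invisible(path)
}

#' @rdname save_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$metrics <- unlist(obj$metrics)
  class(obj) <- "validation_report"
  obj
}

format_report <- function(report) {
  m <- report$metrics
  c(sprintf("QSRR validation report: endpoint %s", report$endpoint),
    sprintf("training n = %d, external n = %d", report$n_tr, report$n_ext),
    sprintf("descriptors: %s", paste(report$descriptors, collapse = ", ")),
    "",
    sprintf("  %-9s %8.4f", names(m), m),
    "",
    sprintf("Acceptability (R2 > 0.6 and R2_EXT > 0.5): %s",
            if (report$acceptable$overall) "PASS" else "FAIL"))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles every tunable of the pipeline: genetic-algorithm settings,
#' pruning thresholds, the train/validation split, and the random seed.
#' `write_config()`/`read_config()` serialize it to YAML with namespaced
#' keys; unknown keys in a file are an error, which catches typos.
#'
#' @param ga list of GA settings, see [ga_config()]
#' @param corr_threshold absolute pairwise Pearson correlation at or above
#'   which one of a descriptor pair is pruned (default 0.95)
#' @param near_constant_freq a descriptor is near-constant when its modal
#'   value occupies more than this fraction of entries (default 0.95)
#' @param n_train training-set size for the systematic split (default 12,
#'   leaving 6 of 18 compounds for external validation)
#' @param split_method `"ranked"` (deterministic, endpoint-sorted) or
#'   `"random"`
#' @param seed integer seed for all stochastic steps
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(ga = ga_config(), corr_threshold = 0.95,
                            near_constant_freq = 0.95, n_train = 12L,
                            split_method = c("ranked", "random"),
                            seed = 1L) {
  split_method <- match.arg(split_method)
  stopifnot(corr_threshold > 0, corr_threshold <= 1,
            near_constant_freq > 0, near_constant_freq <= 1,
            n_train >= 1)
  cfg <- list(ga = ga, corr_threshold = corr_threshold,
              near_constant_freq = near_constant_freq,
              n_train = as.integer(n_train), split_method = split_method,
              seed = as.integer(seed))
  class(cfg) <- "analysis_config"
  cfg
}

#' @rdname analysis_config
#' @param config an `analysis_config`
#' @param path YAML file path
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- yaml::read_yaml(path)
  defaults <- analysis_config()
  unknown <- setdiff(names(obj), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(obj$ga)) {
    unknown_ga <- setdiff(names(obj$ga), names(defaults$ga))
    if (length(unknown_ga) > 0L) {
      stop("unknown config key(s): ",
           paste(paste0("ga.", unknown_ga), collapse = ", "))
    }
    obj$ga <- do.call(ga_config, obj$ga)
  }
  obj$split_method <- obj$split_method %||% defaults$split_method
  merged <- modifyList(unclass(defaults), obj)
  do.call(analysis_config, merged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
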