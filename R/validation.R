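# Train/validation splitting, the OECD-style metric suite, acceptability
# flags and applicability-domain (Williams plot) assessment.

#' Split compounds into training and external validation sets
#'
#' The default `"ranked"` method is a systematic split: compounds are
#' sorted by the endpoint and, starting from the second-ranked compound,
#' every third one goes to the validation set. This spreads the validation
#' compounds across the endpoint range while keeping the extremes (global
#' minimum and maximum) in training, so the external set never requires
#' extrapolation. `"random"` draws a seeded random subset instead.
#'
#' @param table a `retention_table` (or data frame with the endpoint column)
#' @param endpoint endpoint column name used for ranking
#' @param n_train training-set size (default 12, leaving 6 of 18 external)
#' @param method `"ranked"` or `"random"`
#' @param seed seed for the random method
#' @return List with integer row indices `train` and `validation`
#'   (disjoint, exhaustive, in increasing order).
#' @export
split_train_validation <- function(table, endpoint, n_train = 12L,
                                   method = c("ranked", "random"),
                                   seed = 1L) {
  method <- match.arg(method)
  n <- nrow(table)
  if (n_train >= n) stop("n_train must be smaller than the dataset size")
  n_val <- n - n_train
  if (method == "ranked") {
    y <- table[[endpoint]]
    if (is.null(y)) stop("endpoint column not found: ", endpoint)
    ord <- order(y)
    # every third rank starting at 2 -> validation, until n_val filled
    cand <- seq(2L, n, by = 3L)
    if (length(cand) < n_val) {
      stop("ranked split cannot place ", n_val,
           " validation compounds among ", n)
    }
    val <- sort(ord[cand[seq_len(n_val)]])
  } else {
    set.seed(seed)
    val <- sort(sample(n, n_val))
  }
  list(train = setdiff(seq_len(n), val), validation = val)
}

#' Goodness-of-fit / predictivity metrics
#'
#' The coefficient of determination `1 - SS_res / SS_tot` and the root mean
#' square error `sqrt(SS_res / n)`. With `y_ref` left as `y_obs`, `SS_tot`
#' is centred on the mean of `y_obs` itself, the convention used for
#' training R2, LOO Q2 and (by default) external R2; passing a training
#' vector as `y_ref` centres the external denominator on the training mean
#' instead.
#'
#' @param y_obs observed endpoint values
#' @param y_pred predicted (or cross-validated) values, same length
#' @param y_ref values whose mean centres the total sum of squares
#'   (default: `y_obs`)
#' @return List with `r2` and `rmse`.
#' @export
regression_metrics <- function(y_obs, y_pred, y_ref = y_obs) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2L)
  ss_tot <- sum((y_obs - mean(y_ref))^2)
  if (ss_tot == 0) stop("undefined denominator: y_obs is constant")
  ss_res <- sum((y_pred - y_obs)^2)
  list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(ss_res / length(y_obs)))
}

#' Leave-one-out cross-validation of an OLS model
#'
#' Refits the model n times, each time predicting the held-out compound,
#' and reports the cross-validated predictions together with Q2_LOO and
#' RMSE_LOO.
#'
#' @param X descriptor matrix restricted to the model's columns
#' @param y response vector
#' @return List with `y_cv`, `q2_loo`, `rmse_loo`.
#' @export
loo_cross_validate <- function(X, y) {
  X <- as.matrix(unclass(X))
  n <- nrow(X)
  if (n < ncol(X) + 3L) stop("too few compounds for leave-one-out (need n >= p + 3)")
  y_cv <- numeric(n)
  for (i in seq_len(n)) {
    D <- cbind(1, X[-i, , drop = FALSE])
    qrd <- qr(D)
    if (qrd$rank < ncol(D)) {
      stop("singular leave-one-out fold when omitting compound ",
           rownames(X)[i] %||% i)
    }
    coefs <- qr.coef(qrd, y[-i])
    y_cv[i] <- drop(c(1, X[i, ]) %*% coefs)
  }
  m <- regression_metrics(y, y_cv)
  list(y_cv = setNames(y_cv, rownames(X)), q2_loo = m$r2, rmse_loo = m$rmse)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between predicted and observed values, penalizing both scatter
#' and systematic shift:
#' `2 * S_op / (S_oo + S_pp + n * (mean_o - mean_p)^2)` with `S` the
#' centred sums of squares/products. Equals 1 only for perfect agreement
#' and is bounded by the absolute Pearson correlation.
#'
#' @param y_obs observed values
#' @param y_pred predicted values, same length
#' @return Concordance value in \[-1, 1\].
#' @export
ccc_ext <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2L)
  co <- y_obs - mean(y_obs)
  cp <- y_pred - mean(y_pred)
  if (all(co == 0) && all(cp == 0)) {
    stop("undefined concordance: both vectors constant")
  }
  denom <- sum(co^2) + sum(cp^2) +
    length(y_obs) * (mean(y_obs) - mean(y_pred))^2
  2 * sum(co * cp) / denom
}

#' Leverages of query compounds relative to a training design
#'
#' `h_q = x_q' (X'X)^{-1} x_q` on the intercept-augmented design. For
#' training rows these are the hat-matrix diagonals; their sum equals the
#' number of fitted parameters (p + 1).
#'
#' @param X_train training descriptor matrix (model columns only)
#' @param X_query query matrix with the same columns (default: training)
#' @return Numeric leverages, one per query row.
#' @export
leverages <- function(X_train, X_query = X_train) {
  X_train <- as.matrix(unclass(X_train))
  X_query <- as.matrix(unclass(X_query))
  stopifnot(ncol(X_query) == ncol(X_train))
  D <- cbind(1, X_train)
  XtX <- crossprod(D)
  inv <- tryCatch(solve(XtX), error = function(e)
    stop("singular design: cannot invert X'X"))
  Q <- cbind(1, X_query)
  setNames(rowSums((Q %*% inv) * Q), rownames(X_query))
}

#' Critical leverage of the applicability domain
#'
#' The warning threshold `h* = 3 p / (n - 1)`, where `p` counts the model
#' descriptors and `n` the training compounds. By convention the intercept
#' is not counted in `p`; set `count_intercept = TRUE` for the
#' `3 (p + 1) / n`-style variant that does.
#'
#' @param p number of descriptors in the model
#' @param n number of training compounds (> 1)
#' @param count_intercept include the intercept in the parameter count
#' @return The critical leverage value.
#' @examples
#' critical_leverage(2, 12)  # 6/11
#' @export
critical_leverage <- function(p, n, count_intercept = FALSE) {
  stopifnot(p >= 1)
  if (n <= 1) stop("need n > 1 training compounds")
  if (count_intercept) 3 * (p + 1) / n else 3 * p / (n - 1)
}

#' Applicability-domain assessment (Williams plot data)
#'
#' Computes, for the training and external compounds, the leverage relative
#' to the training design and the standardized residual (residual divided
#' by the RMSE of the compound's own set). A compound is in-domain when its
#' leverage does not exceed the critical value [critical_leverage()] and
#' its standardized residual lies within +/- 3 (boundaries inclusive).
#'
#' @param model a `qsrr_model`
#' @param X_train,y_train training descriptors (model columns) and endpoint
#' @param X_ext,y_ext external-set descriptors and endpoint (optional)
#' @return A `domain_assessment`: data frame with `compound`, `set`,
#'   `leverage`, `std_residual`, `in_domain`, plus attribute `h_star`.
#' @export
williams_assessment <- function(model, X_train, y_train,
                                X_ext = NULL, y_ext = NULL) {
  X_train <- as.matrix(unclass(X_train))
  need <- names(model$coefficients)
  X_train <- X_train[, need, drop = FALSE]
  h_star <- critical_leverage(length(need), nrow(X_train))

  assess_set <- function(X, y, set) {
    res <- y - predict(model, X)
    rmse <- sqrt(mean(res^2))
    data.frame(
      compound = rownames(X) %||% paste0(set, seq_len(nrow(X))),
      set = set,
      leverage = unname(leverages(X_train, X)),
      std_residual = if (rmse > 0) res / rmse else res * 0,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- assess_set(X_train, y_train, "training")
  if (!is.null(X_ext)) {
    X_ext <- as.matrix(unclass(X_ext))[, need, drop = FALSE]
    out <- rbind(out, assess_set(X_ext, y_ext, "validation"))
  }
  out$in_domain <- out$leverage <= h_star & abs(out$std_residual) <= 3
  attr(out, "h_star") <- h_star
  class(out) <- c("domain_assessment", "data.frame")
  out
}

#' Model acceptability flags
#'
#' The two published acceptability thresholds for this model class:
#' training R2 above 0.6 and external R2 above 0.5.
#'
#' @param r2_tr training coefficient of determination
#' @param r2_ext external coefficient of determination
#' @return List of logical flags `r2_ok`, `r2_ext_ok`, `overall`.
#' @export
assess_acceptability <- function(r2_tr, r2_ext) {
  flags <- list(r2_ok = r2_tr > 0.6, r2_ext_ok = r2_ext > 0.5)
  flags$overall <- flags$r2_ok && flags$r2_ext_ok
  flags
}

#' Full internal and external validation of a QSRR model
#'
#' Computes the seven-metric suite in one pass: training fit (`r2_tr`,
#' `rmse_tr`), leave-one-out robustness (`q2_loo`, `rmse_loo`) and external
#' predictivity (`r2_ext`, `rmse_p`, `ccc_ext`), together with
#' acceptability flags and the applicability-domain assessment.
#'
#' @inheritParams williams_assessment
#' @param endpoint endpoint name recorded in the report
#' @param ext_center `"external"` (default) centres the external R2
#'   denominator on the external-set mean, as conventionally printed;
#'   `"training"` uses the training mean.
#' @return A `validation_report`.
#' @export
validate_qsrr <- function(model, X_train, y_train, X_ext, y_ext,
                          endpoint = model$endpoint,
                          ext_center = c("external", "training")) {
  ext_center <- match.arg(ext_center)
  need <- names(model$coefficients)
  X_train <- as.matrix(unclass(X_train))[, need, drop = FALSE]
  X_ext <- as.matrix(unclass(X_ext))[, need, drop = FALSE]

  pred_tr <- predict(model, X_train)
  pred_ext <- predict(model, X_ext)
  tr <- regression_metrics(y_train, pred_tr)
  loo <- loo_cross_validate(X_train, y_train)
  ext <- regression_metrics(y_ext, pred_ext,
                            y_ref = if (ext_center == "training") y_train
                                    else y_ext)
  metrics <- c(r2_tr = tr$r2, rmse_tr = tr$rmse,
               q2_loo = loo$q2_loo, rmse_loo = loo$rmse_loo,
               r2_ext = ext$r2, rmse_p = ext$rmse,
               ccc_ext = ccc_ext(y_ext, pred_ext))
  report <- list(
    endpoint = endpoint,
    descriptors = need,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    n_tr = nrow(X_train), n_ext = nrow(X_ext),
    metrics = metrics,
    y_obs_tr = as.numeric(y_train), y_pred_tr = as.numeric(pred_tr),
    y_cv = as.numeric(loo$y_cv),
    y_obs_ext = as.numeric(y_ext), y_pred_ext = as.numeric(pred_ext),
    acceptable = assess_acceptability(metrics[["r2_tr"]],
                                      metrics[["r2_ext"]]))
  class(report) <- "validation_report"
  report
}
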