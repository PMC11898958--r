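# Genetic-algorithm descriptor-subset selection coupled to ordinary
# least-squares multiple linear regression.

#' QSRR model object
#'
#' An intercept plus named descriptor coefficients for one chromatographic
#' endpoint, with optional training bookkeeping. Usually produced by
#' [fit_mlr()] or [ga_select()]; [reference_qsrr_models()] returns published
#' equations in this form.
#'
#' @param endpoint endpoint name (e.g. `"chi_c18"`)
#' @param intercept real intercept
#' @param coefficients named numeric vector, one entry per descriptor
#' @param training_ids identifiers of the training compounds, optional
#' @param fitted fitted values on the training set, optional
#' @param fit_meta list of fit metadata (seed, GA settings, fitness name)
#' @return A `qsrr_model`.
#' @export
qsrr_model <- function(endpoint, intercept, coefficients,
                       training_ids = NULL, fitted = NULL,
                       fit_meta = list()) {
  if (length(coefficients) == 0L || is.null(names(coefficients)) ||
      any(!nzchar(names(coefficients)))) {
    stop("coefficients must be a non-empty named vector")
  }
  obj <- list(endpoint = endpoint, intercept = as.numeric(intercept),
              coefficients = coefficients, training_ids = training_ids,
              fitted = fitted, fit_meta = fit_meta)
  class(obj) <- "qsrr_model"
  obj
}

#' @export
print.qsrr_model <- function(x, ...) {
  terms <- sprintf("%+.4g %s", x$coefficients, names(x$coefficients))
  cat(sprintf("%s = %.4g %s\n", x$endpoint, x$intercept,
              paste(terms, collapse = " ")))
  if (!is.null(x$fit_meta$fitness)) {
    cat(sprintf("  (GA-selected, fitness %s = %.4f, seed %s)\n",
                x$fit_meta$fitness, x$fit_meta$best_fitness,
                x$fit_meta$seed))
  }
  invisible(x)
}

#' Ordinary least-squares multiple linear regression
#'
#' Fits `y = b0 + X b` by least squares. Requires more compounds than
#' fitted parameters and a full-rank design.
#'
#' @param X numeric matrix of descriptor values (rows = compounds); column
#'   names become coefficient names
#' @param y response vector (chromatographic endpoint), length `nrow(X)`
#' @param endpoint endpoint name stored in the model
#' @return A `qsrr_model` with fitted values and residuals in `fit_meta`.
#' @export
fit_mlr <- function(X, y, endpoint = "y") {
  X <- as.matrix(unclass(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("D", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X))
  p <- ncol(X)
  if (nrow(X) <= p + 1L) {
    stop("under-determined fit: need n > p + 1 (n = ", nrow(X),
         ", p = ", p, ")")
  }
  D <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) stop("singular fit: design matrix is rank-deficient")
  coefs <- qr.coef(qrd, y)
  fitted <- drop(D %*% coefs)
  qsrr_model(
    endpoint = endpoint, intercept = coefs[1L], coefficients = coefs[-1L],
    training_ids = rownames(X), fitted = setNames(fitted, rownames(X)),
    fit_meta = list(residuals = y - fitted, n = nrow(X), p = p))
}

#' Predict an endpoint from descriptor values
#'
#' @param object a `qsrr_model`
#' @param newdata named numeric vector, matrix or data frame supplying a
#'   value for every model descriptor (extra columns ignored)
#' @param ... unused
#' @return Numeric vector of predicted endpoint values.
#' @examples
#' m <- reference_qsrr_models()$chi_c18
#' predict(m, c("SpMax_Dz(i)" = 1, "R3s" = 1))  # 82.904
#' @export
predict.qsrr_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.matrix(as.data.frame(unclass(newdata), check.names = FALSE,
                                     optional = TRUE))
  need <- names(object$coefficients)
  missing <- setdiff(need, colnames(newdata))
  if (length(missing) > 0L) {
    stop("newdata lacks model descriptor(s): ",
         paste(missing, collapse = ", "))
  }
  drop(object$intercept +
         newdata[, need, drop = FALSE] %*% object$coefficients)
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the published analysis settings: population 10,
#' per-gene mutation probability 0.20, 500 generations, descriptor subsets
#' of size 2, elitism of one (the best model is always retained).
#'
#' @param population_size number of chromosomes per generation (>= 2)
#' @param mutation_rate per-gene flip probability in \[0, 1\]
#' @param generations number of GA generations
#' @param subset_size number of descriptors per model
#' @param elitism number of top chromosomes carried over unchanged
#' @param fitness `"q2_loo"` (leave-one-out cross-validated R2, the
#'   default: rewards robustness, not just fit) or `"r2"`
#' @param seed integer seed for the GA's random stream
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 10L, mutation_rate = 0.2,
                      generations = 500L, subset_size = 2L, elitism = 1L,
                      fitness = c("q2_loo", "r2"), seed = 1L) {
  fitness <- match.arg(fitness)
  stopifnot(population_size >= 2, mutation_rate >= 0, mutation_rate <= 1,
            generations >= 1, subset_size >= 1, elitism >= 0,
            elitism < population_size)
  cfg <- list(population_size = as.integer(population_size),
              mutation_rate = mutation_rate,
              generations = as.integer(generations),
              subset_size = as.integer(subset_size),
              elitism = as.integer(elitism), fitness = fitness,
              seed = as.integer(seed))
  class(cfg) <- "ga_config"
  cfg
}

#' Uniform crossover of two inclusion masks
#'
#' Each gene of the child is inherited from parent A where the next draw of
#' the random stream is below 0.5, and from parent B otherwise. If
#' `subset_size` is given the child is repaired to exactly that many
#' selected genes.
#'
#' @param a,b logical inclusion masks of equal length
#' @param subset_size optional selected-gene count to repair to
#' @return Logical child mask.
#' @export
crossover <- function(a, b, subset_size = NULL) {
  if (length(a) != length(b)) stop("parent masks differ in length")
  from_a <- runif(length(a)) < 0.5
  child <- ifelse(from_a, a, b)
  if (!is.null(subset_size)) child <- repair_mask(child, subset_size)
  child
}

#' Per-gene mutation of an inclusion mask
#'
#' Each gene flips independently with probability `rate`, then the mask is
#' repaired to `subset_size` selected genes when that is given.
#'
#' @param mask logical inclusion mask
#' @param rate flip probability in \[0, 1\]
#' @inheritParams crossover
#' @return Mutated logical mask.
#' @export
mutate <- function(mask, rate, subset_size = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  flip <- runif(length(mask)) < rate
  out <- xor(mask, flip)
  if (!is.null(subset_size)) out <- repair_mask(out, subset_size)
  out
}

# sample() from a set of any size (avoids the 1:n expansion of length-1 x)
resample <- function(x, size) x[sample.int(length(x), size)]

# Repair a mask to exactly k selected genes by random deselection/selection.
repair_mask <- function(mask, k) {
  n_on <- sum(mask)
  if (n_on > k) {
    mask[resample(which(mask), n_on - k)] <- FALSE
  } else if (n_on < k) {
    mask[resample(which(!mask), k - n_on)] <- TRUE
  }
  mask
}

# Subset fitness on the training data. PRESS identity e_loo = e / (1 - h)
# gives exact leave-one-out residuals from a single OLS fit.
subset_fitness <- function(Xfull, y, idx, fitness) {
  D <- cbind(1, Xfull[, idx, drop = FALSE])
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) return(-Inf)
  res <- qr.resid(qrd, y)
  ss_tot <- sum((y - mean(y))^2)
  if (fitness == "r2") return(1 - sum(res^2) / ss_tot)
  h <- rowSums(qr.Q(qrd)^2)
  if (any(h > 1 - 1e-10)) return(-Inf)
  1 - sum((res / (1 - h))^2) / ss_tot
}

#' Genetic-algorithm descriptor selection
#'
#' Searches binary descriptor-inclusion chromosomes for the subset whose
#' OLS model maximizes the configured fitness (leave-one-out Q2 by
#' default). Selection is a fitness-ranked tournament of size 2, crossover
#' is uniform, mutation is per-gene, and the best chromosome is always
#' retained (elitism), so the best-so-far fitness trace is non-decreasing.
#' The whole run is reproducible from `config$seed`. Fitness values are
#' cached per subset, so repeated visits to the same subset cost nothing.
#'
#' @param X pruned `descriptor_matrix` (or numeric matrix)
#' @param y response vector aligned with the rows of `X`
#' @param config a [ga_config()]
#' @param endpoint endpoint name stored in the returned model
#' @return List with `mask` (named logical chromosome), `model` (the
#'   refitted `qsrr_model` on the selected subset), `fitness` (best fitness
#'   reached) and `trace` (best-so-far fitness per generation).
#' @export
ga_select <- function(X, y, config = ga_config(), endpoint = "y") {
  X <- as.matrix(unclass(X))
  stopifnot(length(y) == nrow(X))
  p <- ncol(X)
  k <- config$subset_size
  if (p < k) stop("descriptor count (", p, ") below subset size (", k, ")")
  if (nrow(X) <= k + 1L) stop("too few compounds for subset size ", k)
  set.seed(config$seed)

  cache <- new.env(parent = emptyenv())
  fit_of <- function(mask) {
    idx <- which(mask)
    key <- paste(idx, collapse = ",")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- subset_fitness(X, y, idx, config$fitness)
      cache[[key]] <- got
    }
    got
  }
  random_mask <- function() {
    m <- rep(FALSE, p)
    m[sample(p, k)] <- TRUE
    m
  }

  pop <- replicate(config$population_size, random_mask(), simplify = FALSE)
  fits <- vapply(pop, fit_of, numeric(1))
  best_i <- which.max(fits)
  best <- list(mask = pop[[best_i]], fit = fits[best_i])
  trace <- numeric(config$generations)

  for (g in seq_len(config$generations)) {
    ord <- order(fits, decreasing = TRUE)
    nxt <- pop[ord[seq_len(config$elitism)]]
    while (length(nxt) < config$population_size) {
      pick <- function() {
        ij <- sample(config$population_size, 2L)
        pop[[ij[if (fits[ij[1L]] >= fits[ij[2L]]) 1L else 2L]]]
      }
      child <- crossover(pick(), pick(), subset_size = k)
      child <- mutate(child, config$mutation_rate, subset_size = k)
      nxt[[length(nxt) + 1L]] <- child
    }
    pop <- nxt
    fits <- vapply(pop, fit_of, numeric(1))
    gen_best <- which.max(fits)
    if (fits[gen_best] > best$fit) {
      best <- list(mask = pop[[gen_best]], fit = fits[gen_best])
    }
    trace[g] <- best$fit
  }

  sel <- colnames(X)[best$mask] %||% which(best$mask)
  model <- fit_mlr(X[, best$mask, drop = FALSE], y, endpoint = endpoint)
  model$fit_meta <- c(model$fit_meta, list(
    seed = config$seed, fitness = config$fitness, best_fitness = best$fit,
    ga = unclass(config)))
  list(mask = setNames(best$mask, colnames(X)), model = model,
       fitness = best$fit, trace = trace, selected = sel)
}

#' Exhaustive descriptor-subset search
#'
#' Scores every size-`subset_size` descriptor subset with the same fitness
#' function as [ga_select()] and returns the best. Feasible for small
#' descriptor pools; used to benchmark the GA.
#'
#' @inheritParams ga_select
#' @return List with `selected` (descriptor names), `fitness`, and `model`.
#' @export
exhaustive_select <- function(X, y, config = ga_config(), endpoint = "y") {
  X <- as.matrix(unclass(X))
  k <- config$subset_size
  combos <- utils::combn(ncol(X), k)
  fits <- apply(combos, 2L, function(idx)
    subset_fitness(X, y, idx, config$fitness))
  best <- which.max(fits)
  idx <- combos[, best]
  list(selected = colnames(X)[idx] %||% idx, fitness = fits[best],
       model = fit_mlr(X[, idx, drop = FALSE], y, endpoint = endpoint))
}
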