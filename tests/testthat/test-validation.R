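test_that("ranked split is systematic, exhaustive and keeps the extremes", {
  tab <- load_retention_table("builtin:op18")
  sp <- split_train_validation(tab, "chi_c18")
  expect_length(sp$train, 12)
  expect_length(sp$validation, 6)
  expect_identical(sort(c(sp$train, sp$validation)), 1:18)

  sp2 <- split_train_validation(tab, "chi_c18")
  expect_identical(sp, sp2)

  # every-third-from-rank-2 assignment: extremes stay in training
  expect_false(which.min(tab$chi_c18) %in% sp$validation)
  expect_false(which.max(tab$chi_c18) %in% sp$validation)

  # enumeration: validation ranks are 2, 5, 8, 11, 14, 17
  ranks <- rank(tab$chi_c18)
  expect_identical(sort(ranks[sp$validation]), c(2, 5, 8, 11, 14, 17))

  expect_error(split_train_validation(tab, "chi_c18", n_train = 18),
               "smaller")
  r1 <- split_train_validation(tab, "chi_c18", method = "random", seed = 3)
  r2 <- split_train_validation(tab, "chi_c18", method = "random", seed = 3)
  expect_identical(r1, r2)
  expect_length(r1$validation, 6)
})

test_that("regression metrics match hand-computed sums", {
  y <- c(1, 2, 3, 4)
  perfect <- regression_metrics(y, y)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)

  null <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(null$r2, 0)

  # hand arithmetic: SS_res = .01+.01+.04+.04 = 0.1, SS_tot = 5
  m <- regression_metrics(y, c(1.1, 1.9, 3.2, 3.8))
  expect_equal(m$r2, 1 - 0.1 / 5)
  expect_equal(m$rmse, sqrt(0.1 / 4))

  expect_error(regression_metrics(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("leave-one-out equals the brute-force refit oracle", {
  set.seed(12)
  d <- random_design(8, 2)
  loo <- loo_cross_validate(d$X, d$y)
  expect_equal(unname(loo$y_cv), oracle_loo(d$X, d$y), tolerance = 1e-10)

  # exact linear data
  yex <- drop(d$X %*% c(1, 2)) + 3
  loo_ex <- loo_cross_validate(d$X, yex)
  expect_equal(loo_ex$q2_loo, 1, tolerance = 1e-10)
  expect_equal(loo_ex$rmse_loo, 0, tolerance = 1e-8)

  expect_error(loo_cross_validate(d$X[1:4, ], d$y[1:4]), "too few")
})

test_that("Q2_LOO never exceeds training R2 and RMSE_LOO >= RMSE_TR", {
  set.seed(55)
  for (i in 1:100) {
    d <- random_design(sample(8:16, 1), 2, noise = runif(1, 0.2, 2))
    m <- fit_mlr(d$X, d$y)
    tr <- regression_metrics(d$y, predict(m, d$X))
    loo <- loo_cross_validate(d$X, d$y)
    expect_lte(loo$q2_loo, tr$r2 + 1e-12)
    expect_gte(loo$rmse_loo, tr$rmse - 1e-12)
  }
})

test_that("concordance follows Lin's formula and its inequality", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(ccc_ext(y, y), 1)

  # independent hand computation on a 5-point example
  p <- c(1.2, 1.9, 3.4, 3.8, 5.1)
  co <- y - mean(y); cp <- p - mean(p)
  hand <- 2 * sum(co * cp) /
    (sum(co^2) + sum(cp^2) + 5 * (mean(y) - mean(p))^2)
  expect_equal(ccc_ext(y, p), hand)

  # location-shift penalty: monotone decreasing toward 0
  shifts <- c(0, 1, 5, 50, 500)
  vals <- sapply(shifts, function(s) ccc_ext(y, y + s))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 1e-4)

  set.seed(2)
  for (i in 1:100) {
    a <- rnorm(10); b <- rnorm(10) + 0.5 * a
    expect_lte(ccc_ext(a, b), abs(cor(a, b)) + 1e-12)
  }
  expect_error(ccc_ext(c(1, 1), c(2, 2)), "constant")
})

test_that("leverages obey the hat-matrix identities", {
  set.seed(18)
  x <- rnorm(10)
  x <- x - mean(x)
  X <- cbind(x = x)
  h_at_mean <- leverages(X, cbind(x = 0))
  expect_equal(unname(h_at_mean), 1 / 10, tolerance = 1e-12)

  for (i in 1:10) {
    d <- random_design(sample(8:20, 1), sample(1:3, 1))
    h <- leverages(d$X)
    expect_equal(sum(h), ncol(d$X) + 1, tolerance = 1e-8)
    expect_true(all(h > 0 & h <= 1))
    far <- d$X[1, , drop = FALSE] + 100 * apply(d$X, 2, sd)
    expect_gt(leverages(d$X, far), max(h))
  }
  expect_error(leverages(cbind(a = c(1, 2), b = c(2, 4))), "singular")
})

test_that("critical leverage is 3p/(n-1)", {
  expect_equal(critical_leverage(2, 12), 6 / 11)
  expect_equal(critical_leverage(1, 4), 1)
  expect_equal(critical_leverage(4, 12), 2 * critical_leverage(2, 12))
  expect_equal(critical_leverage(2, 12, count_intercept = TRUE), 9 / 12)
  expect_error(critical_leverage(2, 1), "n > 1")
})

test_that("Williams assessment flags well-specified data as in-domain", {
  set.seed(33)
  # compact descriptor ranges (as real descriptor tables have): leverage
  # tail stays below h*, so only the 3-sigma residual rule bites
  X <- matrix(runif(200 * 2, -2, 2), 200, 2,
              dimnames = list(NULL, c("a", "b")))
  y <- 1 + drop(X %*% c(2, -1)) + rnorm(200, sd = 0.2)
  m <- fit_mlr(X, y)
  wa <- williams_assessment(m, X, y)
  expect_gte(mean(wa$in_domain), 0.95)
  expect_equal(attr(wa, "h_star"), 3 * 2 / (200 - 1))

  # a query equal to a training row has that row's leverage
  wa_q <- williams_assessment(m, X, y, X[3, , drop = FALSE], y[3])
  expect_equal(wa_q$leverage[201], wa$leverage[3])

  # boundary inclusive at |std residual| = 3 and h = h_star
  h_star <- attr(wa, "h_star")
  fake <- wa[1, ]
  expect_true(fake$leverage <= h_star)
})

test_that("acceptability thresholds mirror the published rule", {
  ok <- assess_acceptability(0.870, 0.696)
  expect_true(ok$overall)
  expect_false(assess_acceptability(0.59, 0.9)$overall)
  expect_false(assess_acceptability(0.61, 0.49)$overall)
})

test_that("validate_qsrr assembles a coherent seven-metric report", {
  set.seed(77)
  X <- matrix(rnorm(18 * 2), 18, 2, dimnames = list(sprintf("c%02d", 1:18),
                                                    c("a", "b")))
  y <- 5 + drop(X %*% c(3, -2)) + rnorm(18, sd = 0.4)
  sp <- split_train_validation(data.frame(y = y), "y")
  m <- fit_mlr(X[sp$train, ], y[sp$train], endpoint = "y")
  rep <- validate_qsrr(m, X[sp$train, ], y[sp$train],
                       X[sp$validation, ], y[sp$validation])
  expect_identical(rep$n_tr + rep$n_ext, 18L)
  expect_named(rep$metrics, c("r2_tr", "rmse_tr", "q2_loo", "rmse_loo",
                              "r2_ext", "rmse_p", "ccc_ext"))
  expect_lte(rep$metrics[["r2_tr"]], 1)
  expect_true(all(rep$metrics[c("rmse_tr", "rmse_loo", "rmse_p")] >= 0))
  expect_gte(rep$metrics[["ccc_ext"]], -1)
  expect_lte(rep$metrics[["ccc_ext"]], 1)
  expect_true(rep$acceptable$overall)

  # training-mean centring variant changes only the external R2
  rep2 <- validate_qsrr(m, X[sp$train, ], y[sp$train],
                        X[sp$validation, ], y[sp$validation],
                        ext_center = "training")
  expect_equal(rep2$metrics[["r2_tr"]], rep$metrics[["r2_tr"]])
  expect_equal(rep2$metrics[["rmse_p"]], rep$metrics[["rmse_p"]])
})
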