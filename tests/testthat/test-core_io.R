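test_that("builtin endpoint table matches the published values cell-for-cell", {
  tab <- load_retention_table("builtin:op18")
  expect_s3_class(tab, "retention_table")
  expect_identical(nrow(tab), 18L)
  expect_identical(tab$id, 1:18)

  expect_equal(tab$chi_c18[tab$name == "Dichlorvos"], 23.17)
  expect_equal(tab$chi_iam[tab$name == "Phorate"], 42.43)
  expect_equal(tab$logk_hsa[tab$name == "Ethoprophos"], -0.41)
  expect_equal(tab$pct_hsa[tab$name == "Fenthion"], 96.04)

  # checksum over all 18 x 4 endpoint values (column sums of the printed table)
  expect_equal(sum(tab$chi_c18), 1515.09)
  expect_equal(sum(tab$chi_iam), 625.44)
  expect_equal(sum(tab$logk_hsa), 11.36)
  expect_equal(sum(tab$pct_hsa), 1394.70)
})

test_that("endpoint-table loader enforces the schema", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.csv")
  writeLines("", empty)
  expect_error(load_retention_table(empty), "schema error")

  partial <- file.path(dir, "partial.csv")
  writeLines(c("name,chi_c18", "A,1.0"), partial)
  expect_error(load_retention_table(partial), "chi_iam")

  bad <- file.path(dir, "bad.csv")
  writeLines(c("name,chi_c18,chi_iam,logk_hsa,pct_hsa",
               "A,1.0,2.0,x,50"), bad)
  expect_error(load_retention_table(bad), "row 1.*logk_hsa")

  dup <- file.path(dir, "dup.csv")
  writeLines(c("name,chi_c18,chi_iam,logk_hsa,pct_hsa",
               "A,1,2,0.1,50", "A,2,3,0.2,60"), dup)
  expect_error(load_retention_table(dup), "unique")
})

test_that("endpoint-table load/save round-trips losslessly in file order", {
  tab <- load_retention_table("builtin:op18")
  path <- file.path(withr::local_tempdir(), "copy.csv")
  save_retention_table(tab, path)
  again <- load_retention_table(path)
  expect_equal(as.data.frame(again), as.data.frame(tab))
})

test_that("Unicode minus is normalized on ingest", {
  path <- file.path(withr::local_tempdir(), "uni.csv")
  writeLines(c("name,chi_c18,chi_iam,logk_hsa,pct_hsa",
               "Naled,31.32,29.79,−0.11,43.86"), path)
  expect_equal(load_retention_table(path)$logk_hsa, -0.11)
})

test_that("descriptor-matrix loader aligns names and rejects bad cells", {
  path <- write_descriptor_csv(data.frame(
    name = c("a", "b", "c"), d1 = c(1, 2, 3), d2 = c(4, 5, 6)))
  X <- load_descriptor_matrix(path)
  expect_identical(dim(X), c(3L, 2L))
  expect_identical(rownames(X), c("a", "b", "c"))
  expect_identical(colnames(X), c("d1", "d2"))

  dup <- write_descriptor_csv(data.frame(
    name = c("a", "a"), d1 = c(1, 2)))
  expect_error(load_descriptor_matrix(dup), "duplicate")

  dir <- withr::local_tempdir()
  blank <- file.path(dir, "blank.csv")
  writeLines(c("name,d1,d2", "a,1,4", "b,,6"), blank)
  expect_error(load_descriptor_matrix(blank), "row 2.*'b'.*d1")
})

test_that("reference model fixtures carry the published equations", {
  mods <- reference_qsrr_models()
  expect_named(mods, c("chi_c18", "chi_iam", "logk_hsa"))
  expect_equal(mods$chi_c18$intercept, 82.496)
  expect_equal(mods$chi_c18$coefficients,
               c("SpMax_Dz(i)" = 17.488, "R3s" = -17.080))
  expect_equal(mods$chi_iam$intercept, 34.273)
  expect_equal(mods$chi_iam$coefficients,
               c("LogP" = 4.836, "PJI3" = 3.392))
  expect_equal(mods$logk_hsa$intercept, 0.600)
  expect_equal(mods$logk_hsa$coefficients,
               c("LogS" = -0.423, "TDB05i" = -0.284))
})

test_that("validation reports round-trip through disk", {
  set.seed(11)
  d <- random_design(18, 2)
  colnames(d$X) <- c("A", "B")
  rownames(d$X) <- sprintf("c%02d", 1:18)
  split <- split_train_validation(data.frame(y = d$y), "y")
  m <- fit_mlr(d$X[split$train, ], d$y[split$train], endpoint = "y")
  rep0 <- validate_qsrr(m, d$X[split$train, ], d$y[split$train],
                        d$X[split$validation, ], d$y[split$validation])

  dir <- withr::local_tempdir()
  path <- file.path(dir, "report.json")
  save_report(rep0, path)
  expect_true(file.exists(file.path(dir, "report.txt")))
  back <- read_report(path)
  expect_equal(back$metrics, rep0$metrics)
  expect_named(back$metrics, c("r2_tr", "rmse_tr", "q2_loo", "rmse_loo",
                               "r2_ext", "rmse_p", "ccc_ext"))
  expect_error(save_report(rep0, file.path(dir, "no_such", "r.json")),
               "I/O error")
})

test_that("analysis config round-trips through YAML and rejects typos", {
  cfg <- analysis_config(ga = ga_config(population_size = 12, seed = 7),
                         corr_threshold = 0.9, seed = 7)
  path <- file.path(withr::local_tempdir(), "config.yaml")
  write_config(cfg, path)
  expect_equal(read_config(path), cfg)

  yaml::write_yaml(list(corr_treshold = 0.9), path)
  expect_error(read_config(path), "unknown config key.*corr_treshold")
  yaml::write_yaml(list(ga = list(popsize = 3)), path)
  expect_error(read_config(path), "ga.popsize")
})
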