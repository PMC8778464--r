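test_that("run_group produces one row per setting and flags the best", {
  tb <- simulate_feature_table(12, n_features = 12, n_informative = 6,
                               seed = 31)
  g <- svr_grid("linear", box_constraint = c(0.1, 10))
  rg <- run_group(tb, sizes = c(5, 10), methods = c("correlation_rank", "pca"),
                  grid = g)
  expect_equal(nrow(rg$table), 4)
  best <- rg$table[rg$table$best, ]
  expect_equal(nrow(best), 1)
  expect_true(all(best$r >= rg$table$r - 1e-12))

  rg2 <- run_group(tb, sizes = c(5, 10), methods = c("correlation_rank", "pca"),
                   grid = g)
  expect_identical(rg$table, rg2$table)      # deterministic re-run

  expect_error(run_group(tb[1:3, ], grid = g), "fewer than 4")
})

test_that("transfer evaluation requires disjoint groups and tracks the law", {
  spec <- list(kernel = "linear", kernel_scale = 1, box_constraint = 0.1)
  A <- simulate_feature_table(16, 16, 6, law_signs = 1, seed = 41, prefix = "A")
  expect_error(transfer_evaluate(A, A, spec), "share subject")

  # same generative law: transfer r close to within-group LOSO r
  g <- svr_grid("linear", box_constraint = c(0.01, 0.1, 10))
  gaps <- vapply(1:3, function(s) {
    A <- simulate_feature_table(16, 16, 6, law_signs = 1, seed = 100 + s,
                                prefix = "A")
    B <- simulate_feature_table(16, 16, 6, law_signs = 1, seed = 200 + s,
                                prefix = "B")
    fmA <- feature_matrix(A)
    within <- nested_loso(fmA$X, fmA$y, n = 6, grid = g)$metrics["r"]
    abs(within - transfer_evaluate(A, B, spec, n = 6)["r"])
  }, numeric(1))
  expect_lt(median(gaps), 0.15)
})

test_that("compare_groups matches exact rank statistics", {
  same <- c(1, 2, 3, 4)
  res <- compare_groups(same, same, paired = TRUE)
  expect_equal(res$p_value, 1)
  expect_equal(res$flag, "all differences zero")

  res2 <- compare_groups(1:10, 101:110)
  expect_equal(res2$statistic, 0)            # no x exceeds any y
  expect_lt(res2$p_value, 0.001)
  expect_equal(res2$test, "mann_whitney_u")

  # brute-force U on random data: count of pairs with x > y
  set.seed(10)
  x <- rnorm(8); y <- rnorm(8)
  res3 <- compare_groups(x, y)
  u_bf <- sum(outer(x, y, ">"))
  expect_equal(res3$statistic, u_bf)

  expect_error(compare_groups(1:3, 1:4, paired = TRUE), "equal lengths")
})

test_that("feature-target correlation table matches a permutation oracle", {
  tb <- simulate_feature_table(20, n_features = 6, n_informative = 2,
                               noise_sd = 1, seed = 51)
  tab <- feature_target_correlations(tb)
  expect_equal(nrow(tab), 6)
  expect_true(all(diff(abs(tab$r)) <= 1e-12))   # sorted by |r| descending
  expect_true(all(c("p_bh", "informative") %in% names(tab)))

  # an exact copy of the target scores r = 1, p ~ 0
  tb2 <- tb; tb2$F006 <- tb2$pigd
  tab2 <- feature_target_correlations(tb2)
  expect_equal(tab2$feature[1], "F006")
  expect_equal(tab2$r[1], 1)
  expect_lt(tab2$p[1], 1e-12)

  # independent feature stays uninformative at n = 100
  set.seed(52)
  big <- simulate_feature_table(100, n_features = 3, n_informative = 1,
                                seed = 53)
  tb3 <- feature_target_correlations(big)
  expect_lt(abs(tb3$r[tb3$feature == "F003"]), 0.3)

  # permutation oracle for one feature's p-value
  fm <- feature_matrix(tb)
  x <- fm$X[, "F001"]; yv <- fm$y
  r_obs <- abs(cor(x, yv))
  set.seed(54)
  r_perm <- replicate(1e4, abs(cor(x, sample(yv))))
  p_perm <- mean(r_perm >= r_obs)
  p_t <- tab$p[tab$feature == "F001"]
  expect_lt(abs(p_perm - p_t), 0.03)
})

test_that("the CLI pipeline runs simulate -> features -> fit", {
  dir <- withr::local_tempdir()
  cohort_dir <- file.path(dir, "cohort")
  cfgfile <- file.path(dir, "config.yaml")
  writeLines(c("n_subjects: 6", "walk_lengths: [6, 6]"), cfgfile)
  expect_message(
    pigdsense_cli(c("simulate", "--config", cfgfile, "--out", cohort_dir,
                    "--seed", "5")),
    "wrote 6 recordings")
  expect_true(file.exists(file.path(cohort_dir, "subjects.csv")))

  feat_csv <- file.path(dir, "features.csv")
  expect_message(
    pigdsense_cli(c("features", "--in", cohort_dir, "--out", feat_csv)),
    "feature rows")
  ft <- read.csv(feat_csv)
  expect_true(all(pigd_feature_names() %in% names(ft)))

  fit_json <- file.path(dir, "fit.json")
  fitcfg <- file.path(dir, "fit.yaml")
  writeLines(c("n: 5", "grid:", "  kernels: [linear]",
               "  box_constraint: [0.1, 10]"), fitcfg)
  out <- capture.output(
    pigdsense_cli(c("fit", "--config", fitcfg, "--in", feat_csv,
                    "--out", fit_json)))
  expect_true(file.exists(fit_json))
  parsed <- jsonlite::read_json(fit_json)
  expect_true(all(c("r", "rmse", "mae") %in% names(parsed$metrics)))
})
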