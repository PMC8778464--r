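test_that("correlation filter ranks by |r| and applies the floor", {
  set.seed(7)
  n <- 200
  y <- runif(n, 0, 20)
  X <- cbind(exact = y,
             neg = -y,
             noisy = y + rnorm(n, 0, sd(y) * 4 / 3),   # r ~ 0.6
             junk = rnorm(n))
  cf <- correlation_filter(X, y, r_floor = 0.4)
  expect_equal(cf$keep[1:2], c("exact", "neg"))        # |r| = 1 first
  expect_true("noisy" %in% cf$keep)
  expect_false("junk" %in% cf$keep)
  expect_equal(unname(cf$r["exact"]), 1)
  expect_equal(unname(abs(cf$r["neg"])), 1)
  expect_equal(unname(cf$r["noisy"]), cor(X[, "noisy"], y))

  # affine transforms of a feature do not change its |r| or the ranking
  X2 <- X; X2[, "noisy"] <- -3 * X[, "noisy"] + 7
  expect_equal(correlation_filter(X2, y)$keep, cf$keep)

  # zero-variance feature gets r = 0 and is dropped
  X3 <- cbind(X, flat = rep(1, n))
  expect_false("flat" %in% correlation_filter(X3, y)$keep)
  expect_error(correlation_filter(X[1:2, ], y[1:2]), "3 rows")
})

test_that("PCA reduction is train-fitted and complete", {
  set.seed(8)
  z <- rnorm(30)
  line <- cbind(a = 2 * z, b = -z, c = 0.5 * z)       # exactly 1-dimensional
  pc <- pca_reduce(line, line[1:3, ], 1)
  expect_equal(pc$explained[1], 1)

  X <- matrix(rnorm(30 * 4), 30, 4)
  pc2 <- pca_reduce(X, X[1:5, ], 4)
  cv <- cov(pc2$train)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-9)        # diagonal covariance
  recon <- pc2$train %*% t(pc2$rotation) +
    matrix(pc2$center, 30, 4, byrow = TRUE)
  expect_equal(recon, X, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pca_reduce(X, X, 10), "exceeds")
})

test_that("normalization scales train to [0,1] and is invertible", {
  tr <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "f"))
  te <- matrix(c(2, 9), ncol = 1, dimnames = list(NULL, "f"))
  nm <- normalize_features(tr, te, y_train = c(10, 0, 5))
  expect_equal(as.vector(nm$train), c(0, 0.5, 1))
  expect_equal(nm$test[1], 0.5)                       # equals a training row
  expect_equal(nm$test[2], 1.5)                       # clipped
  expect_equal(nm$y_inverse(nm$y), c(10, 0, 5), tolerance = 1e-9)

  tr2 <- cbind(tr, flat = 1)
  expect_warning(nm2 <- normalize_features(tr2, cbind(te, flat = 1), 1:3),
                 "zero-variance")
  expect_equal(nm2$columns, "f")
})

test_that("metrics match closed forms and a brute-force oracle", {
  y <- c(0.1, 0.5, 0.9)
  expect_equal(unname(regression_metrics(y, y)), c(1, 0, 0))
  m <- regression_metrics(y, y + 0.1)
  expect_equal(unname(m), c(1, 0.1, 0.1))

  set.seed(9)
  a <- runif(1000); b <- runif(1000)
  m2 <- regression_metrics(a, b)
  # independent sum-formula implementations
  n <- 1000
  r_bf <- (n * sum(a * b) - sum(a) * sum(b)) /
    sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  expect_equal(unname(m2["r"]), r_bf, tolerance = 1e-12)
  expect_equal(unname(m2["rmse"]), sqrt(sum((b - a)^2) / n), tolerance = 1e-12)
  expect_equal(unname(m2["mae"]), sum(abs(b - a)) / n, tolerance = 1e-12)

  flat <- regression_metrics(rep(1, 5), 1:5 / 5)
  expect_equal(unname(flat["r"]), 0)
  expect_true(isTRUE(attr(flat, "degenerate")))
})

test_that("nested LOSO runs N outer folds and N(N-1)G inner fits", {
  tb <- simulate_feature_table(6, n_features = 6, n_informative = 3, seed = 21)
  fm <- feature_matrix(tb)
  g <- svr_grid("linear", box_constraint = c(0.1, 1, 10))
  res <- nested_loso(fm$X, fm$y, n = 4, grid = g, r_floor = 0.2)
  expect_equal(res$n_outer, 6)
  expect_equal(res$n_inner_fits, 6 * 5 * 3)
  expect_equal(nrow(res$chosen), 6)
  expect_length(res$predictions, 6)
})

test_that("a perfectly linear target selects the linear kernel", {
  fx <- linear_law_fixture(seed = 3)
  res <- nested_loso(fx$X, fx$y, method = "correlation_rank", n = ncol(fx$X),
                     grid = small_grid(), r_floor = 0)
  expect_gte(mean(res$chosen$kernel == "linear"), 0.8)
  expect_gte(res$metrics["r"], 0.95)
})

test_that("inner-RMSE ties break by grid order", {
  fx <- linear_law_fixture(seed = 4, n = 8, p = 3)
  # kernel scale is ignored for the linear kernel, so these two cells are
  # provably identical; the first listed (smaller scale) must win
  g <- rbind(data.frame(kernel = "linear", kernel_scale = 1, box_constraint = 1),
             data.frame(kernel = "linear", kernel_scale = 999, box_constraint = 1))
  res <- nested_loso(fx$X, fx$y, n = 3, grid = g, r_floor = 0)
  expect_true(all(res$chosen$kernel_scale == 1))
})

test_that("leakage-safe mode: the held-out subject cannot influence its fold", {
  tb <- simulate_feature_table(10, n_features = 8, n_informative = 4, seed = 22)
  fm <- feature_matrix(tb)
  g <- svr_grid("linear", box_constraint = c(0.1, 10))
  r1 <- nested_loso(fm$X, fm$y, n = 4, grid = g)
  X2 <- fm$X
  X2[1, ] <- X2[1, ] + 5          # perturb the test row of fold 1
  r2 <- nested_loso(X2, fm$y, n = 4, grid = g)
  expect_identical(r1$chosen[1, c("kernel", "kernel_scale", "box_constraint")],
                   r2$chosen[1, c("kernel", "kernel_scale", "box_constraint")])
})

test_that("paper mode preselects features globally", {
  tb <- simulate_feature_table(10, n_features = 8, n_informative = 4, seed = 23)
  fm <- feature_matrix(tb)
  g <- svr_grid("linear", box_constraint = c(0.1, 10))
  expect_no_error(nested_loso(fm$X, fm$y, n = 4, grid = g, mode = "paper"))
  expect_error(nested_loso(fm$X[1:3, ], fm$y[1:3], grid = g), "at least 4")
  expect_error(nested_loso(fm$X, fm$y, grid = g[0, ]), "empty")
})

test_that("increasing feature noise degrades median LOSO r", {
  g <- svr_grid("linear", box_constraint = c(0.1, 10))
  med_r <- vapply(c(0.3, 1.5, 6), function(ns) {
    rs <- vapply(1:3, function(s) {
      tb <- simulate_feature_table(14, n_features = 10, n_informative = 5,
                                   noise_sd = ns, seed = 300 + s)
      fm <- feature_matrix(tb)
      nested_loso(fm$X, fm$y, n = 5, grid = g, r_floor = 0.2)$metrics["r"]
    }, numeric(1))
    median(rs)
  }, numeric(1))
  expect_true(all(diff(med_r) < 0))
})
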