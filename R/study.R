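# Study orchestration: per-group models, cross-population transfer, and
# group-comparison statistics.

#' Run the regression over a grid of reduction settings for one group
#'
#' One [nested_loso()] per (feature-set size, reduction method); the best
#' row is flagged by maximum r, ties broken by minimum RMSE then smaller n.
#'
#' @param rows Subject feature table (metadata + feature columns), e.g. from
#'   [cohort_features()].
#' @param sizes Feature-set sizes to try (published range: 5, 10, 15, 20,
#'   25).
#' @param methods Reduction methods to try.
#' @param grid Hyperparameter grid ([svr_grid()]).
#' @param ... Passed to [nested_loso()].
#' @return List with `table` (one row per setting: n, method, chosen-kernel
#'   mode, r, RMSE, MAE, `best` flag) and `results` (the `pigd_loso`
#'   objects).
#' @export
run_group <- function(rows, sizes = c(5, 10, 15, 20, 25),
                      methods = c("correlation_rank", "pca"),
                      grid = svr_grid(), ...) {
  fm <- feature_matrix(rows)
  if (nrow(fm$X) < 4) stop("group has fewer than 4 subjects")
  out <- list(); results <- list()
  for (m in methods) {
    for (nn in sizes) {
      res <- nested_loso(fm$X, fm$y, method = m, n = nn, grid = grid, ...)
      key <- sprintf("%s_%d", m, nn)
      results[[key]] <- res
      ch <- res$chosen
      mode_kernel <- names(sort(table(ch$kernel), decreasing = TRUE))[1]
      out[[key]] <- data.frame(n = nn, method = m, kernel = mode_kernel,
                               r = unname(res$metrics["r"]),
                               rmse = unname(res$metrics["rmse"]),
                               mae = unname(res$metrics["mae"]))
    }
  }
  tab <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  best <- order(-tab$r, tab$rmse, tab$n)[1]
  tab$best <- seq_len(nrow(tab)) == best
  list(table = tab, results = results)
}

# split a subject feature table into X (feature matrix) and y (pigd)
feature_matrix <- function(rows) {
  meta <- c("subject_id", "condition", "fog_status", "pigd", "n_strides")
  feats <- setdiff(names(rows), meta)
  list(X = as.matrix(rows[, feats, drop = FALSE]), y = rows$pigd,
       ids = rows$subject_id)
}

#' Train on one group, test on a disjoint group
#'
#' Single fit on the full training group with a fixed reduction setting and
#' SVR spec (typically the training group's best configuration), evaluated
#' on the untouched test group. Metrics are reported on the training
#' group's target range normalization.
#'
#' @param train_rows,test_rows Subject feature tables with disjoint
#'   subject-condition sets.
#' @param spec List or one-row data.frame with `kernel`, `kernel_scale`,
#'   `box_constraint`.
#' @param method,n,r_floor Reduction setting.
#' @return Named vector `c(r, rmse, mae)` plus attribute `predictions`.
#' @export
transfer_evaluate <- function(train_rows, test_rows, spec,
                              method = "correlation_rank", n = 10,
                              r_floor = 0.4) {
  key_tr <- paste(train_rows$subject_id, train_rows$condition)
  key_te <- paste(test_rows$subject_id, test_rows$condition)
  if (length(intersect(key_tr, key_te))) {
    stop("training and test groups share subject-conditions")
  }
  tr <- feature_matrix(train_rows); te <- feature_matrix(test_rows)
  nm <- reduce_partition(tr$X, te$X, tr$y, method, n, r_floor)
  if (is.null(nm)) stop("no features survived reduction on the training group")
  fit <- svr_fit(nm$train, nm$y, spec$kernel, spec$kernel_scale,
                 spec$box_constraint)
  pred <- nm$y_inverse(predict(fit, nm$test))
  span <- if (max(tr$y) > min(tr$y)) max(tr$y) - min(tr$y) else 1
  m <- regression_metrics((te$y - min(tr$y)) / span, (pred - min(tr$y)) / span)
  attr(m, "predictions") <- pred
  m
}

#' Compare two groups of values
#'
#' Paired comparisons use the Wilcoxon signed-rank test, unpaired ones the
#' Mann-Whitney U test; exact two-sided p for n <= 25 without ties, normal
#' approximation otherwise.
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Logical.
#' @return List with `statistic`, `p_value`, `test`, and `flag` (set when
#'   all paired differences are zero, in which case p = 1).
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b)) stop("paired comparison needs equal lengths")
  if (paired && all(a == b)) {
    return(list(statistic = 0, p_value = 1,
                test = "wilcoxon_signed_rank", flag = "all differences zero"))
  }
  n <- if (paired) length(a) else max(length(a), length(b))
  ht <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                            exact = n <= 25, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       test = if (paired) "wilcoxon_signed_rank" else "mann_whitney_u",
       flag = NULL)
}

#' Feature-target correlation table
#'
#' Pearson r and two-sided p for every feature against the target, sorted by
#' `|r|`, with a Benjamini-Hochberg adjusted column (reported, not used for
#' selection) and an `informative` flag for `|r| > 0.5`.
#'
#' @param rows Subject feature table.
#' @param target Target vector; defaults to the table's `pigd`.
#' @return data.frame: feature, r, p, p_bh, informative.
#' @export
feature_target_correlations <- function(rows, target = NULL) {
  fm <- feature_matrix(rows)
  if (is.null(target)) target <- fm$y
  if (nrow(fm$X) < 4) stop("need at least 4 rows")
  res <- lapply(colnames(fm$X), function(f) {
    x <- fm$X[, f]
    if (stats::sd(x) == 0) return(data.frame(feature = f, r = 0, p = 1))
    ht <- stats::cor.test(x, target)
    data.frame(feature = f, r = unname(ht$estimate), p = ht$p.value)
  })
  tab <- do.call(rbind, res)
  tab <- tab[order(-abs(tab$r)), ]
  tab$p_bh <- stats::p.adjust(tab$p, "BH")
  tab$informative <- abs(tab$r) > 0.5
  rownames(tab) <- NULL
  tab
}

#' Synthetic subject-level feature table
#'
#' Statistical stand-in for [cohort_features()] output used to study the
#' regression machinery itself: `n_informative` features depend linearly on
#' a severity target through group-specific coefficients, the rest are
#' noise. Flipping `law_signs` between two generated groups emulates
#' populations whose feature-severity laws differ (the mechanism behind
#' cross-population transfer degradation).
#'
#' @param n_subjects Number of subjects.
#' @param n_features Total feature count.
#' @param n_informative Number of severity-linked features.
#' @param law_signs Sign (+1/-1) pattern of the informative coefficients,
#'   recycled.
#' @param noise_sd Residual SD of informative features (target is scaled to
#'   unit SD internally).
#' @param seed Integer seed.
#' @param prefix Subject-id prefix (keep distinct across groups).
#' @return Subject feature table compatible with [run_group()] /
#'   [transfer_evaluate()].
#' @export
simulate_feature_table <- function(n_subjects = 20, n_features = 20,
                                   n_informative = 8, law_signs = 1,
                                   noise_sd = 0.5, seed = 1,
                                   prefix = "A") {
  with_sim_seed(as.integer(seed) %% 2147483647L, {
    sev <- stats::runif(n_subjects, 0, 20)
    z <- (sev - mean(sev)) / stats::sd(sev)
    signs <- rep_len(law_signs, n_informative)
    X <- matrix(stats::rnorm(n_subjects * n_features), n_subjects, n_features)
    for (j in seq_len(n_informative)) {
      X[, j] <- signs[j] * z + stats::rnorm(n_subjects, 0, noise_sd)
    }
    colnames(X) <- sprintf("F%03d", seq_len(n_features))
    cbind(data.frame(subject_id = sprintf("%s%02d", prefix, seq_len(n_subjects)),
                     condition = "ON",
                     fog_status = ifelse(sev >= 8, "FOG+", "FOG-"),
                     pigd = sev, n_strides = 1L),
          as.data.frame(X))
  })
}
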