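test_that("correlations agree with textbook formulas, ties by average rank", {
  expect_equal(correlations(1:10, 1:10), list(pearson = 1, spearman = 1))
  expect_equal(correlations(1:10, 10:1)$spearman, -1)
  withr::with_seed(22, {
    x <- rnorm(10)
    y <- x + rnorm(10)
  })
  got <- correlations(x, y)
  expect_equal(got$pearson, pearson_oracle(x, y))
  expect_equal(got$spearman, spearman_oracle(x, y))
  # ties handled by average ranks
  xt <- c(1, 1, 2, 3, 3, 4)
  yt <- c(2, 1, 1, 4, 5, 6)
  expect_equal(correlations(xt, yt)$spearman, spearman_oracle(xt, yt))
  # missing observations dropped pairwise
  expect_equal(correlations(c(x, NA), c(y, 1))$pearson,
               pearson_oracle(x, y))
  expect_warning(r0 <- correlations(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(r0$pearson))
})

test_that("confusion counts match a hand tally and handle degenerate calls", {
  z <- c(2, 4, 9, 12, 7, 8)   # truth: D D O O D O (Z < 8)
  p <- c(0.9, 0.4, 0.2, 0.1, 0.8, 0.6)
  cc <- confusion_at_threshold(z, p, score_threshold = 0.5)
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 1L, tn = 2L, fn = 1L))
  expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, length(z))
  # all called disordered
  cc2 <- confusion_at_threshold(z, p, score_threshold = 0)
  expect_equal(cc2$tn, 0L)
  expect_equal(cc2$fp, 3L)
  # perfect separation
  cc3 <- confusion_at_threshold(z, as.numeric(z < 8), score_threshold = 0.5)
  expect_equal(cc3$fp + cc3$fn, 0L)
  # Z-like scores call disorder below the threshold
  cc4 <- confusion_at_threshold(z, z, score_threshold = 8,
                                higher_is_disordered = FALSE)
  expect_equal(cc4$fp + cc4$fn, 0L)
})

test_that("MCC matches the closed formula and its conventions and symmetry", {
  expect_equal(mcc(list(tp = 5, fp = 0, tn = 7, fn = 0)), 1)
  expect_equal(mcc(list(tp = 5, fp = 7, tn = 0, fn = 0)), 0)  # single-class call
  expect_equal(mcc(list(tp = 3, fp = 1, tn = 4, fn = 2)),
               mcc_oracle(3, 1, 4, 2))
  # class-relabel symmetry: swapping TP<->TN and FP<->FN preserves MCC
  withr::with_seed(23, {
    for (i in 1:10) {
      cc <- as.list(sample(0:20, 4, replace = TRUE))
      names(cc) <- c("tp", "fp", "tn", "fn")
      swapped <- list(tp = cc$tn, fp = cc$fn, tn = cc$tp, fn = cc$fp)
      expect_equal(mcc(cc), mcc(swapped))
    }
  })
})

test_that("ROC AUC equals the Mann-Whitney identity on random instances", {
  withr::with_seed(24, {
    for (i in 1:20) {
      n <- sample(8:40, 1)
      z <- runif(n, 0, 16)
      if (!any(z < 8)) z[1] <- 2
      if (!any(z >= 8)) z[1] <- 12
      scores <- round(runif(n), 2)  # coarse rounding forces ties
      truth <- z < 8
      got <- roc_auc(z, scores)
      expect_equal(got$auc, mann_whitney_auc_oracle(truth, scores))
    }
  })
  # perfect and inverted rankings
  z <- c(2, 3, 10, 12)
  expect_equal(roc_auc(z, c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(z, c(0.1, 0.2, 0.8, 0.9))$auc, 0)
  expect_error(roc_auc(c(1, 2), c(0.5, 0.6)), "both classes")
})

test_that("random scores at large n give chance-level AUC", {
  withr::with_seed(25, {
    z <- runif(20000, 0, 16)
    scores <- runif(20000)
  })
  expect_equal(roc_auc(z, scores)$auc, 0.5, tolerance = 0.02)
})

test_that("PR AUC matches the brute-force sweep and prevalence limits", {
  withr::with_seed(26, {
    for (i in 1:15) {
      n <- sample(8:30, 1)
      z <- runif(n, 0, 16)
      if (!any(z < 8)) z[1] <- 2
      scores <- round(runif(n), 1)
      got <- pr_auc(z, scores)
      expect_equal(got$auc, pr_auc_oracle(z < 8, scores))
    }
  })
  z <- c(2, 3, 10, 12)
  expect_equal(pr_auc(z, c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  # constant scores: precision equals prevalence at full recall
  expect_equal(pr_auc(z, rep(0.5, 4))$auc, 0.5)
  expect_error(pr_auc(c(10, 12), c(0.2, 0.3)), "positive class")
})

test_that("metrics are invariant under residue permutation", {
  withr::with_seed(27, {
    z <- runif(200, 0, 16)
    p <- runif(200)
    idx <- sample(200)
  })
  expect_equal(roc_auc(z, p)$auc, roc_auc(z[idx], p[idx])$auc)
  expect_equal(pr_auc(z, p)$auc, pr_auc(z[idx], p[idx])$auc)
  expect_equal(correlations(z, p), correlations(z[idx], p[idx]))
})

test_that("per-amino-acid CDFs are proper and medians match a sort-based oracle", {
  db <- small_db()
  res <- per_aa_cdf(db)
  aa <- unlist(lapply(db$entries, function(e) strsplit(e$sequence, "")[[1]]))
  z <- unlist(lapply(db$entries, `[[`, "zscores"), use.names = FALSE)
  for (a in names(res)) {
    zi <- sort(z[aa == a])
    # median oracle from the sorted pool
    n <- length(zi)
    med <- if (n %% 2 == 1) zi[(n + 1) / 2] else (zi[n / 2] + zi[n / 2 + 1]) / 2
    expect_equal(res[[a]]$median, med, info = a)
    expect_equal(res[[a]]$n, n)
    # CDF is non-decreasing from 0 to 1
    grid <- seq(min(zi) - 1, max(zi) + 1, length.out = 50)
    vals <- res[[a]]$cdf(grid)
    expect_true(all(diff(vals) >= 0))
    expect_equal(vals[1], 0)
    expect_equal(vals[50], 1)
  }
  # the disorder-enriched glycine pool sits below the order-enriched isoleucine
  expect_lt(res$G$median, res$I$median)
})

test_that("permutation importance ranks a dominant planted feature first", {
  withr::with_seed(28, {
    X <- matrix(rnorm(2000 * 6), 2000, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- 3 * X[, 1] + 0.3 * X[, 2] + rnorm(2000, sd = 0.5)
  })
  predict_fun <- function(M) 3 * M[, 1] + 0.3 * M[, 2]  # known weights
  imp <- perm_importance_matrix(predict_fun, X, y, repetitions = 5, seed = 9)
  expect_equal(imp$feature[1], "f1")
  # pure-noise features score near zero
  noise <- imp$delta_r2[imp$feature %in% paste0("f", 3:6)]
  expect_true(all(abs(noise) < 0.02))
  # deterministic under the seed
  imp2 <- perm_importance_matrix(predict_fun, X, y, repetitions = 5, seed = 9)
  expect_equal(imp, imp2)
})

test_that("ensemble permutation importance averages over the validation folds", {
  imp <- permutation_importance(small_ensemble(), small_db(),
                                repetitions = 5, seed = 4)
  expect_equal(nrow(imp), 130L)
  expect_setequal(imp$feature, feature_manifest(FALSE)$name)
  expect_true(all(is.finite(imp$delta_r2)))
  expect_false(is.unsorted(rev(imp$delta_r2)))
})

test_that("ROC AUC agrees with an independent reference implementation", {
  withr::with_seed(29, {
    z <- runif(500, 0, 16)
    scores <- runif(500) + 0.5 * (z < 8)
  })
  ours <- roc_auc(z, scores)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(
    response = factor(z < 8, levels = c(FALSE, TRUE)),
    predictor = scores, direction = "<")))
  expect_equal(ours, ref)
})
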