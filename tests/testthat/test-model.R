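test_that("cross-validation split is a seeded balanced partition", {
  entries <- lapply(seq_len(1325), function(i) {
    protein_entry(paste0("e", i), "ACDEFG")
  })
  db <- chezod_db(entries)
  a <- split_crossval(db, k = 10, seed = 3)
  expect_true(all(sort(unique(a)) == 1:10))
  expect_true(all(table(a) %in% c(132L, 133L)))
  expect_equal(sum(table(a)), 1325L)
  expect_identical(a, split_crossval(db, k = 10, seed = 3))
  expect_false(identical(a, split_crossval(db, k = 10, seed = 4)))
  expect_error(split_crossval(db, k = 1), "at least 2")
})

test_that("fold roles follow the validation-n / test-(n-1) scheme with wraparound", {
  s3 <- model_sets(3)
  expect_equal(s3$validation, 3L)
  expect_equal(s3$test, 2L)
  expect_equal(s3$train, setdiff(1:10, c(2L, 3L)))
  s1 <- model_sets(1)
  expect_equal(s1$test, 10L)
  for (n in 1:10) {
    s <- model_sets(n)
    all_folds <- c(s$train, s$test, s$validation)
    expect_equal(sort(all_folds), 1:10)  # disjoint cover
  }
  expect_error(model_sets(0), "1..10")
  expect_error(model_sets(11), "1..10")
})

test_that("network parameters have the layer-algebra shapes", {
  par <- withr::with_seed(1, chezodr:::init_params(130L,
                                                   c(40L, 10L, 25L, 40L, 8L)))
  dims <- c(130, 40, 10, 25, 40, 8, 1)
  for (l in seq_along(par$W)) {
    expect_equal(dim(par$W[[l]]), c(dims[l], dims[l + 1]))
    expect_length(par$b[[l]], dims[l + 1])
  }
})

test_that("a hand-set network reproduces manual matrix arithmetic", {
  spec <- network_spec(hidden_widths = c(3L, 2L), seed = 1)
  # build a minimal trained_model shell with fixed weights on 2 features
  W1 <- matrix(c(1, 0, 0, 1, 1, -1), 2, 3)
  b1 <- c(0.5, -0.5, 0)
  W2 <- matrix(c(1, -1, 0.5, 2, 0, 1), 3, 2)
  b2 <- c(0, 0.25)
  W3 <- matrix(c(2, -1), 2, 1)
  b3 <- 0.1
  model <- structure(
    list(par = list(W = list(W1, W2, W3), b = list(b1, b2, b3)),
         spec = spec, n_features = 2L),
    class = "trained_model")
  X <- matrix(c(0.3, -1.2, 2.0, 0.7), 2, 2)
  manual_A1 <- sweep(X %*% W1, 2, b1, "+")
  manual_H2 <- pmax(sweep(manual_A1 %*% W2, 2, b2, "+"), 0)
  manual_out <- drop(manual_H2 %*% W3 + b3)
  expect_equal(predict_model(model, X), manual_out)
  # zero weights: output equals the bias everywhere
  zero <- model
  zero$par$W <- lapply(zero$par$W, function(w) w * 0)
  expect_equal(predict_model(zero, X), rep(0.1, 2))
  # determinism (no noise at inference)
  expect_identical(predict_model(model, X), predict_model(model, X))
  expect_error(predict_model(model, cbind(X, X)), "expects")
})

test_that("training learns a planted linear map and selects the best test epoch", {
  withr::with_seed(21, {
    mk_seq <- function(L) {
      X <- matrix(rnorm(L * 5), L, 5)
      list(X = X, y = 2 * X[, 1] - X[, 3] + rnorm(L, sd = 0.3))
    }
    train <- lapply(rep(30, 12), mk_seq)
    test <- lapply(rep(30, 3), mk_seq)
  })
  spec <- network_spec(hidden_widths = c(8L, 4L, 4L), epochs = 40L,
                       batch_sequences = 4L, learning_rate = 0.01,
                       seed = 5L)
  model <- train_model(spec, train, test)
  h <- model$history
  expect_equal(nrow(h), 40L)
  expect_lt(h$test_mse[40], h$test_mse[1])
  expect_equal(model$selected_epoch, which.min(h$test_mse))
  # returned weights reproduce the selected epoch's recorded test MSE
  te <- chezodr:::stack_sequences(test)
  mse_now <- mean((predict_model(model, te$X) - te$y)^2)
  expect_equal(mse_now, h$test_mse[model$selected_epoch], tolerance = 1e-12)
  # reproducibility under the same seed
  model2 <- train_model(spec, train, test)
  expect_equal(model$par, model2$par)
  expect_error(train_model(spec, list(), test))
})

test_that("training MSE decreases over early epochs on learnable data", {
  withr::with_seed(31, {
    mk_seq <- function(L) {
      X <- matrix(rnorm(L * 4), L, 4)
      list(X = X, y = X[, 1] + 0.5 * X[, 2])
    }
    train <- lapply(rep(25, 10), mk_seq)
    test <- lapply(rep(25, 2), mk_seq)
  })
  spec <- network_spec(hidden_widths = c(8L, 4L), epochs = 15L,
                       batch_sequences = 5L, learning_rate = 0.01, seed = 2L)
  model <- train_model(spec, train, test)
  h <- model$history$train_mse
  expect_lt(mean(h[11:15]), mean(h[1:5]))
})

test_that("ensemble prediction is the model mean with population-sd spread", {
  ens <- small_ensemble()
  expect_length(ens$models, 10L)
  entry <- withr::with_seed(88, generate_entry(synthetic_config(), "probe"))
  res <- predict_ensemble(ens, entry)
  expect_s3_class(res, "prediction_result")
  expect_equal(nrow(res), nchar(entry$sequence))
  # oracle: recompute mean and population sd from individual model calls
  feats <- build_feature_matrix(entry)
  per_model <- sapply(ens$models, function(m) {
    predict_model(m, apply_normalizer(feats, m$normalizer))
  })
  expect_equal(res$z_pred, rowMeans(per_model))
  expect_equal(res$s_z, apply(per_model, 1, function(x) {
    sqrt(mean((x - mean(x))^2))
  }))
  expect_true(all(res$z_err >= 0))
  # mean is invariant under model reordering
  ens_shuffled <- ens
  ens_shuffled$models <- ens$models[c(4:10, 1:3)]
  res2 <- predict_ensemble(ens_shuffled, entry)
  expect_equal(res2$z_pred, res$z_pred)
  expect_equal(res2$s_z, res$s_z)
})

test_that("identical models give zero ensemble spread", {
  ens <- small_ensemble()
  clone <- ens
  clone$models <- rep(ens$models[1], 10)
  entry <- withr::with_seed(89, generate_entry(synthetic_config(), "probe2"))
  res <- predict_ensemble(clone, entry)
  expect_true(all(res$s_z == 0))
})

test_that("every entry gets exactly one blind prediction from its validation model", {
  ens <- small_ensemble()
  db <- small_db()
  expect_setequal(unique(ens$blind$id), names(db$entries))
  for (id in names(db$entries)) {
    fold <- ens$assignment[[id]]
    model <- ens$models[[fold]]
    # the predicting model never saw this entry in training or testing
    expect_equal(model$sets$validation, fold)
    expect_false(fold %in% model$sets$train)
    expect_false(fold == model$sets$test)
    # and the recorded blind prediction comes from that model
    feats <- build_feature_matrix(db$entries[[id]])
    expected <- predict_model(model,
                              apply_normalizer(feats, model$normalizer))
    expect_equal(ens$blind$z_pred[ens$blind$id == id], expected)
  }
  # rerun with the same seed reproduces the blind predictions exactly
  ens2 <- train_ensemble(small_db(), small_spec(), seed = 404L)
  expect_equal(ens2$blind$z_pred, ens$blind$z_pred)
})

test_that("error calibration recovers the noise scale and is monotone", {
  withr::with_seed(61, {
    n <- 5000
    s_z <- runif(n, 0.2, 3)
    z_obs <- runif(n, -2, 14)
    z_pred <- z_obs + rnorm(n, sd = s_z)  # error scale tied to s_z
  })
  curve <- calibrate_error(z_pred, s_z, z_obs)
  expect_true(all(diff(curve$z_err) >= 0))
  # per-bin mean absolute error of N(0, sigma) is sigma * sqrt(2/pi)
  expected <- curve$s_z_mean * sqrt(2 / pi)
  expect_equal(curve$z_err, expected, tolerance = 0.15)
  # lookups clamp at the ends and stay monotone
  grid <- seq(0, 4, by = 0.05)
  vals <- predict_zerr(curve, grid)
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[1], curve$z_err[1])
  expect_equal(vals[length(vals)], curve$z_err[length(curve$z_err)])
  # perfect predictions give an (essentially) zero curve
  perfect <- calibrate_error(z_obs, s_z, z_obs)
  expect_true(all(perfect$z_err < 1e-12))
  expect_warning(calibrate_error(1:5, 1:5, 1:5), "reducing")
})
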