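# 10-fold cross-validation ensemble: fold assignment, per-model
# train/test/validation roles, ensemble training with blind predictions,
# and ensemble inference with precision and calibrated error.

#' Random k-fold assignment of database entries
#'
#' Splits the entries randomly into `k` disjoint folds whose sizes differ by
#' at most one. Seeded and reproducible.
#'
#' @param db A [chezod_db()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Named integer vector mapping entry id to fold in `1..k`.
#' @export
split_crossval <- function(db, k = 10L, seed = 1L) {
  stopifnot(inherits(db, "chezod_db"))
  n <- length(db)
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("need at least k entries")
  assignment <- withr::with_seed(seed,
    sample(rep_len(seq_len(k), n))
  )
  names(assignment) <- names(db$entries)
  assignment
}

#' Fold roles for cross-validation model n
#'
#' In model `n`, fold `n` is the validation set (blind predictions) and fold
#' `n - 1` the testing set used for epoch selection, with wraparound for
#' `n = 1` (test fold `k`); the remaining `k - 2` folds are the training set.
#'
#' @param n Model index in `1..k`.
#' @param k Number of folds (default 10).
#' @return List with integer fields `train`, `test`, `validation`.
#' @export
#' @examples
#' model_sets(3)  # validation 3, test 2, train the rest
model_sets <- function(n, k = 10L) {
  stopifnot(k >= 3L)
  if (!(is.numeric(n) && length(n) == 1L && n == round(n) && n >= 1 &&
        n <= k)) {
    stop("model index n must be an integer in 1..", k)
  }
  n <- as.integer(n)
  test <- if (n == 1L) as.integer(k) else n - 1L
  list(train = setdiff(seq_len(as.integer(k)), c(n, test)),
       test = test, validation = n)
}

# feature matrices for every entry (computed once, unnormalized)
db_features <- function(db, msas = NULL, evolution = !is.null(msas), ...) {
  lapply(db$entries, function(e) {
    msa <- if (!is.null(msas)) msas[[e$id]]
    build_feature_matrix(e, msa = msa, evolution = evolution, ...)
  })
}

# per-sequence example lists for a set of entry ids under one normalizer
make_examples <- function(db, feats, ids, normalizer) {
  lapply(ids, function(id) {
    list(X = apply_normalizer(feats[[id]], normalizer),
         y = db$entries[[id]]$zscores)
  })
}

#' Train the 10-fold cross-validation ensemble
#'
#' Assigns entries to folds, then trains one model per fold role given by
#' [model_sets()]. Each model's normalizer is fitted on its own training
#' folds only (no leakage from its test or validation entries). Blind
#' cross-validated predictions are collected — each entry is predicted by
#' the single model whose validation fold contains it — and used to fit the
#' precision-to-error calibration curve: the blind prediction supplies the
#' error `|Z_obs - Z_pred|` while the spread of all 10 models supplies the
#' precision `s_Z`.
#'
#' @param db A [chezod_db()] whose entries carry Z-scores.
#' @param spec A [network_spec()]; per-model seeds are derived
#'   deterministically from `seed`.
#' @param seed Master integer seed (fold split and per-model training).
#' @param k Number of folds/models (default 10).
#' @param msas Optional named list of alignments for evolutionary features.
#' @param ... Passed to [build_feature_matrix()].
#' @return An object of class `trained_ensemble` with fields `models` (each
#'   with its normalizer and fold roles), `assignment`, `calibration`,
#'   `blind` (per-residue blind predictions), `manifest`, `spec`.
#' @export
train_ensemble <- function(db, spec = network_spec(), seed = 1L, k = 10L,
                           msas = NULL, ...) {
  stopifnot(inherits(db, "chezod_db"), inherits(spec, "network_spec"))
  feats <- db_features(db, msas = msas, ...)
  manifest <- feats[[1L]]$names
  assignment <- split_crossval(db, k = k, seed = seed)
  ids <- names(assignment)
  models <- vector("list", k)
  for (n in seq_len(k)) {
    sets <- model_sets(n, k)
    train_ids <- ids[assignment %in% sets$train]
    test_ids <- ids[assignment == sets$test]
    normalizer <- fit_normalizer(feats[train_ids])
    spec_n <- spec
    spec_n$seed <- as.integer((seed * 1009L + n) %% .Machine$integer.max)
    model <- train_model(spec_n,
                         train = make_examples(db, feats, train_ids,
                                               normalizer),
                         test = make_examples(db, feats, test_ids,
                                              normalizer))
    model$normalizer <- normalizer
    model$sets <- sets
    models[[n]] <- model
  }
  # blind predictions and ensemble spread for every entry
  blind <- lapply(ids, function(id) {
    per_model <- vapply(models, function(m) {
      predict_model(m, apply_normalizer(feats[[id]], m$normalizer))
    }, numeric(nrow(feats[[id]]$values)))
    per_model <- matrix(per_model, nrow = nrow(feats[[id]]$values))
    fold <- assignment[[id]]
    data.frame(
      id = id,
      resnum = seq_len(nrow(per_model)),
      z_obs = if (is.null(db$entries[[id]]$zscores)) NA_real_ else
        db$entries[[id]]$zscores,
      z_pred = per_model[, fold],
      s_z = apply(per_model, 1L, sd_pop),
      stringsAsFactors = FALSE
    )
  })
  blind <- do.call(rbind, blind)
  ok <- !is.na(blind$z_obs)
  calibration <- calibrate_error(blind$z_pred[ok], blind$s_z[ok],
                                 blind$z_obs[ok])
  structure(
    list(models = models, assignment = assignment, calibration = calibration,
         blind = blind, manifest = manifest, spec = spec, seed = seed),
    class = "trained_ensemble"
  )
}

# population standard deviation (spread of the k model predictions)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.trained_ensemble <- function(x, ...) {
  cat("<trained_ensemble> ", length(x$models), " models, ",
      length(x$manifest), " features; blind predictions for ",
      length(unique(x$blind$id)), " entries\n", sep = "")
  invisible(x)
}

#' Predict disorder Z-scores with the ensemble
#'
#' The final prediction is the mean of the 10 per-model predictions; the
#' population standard deviation across models, `s_Z`, estimates the
#' precision, and the calibration curve converts it into an expected
#' absolute error `Z_err`.
#'
#' @param ensemble A [train_ensemble()] result.
#' @param entry A [protein_entry()] or sequence string.
#' @param msa Optional alignment (required if the ensemble was trained with
#'   evolutionary features).
#' @param ... Passed to [build_feature_matrix()].
#' @return A `prediction_result` data frame with columns `resnum`, `aa`,
#'   `z_pred`, `s_z`, `z_err`.
#' @export
predict_ensemble <- function(ensemble, entry, msa = NULL, ...) {
  stopifnot(inherits(ensemble, "trained_ensemble"))
  if (is.character(entry)) entry <- protein_entry("query", entry)
  feats <- build_feature_matrix(entry, msa = msa,
                                evolution = !is.null(msa), ...)
  if (!identical(feats$names, ensemble$manifest)) {
    stop("feature manifest mismatch between input and ensemble")
  }
  per_model <- vapply(ensemble$models, function(m) {
    predict_model(m, apply_normalizer(feats, m$normalizer))
  }, numeric(nrow(feats$values)))
  per_model <- matrix(per_model, nrow = nrow(feats$values))
  s_z <- apply(per_model, 1L, sd_pop)
  out <- data.frame(
    resnum = seq_len(nrow(per_model)),
    aa = seq_chars(entry$sequence),
    z_pred = rowMeans(per_model),
    s_z = s_z,
    z_err = predict_zerr(ensemble$calibration, s_z),
    stringsAsFactors = FALSE
  )
  class(out) <- c("prediction_result", class(out))
  attr(out, "entry_id") <- entry$id
  out
}
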