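# Permutation feature importance: drop in squared Pearson correlation when
# one feature column is shuffled while all others are kept fixed.

#' Permutation importance for an arbitrary predictor
#'
#' For each feature column, shuffles that column (keeping all others fixed)
#' `repetitions` times, recomputes the squared Pearson correlation between
#' predictions and targets, and reports the drop from the baseline R^2
#' averaged over the shuffles.
#'
#' @param predict_fun Function taking a feature matrix and returning one
#'   prediction per row.
#' @param X Numeric feature matrix.
#' @param y Numeric target vector (length `nrow(X)`).
#' @param repetitions Number of shuffle rounds per feature (default 5).
#' @param seed Integer seed for the shuffles.
#' @return Data frame with columns `feature`, `delta_r2`, `baseline_r2`,
#'   sorted by decreasing `delta_r2`.
#' @export
perm_importance_matrix <- function(predict_fun, X, y, repetitions = 5L,
                                   seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), repetitions >= 1L)
  r2 <- function(pred) {
    if (stats::sd(pred) == 0) return(0)
    stats::cor(pred, y)^2
  }
  baseline <- r2(predict_fun(X))
  nf <- ncol(X)
  delta <- numeric(nf)
  withr::with_seed(seed, {
    for (f in seq_len(nf)) {
      shuffled_r2 <- numeric(repetitions)
      for (r in seq_len(repetitions)) {
        Xs <- X
        Xs[, f] <- X[sample.int(nrow(X)), f]
        shuffled_r2[r] <- r2(predict_fun(Xs))
      }
      delta[f] <- baseline - mean(shuffled_r2)
    }
  })
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("f", seq_len(nf))
  out <- data.frame(feature = nm, delta_r2 = delta, baseline_r2 = baseline,
                    stringsAsFactors = FALSE)
  out[order(-out$delta_r2), ]
}

#' Permutation importance of the ensemble's features
#'
#' Applies the permutation-importance procedure to every cross-validation
#' model on its own blind validation fold: each feature is shuffled
#' one-by-one (5 repetitions by default) across the validation residues,
#' the squared Pearson correlation between predictions and observed
#' Z-scores is recomputed, and the per-model R^2 drops are averaged over
#' models. Features are ranked by decreasing mean drop.
#'
#' @param ensemble A [train_ensemble()] result.
#' @param db The [chezod_db()] the ensemble was trained on.
#' @param repetitions Shuffle rounds per feature (default 5).
#' @param seed Integer seed.
#' @param msas Optional named list of alignments (if the ensemble uses
#'   evolutionary features).
#' @param ... Passed to [build_feature_matrix()].
#' @return Data frame with `feature`, `group`, `delta_r2` (mean over
#'   models), sorted by decreasing importance.
#' @export
permutation_importance <- function(ensemble, db, repetitions = 5L, seed = 1L,
                                   msas = NULL, ...) {
  stopifnot(inherits(ensemble, "trained_ensemble"),
            inherits(db, "chezod_db"))
  feats <- db_features(db, msas = msas, ...)
  assignment <- ensemble$assignment
  ids <- names(assignment)
  k <- length(ensemble$models)
  per_model <- vector("list", k)
  for (n in seq_len(k)) {
    model <- ensemble$models[[n]]
    val_ids <- ids[assignment == model$sets$validation]
    ex <- make_examples(db, feats, val_ids, model$normalizer)
    st <- stack_sequences(ex)
    imp <- perm_importance_matrix(function(X) predict_model(model, X),
                                  st$X, st$y, repetitions = repetitions,
                                  seed = as.integer((seed * 131L + n) %%
                                                      .Machine$integer.max))
    per_model[[n]] <- imp$delta_r2[match(ensemble$manifest, imp$feature)]
  }
  delta <- rowMeans(do.call(cbind, per_model))
  manifest <- feature_manifest(evolution =
                                 length(ensemble$manifest) > 130L)
  out <- data.frame(feature = ensemble$manifest,
                    group = manifest$group[match(ensemble$manifest,
                                                 manifest$name)],
                    delta_r2 = delta, stringsAsFactors = FALSE)
  out[order(-out$delta_r2), ]
}
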