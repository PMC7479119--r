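# Performance metrics for continuous and binary disorder prediction.
# Positive class = disordered throughout.

#' Pearson and Spearman correlation between observed and predicted values
#'
#' Pairs with a missing observation are dropped; Spearman uses average ranks
#' for ties. A zero-variance input yields `NA` with a warning.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 3 complete
#'   pairs).
#' @return List with `pearson` and `spearman`.
#' @export
correlations <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  keep <- is.finite(observed) & is.finite(predicted)
  x <- observed[keep]
  y <- predicted[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlations undefined")
    return(list(pearson = NA_real_, spearman = NA_real_))
  }
  list(pearson = stats::cor(x, y),
       spearman = stats::cor(x, y, method = "spearman"))
}

#' Confusion counts at a threshold
#'
#' Truth: a residue is disordered when its observed Z-score is below
#' `z_threshold`. Call: the score is beyond `score_threshold` on the
#' disorder side — above it when `higher_is_disordered` (probabilities),
#' below it otherwise (Z-like scores).
#'
#' @param z_obs Observed Z-scores.
#' @param scores Prediction scores (same length).
#' @param z_threshold Order/disorder threshold on observed Z (default 8).
#' @param score_threshold Decision threshold on the scores.
#' @param higher_is_disordered Direction of the score (default `TRUE`).
#' @return List of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(z_obs, scores, z_threshold = 8.0,
                                   score_threshold,
                                   higher_is_disordered = TRUE) {
  stopifnot(length(z_obs) == length(scores))
  keep <- is.finite(z_obs) & is.finite(scores)
  truth <- z_obs[keep] < z_threshold
  call <- if (higher_is_disordered) scores[keep] > score_threshold else
    scores[keep] < score_threshold
  structure(
    list(tp = sum(truth & call), fp = sum(!truth & call),
         tn = sum(!truth & !call), fn = sum(truth & !call)),
    class = "confusion_counts"
  )
}

#' Matthews correlation coefficient
#'
#' @param confusion A [confusion_at_threshold()] result, or a list/vector
#'   with elements `tp`, `fp`, `tn`, `fn`.
#' @return MCC in \[-1, 1\]; 0 by convention when any denominator factor is
#'   zero (e.g. single-class predictions).
#' @export
mcc <- function(confusion) {
  cc <- as.list(confusion)
  tp <- as.numeric(cc$tp); fp <- as.numeric(cc$fp)
  tn <- as.numeric(cc$tn); fn <- as.numeric(cc$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# order scores from most to least disorder-like, grouping ties
sweep_counts <- function(truth, scores) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t)
  fp <- cumsum(!t)
  last <- !duplicated(grp, fromLast = TRUE)  # last index of each tie group
  list(tp = tp[last], fp = fp[last], thr = s[last],
       n_pos = sum(t), n_neg = sum(!t))
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over the unique score values (ties
#' grouped), plotting true-positive rate against false-positive rate, and
#' integrates by the trapezoidal rule. Positive class = disordered
#' (observed Z below `z_threshold`).
#'
#' @inheritParams confusion_at_threshold
#' @return List with `curve` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(z_obs, scores, z_threshold = 8.0,
                    higher_is_disordered = TRUE) {
  stopifnot(length(z_obs) == length(scores))
  keep <- is.finite(z_obs) & is.finite(scores)
  truth <- z_obs[keep] < z_threshold
  sc <- if (higher_is_disordered) scores[keep] else -scores[keep]
  if (!any(truth) || all(truth)) {
    stop("both classes must be present for a ROC curve")
  }
  sw <- sweep_counts(truth, sc)
  tpr <- c(0, sw$tp / sw$n_pos)
  fpr <- c(0, sw$fp / sw$n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = c(Inf, sw$thr), fpr = fpr, tpr = tpr),
       auc = auc)
}

#' Precision-recall curve and area under it
#'
#' Threshold sweep with ties grouped; the area uses step interpolation
#' (each recall increment weighted by the precision reached there), so a
#' constant score yields the positive-class prevalence.
#'
#' @inheritParams confusion_at_threshold
#' @return List with `curve` (data frame `threshold`, `recall`,
#'   `precision`) and `auc`.
#' @export
pr_auc <- function(z_obs, scores, z_threshold = 8.0,
                   higher_is_disordered = TRUE) {
  stopifnot(length(z_obs) == length(scores))
  keep <- is.finite(z_obs) & is.finite(scores)
  truth <- z_obs[keep] < z_threshold
  sc <- if (higher_is_disordered) scores[keep] else -scores[keep]
  if (!any(truth)) stop("positive class absent")
  sw <- sweep_counts(truth, sc)
  recall <- sw$tp / sw$n_pos
  precision <- sw$tp / (sw$tp + sw$fp)
  auc <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = sw$thr, recall = recall,
                          precision = precision),
       auc = auc)
}

#' Per-amino-acid Z-score distributions
#'
#' Pools the observed Z-scores of a database by residue type and returns,
#' for each amino acid present, its empirical cumulative distribution
#' function and median Z. Amino acids without any observed Z-score are
#' omitted with a warning.
#'
#' @param db A [chezod_db()] with Z-scores.
#' @return Named list (per amino acid) of lists with `cdf` (an
#'   [stats::ecdf()]), `median`, and `n`.
#' @export
per_aa_cdf <- function(db) {
  stopifnot(inherits(db, "chezod_db"))
  aa <- unlist(lapply(db$entries, function(e) seq_chars(e$sequence)),
               use.names = FALSE)
  z <- unlist(lapply(db$entries, function(e) {
    if (is.null(e$zscores)) rep(NA_real_, nchar(e$sequence)) else e$zscores
  }), use.names = FALSE)
  keep <- !is.na(z) & aa %in% AA_ALPHABET
  aa <- aa[keep]
  z <- z[keep]
  absent <- setdiff(AA_ALPHABET, unique(aa))
  if (length(absent)) {
    warning("no Z-scores for amino acid(s): ", paste(absent, collapse = ","))
  }
  out <- lapply(split(z, aa), function(zi) {
    list(cdf = stats::ecdf(zi), median = stats::median(zi),
         n = length(zi))
  })
  out[order(names(out))]
}

#' Full metrics report for Z-score predictions
#'
#' Convenience wrapper computing the continuous correlations, the
#' confusion counts and MCC at the Z = 8 threshold (predicted Z below
#' threshold calls disorder), and the ROC/PR areas using the negated
#' predicted Z-score as the disorder score.
#'
#' @param z_obs,z_pred Observed and predicted Z-scores.
#' @param z_threshold Order/disorder threshold (default 8).
#' @return List with `r_pearson`, `r_spearman`, `mcc`, `auc_roc`, `auc_pr`,
#'   `confusion`, `n_residues`.
#' @export
evaluate_predictions <- function(z_obs, z_pred, z_threshold = 8.0) {
  keep <- is.finite(z_obs) & is.finite(z_pred)
  cors <- correlations(z_obs[keep], z_pred[keep])
  conf <- confusion_at_threshold(z_obs[keep], z_pred[keep],
                                 z_threshold = z_threshold,
                                 score_threshold = z_threshold,
                                 higher_is_disordered = FALSE)
  list(
    r_pearson = cors$pearson,
    r_spearman = cors$spearman,
    mcc = mcc(conf),
    auc_roc = roc_auc(z_obs[keep], z_pred[keep], z_threshold,
                      higher_is_disordered = FALSE)$auc,
    auc_pr = pr_auc(z_obs[keep], z_pred[keep], z_threshold,
                    higher_is_disordered = FALSE)$auc,
    confusion = conf,
    n_residues = sum(keep)
  )
}
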