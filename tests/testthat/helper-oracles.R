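# Independent oracles used to check package computations. These are written
# directly from definitions (loops, closed forms, rank statistics) and share
# no code with the implementation they verify.

# Hamming-based identity for pairs constructed so that the optimal global
# alignment is gapless (equal lengths, enough matches that gaps cannot pay
# for themselves under match 1 / mismatch 0 / gap -1).
hamming_identity_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca == cb) / length(ca)
}

pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  num / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

spearman_oracle <- function(x, y) {
  pearson_oracle(rank(x), rank(y))  # average ranks for ties
}

# ROC AUC via the Mann-Whitney U identity, ties counted half
mann_whitney_auc_oracle <- function(truth, scores) {
  pos <- scores[truth]
  neg <- scores[!truth]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

mcc_oracle <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# brute-force precision-recall sweep with step-interpolated area
pr_auc_oracle <- function(truth, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  recall_prev <- 0
  area <- 0
  for (t in thr) {
    call <- scores >= t
    tp <- sum(truth & call)
    prec <- tp / sum(call)
    rec <- tp / sum(truth)
    area <- area + (rec - recall_prev) * prec
    recall_prev <- rec
  }
  area
}

# per-position windowed mean by explicit looping (truncated windows,
# NA-excluding)
window_mean_oracle <- function(x, w) {
  h <- (w - 1) %/% 2
  vapply(seq_along(x), function(i) {
    win <- x[max(1, i - h):min(length(x), i + h)]
    win <- win[!is.na(win)]
    if (length(win)) mean(win) else 0
  }, numeric(1))
}

random_sequence <- function(L, letters = chezodr::AA_ALPHABET) {
  paste(sample(letters, L, replace = TRUE), collapse = "")
}
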