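# Derive a reproducible child seed from a master seed and a salt string.
# Keeps results within [0, 2^31 - 2] so they remain valid R integer seeds.
derive_seed <- function(seed, salt) {
  h <- sum(utf8ToInt(as.character(salt)) * seq_along(utf8ToInt(as.character(salt))))
  as.integer((as.double(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

# Rank-based AUC (Mann-Whitney) of scores for binary labels (logical or 0/1,
# TRUE/1 = positive class). Ties handled by midranks.
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Matthews correlation coefficient from a confusion count.
mcc_value <- function(tp, tn, fp, fn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

# Choose the classification threshold maximising MCC over midpoints of
# sorted unique scores; returns threshold plus metrics at it. Scores above
# the threshold are called positive.
mcc_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  cand <- if (length(u) >= 2) (u[-1] + u[-length(u)]) / 2 else u
  best <- NULL
  for (th in cand) {
    pred <- scores > th
    m <- mcc_value(sum(pred & labels), sum(!pred & !labels),
                   sum(pred & !labels), sum(!pred & labels))
    if (is.null(best) || m > best$mcc + 1e-12) best <- list(threshold = th, mcc = m)
  }
  if (is.null(best)) best <- list(threshold = u[1] - 1, mcc = 0)
  pred <- scores > best$threshold
  tp <- sum(pred & labels); tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels); fn <- sum(!pred & labels)
  list(threshold = best$threshold, mcc = best$mcc,
       accuracy = (tp + tn) / length(labels),
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
}
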