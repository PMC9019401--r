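# Independent AUC oracles kept deliberately naive: an exhaustive O(n*m)
# pair count and a literal trapezoid integration of the empirical ROC
# polygon. They share no code with roc_analysis().
auc_pair_count <- function(cases, controls) {
  s <- 0
  for (x in cases)
    for (y in controls)
      s <- s + (x > y) + 0.5 * (x == y)
  s / (length(cases) * length(controls))
}

auc_trapezoid <- function(cases, controls) {
  thr <- sort(unique(c(cases, controls, -Inf, Inf)))
  tpr <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(controls >= t), numeric(1))
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}
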