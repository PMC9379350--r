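#' True Skill Statistic from a confusion matrix
#'
#' `TSS = sensitivity + specificity - 1 = tp/(tp+fn) + tn/(fp+tn) - 1`,
#' ranging from -1 to +1 with +1 indicating perfect agreement and values near
#' 0 chance performance. Unlike kappa it is unaffected by prevalence.
#'
#' @param tp,fp,fn,tn confusion-matrix counts (non-negative; both observed
#'   classes must be represented: `tp + fn > 0` and `fp + tn > 0`).
#' @return numeric scalar in `[-1, 1]`.
#' @export
compute_tss <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (tp + fn == 0) stop("no observed presences: sensitivity undefined")
  if (fp + tn == 0) stop("no observed absences: specificity undefined")
  tp / (tp + fn) + tn / (fp + tn) - 1
}

# Confusion counts for predicted = (probs >= threshold).
confusion_counts <- function(probs, labels, threshold) {
  pred <- probs >= threshold
  c(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
    fn = sum(!pred & labels == 1), tn = sum(!pred & labels == 0))
}

#' Probability cutoff maximizing the True Skill Statistic
#'
#' Scans candidate thresholds at the midpoints between consecutive sorted
#' unique predicted probabilities, plus the lowest probability itself (the
#' all-presence cutoff, TSS 0), so every distinct confusion matrix reachable
#' by any cutoff is visited: a cutoff above all probabilities (all-absence)
#' also has TSS 0 and so can never beat the included all-presence candidate.
#' Returns the cutoff with maximal TSS. Ties are broken toward the lower
#' threshold, which favors sensitivity.
#'
#' @param probs predicted probabilities.
#' @param labels observed 0/1 labels (both classes must be present).
#' @return list with elements `threshold` and `tss`.
#' @export
max_tss_threshold <- function(probs, labels) {
  if (length(probs) != length(labels)) stop("probs and labels differ in length")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop("both classes must be present to optimize TSS")
  u <- sort(unique(probs))
  if (length(u) < 2) stop("all predicted probabilities identical; no threshold exists")
  cand <- c(u[1], (u[-length(u)] + u[-1]) / 2)
  tss <- vapply(cand, function(th) {
    cc <- confusion_counts(probs, labels, th)
    compute_tss(cc["tp"], cc["fp"], cc["fn"], cc["tn"])
  }, numeric(1))
  best <- which(tss >= max(tss) - 1e-12)[1] # lowest threshold among ties
  list(threshold = cand[best], tss = tss[best])
}
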