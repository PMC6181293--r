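#' Area under the ROC curve (Mann-Whitney form)
#'
#' The AUC equals the probability that a randomly chosen positive
#' outscores a randomly chosen negative, with half credit for ties:
#' the mean over all (positive, negative) pairs of
#' \eqn{[s_+ > s_-] + \frac{1}{2}[s_+ = s_-]}. Computed via midranks.
#'
#' @param scores numeric scores (class-of-interest probabilities).
#' @param labels logical (or 0/1) one-vs-rest labels; `TRUE` = positive.
#' @return the AUC in `[0, 1]`, or `NA` (with a warning) when either
#'   class is absent — an undefined AUC is reported missing, never 0.5.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUC undefined: one class absent; reported as NA")
    return(NA_real_)
  }
  r <- rank(scores)   # midranks give the half-credit tie convention
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall curve on a fixed recall grid
#'
#' Precision and recall are computed at every distinct score threshold
#' (the same confusion counts that generate the ROC curve, hence the
#' one-to-one correspondence between the two curves), then precision is
#' linearly interpolated onto a fixed recall grid so curves from
#' different train/test combinations can be averaged point-wise.
#' Where several thresholds share a recall value the best precision at
#' that recall is kept.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) labels; `TRUE` = positive.
#' @param recall_grid common abscissa (default 101 points on `[0, 1]`).
#' @return a data frame with columns `recall` and `precision`, or `NA`
#'   (with a warning) when no positive item exists.
#' @export
prc_curve <- function(scores, labels, recall_grid = seq(0, 1, length.out = 101)) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n_pos <- sum(labels)
  if (n_pos == 0L) {
    warning("PRC undefined: no positive items; reported as NA")
    return(NA)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(labels & scores >= t), numeric(1))
  pp <- vapply(thr, function(t) sum(scores >= t), numeric(1))
  recall <- tp / n_pos
  precision <- tp / pp
  # keep the best precision at each achieved recall level
  best <- tapply(precision, recall, max)
  r_pts <- as.numeric(names(best))
  p_pts <- as.numeric(best)
  ord <- order(r_pts)
  r_pts <- r_pts[ord]; p_pts <- p_pts[ord]
  if (r_pts[1L] > 0) {           # anchor: extend first precision to recall 0
    r_pts <- c(0, r_pts)
    p_pts <- c(p_pts[1L], p_pts)
  }
  interp <- stats::approx(r_pts, p_pts, xout = recall_grid, rule = 2,
                          ties = "ordered")$y
  data.frame(recall = recall_grid, precision = interp)
}
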