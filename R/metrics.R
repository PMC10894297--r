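#' Confusion counts between predicted and true vessel masks
#'
#' Counts are taken over in-FOV pixels only (full frame when `fov` is
#' absent); the positive class is vessel (= 1).
#'
#' @param pred Binary predicted mask.
#' @param gt Binary ground-truth mask.
#' @param fov Optional binary field-of-view mask.
#' @return A `vs_confusion` list: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, gt, fov = NULL) {
  if (!identical(dim(pred), dim(gt))) stop_vs("pred/gt shape mismatch")
  if (!is.null(fov)) {
    if (!identical(dim(fov), dim(gt))) stop_vs("fov shape mismatch")
    keep <- fov != 0
    pred <- pred[keep]; gt <- gt[keep]
  }
  p <- pred != 0; g <- gt != 0
  structure(list(tp = sum(p & g), fp = sum(p & !g),
                 fn = sum(!p & g), tn = sum(!p & !g)),
            class = "vs_confusion")
}

#' Classification metrics from confusion counts
#'
#' Computes the Jaccard index, F1 (Dice), recall (= sensitivity; one stored
#' value), precision, accuracy, Cohen's kappa and specificity:
#' \deqn{J = \frac{TP}{TP+FP+FN},\quad F1 = \frac{2PR}{P+R},\quad
#'   R = \frac{TP}{TP+FN},\quad P = \frac{TP}{TP+FP},}
#' \deqn{Acc = \frac{TP+TN}{N},\quad
#'   \kappa = \frac{p_o - p_e}{1 - p_e},\quad Spec = \frac{TN}{TN+FP},}
#' with \eqn{p_o = Acc} and \eqn{p_e = [(TP+FN)(TP+FP) +
#' (TN+FP)(TN+FN)]/N^2}. Ratios with zero denominators are reported as
#' `NaN` (flagged undefined), never raised as errors, so that aggregation
#' code can treat them explicitly.
#'
#' @param counts A `vs_confusion` from [confusion_counts()].
#' @return A `vs_metrics` list: `jaccard`, `f1`, `recall`, `precision`,
#'   `accuracy`, `kappa`, `specificity`, `counts`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop_vs("no pixels to evaluate (total count is 0)")
  sdiv <- function(num, den) if (den == 0) NaN else num / den
  jaccard <- sdiv(tp, tp + fp + fn)
  recall <- sdiv(tp, tp + fn)
  precision <- sdiv(tp, tp + fp)
  f1 <- if (is.nan(recall) || is.nan(precision) || precision + recall == 0) NaN else
    2 * precision * recall / (precision + recall)
  accuracy <- (tp + tn) / total
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / total^2
  kappa <- if (p_e == 1) NaN else (accuracy - p_e) / (1 - p_e)
  specificity <- sdiv(tn, tn + fp)
  structure(list(jaccard = jaccard, f1 = f1, recall = recall,
                 precision = precision, accuracy = accuracy, kappa = kappa,
                 specificity = specificity, counts = counts),
            class = "vs_metrics")
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen vessel pixel
#' receives a higher score than a randomly chosen background pixel, ties
#' counting one half. Equivalent to the trapezoidal area under the ROC
#' curve.
#'
#' @param V Probability map (object or matrix), or a numeric vector.
#' @param gt Binary ground truth of matching shape.
#' @param fov Optional binary field-of-view mask.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(V, gt, fov = NULL) {
  v <- if (inherits(V, "vs_probability_map")) V$values else V
  if (!is.null(dim(v)) && !identical(dim(v), dim(gt))) stop_vs("V/gt shape mismatch")
  if (!is.null(fov)) {
    keep <- fov != 0
    v <- v[keep]; gt <- gt[keep]
  }
  v <- as.numeric(v); g <- as.numeric(gt) != 0
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 == 0 || n0 == 0) stop_vs("AUC needs at least one positive and one negative pixel")
  r <- rank(v, ties.method = "average")
  (sum(r[g]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Frames-per-second throughput
#'
#' @param total_frames Number of images processed.
#' @param total_time Wall time in seconds (> 0).
#' @return `total_frames / total_time`.
#' @export
fps <- function(total_frames, total_time) {
  if (total_time <= 0) stop_vs("total_time must be positive")
  total_frames / total_time
}

#' Evaluate one probability map against its ground truth
#'
#' Thresholds and refines `V` via the post-processing parameters, derives
#' confusion counts within the FOV, and reports all classification metrics
#' plus AUC (computed on the raw probabilities) and FPS (from `elapsed`
#' when provided).
#'
#' @param V Probability map (object or matrix).
#' @param gt Binary ground truth.
#' @param fov Optional binary FOV mask.
#' @param postproc A [postproc_params()], or `NULL` to threshold at 0.5 with
#'   no morphology.
#' @param elapsed Optional processing wall time in seconds for this sample.
#' @return A `vs_metrics_report`: all `vs_metrics` fields plus `auc`, `fps`
#'   and the binary mask used (`mask`).
#' @export
evaluate_sample <- function(V, gt, fov = NULL, postproc = postproc_params(),
                            elapsed = NA_real_) {
  B <- if (is.null(postproc)) apply_threshold(V, 0.5) else postprocess(V, postproc)
  counts <- confusion_counts(B, gt, fov)
  m <- compute_metrics(counts)
  m$auc <- auc_score(V, gt, fov)
  m$fps <- if (is.na(elapsed)) NA_real_ else fps(1, elapsed)
  m$mask <- B
  class(m) <- c("vs_metrics_report", "vs_metrics")
  m
}

#' Aggregate per-sample reports
#'
#' Mean of every metric over samples; `NaN` (flagged-undefined) values are
#' excluded per metric and the number of contributing samples reported.
#'
#' @param reports List of `vs_metrics` / `vs_metrics_report` objects.
#' @return A data frame with one row per metric: `metric`, `mean`, `n_used`.
#' @export
aggregate_reports <- function(reports) {
  fields <- c("jaccard", "f1", "recall", "precision", "accuracy", "kappa",
              "auc", "specificity", "fps")
  rows <- lapply(fields, function(f) {
    vals <- vapply(reports, function(r) {
      v <- r[[f]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    ok <- !is.na(vals) & !is.nan(vals)
    data.frame(metric = f,
               mean = if (any(ok)) mean(vals[ok]) else NaN,
               n_used = sum(ok))
  })
  do.call(rbind, rows)
}

#' @export
print.vs_metrics <- function(x, ...) {
  cat("<vs_metrics>\n")
  for (f in c("jaccard", "f1", "recall", "precision", "accuracy", "kappa",
              "auc", "specificity")) {
    if (!is.null(x[[f]])) cat(sprintf("  %-11s %.4f\n", f, x[[f]]))
  }
  invisible(x)
}
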