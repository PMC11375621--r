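# Annotation-performance validation against spiked ground truth.
#
# Counting convention (deliberately not the textbook confusion matrix): a
# feature annotated with the wrong structure increments BOTH the false
# negatives (the true chemical was missed) and the false positives (a wrong
# structure was asserted); an unannotated feature is a false negative only.
# Under this convention tp + fn equals the evaluable universe.

#' Score predicted annotations against ground truth
#'
#' @param predicted data.frame with `feature_id` and `structure_id`
#'   (`NA`/empty = unannotated). Features absent from `predicted` count as
#'   unannotated.
#' @param truth data.frame with `feature_id` and `structure_id`, one row per
#'   evaluable feature (the closed evaluation universe).
#' @return A `confusion_counts`: list with `tp`, `fp`, `fn`, `universe`.
#' @export
score_annotations <- function(predicted, truth) {
  stopifnot(all(c("feature_id", "structure_id") %in% names(predicted)),
            all(c("feature_id", "structure_id") %in% names(truth)))
  if (anyDuplicated(truth$feature_id))
    stop("truth contains duplicated feature ids")
  extra <- setdiff(predicted$feature_id, truth$feature_id)
  if (length(extra))
    stop("predicted feature(s) outside the evaluation universe: ",
         paste(extra, collapse = ", "))
  pred <- predicted$structure_id[match(truth$feature_id,
                                       predicted$feature_id)]
  pred[!is.na(pred) & !nzchar(pred)] <- NA
  annotated <- !is.na(pred)
  correct <- annotated & pred == truth$structure_id
  tp <- sum(correct)
  fp <- sum(annotated & !correct)
  fn <- sum(!correct)            # wrong or unannotated
  structure(list(tp = tp, fp = fp, fn = fn, universe = nrow(truth)),
            class = "confusion_counts")
}

#' True positive rate, precision and F1
#'
#' `tpr = tp / (tp + fn)`, `precision = tp / (tp + fp)`,
#' `f1 = 2 * tpr * precision / (tpr + precision)`. A metric with a zero
#' denominator is undefined and reported as `NA`, never silently zero.
#' Full-precision values are kept; `report` carries the values rounded half
#' away from zero to 2 decimal places.
#'
#' @param counts A `confusion_counts` (or list with `tp`, `fp`, `fn`).
#' @return A `metric_set`: list with `tpr`, `precision`, `f1` and `report`
#'   (named numeric, 2 dp).
#' @export
#' @examples
#' compute_metrics(list(tp = 17, fp = 2, fn = 4))
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(tpr) && !is.na(precision) && (tpr + precision) > 0)
    2 * tpr * precision / (tpr + precision) else NA_real_
  structure(list(tpr = tpr, precision = precision, f1 = f1,
                 report = c(tpr = round_half_away(tpr, 2),
                            precision = round_half_away(precision, 2),
                            f1 = round_half_away(f1, 2))),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> TPR %.2f, precision %.2f, F1 %.2f\n",
              x$tpr, x$precision, x$f1))
  invisible(x)
}

#' Detection frequency of features across samples
#'
#' Percent of samples in which each feature is present (detected in at least
#' one replicate of the sample), rounded to a whole percent.
#'
#' @param features Feature table.
#' @param design An [experiment_design()].
#' @return Named integer vector (feature id -> percent).
#' @export
#' @examples
#' # 9 of 13 samples -> 69
detection_frequency <- function(features, design) {
  .check_features(features, design)
  samples <- .design_samples(design)
  if (length(samples) == 0) stop("design contains no samples")
  rep_of <- split(design$replicate_id[!design$is_blank],
                  design$sample_id[!design$is_blank])
  m <- .intensity_matrix(features, design$replicate_id)
  out <- vapply(seq_len(nrow(features)), function(i) {
    present <- vapply(samples, function(s) any(m[i, rep_of[[s]]] > 0),
                      logical(1))
    as.integer(round_half_away(100 * sum(present) / length(samples)))
  }, integer(1))
  stats::setNames(out, features$feature_id)
}

#' Validation report for several annotation engines
#'
#' Computes the confusion counts and metrics per engine and mode, mirroring
#' the standard layout of workflow-validation tables (rows TPR, precision,
#' F1; one column per engine and polarity).
#'
#' @param predictions Named list: engine -> data.frame(`feature_id`,
#'   `structure_id`).
#' @param truth Ground-truth data.frame (`feature_id`, `structure_id`).
#' @return data.frame with one row per engine: `engine`, `tp`, `fp`, `fn`,
#'   `tpr`, `precision`, `f1` (2 dp report values).
#' @export
validation_report <- function(predictions, truth) {
  rows <- lapply(names(predictions), function(eng) {
    cc <- score_annotations(predictions[[eng]], truth)
    m <- compute_metrics(cc)
    data.frame(engine = eng, tp = cc$tp, fp = cc$fp, fn = cc$fn,
               tpr = m$report[["tpr"]], precision = m$report[["precision"]],
               f1 = m$report[["f1"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
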