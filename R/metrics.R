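# Overlap metrics used to evaluate zonal segmentations: Dice, positive
# predictive value and sensitivity, computed from pooled pixel counts, plus
# the per-volume aggregation that turns slice predictions into a report.

check_binary_pair <- function(pred, truth) {
  if (!all(dim(pred) %||% length(pred) == (dim(truth) %||% length(truth))))
    stop("`pred` and `truth` must have identical shapes", call. = FALSE)
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("masks must be binary (0/1)", call. = FALSE)
}

#' Dice overlap coefficient
#'
#' `2 * |pred & truth| / (|pred| + |truth|)`, in `[0, 1]`; two empty masks are
#' defined to agree perfectly (Dice 1).
#'
#' @param pred,truth Binary arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  check_binary_pair(pred, truth)
  np <- sum(pred); nt <- sum(truth)
  if (np + nt == 0) return(1)
  2 * sum(pred * truth) / (np + nt)
}

#' Positive predictive value (precision)
#'
#' `|pred & truth| / |pred|`; an empty prediction scores 1 if the truth is
#' also empty, else 0.
#'
#' @inheritParams dice_coefficient
#' @return Scalar in `[0, 1]`.
#' @export
ppv <- function(pred, truth) {
  check_binary_pair(pred, truth)
  np <- sum(pred)
  if (np == 0) return(if (sum(truth) == 0) 1 else 0)
  sum(pred * truth) / np
}

#' Sensitivity (recall)
#'
#' `|pred & truth| / |truth|`; an empty truth scores 1 if the prediction is
#' also empty, else 0.
#'
#' @inheritParams dice_coefficient
#' @return Scalar in `[0, 1]`.
#' @export
sensitivity <- function(pred, truth) {
  check_binary_pair(pred, truth)
  nt <- sum(truth)
  if (nt == 0) return(if (sum(pred) == 0) 1 else 0)
  sum(pred * truth) / nt
}

#' Per-volume segmentation metrics
#'
#' Pools pixel counts over all slices of one volume and computes Dice, PPV
#' and sensitivity once per class, so slices where a zone is absent do not
#' distort the average.
#'
#' @param pred,truth 4-D binary arrays `(H, W, K, S)` (class channel 3, slice
#'   axis 4), or 3-D `(H, W, K)` for a single slice.
#' @param classes Optional class names (default `"PZ"`, `"TZ"` for K = 2).
#' @param volume_id Identifier recorded in the report.
#' @return Data frame with one row per class: counts and the three metrics.
#' @export
evaluate_volume <- function(pred, truth, classes = NULL, volume_id = NA_character_) {
  if (length(dim(pred)) == 3L) dim(pred) <- c(dim(pred), 1L)
  if (length(dim(truth)) == 3L) dim(truth) <- c(dim(truth), 1L)
  if (!all(dim(pred) == dim(truth)))
    stop("prediction and truth volumes must have identical dimensions", call. = FALSE)
  K <- dim(pred)[3]
  if (is.null(classes))
    classes <- if (K == 2L) c("PZ", "TZ") else paste0("class", seq_len(K))
  rows <- lapply(seq_len(K), function(k) {
    p <- pred[, , k, , drop = FALSE]
    t <- truth[, , k, , drop = FALSE]
    check_binary_pair(p, t)
    np <- sum(p); nt <- sum(t); ov <- sum(p * t)
    data.frame(volume_id = volume_id, class = classes[k],
               n_pred = np, n_true = nt, n_overlap = ov,
               dice = if (np + nt == 0) 1 else 2 * ov / (np + nt),
               ppv = if (np == 0) (if (nt == 0) 1 else 0) else ov / np,
               sensitivity = if (nt == 0) (if (np == 0) 1 else 0) else ov / nt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize a metrics report over volumes
#'
#' @param report Data frame from [evaluate_volume()] rows (possibly several
#'   volumes bound together).
#' @return Data frame with the per-class mean of each metric over volumes.
#' @export
summarize_metrics <- function(report) {
  agg <- stats::aggregate(report[c("dice", "ppv", "sensitivity")],
                          by = list(class = report$class), FUN = mean)
  agg[order(agg$class), , drop = FALSE]
}

#' Write a metrics report to CSV and a JSON summary
#'
#' @param report Data frame of per-volume, per-class metrics.
#' @param csv_path Path for the per-volume CSV.
#' @param json_path Optional path for a JSON file of dataset means.
#' @return `report`, invisibly.
#' @export
write_metrics_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(report, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    s <- summarize_metrics(report)
    out <- lapply(seq_len(nrow(s)), function(i)
      list(dice = s$dice[i], ppv = s$ppv[i], sensitivity = s$sensitivity[i]))
    names(out) <- s$class
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
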