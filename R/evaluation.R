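#' Micro-averaged confusion metrics at a decision threshold
#'
#' Pools every (sample, tooth) decision into one confusion table —
#' micro-averaging, the only aggregation that keeps the confusion counts
#' well-defined across teeth of different prevalence — thresholding scores
#' at `score >= threshold`, and reports the tooth-level metric suite:
#' AUROC, F1 (harmonic mean of PPV and sensitivity), sensitivity,
#' specificity, PPV and NPV. Ratios with zero denominators are reported as
#' `NA` (absent), never as 0.
#'
#' @param scores Numeric vector/matrix of scores in `[0, 1]`.
#' @param labels Binary vector/matrix of the same length.
#' @param threshold Decision threshold in `[0, 1]` (default 0.5).
#' @return A one-row tibble: `auroc`, `f1`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `tp`, `fp`, `tn`, `fn`, `threshold`. AUROC is `NA` when
#'   only one class is present.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  s <- as.numeric(scores); y <- as.numeric(labels)
  if (length(s) != length(y)) stop("scores and labels must have equal length")
  if (!all(y %in% c(0, 1))) stop("labels must be binary (0/1)")
  pred <- s >= threshold
  tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
  tn <- sum(!pred & y == 0); fn <- sum(!pred & y == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  f1 <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  auc <- if (length(unique(y)) == 2L) auroc(s, y) else NA_real_
  tibble::tibble(auroc = auc, f1 = f1, sensitivity = sens,
                 specificity = spec, ppv = ppv, npv = npv,
                 tp = tp, fp = fp, tn = tn, fn = fn, threshold = threshold)
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' The probability that a uniformly drawn positive outscores a uniformly
#' drawn negative, ties counting one half — computed from rank sums, so it
#' is exact and invariant to strictly increasing score transforms.
#'
#' @inheritParams confusion_metrics
#' @return Scalar in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  s <- as.numeric(scores); y <- as.numeric(labels)
  if (length(s) != length(y)) stop("scores and labels must have equal length")
  if (!all(y %in% c(0, 1))) stop("labels must be binary (0/1)")
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0L || nneg == 0L)
    stop("AUROC needs both classes present (got ", npos, " positives, ",
         nneg, " negatives)")
  r <- rank(s)
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Select a decision threshold on validation data
#'
#' Sweeps the grid of observed unique validation scores plus `{0, 1}` and
#' picks the operating point for the requested mode:
#' * `balanced`: the threshold maximising validation F1;
#' * `high_sensitivity`: the threshold whose validation specificity is
#'   nearest the worst (minimum) clinician specificity;
#' * `high_specificity`: the threshold whose validation sensitivity is
#'   nearest the worst (minimum) clinician sensitivity.
#'
#' Ties are broken toward the higher threshold (the more conservative
#' positive call). Thresholds must be chosen on validation data, never on
#' the test set. The two clinician-referenced modes require
#' `clinician_stats`.
#'
#' @param val_scores,val_labels Validation score/label pool (both classes
#'   must be present).
#' @param mode `"balanced"`, `"high_sensitivity"` or `"high_specificity"`.
#' @param clinician_stats Data frame with `sensitivity` and `specificity`
#'   columns, one row per clinician (e.g. from [clinician_performance()]).
#' @return An `operating_point` object: `mode`, `threshold`, `reference`
#'   (the clinician value targeted, or `NA`), and the validation `metrics`
#'   row achieved at the selected threshold.
#' @export
select_operating_point <- function(val_scores, val_labels,
                                   mode = c("balanced", "high_sensitivity",
                                            "high_specificity"),
                                   clinician_stats = NULL) {
  mode <- match.arg(mode)
  s <- as.numeric(val_scores); y <- as.numeric(val_labels)
  if (length(unique(y)) != 2L)
    stop("validation pool must contain both classes")
  grid <- sort(unique(c(0, 1, s)))
  sweep <- dplyr::bind_rows(lapply(grid, function(t)
    confusion_metrics(s, y, t)))
  reference <- NA_real_
  if (mode == "balanced") {
    obj <- ifelse(is.na(sweep$f1), -Inf, sweep$f1)
    best <- max(obj)
    pick <- max(which(obj == best))
  } else {
    if (is.null(clinician_stats))
      stop("clinician_stats is required for mode ", mode)
    if (mode == "high_sensitivity") {
      reference <- min(clinician_stats$specificity, na.rm = TRUE)
      gap <- abs(sweep$specificity - reference)
    } else {
      reference <- min(clinician_stats$sensitivity, na.rm = TRUE)
      gap <- abs(sweep$sensitivity - reference)
    }
    gap[is.na(gap)] <- Inf
    pick <- max(which(gap == min(gap)))
  }
  structure(list(mode = mode, threshold = grid[pick], reference = reference,
                 metrics = sweep[pick, ]),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat("Operating point [", x$mode, "]: threshold ",
      sprintf("%.4f", x$threshold), sep = "")
  if (!is.na(x$reference))
    cat(" (worst-clinician reference ", sprintf("%.3f", x$reference), ")",
        sep = "")
  cat("\n  validation: F1 ", sprintf("%.3f", x$metrics$f1),
      ", sens ", sprintf("%.3f", x$metrics$sensitivity),
      ", spec ", sprintf("%.3f", x$metrics$specificity), "\n", sep = "")
  invisible(x)
}

#' @export
glance.operating_point <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(mode = x$mode, threshold = x$threshold,
                                  reference = x$reference),
                   x$metrics[, c("f1", "sensitivity", "specificity")])
}

#' Per-clinician performance against the majority-vote reference
#'
#' Scores each annotator's binary tooth decisions against the aggregated
#' reference standard (majority vote of all annotators), exactly how
#' clinician rows of a reader study table are computed.
#'
#' @param votes `L x M` binary matrix of pooled per-annotator decisions
#'   (rows = annotators), or a list of per-image `L x 32` matrices which is
#'   pooled by column-binding.
#' @param reference Binary vector of length `M`: the aggregated reference
#'   (e.g. [aggregate_tooth_labels()] pooled the same way).
#' @return Tibble with one metrics row per annotator plus an `annotator`
#'   column.
#' @export
clinician_performance <- function(votes, reference) {
  if (is.list(votes) && !is.matrix(votes)) votes <- do.call(cbind, votes)
  if (!is.matrix(votes)) stop("votes must be a matrix or list of matrices")
  reference <- as.numeric(reference)
  if (ncol(votes) != length(reference))
    stop("votes and reference disagree on the number of decisions")
  ann <- rownames(votes)
  if (is.null(ann)) ann <- as.character(seq_len(nrow(votes)))
  dplyr::bind_rows(lapply(seq_len(nrow(votes)), function(l)
    dplyr::bind_cols(tibble::tibble(annotator = ann[l]),
                     confusion_metrics(votes[l, ], reference, 0.5))))
}

#' Metrics pooled by tooth type
#'
#' Computes the micro-averaged metric suite within each tooth-type subset
#' (8 incisors, 4 canines, 8 premolars, 12 molars per radiograph) and over
#' all 32 teeth.
#'
#' @param scores,labels `N x 32` matrices in the fixed FDI slot order.
#' @param threshold Decision threshold (scalar, or an `operating_point`).
#' @return Tibble keyed by `tooth_type` in
#'   `c("incisor", "canine", "premolar", "molar", "all")`.
#' @export
per_tooth_type_report <- function(scores, labels, threshold = 0.5) {
  if (inherits(threshold, "operating_point")) threshold <- threshold$threshold
  scores <- rbind_vector(scores); labels <- rbind_vector(labels)
  if (ncol(scores) != 32L || ncol(labels) != 32L)
    stop("scores and labels must have 32 columns")
  ch <- fdi_chart()
  one <- function(type) {
    cols <- if (type == "all") 1:32 else ch$index[ch$type == type] + 1L
    dplyr::bind_cols(
      tibble::tibble(tooth_type = type, n_teeth = length(cols)),
      confusion_metrics(scores[, cols], labels[, cols], threshold))
  }
  dplyr::bind_rows(lapply(c("incisor", "canine", "premolar", "molar", "all"),
                          one))
}
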