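#' Aggregate per-annotator tooth labels by thresholded voting
#'
#' Each of `L` annotators marks every tooth as diseased (1) or healthy (0).
#' The reference label for tooth `j` is 1 when at least `c_r` annotators
#' voted 1. The default `c_r = 3` with five annotators is majority voting,
#' which is how the reference standard for periodontal bone loss is built.
#' Ties at exactly `c_r` votes count as positive.
#'
#' @param votes An `L x T` binary matrix (annotators in rows, teeth in
#'   columns) or a list of `L` equal-length binary vectors.
#' @param c_r Vote threshold, integer in `1..L`.
#' @return Integer 0/1 vector of length `T`.
#' @examples
#' votes <- rbind(c(1, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
#' aggregate_tooth_labels(votes)        # majority: c(1, 0)
#' aggregate_tooth_labels(votes, c_r = 1)
#' @export
aggregate_tooth_labels <- function(votes, c_r = 3L) {
  votes <- as_vote_matrix(votes)
  L <- nrow(votes)
  c_r <- as.integer(c_r)
  if (is.na(c_r) || c_r < 1L || c_r > L)
    stop("c_r must be an integer in 1..", L)
  as.integer(colSums(votes) >= c_r)
}

#' Aggregate per-annotator lesion masks by pixelwise vote threshold
#'
#' A pixel of the aggregated lesion mask is positive when at least `c_s`
#' annotator masks mark it. The default `c_s = 1` is the pixel union of all
#' masks, chosen to maximise recall of lesion pixels for segmentation
#' pre-training; `c_s = L` is the pixel intersection.
#'
#' @param masks A list of `L` binary matrices with identical dimensions, or
#'   an `H x W x L` array.
#' @param c_s Vote threshold, integer in `1..L`.
#' @return Binary integer matrix of the shared dimensions.
#' @export
aggregate_lesion_mask <- function(masks, c_s = 1L) {
  if (is.array(masks) && length(dim(masks)) == 3L)
    masks <- lapply(seq_len(dim(masks)[3]), function(l) masks[, , l])
  if (!is.list(masks) || length(masks) < 1L)
    stop("masks must be a non-empty list of binary matrices")
  d <- dim(masks[[1]])
  if (is.null(d)) stop("masks must be matrices")
  for (m in masks)
    if (!identical(dim(m), d))
      stop("all annotator masks must share one shape")
  L <- length(masks)
  c_s <- as.integer(c_s)
  if (is.na(c_s) || c_s < 1L || c_s > L)
    stop("c_s must be an integer in 1..", L)
  counts <- Reduce(`+`, lapply(masks, function(m) (m > 0) + 0L))
  out <- (counts >= c_s) + 0L
  dim(out) <- d
  out
}

as_vote_matrix <- function(votes) {
  if (is.list(votes)) {
    len <- unique(vapply(votes, length, 1L))
    if (length(len) != 1L)
      stop("all annotator label vectors must have equal length")
    votes <- do.call(rbind, votes)
  }
  if (!is.matrix(votes)) stop("votes must be a matrix or list of vectors")
  if (!all(votes %in% c(0, 1))) stop("votes must be binary (0/1)")
  votes
}

#' Per-jaw tooth-level co-occurrence matrices of periodontal bone loss
#'
#' Builds, separately for the upper (maxillary) and lower (mandibular) jaw,
#' the 16 x 16 matrix of joint occurrence frequencies
#' `C[j, j'] = #\{i : y[i, j] = 1 and y[i, j'] = 1\} / N` over `N` label
#' vectors. The diagonal is the per-tooth prevalence. Because the auxiliary
#' co-occurrence target is max-normalised, any positive rescaling of `C`
#' (counts, frequencies) yields the same target; the frequency scale is used
#' as the canonical one. Horizontally adjacent diseased teeth make the
#' off-diagonal band of these matrices prominent.
#'
#' @param labels `N x 32` binary matrix of tooth-label vectors (rows =
#'   radiographs, columns = the fixed FDI slot order), or a list of them.
#' @return An object of class `pbl_cooccurrence`: list with `upper` and
#'   `lower` 16 x 16 symmetric matrices (entries in `[0, 1]`) and `n`.
#' @export
build_cooccurrence <- function(labels) {
  if (is.list(labels) && !is.matrix(labels)) labels <- do.call(rbind, labels)
  if (!is.matrix(labels) || ncol(labels) != 32L)
    stop("labels must be an N x 32 binary matrix")
  if (nrow(labels) < 1L) stop("at least one label vector is required")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
  n <- nrow(labels)
  jaw <- function(idx0) {
    y <- labels[, idx0 + 1L, drop = FALSE]
    crossprod(y) / n
  }
  structure(list(upper = jaw(upper_indices()), lower = jaw(lower_indices()),
                 n = n),
            class = "pbl_cooccurrence")
}

#' @export
print.pbl_cooccurrence <- function(x, ...) {
  cat("Tooth co-occurrence matrices (joint frequency, n =", x$n, "images)\n")
  cat("  upper jaw: 16 x 16, mean prevalence",
      sprintf("%.3f", mean(diag(x$upper))), "\n")
  cat("  lower jaw: 16 x 16, mean prevalence",
      sprintf("%.3f", mean(diag(x$lower))), "\n")
  invisible(x)
}

#' @export
tidy.pbl_cooccurrence <- function(x, ...) {
  one <- function(m, jaw) {
    tibble::tibble(jaw = jaw,
                   tooth_a = rep(seq_len(16L), times = 16L),
                   tooth_b = rep(seq_len(16L), each = 16L),
                   cooccurrence = as.vector(m))
  }
  dplyr::bind_rows(one(x$upper, "upper"), one(x$lower, "lower"))
}

#' Auxiliary co-occurrence target vector
#'
#' For a within-jaw label vector `y` (length `k = 16`) and co-occurrence
#' matrix `C`, the auxiliary regression target is
#' `c_j = (1/Z) * sum_j' y_j' C[j, j']` with `Z = max_j` of the unnormalised
#' sums, so all entries lie in `[0, 1]` and the maximum is exactly 1 whenever
#' any tooth is positive. A lesion-free mouth (`y` all zero, `Z` would be 0)
#' yields the all-zero target by convention: the auxiliary target for a
#' healthy jaw is "no lesions anywhere". The target is invariant to positive
#' rescaling of `C`.
#'
#' @param y Binary vector of length `k`.
#' @param C `k x k` nonnegative co-occurrence matrix.
#' @return Numeric vector of length `k` in `[0, 1]`.
#' @export
cooccurrence_target <- function(y, C) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop("C must be a square matrix")
  if (length(y) != nrow(C)) stop("length(y) must match nrow(C)")
  if (any(C < 0)) stop("co-occurrence matrix entries must be nonnegative")
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)")
  ct <- as.vector(C %*% y)
  z <- max(ct)
  if (z <= 0) return(rep(0, length(y)))
  ct / z
}

#' Read and write the tooth-label CSV interchange format
#'
#' Long-format CSV with columns `image_id`, `annotator_id`, `fdi_tooth`
#' (two-digit FDI code, e.g. `"36"`) and `label` (0/1). `read_tooth_labels()`
#' returns a tibble; `tooth_label_matrix()` pivots one image's rows into the
#' `L x 32` vote matrix consumed by [aggregate_tooth_labels()]. Teeth absent
#' from the file are taken as label 0.
#'
#' @param path CSV file path.
#' @return `read_tooth_labels()`: tibble of the raw rows.
#' @export
read_tooth_labels <- function(path) {
  df <- utils::read.csv(path, colClasses = c(fdi_tooth = "character"))
  need <- c("image_id", "annotator_id", "fdi_tooth", "label")
  if (!all(need %in% names(df)))
    stop("label CSV must have columns ", paste(need, collapse = ", "))
  tibble::as_tibble(df)
}

#' @rdname read_tooth_labels
#' @param labels Tibble as returned by `read_tooth_labels()`.
#' @param image One `image_id`.
#' @return `tooth_label_matrix()`: `L x 32` binary matrix, rows named by
#'   annotator, columns in the fixed FDI slot order.
#' @export
tooth_label_matrix <- function(labels, image) {
  sub <- labels[labels$image_id == image, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for image_id ", image)
  annot <- sort(unique(sub$annotator_id))
  q <- as.integer(substr(sub$fdi_tooth, 1, 1))
  p <- as.integer(substr(sub$fdi_tooth, 2, 2))
  slot <- fdi_to_index(q, p) + 1L
  m <- matrix(0L, nrow = length(annot), ncol = 32L,
              dimnames = list(annot, fdi_chart()$code))
  m[cbind(match(sub$annotator_id, annot), slot)] <- as.integer(sub$label)
  m
}

#' @rdname read_tooth_labels
#' @param votes_by_image Named list of `L x 32` matrices keyed by image id.
#' @export
write_tooth_labels <- function(votes_by_image, path) {
  codes <- fdi_chart()$code
  rows <- purrr::imap(votes_by_image, function(m, img) {
    ann <- rownames(m)
    if (is.null(ann)) ann <- as.character(seq_len(nrow(m)))
    tibble::tibble(image_id = img,
                   annotator_id = rep(ann, times = 32L),
                   fdi_tooth = rep(codes, each = nrow(m)),
                   label = as.integer(m))
  })
  df <- dplyr::bind_rows(rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
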