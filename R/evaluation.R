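# Region rasterization and overlap metrics.

#' Rasterize a closed contour to a binary mask
#'
#' Even-odd (crossing-number) rasterization: a pixel is inside when a
#' horizontal ray from its center crosses the closed polygon an odd number
#' of times.  Pixel centers sit at integer `(x, y) = (col - 1, row - 1)`
#' coordinates.  The rule is orientation-invariant and deterministic for
#' self-intersecting polygons; the same convention generates the ground-truth
#' masks of the synthetic fixtures, so self-comparison is exact.
#'
#' @param contour An `n x 2` matrix of `(x, y)` points (closed implicitly).
#' @param shape Integer `c(H, W)` mask shape.
#' @return A logical `H x W` matrix.
#' @examples
#' sq <- cbind(c(-0.5, 9.5, 9.5, -0.5), c(-0.5, -0.5, 9.5, 9.5))
#' sum(contour_to_mask(sq, c(16, 16)))  # 100 pixels
#' @export
contour_to_mask <- function(contour, shape) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  xs <- 0:(W - 1L)
  yc <- 0:(H - 1L)
  counts <- matrix(0L, H, W)
  n <- nrow(contour)
  x1 <- contour[, 1]; y1 <- contour[, 2]
  nxt <- c(seq_len(n)[-1L], 1L)
  x2 <- x1[nxt]; y2 <- y1[nxt]
  for (i in seq_len(n)) {
    if (y1[i] == y2[i]) next
    rows <- which((y1[i] > yc) != (y2[i] > yc))
    if (length(rows) == 0L) next
    xint <- x1[i] + (yc[rows] - y1[i]) * (x2[i] - x1[i]) / (y2[i] - y1[i])
    counts[rows, ] <- counts[rows, ] + outer(xint, xs, ">")
  }
  mask <- counts %% 2L == 1L
  if (!any(mask)) warning("contour encloses no pixel centers", call. = FALSE)
  mask
}

#' Precision, recall and F1 of two binary masks
#'
#' Pixel-level contingency metrics: `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`, and `f1` their harmonic mean (identical to the
#' Dice coefficient of the two masks).  Conventions: if both masks are empty
#' all three scores are 1 (a degenerate no-object case counted as correct);
#' if exactly one is empty, all three are 0.
#'
#' @param pred Predicted logical mask.
#' @param gt Ground-truth logical mask, same shape.
#' @return List of class `score_triple`: `precision`, `recall`, `f1`.
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
#' precision_recall_f1(a, a)
#' @export
precision_recall_f1 <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("mask shapes differ", call. = FALSE)
  pred <- as.logical(pred); gt <- as.logical(gt)
  tp <- sum(pred & gt)
  np <- sum(pred); ng <- sum(gt)
  if (np == 0L && ng == 0L) {
    out <- list(precision = 1, recall = 1, f1 = 1)
  } else if (np == 0L || ng == 0L) {
    out <- list(precision = 0, recall = 0, f1 = 0)
  } else {
    precision <- tp / np
    recall <- tp / ng
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    out <- list(precision = precision, recall = recall, f1 = f1)
  }
  structure(out, class = "score_triple")
}

#' @export
print.score_triple <- function(x, ...) {
  cat(sprintf("precision = %.4f, recall = %.4f, F1 = %.4f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}
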