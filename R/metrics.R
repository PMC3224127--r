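#' Voxelwise confusion counts
#'
#' Tallies true/false positives/negatives of a test mask against a truth
#' mask within an evaluation region (default: the whole grid). Restricting
#' the region to the tube mask avoids inflating accuracy with the trivially
#' agreeing exterior background.
#'
#' @param test,truth [binary_mask()] objects on a common grid.
#' @param region optional [binary_mask()] delimiting the evaluation region.
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
confusion <- function(test, truth, region = NULL) {
  if (!same_grid(test, truth)) stop("test and truth grids differ")
  sel <- if (is.null(region)) TRUE else {
    if (!same_grid(test, region)) stop("region grid differs")
    region$values == 1L
  }
  a <- test$values[sel]
  b <- truth$values[sel]
  out <- list(tp = sum(a == 1L & b == 1L), fp = sum(a == 1L & b == 0L),
              fn = sum(a == 0L & b == 1L), tn = sum(a == 0L & b == 0L))
  out$n <- out$tp + out$fp + out$fn + out$tn
  structure(out, class = "confusion_counts")
}

#' Segmentation agreement scores
#'
#' `kappa_score()` is Cohen's kappa `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (tp + tn) / n` and chance agreement `p_e` from the
#' marginals. `specificity_score()` is `tn / (tn + fp)` and
#' `accuracy_score()` is `(tp + tn) / n`. `dice_score()` is the overlap
#' `2 |A n B| / (|A| + |B|)` of two masks (1 when identical, and defined as
#' 1 when both masks are empty).
#'
#' @param counts a [confusion()] result.
#' @return A numeric score.
#' @export
kappa_score <- function(counts) {
  n <- counts$n
  p_o <- (counts$tp + counts$tn) / n
  p_yes <- ((counts$tp + counts$fp) / n) * ((counts$tp + counts$fn) / n)
  p_no <- ((counts$fn + counts$tn) / n) * ((counts$fp + counts$tn) / n)
  p_e <- p_yes + p_no
  if (1 - p_e == 0)
    stop("kappa undefined: both raters are constant")
  (p_o - p_e) / (1 - p_e)
}

#' @rdname kappa_score
#' @export
specificity_score <- function(counts) {
  if (counts$tn + counts$fp == 0)
    stop("specificity undefined: no true-negative or false-positive voxels")
  counts$tn / (counts$tn + counts$fp)
}

#' @rdname kappa_score
#' @export
accuracy_score <- function(counts) (counts$tp + counts$tn) / counts$n

#' @rdname kappa_score
#' @param a,b [binary_mask()] objects on a common grid.
#' @export
dice_score <- function(a, b) {
  if (!same_grid(a, b)) stop("mask grids differ")
  sa <- sum(a$values)
  sb <- sum(b$values)
  if (sa + sb == 0) return(1)
  2 * sum(a$values == 1L & b$values == 1L) / (sa + sb)
}

#' Evaluate segmentation masks against ground truth
#'
#' Pairs each test mask with the truth mask of the same index and reports
#' kappa, specificity, accuracy and Dice per object together with their
#' mean and standard deviation, in the shape of a validation table.
#'
#' @param tests,truths lists of [binary_mask()] objects (same length).
#' @param region optional evaluation region mask (e.g. the tube mask).
#' @return A data frame with one row per object plus attributes `mean` and
#'   `sd` (named numeric vectors over the four scores).
#' @export
evaluate_masks <- function(tests, truths, region = NULL) {
  if (length(tests) != length(truths))
    stop("test and truth lists differ in length")
  rows <- lapply(seq_along(tests), function(i) {
    cc <- confusion(tests[[i]], truths[[i]], region)
    data.frame(object = i, kappa = kappa_score(cc),
               specificity = specificity_score(cc),
               accuracy = accuracy_score(cc),
               dice = dice_score(tests[[i]], truths[[i]]))
  })
  out <- do.call(rbind, rows)
  scores <- out[, c("kappa", "specificity", "accuracy", "dice")]
  attr(out, "mean") <- colMeans(scores)
  attr(out, "sd") <- apply(scores, 2L, stats::sd)
  out
}
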