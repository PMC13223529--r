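#' Dice coefficient between two binary masks
#'
#' `2|A ∩ B| / (|A| + |B|)`, with the convention that two empty masks score
#' 1 (nothing to segment, nothing segmented).
#'
#' @param pred,true Binary masks (logical or 0/1) of identical shape.
#' @return Numeric in `[0, 1]`.
#' @examples
#' dice_coefficient(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2))
#' @export
dice_coefficient <- function(pred, true) {
  if (!identical(dim(pred), dim(true)) || length(pred) != length(true))
    stop("mask shapes differ: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(true), collapse = "x"))
  a <- sum(pred != 0); b <- sum(true != 0)
  if (a + b == 0) return(1)
  2 * sum(pred != 0 & true != 0) / (a + b)
}

## class codes for the multi-class brain-tumor task
BRATS_CLASSES <- c(background = 0L, ET = 1L, ED = 2L, NET = 3L)

#' Map a 4-class brain-tumor label map to nested sub-regions
#'
#' From labels background/ET/ED/NET (coded 0/1/2/3) derives the three nested
#' evaluation regions: whole tumor `WT = ET ∪ ED ∪ NET`, tumor core
#' `TC = ET ∪ NET`, and enhancing tumor `ET`. By construction
#' `ET ⊆ TC ⊆ WT`.
#'
#' @param label Integer array with values in 0..3.
#' @return Object of class `"region_set"`: list of logical masks `wt`, `tc`,
#'   `et` with the label's shape.
#' @export
map_nested_regions <- function(label) {
  if (any(!label %in% BRATS_CLASSES))
    stop("unknown label value(s): ",
         paste(unique(label[!label %in% BRATS_CLASSES]), collapse = ", "),
         " (expected 0=background, 1=ET, 2=ED, 3=NET)")
  keep_dim <- function(m) { dim(m) <- dim(label); m }
  structure(list(wt = keep_dim(label %in% c(1L, 2L, 3L)),
                 tc = keep_dim(label %in% c(1L, 3L)),
                 et = keep_dim(label == 1L)),
            class = "region_set")
}

#' Nested sub-region Dice evaluation for the brain-tumor task
#'
#' Computes the per-slice Dice coefficient for each nested region (WT, TC,
#' ET), averages each region arithmetically over the slices, and reports the
#' mean of the three region averages.
#'
#' @param pred_labels,true_labels Integer label arrays `c(H, W)` or
#'   `c(H, W, slices)` with values in 0..3.
#' @return Named numeric vector `c(mean, wt, tc, et)`.
#' @export
evaluate_brats <- function(pred_labels, true_labels) {
  if (!identical(dim(pred_labels), dim(true_labels)))
    stop("prediction and truth shapes differ")
  if (length(dim(pred_labels)) == 2L) {
    dim(pred_labels) <- c(dim(pred_labels), 1L)
    dim(true_labels) <- c(dim(true_labels), 1L)
  }
  ns <- dim(pred_labels)[3]
  per <- sapply(seq_len(ns), function(s) {
    rp <- map_nested_regions(pred_labels[, , s])
    rt <- map_nested_regions(true_labels[, , s])
    c(wt = dice_coefficient(rp$wt, rt$wt),
      tc = dice_coefficient(rp$tc, rt$tc),
      et = dice_coefficient(rp$et, rt$et))
  })
  avg <- rowMeans(per)
  c(mean = mean(avg), avg)
}

#' Per-slice binary Dice for a batch of predictions
#'
#' Foreground Dice (label != 0) per slice, plus the arithmetic mean.
#' @param pred_labels,true_labels Integer label arrays `c(H, W, slices)`.
#' @return List with `per_slice` numeric vector and `mean`.
#' @export
evaluate_binary <- function(pred_labels, true_labels) {
  if (!identical(dim(pred_labels), dim(true_labels)))
    stop("prediction and truth shapes differ")
  if (length(dim(pred_labels)) == 2L) {
    dim(pred_labels) <- c(dim(pred_labels), 1L)
    dim(true_labels) <- c(dim(true_labels), 1L)
  }
  per <- vapply(seq_len(dim(pred_labels)[3]), function(s)
    dice_coefficient(pred_labels[, , s] != 0, true_labels[, , s] != 0), 0)
  list(per_slice = per, mean = mean(per))
}
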