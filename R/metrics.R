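# Overlap and agreement metrics: Dice score and Bland-Altman analysis.

#' Voxel confusion counts between a predicted and a reference mask
#'
#' @param prediction,truth binary arrays of identical shape
#' @return object of class `confusion_counts`: `TP`, `FP`, `FN`
#' @export
confusion_counts <- function(prediction, truth) {
  if (!identical(dim(prediction), dim(truth)) ||
      length(prediction) != length(truth))
    stop("prediction and truth must share a shape")
  if (!is_binary_array(prediction) || !is_binary_array(truth))
    stop("masks must be binary")
  tp <- sum(prediction == 1 & truth == 1)
  structure(list(TP = tp,
                 FP = sum(prediction) - tp,
                 FN = sum(truth) - tp),
            class = "confusion_counts")
}

#' Dice score coefficient
#'
#' `DSC = 2 TP / (FP + 2 TP + FN)`, the F1 score on voxels.  Undefined
#' (error) when all counts are zero, i.e. both masks empty — an empty-vs-
#' empty comparison is reported as an error rather than a silent 1.0.
#'
#' @param counts a [confusion_counts()], or a binary prediction array when
#'   `truth` is supplied
#' @param truth optional binary reference mask
#' @return Dice score in [0, 1]
#' @export
dsc <- function(counts, truth = NULL) {
  if (!is.null(truth)) counts <- confusion_counts(counts, truth)
  stopifnot(inherits(counts, "confusion_counts"))
  denom <- counts$FP + 2 * counts$TP + counts$FN
  if (denom == 0)
    stop("DSC undefined: prediction and truth are both empty")
  2 * counts$TP / denom
}

#' Bland-Altman agreement summary
#'
#' Per pair, the percent difference is `100 * (auto - manual) /
#' mean(auto, manual)` (pairwise-mean denominator); the bias is the mean
#' percent difference and the 95% limits of agreement are
#' `bias +/- 1.96 * SD`.
#'
#' @param auto,manual positive paired volumes (ml), length >= 2; `auto`
#'   may also be a 2-column matrix/data.frame of pairs
#' @return object of class `bland_altman`: `bias`, `loa_lower`,
#'   `loa_upper`, `sd`, `n`, `pct_diff`
#' @export
bland_altman <- function(auto, manual = NULL) {
  if (is.null(manual)) {
    stopifnot(ncol(auto) == 2L)
    manual <- auto[, 2]; auto <- auto[, 1]
  }
  auto <- as.numeric(auto); manual <- as.numeric(manual)
  if (length(auto) != length(manual)) stop("pairs must have equal length")
  if (length(auto) < 2L) stop("need at least two pairs")
  if (any(auto <= 0) || any(manual <= 0)) stop("volumes must be positive")
  pct <- 100 * (auto - manual) / ((auto + manual) / 2)
  bias <- mean(pct); s <- sd(pct)
  structure(list(bias = bias,
                 loa_lower = bias - 1.96 * s,
                 loa_upper = bias + 1.96 * s,
                 sd = s, n = length(pct), pct_diff = pct),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n=%d  bias %.2f%%  95%% limits of agreement [%.2f%%, %.2f%%]\n",
    x$n, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x a [bland_altman()] result
#' @param auto,manual the paired volumes used to build it
#' @param ... passed to [plot()]
#' @export
plot_bland_altman <- function(x, auto, manual, ...) {
  means <- (auto + manual) / 2
  plot(means, x$pct_diff, xlab = "mean of methods (ml)",
       ylab = "percent difference (%)", pch = 16, ...)
  abline(h = c(x$bias, x$loa_lower, x$loa_upper), lty = c(2, 3, 3))
}
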