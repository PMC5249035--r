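# Segmentation evaluation: boundary recall and under-segmentation error for
# superpixel quality, Dice-based scores for final segmentations.

.contingency <- function(pred, gt) {
  # overlap counts between compacted gt and pred labels
  pv <- as.vector(pred)
  gv <- as.vector(gt)
  pu <- sort(unique(pv))
  gu <- sort(unique(gv))
  pidx <- match(pv, pu)
  gidx <- match(gv, gu)
  cnt <- tabulate((gidx - 1L) * length(pu) + pidx, length(pu) * length(gu))
  list(cnt = matrix(cnt, length(pu), length(gu)),
       pred_ids = pu, gt_ids = gu,
       pred_sizes = tabulate(pidx, length(pu)),
       gt_sizes = tabulate(gidx, length(gu)))
}

#' Boundary recall of a predicted label map
#'
#' Fraction of ground-truth boundary pixels lying within Chebyshev distance
#' \code{d} of at least one predicted boundary pixel.  Boundary pixels are
#' pixels with a 4-neighbor of a different label; the image border is not a
#' boundary by itself.
#'
#' @param pred,gt \linkS4class{LabelMap}s of the same shape.
#' @param d tolerance in pixels (default 2, the standard benchmark value).
#' @return recall in [0, 1].
#' @export
boundaryRecall <- function(pred, gt, d = 2) {
  stopifnot(all(dim(pred@labels) == dim(gt@labels)), d >= 0)
  gtB <- cpp_boundary_mask(gt@labels)
  if (!any(gtB)) stop("no ground-truth edges")
  predB <- cpp_boundary_mask(pred@labels)
  if (d > 0 && any(predB)) {
    kern <- EBImage::makeBrush(2 * d + 1, shape = "box")
    predB <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(predB * 1), kern)) > 0
  }
  sum(gtB & predB) / sum(gtB)
}

#' Under-segmentation error
#'
#' Measures how much predicted regions flood across ground-truth borders.
#' The default is the corrected benchmark formulation
#' \deqn{USE = \frac{1}{N} \sum_g \sum_{s : s \cap g \neq \emptyset}
#'   \min(|s \cap g|, |s \setminus g|),}
#' which does not over-penalize large superpixels; \code{variant =
#' "flood"} gives the older \eqn{(\sum_{s} |s|) - |g|} form for
#' cross-comparison.
#'
#' @param pred,gt \linkS4class{LabelMap}s of the same shape.
#' @param variant "min" (default) or "flood".
#' @return error >= 0 (0 for a perfect coarsening; lower is better).
#' @export
underSegmentationError <- function(pred, gt, variant = c("min", "flood")) {
  variant <- match.arg(variant)
  stopifnot(all(dim(pred@labels) == dim(gt@labels)))
  ct <- .contingency(pred@labels, gt@labels)
  N <- length(pred@labels)
  if (variant == "min") {
    inside <- ct$cnt
    outside <- ct$pred_sizes - ct$cnt
    sum(pmin(inside, outside)[inside > 0]) / N
  } else {
    tot <- sum(vapply(seq_along(ct$gt_ids), function(g) {
      s <- ct$cnt[, g]
      sum(ct$pred_sizes[s > 0]) - ct$gt_sizes[g]
    }, numeric(1)))
    tot / N
  }
}

#' Dice similarity coefficient of two pixel sets
#'
#' \eqn{DSC = 2|X \cap Y| / (|X| + |Y|)}.  Two empty sets score 1
#' (degenerate agreement).
#'
#' @param X,Y logical masks over the same image domain.
#' @return DSC in [0, 1].
#' @export
diceCoefficient <- function(X, Y) {
  stopifnot(all(dim(X) == dim(Y)))
  nx <- sum(X)
  ny <- sum(Y)
  if (nx + ny == 0) return(1)
  2 * sum(X & Y) / (nx + ny)
}

#' Median Dice coefficient over ground-truth segments
#'
#' Every ground-truth segment \eqn{g_i} is matched to the predicted segment
#' with the largest overlap (ties: lowest predicted label) and scored with
#' the Dice coefficient; medDSC is the median of those scores.  Segments
#' with DSC > 0.70 are flagged as good, the conventional quality cutoff.
#'
#' @param pred,gt \linkS4class{LabelMap}s of the same shape.
#' @return list with \code{medDSC} and \code{table} (gt_label, matched
#'   pred label, overlap, dsc, good).
#' @export
medianDice <- function(pred, gt) {
  stopifnot(all(dim(pred@labels) == dim(gt@labels)))
  ct <- .contingency(pred@labels, gt@labels)
  ng <- length(ct$gt_ids)
  if (ng < 1) stop("ground truth has no segments")
  tab <- lapply(seq_len(ng), function(g) {
    f <- which.max(ct$cnt[, g])  # first max = lowest pred id (ids sorted)
    ov <- ct$cnt[f, g]
    dsc <- 2 * ov / (ct$gt_sizes[g] + ct$pred_sizes[f])
    data.frame(gt_label = ct$gt_ids[g], pred_label = ct$pred_ids[f],
               overlap = ov, dsc = dsc)
  })
  tab <- do.call(rbind, tab)
  tab$good <- tab$dsc > 0.70
  list(medDSC = stats::median(tab$dsc), table = tab)
}

#' Fraction of ground-truth segments with DSC >= X/100
#'
#' @param per_segment the table from \code{\link{medianDice}}, or a numeric
#'   vector of per-segment DSC values.
#' @param X quality level between 0 and 100 (e.g. 75).
#' @return fraction in [0, 1].
#' @export
dscAtX <- function(per_segment, X) {
  v <- if (is.data.frame(per_segment)) per_segment$dsc else per_segment
  if (length(v) == 0) stop("empty per-segment table")
  mean(v >= X / 100)
}

#' Full evaluation report for a segmentation
#'
#' @param pred predicted \linkS4class{LabelMap}.
#' @param gt ground-truth \linkS4class{LabelMap}.
#' @param d boundary-recall tolerance in pixels.
#' @param X_grid levels at which to tabulate DSC_X.
#' @param K_used number of superpixels used upstream (recorded only).
#' @param runtime_s wall time of the producing run (recorded only).
#' @return list of class \code{EvalReport}: boundary_recall,
#'   under_seg_error, dsc_per_segment, medDSC, dsc_x, K_used, runtime_s.
#' @export
evaluateSegmentation <- function(pred, gt, d = 2,
                                 X_grid = c(50, 60, 70, 75, 80, 90),
                                 K_used = NA_integer_, runtime_s = NA_real_) {
  md <- medianDice(pred, gt)
  dx <- vapply(X_grid, function(X) dscAtX(md$table, X), numeric(1))
  names(dx) <- paste0("DSC_", X_grid)
  rep <- list(boundary_recall = boundaryRecall(pred, gt, d),
              under_seg_error = underSegmentationError(pred, gt),
              dsc_per_segment = md$table,
              medDSC = md$medDSC,
              dsc_x = dx,
              K_used = K_used,
              runtime_s = runtime_s)
  class(rep) <- "EvalReport"
  rep
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: boundary recall %.3f | under-seg error %.4f | medDSC %.3f\n",
              x$boundary_recall, x$under_seg_error, x$medDSC))
  cat(sprintf("  good segments (DSC > 0.70): %d / %d\n",
              sum(x$dsc_per_segment$good), nrow(x$dsc_per_segment)))
  cat("  DSC_X:", paste(sprintf("%s=%.2f", names(x$dsc_x), x$dsc_x),
                        collapse = " "), "\n")
  invisible(x)
}

#' Serialize an EvalReport to JSON (and optionally the DSC table to CSV)
#' @param report an EvalReport.
#' @param json_path output JSON file.
#' @param csv_path optional CSV for the per-segment table.
#' @return invisibly, the JSON path.
#' @export
exportReport <- function(report, json_path, csv_path = NULL) {
  x <- unclass(report)
  x$dsc_per_segment <- NULL
  jsonlite::write_json(x, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path))
    utils::write.csv(report$dsc_per_segment, csv_path, row.names = FALSE)
  invisible(json_path)
}
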