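# End-to-end orchestration: preprocess -> nuclei -> edge map -> SLIC-MMED
# -> superpixel merging -> optional scripted refinement -> combine with
# nuclei, with optional evaluation against ground truth.

#' Pipeline configuration with documented defaults
#'
#' All tunable parameters of the framework in one list.  Compactness,
#' edge weight and iteration count default to the standard values m = 20,
#' alpha = 20, 10 sweeps.
#'
#' @param lo_pct,hi_pct normalization percentiles (plain min-max by
#'   default).
#' @param denoise_radius median-filter radius; 0 disables denoising.
#' @param nuclei nuclei parameters: threshold, min_area, max_area,
#'   min_solidity, opening_radius.
#' @param edge_sigma,edge_norm_pct edge-detector parameters.
#' @param K,m,alpha,iterations superpixel parameters.
#' @param edgeAware FALSE runs the plain SLIC distance.
#' @param thres_dC,thres_edge,thres_size,thres_bg,bins merge thresholds.
#' @param refinement optional list of refinement actions (see
#'   \code{\link{applyRefinement}}).
#' @return list of class \code{RunConfig}.
#' @export
pipelineConfig <- function(lo_pct = 0, hi_pct = 1, denoise_radius = 0,
                           nuclei = list(threshold = "otsu", min_area = 30,
                                         max_area = 2000,
                                         min_solidity = 0.8,
                                         opening_radius = 1),
                           edge_sigma = 1.5, edge_norm_pct = 0.99,
                           K = 800, m = 20, alpha = 20, iterations = 10,
                           edgeAware = TRUE, thres_dC = 0.4,
                           thres_edge = 0.5, thres_size = 0.05,
                           thres_bg = 10, bins = 16, refinement = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

#' Replay scripted refinement actions
#'
#' Replays a recorded list of the two refinement operations: merging all
#' regions along a curve, and restoring the original superpixels around a
#' position.  Each action is a list with \code{op = "merge_path"} (fields
#' \code{path}: n x 2 (x, y) matrix) or \code{op = "restore"} (fields
#' \code{position}, \code{radius}).
#'
#' @param segments the merged \linkS4class{LabelMap}.
#' @param original the pre-merge superpixel \linkS4class{LabelMap}.
#' @param actions list of actions.
#' @return The refined \linkS4class{LabelMap}.
#' @export
applyRefinement <- function(segments, original, actions) {
  for (a in actions) {
    segments <- switch(a$op,
      merge_path = mergeAlongPath(segments, a$path),
      restore = restoreSuperpixels(segments, original, a$position,
                                   if (is.null(a$radius)) Inf else a$radius),
      stop("unknown refinement op: ", a$op))
  }
  segments
}

#' Construct a merge-path action that repairs the worst ground-truth region
#'
#' Scripted stand-in for the interactive "draw a curve" refinement: finds
#' the ground-truth segment with the lowest Dice score, collects the
#' predicted segments lying mostly inside it, and builds a polyline through
#' interior representative points of those segments.  Replaying the action
#' merges them, emulating what an annotator would draw.
#'
#' @param segments predicted \linkS4class{LabelMap}.
#' @param gt ground-truth \linkS4class{LabelMap}.
#' @param inside_frac minimum fraction of a predicted segment inside the
#'   target region for it to be merged (default 0.6).
#' @return a refinement action list, or NULL if nothing can be repaired.
#' @export
worstRegionAction <- function(segments, gt, inside_frac = 0.6) {
  md <- medianDice(segments, gt)
  tab <- md$table[order(md$table$dsc), , drop = FALSE]
  for (row in seq_len(nrow(tab))) {
    g <- tab$gt_label[row]
    if (tab$dsc[row] >= 0.999) break
    gmask <- gt@labels == g
    # interior: clear of the gt boundary so Bresenham segments stay inside
    er <- EBImage::imageData(EBImage::erode(
      EBImage::Image(gmask * 1), EBImage::makeBrush(7, "box"))) > 0
    if (!any(er)) next
    labs <- segments@labels
    cand <- sort(unique(labs[er]))
    sizes <- tabulate(labs, max(labs))
    pts <- NULL
    for (s in cand) {
      smask <- labs == s & er
      if (sum(labs == s & gmask) / sizes[s] < inside_frac) next
      w <- which(smask, arr.ind = TRUE)
      if (nrow(w) == 0) next
      cx <- mean(w[, 2]); cy <- mean(w[, 1])
      pick <- which.min((w[, 2] - cx)^2 + (w[, 1] - cy)^2)
      pts <- rbind(pts, c(w[pick, 2] - 1, w[pick, 1] - 1))
    }
    if (is.null(pts) || nrow(pts) < 2) next
    ord <- order(pts[, 1], pts[, 2])
    return(list(op = "merge_path", path = pts[ord, , drop = FALSE]))
  }
  NULL
}

#' Run the full segmentation framework
#'
#' Executes normalize -> denoise -> nuclear segmentation (green) -> edge
#' map (cyan/yellow/red) -> SLIC-MMED -> superpixel merging -> optional
#' scripted refinement -> nuclei overlay.  If ground truth is supplied the
#' fibre segmentation (before the nuclei overlay) is evaluated.
#'
#' @param img a raw or normalized \linkS4class{MultiChannelImage} with the
#'   cyan, green, yellow, red channels (green optional).
#' @param config a \code{\link{pipelineConfig}}.
#' @param gt optional ground-truth \linkS4class{LabelMap}.
#' @param outputDir optional directory for intermediate outputs.
#' @return list: \code{final}, \code{segments} (pre-nuclei fibre map),
#'   \code{superpixels}, \code{nuclei}, \code{edge}, \code{report} (NULL
#'   without gt), \code{timings} (seconds per stage).
#' @export
runPipeline <- function(img, config = pipelineConfig(), gt = NULL,
                        outputDir = NULL) {
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  norm <- normalizeImage(img, config$lo_pct, config$hi_pct)
  if (config$denoise_radius > 0)
    norm <- denoiseImage(norm, config$denoise_radius)
  timings["preprocess"] <- tic() - t0

  t0 <- tic()
  nuclei <- if ("green" %in% channelNames(norm)) {
    np <- config$nuclei
    segmentNuclei(getPlane(norm, "green"), threshold = np$threshold,
                  min_area = np$min_area, max_area = np$max_area,
                  min_solidity = np$min_solidity,
                  opening_radius = np$opening_radius)
  } else {
    new("NucleiMask", mask = matrix(FALSE, dim(norm)[1], dim(norm)[2]),
        components = .measureComponents(matrix(0L, 1, 1)))
  }
  timings["nuclei"] <- tic() - t0

  t0 <- tic()
  edge <- edgeProbability(norm, smoothing_sigma = config$edge_sigma,
                          norm_pct = config$edge_norm_pct)
  timings["edges"] <- tic() - t0

  t0 <- tic()
  sp <- runSlicMmed(norm, edge, K = config$K, m = config$m,
                    alpha = config$alpha, iterations = config$iterations,
                    edgeAware = config$edgeAware)
  timings["superpixels"] <- tic() - t0

  t0 <- tic()
  merged <- mergeSuperpixels(sp, norm, edge, thres_dC = config$thres_dC,
                             thres_edge = config$thres_edge,
                             thres_size = config$thres_size,
                             thres_bg = config$thres_bg, bins = config$bins)
  timings["merging"] <- tic() - t0

  segments <- merged
  if (!is.null(config$refinement)) {
    t0 <- tic()
    segments <- applyRefinement(segments, sp, config$refinement)
    timings["refinement"] <- tic() - t0
  }
  final <- combineWithNuclei(segments, nuclei)

  report <- NULL
  if (!is.null(gt)) {
    report <- evaluateSegmentation(segments, gt, K_used = nLabels(sp),
                                   runtime_s = sum(timings))
  }
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    exportLabelMapPNG(sp, file.path(outputDir, "superpixels.png"))
    exportLabelMapCSV(sp, file.path(outputDir, "superpixels.csv"))
    exportLabelMapPNG(final, file.path(outputDir, "final.png"))
    exportLabelMapCSV(final, file.path(outputDir, "final.csv"))
    exportEdgeMapPNG(edge, file.path(outputDir, "edgemap.png"))
    exportNuclei(nuclei, file.path(outputDir, "nuclei.png"),
                 file.path(outputDir, "nuclei.csv"))
    if (!is.null(report))
      exportReport(report, file.path(outputDir, "report.json"),
                   file.path(outputDir, "dsc_per_segment.csv"))
  }
  list(final = final, segments = segments, superpixels = sp,
       nuclei = nuclei, edge = edge, report = report, timings = timings)
}

#' Superpixel quality sweep over K
#'
#' Runs superpixel generation at each K, in both edge-aware (SLIC-MMED)
#' and plain-SLIC mode, and scores boundary recall (d = 2) and
#' under-segmentation error against ground truth.
#'
#' @param img a \linkS4class{MultiChannelImage}.
#' @param gt ground-truth \linkS4class{LabelMap}.
#' @param K_values numeric vector of superpixel counts.
#' @param config a \code{\link{pipelineConfig}} supplying the remaining
#'   parameters.
#' @return data.frame: K, mode, boundary_recall, under_seg_error,
#'   wall_time_s.
#' @export
sweepSuperpixels <- function(img, gt, K_values, config = pipelineConfig()) {
  norm <- normalizeImage(img, config$lo_pct, config$hi_pct)
  if (config$denoise_radius > 0)
    norm <- denoiseImage(norm, config$denoise_radius)
  edge <- edgeProbability(norm, smoothing_sigma = config$edge_sigma,
                          norm_pct = config$edge_norm_pct)
  rows <- list()
  for (K in K_values) {
    for (mode in c("slic-mmed", "slic")) {
      t0 <- proc.time()[["elapsed"]]
      sp <- runSlicMmed(norm, edge, K = K, m = config$m,
                        alpha = config$alpha,
                        iterations = config$iterations,
                        edgeAware = (mode == "slic-mmed"))
      dt <- proc.time()[["elapsed"]] - t0
      rows[[length(rows) + 1]] <- data.frame(
        K = K, mode = mode,
        boundary_recall = boundaryRecall(sp, gt, d = 2),
        under_seg_error = underSegmentationError(sp, gt),
        wall_time_s = dt)
    }
  }
  do.call(rbind, rows)
}
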