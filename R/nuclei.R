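# Nuclear segmentation from the green channel.  In confetti labelling the
# green fluorophore is nuclear-localized, so nuclei are segmented from the
# green plane alone and kept out of the fibre feature vector.

.measureComponents <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids) == 0)
    return(data.frame(label = integer(), area = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      solidity = numeric()))
  out <- lapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    x <- w[, 2] - 1
    y <- w[, 1] - 1
    area <- nrow(w)
    # solidity: pixel area / area of the convex hull of the pixel squares
    cx <- c(x - 0.5, x + 0.5, x - 0.5, x + 0.5)
    cy <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
    h <- grDevices::chull(cx, cy)
    hx <- cx[h]; hy <- cy[h]
    n <- length(h)
    hull_area <- abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2
    data.frame(label = id, area = area, centroid_x = mean(x),
               centroid_y = mean(y),
               solidity = min(1, area / max(hull_area, .Machine$double.eps)))
  })
  do.call(rbind, out)
}

#' Segment nuclei from the green channel
#'
#' Thresholds the green plane (Otsu by default), removes speckle by
#' morphological opening with a disk, fills holes, and discards connected
#' components outside the area bounds or below the solidity bound.  The
#' solidity filter encodes the rounded/ellipsoidal nucleus morphology; the
#' area bounds reject debris and large bled-through patches.
#'
#' @param green a numeric matrix (the normalized green plane, values on
#'   [0, 255]) or a \linkS4class{MultiChannelImage} with a green channel.
#' @param threshold intensity cutoff on [0, 255], or \code{"otsu"}.
#' @param min_area,max_area component area bounds in pixels.
#' @param min_solidity minimum solidity (area / convex hull area).
#' @param opening_radius disk radius for the opening, in pixels (0 = skip).
#' @return A \linkS4class{NucleiMask}.
#' @export
segmentNuclei <- function(green, threshold = "otsu", min_area = 30,
                          max_area = 2000, min_solidity = 0.8,
                          opening_radius = 1) {
  if (is(green, "MultiChannelImage")) green <- getPlane(green, "green")
  stopifnot(min_area <= max_area)
  H <- nrow(green); W <- ncol(green)
  empty <- function() new("NucleiMask",
                          mask = matrix(FALSE, H, W),
                          components = .measureComponents(matrix(0L, H, W)))
  if (max(green) <= 0) return(empty())
  if (identical(threshold, "otsu")) {
    threshold <- EBImage::otsu(EBImage::Image(green / 255)) * 255
  }
  bin <- green > threshold
  if (!any(bin)) return(empty())
  img <- EBImage::Image(bin * 1)
  if (opening_radius > 0) {
    kern <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
    img <- EBImage::opening(img, kern)
  }
  img <- EBImage::fillHull(img)
  lab <- EBImage::imageData(EBImage::bwlabel(img))
  storage.mode(lab) <- "integer"
  comps <- .measureComponents(lab)
  keep <- comps$area >= min_area & comps$area <= max_area &
    comps$solidity >= min_solidity
  comps <- comps[keep, , drop = FALSE]
  mask <- matrix(FALSE, H, W)
  mask[lab %in% comps$label] <- TRUE
  comps$label <- seq_len(nrow(comps))
  rownames(comps) <- NULL
  new("NucleiMask", mask = mask, components = comps)
}

#' Write a nuclei mask to PNG and its component table to CSV
#' @param nuclei a \linkS4class{NucleiMask}.
#' @param png_path,csv_path output files (either may be NULL to skip).
#' @return invisibly, the component table.
#' @export
exportNuclei <- function(nuclei, png_path = NULL, csv_path = NULL) {
  if (!is.null(png_path))
    png::writePNG(nuclei@mask * 1, png_path)
  if (!is.null(csv_path))
    utils::write.csv(nuclei@components, csv_path, row.names = FALSE)
  invisible(nuclei@components)
}
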