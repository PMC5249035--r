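# SLIC-MMED superpixel generation.
#
# k-means-style local clustering of the pixel feature vectors [c, y, r, x, y]
# (cyan/yellow/red intensities plus position) with the edge-augmented
# distance
#
#   D' = sqrt( (d'_c / m)^2 + (d_s / S)^2 + alpha * d_e^2 )
#
# where d'_c is the Euclidean intensity distance, d_s the Euclidean spatial
# distance, S = sqrt(N/K) the seeding interval, m the compactness, and d_e
# the maximum edge probability along the line joining pixel and centroid.
# With an all-zero edge map (or alpha = 0) D' reduces to the original SLIC
# distance.  The green channel carries only nuclei and is excluded.

.requireFiberChannels <- function(img) {
  missing <- setdiff(.FIBER_CHANNELS, channelNames(img))
  if (length(missing))
    stop("superpixel generation requires the cyan, yellow and red channels; ",
         "missing: ", paste(missing, collapse = ", "))
}

#' Seed superpixel centroids on a regular grid
#'
#' Centroids are seeded at interval \eqn{S = \sqrt{N/K}} and each is moved
#' to the lowest-gradient pixel of its 3x3 neighborhood, so that no
#' superpixel starts centered on an edge or a noisy pixel.  Ties keep the
#' grid position.  The centroid feature vector is read from the (possibly
#' moved) pixel.  The realized number of centroids is the nearest grid
#' count to K.
#'
#' @param img a \linkS4class{MultiChannelImage} with cyan, yellow, red.
#' @param K requested number of superpixels (K <= number of pixels).
#' @param gradient an \linkS4class{EdgeMap} or a numeric matrix used as the
#'   gradient surface for the 3x3 perturbation.
#' @param m compactness (stored in the state; default 20).
#' @param alpha edge weight (stored in the state; default 20).
#' @return A \linkS4class{SuperpixelState}.
#' @export
initCentroids <- function(img, K, gradient, m = 20, alpha = 20) {
  .requireFiberChannels(img)
  d <- dim(img)
  H <- d[1]; W <- d[2]
  N <- H * W
  if (K > N) stop("K exceeds the number of pixels")
  if (K < 1) stop("K must be >= 1")
  S <- sqrt(N / K)
  g <- if (is(gradient, "EdgeMap")) gradient@p else gradient
  stopifnot(all(dim(g) == d))
  nx <- max(1L, as.integer(round(W / S)))
  ny <- max(1L, as.integer(round(H / S)))
  xs <- floor((W / nx) * (seq_len(nx) - 0.5))
  ys <- floor((H / ny) * (seq_len(ny) - 0.5))
  cc <- getPlane(img, "cyan")
  yy <- getPlane(img, "yellow")
  rr <- getPlane(img, "red")
  cent <- matrix(0, nx * ny, 5)
  colnames(cent) <- c("c", "y", "r", "x", "y")
  k <- 0
  for (gy in ys) for (gx in xs) {
    k <- k + 1
    bx <- gx; by <- gy
    best <- g[gy + 1, gx + 1]
    for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0) next
      px <- gx + dx; py <- gy + dy
      if (px < 0 || px >= W || py < 0 || py >= H) next
      if (g[py + 1, px + 1] < best) {  # strict: ties keep the grid seed
        best <- g[py + 1, px + 1]
        bx <- px; by <- py
      }
    }
    cent[k, ] <- c(cc[by + 1, bx + 1], yy[by + 1, bx + 1],
                   rr[by + 1, bx + 1], bx, by)
  }
  new("SuperpixelState", centroids = cent, S = S, m = m, alpha = alpha)
}

#' SLIC-MMED distance between a centroid and a pixel
#'
#' Evaluates \eqn{D'} for one centroid/pixel pair.  \code{d_e} is computed
#' from the pixel to the centroid's integer-rounded position.
#'
#' @param state a \linkS4class{SuperpixelState}.
#' @param k centroid index (1-based row of the centroid matrix).
#' @param pixel c(x, y), 0-based.
#' @param img the \linkS4class{MultiChannelImage} supplying the pixel
#'   features.
#' @param edge an \linkS4class{EdgeMap}, or NULL for the plain SLIC
#'   distance.
#' @return the scalar distance D'.
#' @export
pixelDistance <- function(state, k, pixel, img, edge = NULL) {
  cent <- state@centroids[k, ]
  x <- pixel[1]; y <- pixel[2]
  f <- c(getPlane(img, "cyan")[y + 1, x + 1],
         getPlane(img, "yellow")[y + 1, x + 1],
         getPlane(img, "red")[y + 1, x + 1])
  dc2 <- sum((f - cent[1:3])^2)
  ds2 <- (x - cent[4])^2 + (y - cent[5])^2
  de <- 0
  if (!is.null(edge)) {
    cx <- min(max(round(cent[4]), 0), ncol(edge@p) - 1)
    cy <- min(max(round(cent[5]), 0), nrow(edge@p) - 1)
    de <- cpp_line_max(edge@p, as.integer(x), as.integer(y),
                       as.integer(cx), as.integer(cy))
  }
  sqrt(dc2 / state@m^2 + ds2 / state@S^2 + state@alpha * de^2)
}

#' Generate superpixels with SLIC-MMED
#'
#' Iterative local clustering: each centroid scans the 2S x 2S window
#' around its current position; a pixel adopts centroid k when D'(k, pixel)
#' is strictly smaller than its current distance (ties keep the incumbent).
#' After each sweep, centroids move to the mean feature vector of their
#' members; emptied clusters are frozen and dropped at compaction.  A final
#' connectivity-enforcement step relabels disjoint fragments: components
#' smaller than S^2/4 are absorbed by the neighbor sharing the largest
#' border, larger detached components become labels of their own.  The
#' algorithm is fully deterministic.
#'
#' @param img a \linkS4class{MultiChannelImage} with cyan, yellow, red
#'   (green, if present, is ignored here and handled by
#'   \code{\link{segmentNuclei}}).
#' @param edge an \linkS4class{EdgeMap} on the same grid.  Also supplies
#'   the gradient surface for seed perturbation.
#' @param K requested number of superpixels.
#' @param m compactness (default 20).
#' @param alpha edge weight (default 20).
#' @param iterations number of assign/update sweeps (default 10).
#' @param edgeAware if FALSE, run the plain SLIC distance (no d_e term);
#'   with an all-zero edge map both modes give bit-identical label maps.
#' @return A finalized \linkS4class{LabelMap} (contiguous labels 1..L).
#' @export
runSlicMmed <- function(img, edge, K, m = 20, alpha = 20, iterations = 10,
                        edgeAware = TRUE) {
  .requireFiberChannels(img)
  stopifnot(iterations >= 1)
  d <- dim(img)
  stopifnot(all(dim(edge@p) == d))
  state <- initCentroids(img, K, edge, m = m, alpha = alpha)
  res <- cpp_slic(getPlane(img, "cyan"), getPlane(img, "yellow"),
                  getPlane(img, "red"), edge@p, state@centroids,
                  state@S, m, alpha, as.integer(iterations),
                  isTRUE(edgeAware))
  min_size <- max(1L, as.integer(floor(state@S^2 / 4)))
  lab <- cpp_enforce_connectivity(res$labels, min_size)
  LabelMap(lab)
}
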