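# Edge-probability map over the fibre channels.  The detector is a Di Zenzo
# colour structure tensor: per-channel spatial gradients are combined into
# the 2x2 tensor J = sum_c grad I_c grad I_c^T, J is Gaussian-smoothed, and
# the edge magnitude is the square root of its largest eigenvalue.  The map
# is rescaled by a high percentile and clipped, giving probabilities in
# [0, 1].  The detector is pluggable: any function producing an EdgeMap can
# stand in for it downstream.

.shiftPad <- function(m, dy, dx) {
  # shift with replicated borders
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + dy, 1), H)
  ci <- pmin(pmax(seq_len(W) + dx, 1), W)
  m[ri, ci, drop = FALSE]
}

.gradients <- function(m) {
  gx <- (.shiftPad(m, 0, 1) - .shiftPad(m, 0, -1)) / 2
  gy <- (.shiftPad(m, 1, 0) - .shiftPad(m, -1, 0)) / 2
  list(gx = gx, gy = gy)
}

.gblur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  out <- EBImage::gblur(EBImage::Image(m), sigma = sigma)
  as.matrix(EBImage::imageData(out))
}

#' Per-pixel edge probability over selected channels
#'
#' Computes the multi-channel structure-tensor gradient magnitude (largest
#' eigenvalue's square root of the summed per-channel outer product of the
#' spatial gradients, Gaussian-smoothed with \code{smoothing_sigma}),
#' rescales it by its \code{norm_pct} percentile and clips to [0, 1].  A
#' spatially constant image yields an all-zero map, and the output is
#' invariant under adding a constant to every channel.
#'
#' Gradients are taken at a differentiation scale \code{grad_sigma} (each
#' plane is Gaussian pre-smoothed before central differencing): squared
#' noise gradients have a positive mean, so without pre-smoothing the
#' tensor smoothing converges to a noise floor instead of removing it.
#'
#' @param img a \linkS4class{MultiChannelImage}.
#' @param channels channels to use; defaults to the fibre channels (cyan,
#'   yellow, red) that are present.
#' @param smoothing_sigma integration scale: Gaussian smoothing of the
#'   tensor, in pixels.
#' @param norm_pct percentile used for normalization (default 0.99).
#' @param grad_sigma differentiation scale: Gaussian pre-smoothing of each
#'   plane before differencing, in pixels (0 = plain central differences).
#' @return An \linkS4class{EdgeMap}.
#' @export
edgeProbability <- function(img, channels = NULL, smoothing_sigma = 1.5,
                            norm_pct = 0.99, grad_sigma = 1) {
  if (is.null(channels))
    channels <- intersect(.FIBER_CHANNELS, channelNames(img))
  stopifnot(length(channels) >= 1, smoothing_sigma >= 0, grad_sigma >= 0)
  d <- dim(img)
  J11 <- matrix(0, d[1], d[2])
  J22 <- matrix(0, d[1], d[2])
  J12 <- matrix(0, d[1], d[2])
  for (ch in channels) {
    g <- .gradients(.gblur(getPlane(img, ch), grad_sigma))
    J11 <- J11 + g$gx^2
    J22 <- J22 + g$gy^2
    J12 <- J12 + g$gx * g$gy
  }
  J11 <- .gblur(J11, smoothing_sigma)
  J22 <- .gblur(J22, smoothing_sigma)
  J12 <- .gblur(J12, smoothing_sigma)
  lam <- 0.5 * (J11 + J22 + sqrt(pmax((J11 - J22)^2 + 4 * J12^2, 0)))
  p <- sqrt(pmax(lam, 0))
  q <- stats::quantile(p, norm_pct, names = FALSE, type = 7)
  if (q <= 0) return(new("EdgeMap", p = matrix(0, d[1], d[2])))
  p <- pmin(p / q, 1)
  new("EdgeMap", p = p)
}

#' Maximum edge probability along the line between two pixels
#'
#' The edge distance \eqn{d_e} of the SLIC-MMED distance: the maximum of
#' the edge probability over all pixels on the Bresenham raster of the
#' segment joining pixels i and j, endpoints included.  The raster
#' direction is canonicalized so the result is symmetric in (i, j).
#'
#' @param edge an \linkS4class{EdgeMap}.
#' @param i,j pixels as c(x, y), 0-based (x = column, y = row).
#' @return the maximum edge probability, a scalar in [0, 1].
#' @export
lineEdgeDistance <- function(edge, i, j) {
  p <- edge@p
  cpp_line_max(p, as.integer(i[1]), as.integer(i[2]),
               as.integer(j[1]), as.integer(j[2]))
}

#' Write an edge map as an 8-bit grayscale PNG
#' @param edge an \linkS4class{EdgeMap}.
#' @param path output PNG file.
#' @return invisibly, the path.
#' @export
exportEdgeMapPNG <- function(edge, path) {
  png::writePNG(edge@p, path)
  invisible(path)
}
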