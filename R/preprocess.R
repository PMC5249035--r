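#' Load a multi-channel microscopy image
#'
#' Reads one multi-page TIFF (one page per channel) or a vector of
#' single-plane TIFF/PNG files, and labels the planes with the supplied
#' channel order.  Intensities are returned on their native integer scale
#' (raw, un-normalized); the source bit depth is recorded.
#'
#' @param paths character vector: a single multi-page TIFF, or one file per
#'   channel.
#' @param channels character vector of channel names in plane order; drawn
#'   from cyan, green, yellow, red.
#' @return A \linkS4class{MultiChannelImage} on the raw intensity scale.
#' @export
loadImage <- function(paths, channels) {
  if (any(!channels %in% .CHANNELS))
    stop(sprintf("unknown channel name(s): %s",
                 paste(setdiff(channels, .CHANNELS), collapse = ", ")))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("file not found: ", missing[1])
  planes <- list()
  depth <- 8L
  if (length(paths) == 1 && grepl("\\.tiff?$", paths, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(paths, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != length(channels))
      stop(sprintf("file has %d page(s) but %d channel name(s) were given",
                   length(pages), length(channels)))
    bits <- attr(pages[[1]], "bits.per.sample")
    if (!is.null(bits)) depth <- as.integer(bits)
    planes <- pages
  } else {
    if (length(paths) != length(channels))
      stop("need one file per channel")
    planes <- lapply(seq_along(paths), function(i) {
      f <- paths[i]
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        x <- png::readPNG(f, info = TRUE)
        bits <- attr(x, "info")$bit.depth
        if (is.null(bits)) bits <- 8L
        depth <<- max(depth, as.integer(bits))
        if (length(dim(x)) == 3) x <- x[, , 1]
        x * (2^as.integer(bits) - 1)
      } else {
        x <- tiff::readTIFF(f, as.is = TRUE, info = TRUE)
        bits <- attr(x, "bits.per.sample")
        if (!is.null(bits)) depth <<- max(depth, as.integer(bits))
        if (length(dim(x)) == 3) x <- x[, , 1]
        x
      }
    })
  }
  planes <- lapply(planes, function(m) {
    m <- unclass(m)
    attributes(m) <- list(dim = dim(m))
    storage.mode(m) <- "double"
    m
  })
  names(planes) <- channels
  dims <- vapply(planes, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad))
    stop(sprintf("plane '%s' (%dx%d) does not match plane '%s' (%dx%d)",
                 channels[bad[1]], dims[1, bad[1]], dims[2, bad[1]],
                 channels[1], dims[1, 1], dims[2, 1]))
  if (!depth %in% c(8L, 12L, 16L))
    stop("unsupported bit depth: ", depth)
  new("MultiChannelImage", planes = planes,
      scale = c(0, 2^depth - 1), bitDepth = depth)
}

#' Normalize channels to the [0, 255] range
#'
#' Each channel is independently rescaled so that its \code{lo_pct}
#' percentile maps to 0 and its \code{hi_pct} percentile maps to 255, with
#' values clipped to [0, 255].  The defaults (0, 1) give plain min-max
#' normalization; interior percentiles provide robustness against hot
#' pixels.  A constant plane maps to all zeros.  Percentiles use the
#' standard linear-interpolation order statistic (\code{quantile} type 7).
#'
#' @param img a \linkS4class{MultiChannelImage}.
#' @param lo_pct,hi_pct percentile fractions, 0 <= lo_pct < hi_pct <= 1.
#' @return A normalized \linkS4class{MultiChannelImage} with scale [0, 255].
#' @export
normalizeImage <- function(img, lo_pct = 0, hi_pct = 1) {
  stopifnot(lo_pct >= 0, hi_pct <= 1, lo_pct < hi_pct)
  planes <- lapply(img@planes, function(m) {
    lo <- stats::quantile(m, lo_pct, names = FALSE, type = 7)
    hi <- stats::quantile(m, hi_pct, names = FALSE, type = 7)
    if (hi <= lo) return(matrix(0, nrow(m), ncol(m)))
    out <- (m - lo) / (hi - lo) * 255
    out[out < 0] <- 0
    out[out > 255] <- 255
    out
  })
  new("MultiChannelImage", planes = planes, scale = c(0, 255),
      bitDepth = img@bitDepth)
}

#' Median-filter all channels
#'
#' Per-channel median filter over a (2 * radius + 1)^2 window with reflect
#' padding at the borders (so border pixels are not darkened).  Radius 0 is
#' the identity.
#'
#' @param img a \linkS4class{MultiChannelImage}.
#' @param radius window radius in pixels, >= 0.
#' @return The filtered \linkS4class{MultiChannelImage}.
#' @export
denoiseImage <- function(img, radius = 1) {
  stopifnot(radius >= 0)
  if (radius == 0) return(img)
  planes <- lapply(img@planes, cpp_median_filter, radius = as.integer(radius))
  new("MultiChannelImage", planes = planes, scale = img@scale,
      bitDepth = img@bitDepth)
}

#' Keep a subset of channels
#' @param img a \linkS4class{MultiChannelImage}.
#' @param channels channel names to retain.
#' @return A \linkS4class{MultiChannelImage} with only those planes.
#' @export
selectChannels <- function(img, channels) {
  planes <- lapply(channels, function(ch) getPlane(img, ch))
  names(planes) <- channels
  new("MultiChannelImage", planes = planes, scale = img@scale,
      bitDepth = img@bitDepth)
}
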