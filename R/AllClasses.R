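#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib slicmmed, .registration = TRUE
NULL

.CHANNELS <- c("cyan", "green", "yellow", "red")
.FIBER_CHANNELS <- c("cyan", "yellow", "red")

#' Multi-channel fluorescence image
#'
#' Container for one grayscale plane per fluorescence channel of a
#' multi-colour ("confetti") microscopy image.  Channels are named from
#' \code{cyan}, \code{green}, \code{yellow}, \code{red}; all planes share
#' one H x W shape.  Pixel coordinates follow the image convention used
#' throughout the package: \code{x} is the 0-based column index and
#' \code{y} the 0-based row index, so plane element \code{[y + 1, x + 1]}
#' is pixel \code{(x, y)}.
#'
#' @slot planes named list of numeric H x W matrices.
#' @slot scale numeric(2), the declared intensity range of the planes.
#' @slot bitDepth integer, bit depth of the source data (8, 12 or 16).
#'
#' @exportClass MultiChannelImage
setClass("MultiChannelImage",
  representation(planes = "list", scale = "numeric", bitDepth = "integer"),
  prototype(planes = list(), scale = c(0, 255), bitDepth = 8L)
)

setValidity("MultiChannelImage", function(object) {
  pl <- object@planes
  if (length(pl) == 0) return("image has no planes")
  nm <- names(pl)
  if (is.null(nm) || any(!nm %in% .CHANNELS))
    return(sprintf("channel names must be drawn from {%s}",
                   paste(.CHANNELS, collapse = ", ")))
  if (anyDuplicated(nm)) return("each channel may be present at most once")
  dims <- vapply(pl, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return(sprintf("plane '%s' has a different shape",
                   nm[which(dims[1, ] != dims[1, 1] |
                            dims[2, ] != dims[2, 1])[1]]))
  if (length(object@scale) != 2 || object@scale[1] >= object@scale[2])
    return("scale must be an increasing range of length 2")
  TRUE
})

#' Per-pixel edge probability map
#'
#' Holds the probability \eqn{p_i \in [0,1]} of each pixel lying on an
#' object boundary, as produced by \code{\link{edgeProbability}}.
#'
#' @slot p numeric matrix of edge probabilities in [0, 1].
#' @exportClass EdgeMap
setClass("EdgeMap", representation(p = "matrix"))

setValidity("EdgeMap", function(object) {
  if (!is.numeric(object@p)) return("p must be numeric")
  if (any(object@p < 0 | object@p > 1)) return("edge probabilities must lie in [0, 1]")
  TRUE
})

#' Integer label map
#'
#' Segmentation labels, one positive integer per pixel.  Finalized maps are
#' partitions with contiguous ids \code{1..L}; the value 0 is reserved for
#' "unassigned" during construction only and never appears in a finalized
#' map.
#'
#' @slot labels integer H x W matrix.
#' @exportClass LabelMap
setClass("LabelMap", representation(labels = "matrix"))

setValidity("LabelMap", function(object) {
  l <- object@labels
  if (!is.numeric(l)) return("labels must be integer")
  if (any(l < 0)) return("labels must be non-negative")
  TRUE
})

#' Nuclei segmentation result
#'
#' Binary nuclei mask from the green channel plus a component table with
#' per-nucleus area, centroid and solidity.
#'
#' @slot mask logical H x W matrix.
#' @slot components data.frame with columns \code{label}, \code{area},
#'   \code{centroid_x}, \code{centroid_y}, \code{solidity}.
#' @exportClass NucleiMask
setClass("NucleiMask",
  representation(mask = "matrix", components = "data.frame"))

#' Superpixel clustering state
#'
#' Seeded centroids and parameters of a SLIC-MMED run.  Centroid rows are
#' the feature vectors [c, y, r, x, y]: mean intensities in the cyan,
#' yellow and red channels followed by the spatial position.
#'
#' @slot centroids numeric K x 5 matrix with columns c, y, r, x, y.
#' @slot S numeric, grid interval \eqn{S = \sqrt{N/K}} in pixels.
#' @slot m numeric, compactness.
#' @slot alpha numeric, edge weight.
#' @exportClass SuperpixelState
setClass("SuperpixelState",
  representation(centroids = "matrix", S = "numeric", m = "numeric",
                 alpha = "numeric"))

# ---- constructors ---------------------------------------------------------

#' Create a MultiChannelImage from matrices
#'
#' @param ... named numeric matrices (channel name = plane), or a single
#'   named list of matrices.
#' @param scale declared intensity range, default c(0, 255).
#' @param bitDepth source bit depth.
#' @return A \linkS4class{MultiChannelImage}.
#' @examples
#' img <- MultiChannelImage(cyan = matrix(0, 4, 4), red = matrix(1, 4, 4))
#' channelNames(img)
#' @export
MultiChannelImage <- function(..., scale = c(0, 255), bitDepth = 8L) {
  planes <- list(...)
  if (length(planes) == 1 && is.list(planes[[1]]) && is.null(dim(planes[[1]])))
    planes <- planes[[1]]
  planes <- lapply(planes, function(m) {
    storage.mode(m) <- "double"
    m
  })
  new("MultiChannelImage", planes = planes, scale = as.numeric(scale),
      bitDepth = as.integer(bitDepth))
}

#' Create a LabelMap from an integer matrix
#' @param labels integer matrix of per-pixel labels.
#' @return A \linkS4class{LabelMap}.
#' @export
LabelMap <- function(labels) {
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels)
}

#' Create an EdgeMap from a probability matrix
#' @param p numeric matrix of per-pixel edge probabilities in [0, 1].
#' @return An \linkS4class{EdgeMap}.
#' @export
EdgeMap <- function(p) new("EdgeMap", p = p)

# ---- generics and accessors ----------------------------------------------

#' @describeIn MultiChannelImage-class channel names present in the image
#' @param x object
#' @export
channelNames <- function(x) names(x@planes)

#' Extract one channel plane
#' @param x a MultiChannelImage
#' @param channel channel name
#' @return numeric matrix
#' @export
getPlane <- function(x, channel) {
  if (!channel %in% names(x@planes))
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(names(x@planes), collapse = ", ")))
  x@planes[[channel]]
}

#' @export
setMethod("dim", "MultiChannelImage", function(x) dim(x@planes[[1]]))

#' @export
setMethod("dim", "LabelMap", function(x) dim(x@labels))

#' @export
setMethod("dim", "EdgeMap", function(x) dim(x@p))

#' Number of distinct labels in a label map
#' @param x a LabelMap
#' @return integer count of distinct labels
#' @export
nLabels <- function(x) length(unique(as.vector(x@labels)))

#' Pixel counts per label
#' @param x a LabelMap
#' @return named integer vector of label sizes
#' @export
labelSizes <- function(x) {
  tab <- tabulate(x@labels)
  names(tab) <- seq_along(tab)
  tab[tab > 0]
}

#' Extract the label matrix
#' @param x a LabelMap
#' @return integer matrix
#' @export
labelMatrix <- function(x) x@labels

#' Extract the edge-probability matrix
#' @param x an EdgeMap
#' @return numeric matrix
#' @export
edgeMatrix <- function(x) x@p

#' Nuclei component table
#' @param x a NucleiMask
#' @return data.frame of per-nucleus measurements
#' @export
nucleiComponents <- function(x) x@components

#' Nuclei binary mask
#' @param x a NucleiMask
#' @return logical matrix
#' @export
nucleiMaskMatrix <- function(x) x@mask

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object)
  cat(sprintf("MultiChannelImage: %d x %d px, %d-bit source, channels: %s\n",
              d[1], d[2], object@bitDepth,
              paste(names(object@planes), collapse = ", ")))
  cat(sprintf("  declared scale [%g, %g]\n", object@scale[1], object@scale[2]))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object)
  cat(sprintf("LabelMap: %d x %d px, %d labels\n", d[1], d[2],
              nLabels(object)))
})

setMethod("show", "EdgeMap", function(object) {
  d <- dim(object)
  cat(sprintf("EdgeMap: %d x %d px, p in [%.3f, %.3f]\n", d[1], d[2],
              min(object@p), max(object@p)))
})

setMethod("show", "NucleiMask", function(object) {
  cat(sprintf("NucleiMask: %d x %d px, %d nuclei\n", nrow(object@mask),
              ncol(object@mask), nrow(object@components)))
})

setMethod("show", "SuperpixelState", function(object) {
  cat(sprintf("SuperpixelState: K = %d centroids, S = %.2f, m = %g, alpha = %g\n",
              nrow(object@centroids), object@S, object@m, object@alpha))
})
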