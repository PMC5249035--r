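# Superpixel merging into fibre segments.
#
# Adjacent regions are compared by the chi-squared distance between their
# per-channel intensity histograms,
#   chi2(P, Q) = 1/2 * sum_k (P_k - Q_k)^2 / (P_k + Q_k)
#   D_C(i, j)  = sqrt( chi2_c^2 + chi2_y^2 + chi2_r^2 )
# and by directed border edge strengths E_ij (mean edge probability over
# the pixels of i facing j).  Similar-colour neighbors merge only when both
# edge strengths are low; a size cap prevents over-merged fibres but is
# waived when both regions are background (near-black).

#' Region adjacency graph with histograms and edge strengths
#'
#' @slot sizes integer vector of region sizes (pixels), indexed by label.
#' @slot histograms numeric array L x 3 x bins of per-channel histograms
#'   (channels in order cyan, yellow, red), each normalized to sum 1.
#' @slot meanIntensity numeric vector, per-region mean of (c + y + r)/3.
#' @slot isBackground logical vector, meanIntensity < thres_bg.
#' @slot edges data.frame of directed adjacencies: \code{i}, \code{j},
#'   \code{n} (border pixels of i facing j) and \code{E} (edge strength).
#' @slot bins integer, histogram bin count over [0, 255].
#' @exportClass RegionGraph
setClass("RegionGraph",
  representation(sizes = "integer", histograms = "array",
                 meanIntensity = "numeric", isBackground = "logical",
                 edges = "data.frame", bins = "integer"))

setMethod("show", "RegionGraph", function(object) {
  cat(sprintf("RegionGraph: %d regions (%d background), %d directed adjacencies, %d histogram bins\n",
              length(object@sizes), sum(object@isBackground),
              nrow(object@edges), object@bins))
})

#' Chi-squared distance between two histograms
#'
#' \eqn{\chi^2(P,Q) = \frac{1}{2}\sum_k (P_k - Q_k)^2 / (P_k + Q_k)}, with
#' empty bins (\eqn{P_k + Q_k = 0}) contributing zero.
#'
#' @param P,Q nonnegative numeric vectors of equal length, each summing
#'   to 1.
#' @return the chi-squared distance, a scalar >= 0.
#' @export
chi2Distance <- function(P, Q) {
  if (length(P) != length(Q)) stop("histograms have different bin counts")
  s <- P + Q
  keep <- s > 0
  0.5 * sum((P[keep] - Q[keep])^2 / s[keep])
}

#' Build the region adjacency graph of a label map
#'
#' @param labels a finalized \linkS4class{LabelMap}.
#' @param img the normalized \linkS4class{MultiChannelImage} (cyan, yellow,
#'   red on [0, 255]).
#' @param edge an \linkS4class{EdgeMap} on the same grid.
#' @param bins histogram bins over [0, 255] (default 16).
#' @param thres_bg background intensity threshold on [0, 255] (default 10).
#' @return A \linkS4class{RegionGraph}.
#' @export
buildRegionGraph <- function(labels, img, edge, bins = 16, thres_bg = 10) {
  lab <- labels@labels
  st <- cpp_region_stats(lab, getPlane(img, "cyan"), getPlane(img, "yellow"),
                         getPlane(img, "red"), edge@p, as.integer(bins))
  L <- length(st$sizes)
  if (any(st$sizes == 0)) stop("label map has empty labels; compact it first")
  h <- array(0, c(L, 3, bins))
  for (ch in 1:3)
    h[, ch, ] <- st$hist[, ((ch - 1) * bins + 1):(ch * bins), drop = FALSE] /
      st$sizes
  mi <- st$intensity_sum / st$sizes
  ed <- data.frame(i = st$edge_i, j = st$edge_j, n = st$edge_n,
                   E = ifelse(st$edge_n > 0, st$edge_psum / st$edge_n, 0))
  new("RegionGraph", sizes = st$sizes, histograms = h, meanIntensity = mi,
      isBackground = mi < thres_bg, edges = ed, bins = as.integer(bins))
}

#' Histogram distance D_C between two regions of a graph
#'
#' @param graph a \linkS4class{RegionGraph}.
#' @param i,j region labels.
#' @return \eqn{D_C(i,j)}, the Euclidean combination of the three
#'   per-channel chi-squared distances.
#' @export
regionDistance <- function(graph, i, j) {
  L <- length(graph@sizes)
  if (i < 1 || i > L || j < 1 || j > L) stop("unknown region label")
  x2 <- vapply(1:3, function(ch)
    chi2Distance(graph@histograms[i, ch, ], graph@histograms[j, ch, ]),
    numeric(1))
  sqrt(sum(x2^2))
}

#' Directed edge strength between two adjacent regions
#'
#' E_ij: the mean edge probability over the pixels of region i that have at
#' least one 4-neighbor in region j.  Generally E_ij != E_ji.
#'
#' @param edge an \linkS4class{EdgeMap}.
#' @param assignment a \linkS4class{LabelMap}.
#' @param i,j region labels (must be 4-adjacent).
#' @return the mean edge probability, a scalar in [0, 1].
#' @export
edgeStrength <- function(edge, assignment, i, j) {
  lab <- assignment@labels
  mi <- lab == i
  nb <- .shiftPad(lab, 0, 1) == j | .shiftPad(lab, 0, -1) == j |
        .shiftPad(lab, 1, 0) == j | .shiftPad(lab, -1, 0) == j
  # replicated borders make a pixel its own neighbor at the image edge;
  # that self-copy carries its own label i != j, so it never counts.
  sel <- mi & nb
  if (!any(sel)) stop(sprintf("regions %d and %d are not adjacent", i, j))
  mean(edge@p[sel])
}

# vectorized D_C for a set of (i, j) pairs given normalized histograms
.pairDC <- function(h, pi, pj) {
  x2sum <- 0
  for (ch in 1:3) {
    A <- h[pi, ch, , drop = FALSE]
    B <- h[pj, ch, , drop = FALSE]
    s <- A + B
    num <- (A - B)^2
    term <- num / s
    term[s == 0] <- 0
    x2 <- 0.5 * apply(term, 1, sum)
    x2sum <- x2sum + x2^2
  }
  sqrt(x2sum)
}

#' Merge superpixels into fibre segments
#'
#' Iterative pass-wise merging to a fixpoint.  Within a pass, candidate
#' adjacent pairs are visited in ascending (i, j) label order and a region
#' takes part in at most one merge per pass.  A pair merges when all hold:
#' \itemize{
#'   \item \eqn{D_C(i,j) \le} \code{thres_dC} (similar colour content),
#'   \item \eqn{E_{ij} \le} \code{thres_edge} and \eqn{E_{ji} \le}
#'     \code{thres_edge} (no strong boundary between them),
#'   \item merged size \eqn{\le} \code{thres_size}, waived when both
#'     regions are background.
#' }
#' After each pass all statistics are recomputed from raw pixels.  The
#' algorithm stops when a pass merges nothing; the result is a coarsening
#' of the input partition and re-running it changes nothing.
#'
#' @param superpixels a finalized \linkS4class{LabelMap}.
#' @param img normalized \linkS4class{MultiChannelImage}.
#' @param edge an \linkS4class{EdgeMap}.
#' @param thres_dC histogram-distance threshold (default 0.4, calibrated
#'   on the synthetic fixture suite).
#' @param thres_edge edge-strength threshold (default 0.5, calibrated on
#'   the synthetic fixture suite).
#' @param thres_size maximum merged region size; values <= 1 are a fraction
#'   of the image area, larger values absolute pixels (default 0.05).
#' @param thres_bg background mean-intensity threshold (default 10).
#' @param bins histogram bins (default 16).
#' @return A compacted \linkS4class{LabelMap} of merged segments.
#' @export
mergeSuperpixels <- function(superpixels, img, edge, thres_dC = 0.4,
                             thres_edge = 0.5, thres_size = 0.05,
                             thres_bg = 10, bins = 16) {
  lab <- superpixels@labels
  N <- length(lab)
  ts_abs <- if (thres_size <= 1) thres_size * N else thres_size
  cc <- getPlane(img, "cyan")
  yy <- getPlane(img, "yellow")
  rr <- getPlane(img, "red")
  repeat {
    st <- cpp_region_stats(lab, cc, yy, rr, edge@p, as.integer(bins))
    L <- length(st$sizes)
    if (L <= 1) break
    h <- array(0, c(L, 3, bins))
    for (ch in 1:3)
      h[, ch, ] <- st$hist[, ((ch - 1) * bins + 1):(ch * bins),
                           drop = FALSE] / st$sizes
    bg <- (st$intensity_sum / st$sizes) < thres_bg
    E <- st$edge_psum / pmax(st$edge_n, 1)
    # directed strengths keyed for O(1) lookup of the reverse direction
    key <- paste(st$edge_i, st$edge_j)
    Erev <- E[match(paste(st$edge_j, st$edge_i), key)]
    und <- st$edge_i < st$edge_j
    pi <- st$edge_i[und]; pj <- st$edge_j[und]
    Eij <- E[und]; Eji <- Erev[und]
    ord <- order(pi, pj)
    pi <- pi[ord]; pj <- pj[ord]; Eij <- Eij[ord]; Eji <- Eji[ord]
    dC <- .pairDC(h, pi, pj)
    ok <- dC <= thres_dC & Eij <= thres_edge & !is.na(Eji) &
      Eji <= thres_edge &
      (st$sizes[pi] + st$sizes[pj] <= ts_abs | (bg[pi] & bg[pj]))
    mapping <- seq_len(L)
    used <- logical(L)
    any_merge <- FALSE
    for (t in which(ok)) {
      a <- pi[t]; b <- pj[t]
      if (used[a] || used[b]) next
      mapping[b] <- a
      used[a] <- TRUE
      used[b] <- TRUE
      any_merge <- TRUE
    }
    if (!any_merge) break
    lab2 <- mapping[lab]
    u <- sort(unique(lab2))
    lab <- matrix(match(lab2, u), nrow(lab), ncol(lab))
    storage.mode(lab) <- "integer"
  }
  LabelMap(lab)
}

#' Merge all regions traversed by a freehand curve
#'
#' Programmatic version of the "draw a curve to merge regions" refinement:
#' the path vertices are joined by Bresenham segments and every label the
#' raster touches is unioned under the lowest traversed label id.
#'
#' @param segments a \linkS4class{LabelMap}.
#' @param path n x 2 matrix of (x, y) vertices, 0-based.
#' @return A \linkS4class{LabelMap} (labels are not renumbered, so the
#'   surviving region keeps its id).
#' @export
mergeAlongPath <- function(segments, path) {
  if (is.null(path) || NROW(path) == 0) stop("empty path")
  path <- matrix(as.integer(path), ncol = 2)
  lab <- segments@labels
  ras <- cpp_rasterize_polyline(path, nrow(lab), ncol(lab))
  hit <- unique(lab[cbind(ras[, 2] + 1, ras[, 1] + 1)])
  if (length(hit) <= 1) return(segments)
  target <- min(hit)
  lab[lab %in% hit] <- target
  LabelMap(lab)
}

#' Restore the original superpixels around a position
#'
#' Programmatic version of the "restore superpixels" refinement: within the
#' merged region containing \code{position} (optionally intersected with a
#' disk of \code{radius}), labels revert to the pre-merge superpixel ids,
#' offset to avoid collisions with existing labels.  A region that is a
#' single original superpixel is returned unchanged.
#'
#' @param segments the merged \linkS4class{LabelMap}.
#' @param original the pre-merge superpixel \linkS4class{LabelMap}.
#' @param position c(x, y), 0-based.
#' @param radius restore radius in pixels; Inf restores the whole region.
#' @return A \linkS4class{LabelMap}.
#' @export
restoreSuperpixels <- function(segments, original, position, radius = Inf) {
  lab <- segments@labels
  H <- nrow(lab); W <- ncol(lab)
  x <- position[1]; y <- position[2]
  if (x < 0 || x >= W || y < 0 || y >= H) stop("position outside the image")
  target <- lab[y + 1, x + 1]
  region <- lab == target
  sel <- region
  if (is.finite(radius)) {
    d2 <- outer((seq_len(H) - 1 - y)^2, (seq_len(W) - 1 - x)^2, "+")
    sel <- region & d2 <= radius^2
  }
  orig <- original@labels
  if (length(unique(orig[sel])) <= 1 && all(region == sel)) return(segments)
  offset <- max(lab)
  lab[sel] <- orig[sel] + offset
  LabelMap(lab)
}

#' Stamp nuclei as dedicated labels over a fibre segmentation
#'
#' Each connected nucleus component becomes its own label on top of the
#' fibre segments; fibre labels keep their remaining pixels.
#'
#' @param segments a \linkS4class{LabelMap}.
#' @param nuclei a \linkS4class{NucleiMask} of the same shape.
#' @return A \linkS4class{LabelMap}.
#' @export
combineWithNuclei <- function(segments, nuclei) {
  lab <- segments@labels
  if (!all(dim(lab) == dim(nuclei@mask)))
    stop("segmentation and nuclei mask have different shapes")
  if (!any(nuclei@mask)) return(segments)
  comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(nuclei@mask * 1)))
  storage.mode(comp) <- "integer"
  offset <- max(lab)
  lab[comp > 0] <- comp[comp > 0] + offset
  LabelMap(lab)
}

#' Renumber labels to contiguous 1..L
#' @param x a \linkS4class{LabelMap}.
#' @return A \linkS4class{LabelMap} with labels 1..L (ascending id order).
#' @export
compactLabels <- function(x) {
  lab <- x@labels
  u <- sort(unique(as.vector(lab)))
  out <- matrix(match(lab, u), nrow(lab), ncol(lab))
  storage.mode(out) <- "integer"
  LabelMap(out)
}
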