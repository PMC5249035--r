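# Synthetic confetti-like fixtures with known ground truth.
#
# The generator emulates the image properties of multi-colour muscle
# sections: piecewise-constant fibre colours in cyan/yellow/red with
# per-fibre brightness variation, a cyan membrane ridge along fibre
# borders, blurry borders, additive noise, green nuclear disks, dark
# background regions, and small near-black holes (ice-crystal artifacts).
# All randomness is driven by one seed recorded in the spec.

.FIBER_PROFILES <- matrix(c(
  70, 200,  25,   # yellow fibre
  70,  25, 205,   # red fibre
  200,  30,  30,  # cyan fibre
  60, 170, 170,   # yellow + red
  45, 110,  20,   # dim yellow
  45,  20, 115    # dim red
), ncol = 3, byrow = TRUE, dimnames = list(NULL, c("c", "y", "r")))

.BG_PROFILE <- c(6, 4, 4)

#' Specification of a synthetic confetti mosaic
#'
#' The defaults describe the standard evaluation fixture: a 512 x 512
#' four-channel image with 40 fibre-like regions, 1.5 px border blur and
#' noise of sd 8 on the [0, 255] scale.
#'
#' @param H,W image size in pixels.
#' @param n_regions number of ground-truth regions.
#' @param intensity_jitter sd of per-region intensity jitter.
#' @param border_blur_sigma Gaussian blur of region borders, pixels.
#' @param noise_sd additive Gaussian noise sd on [0, 255].
#' @param n_nuclei number of green nuclear disks.
#' @param nucleus_radius integer range c(min, max) of nucleus radii, px.
#' @param n_holes number of near-black artifact holes.
#' @param hole_radius integer range of hole radii, px.
#' @param background_frac fraction of regions rendered as near-black
#'   background (placed mutually non-adjacent).
#' @param membrane_intensity cyan intensity of the border membrane ridge.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return A list of class \code{MosaicSpec}.
#' @export
mosaicSpec <- function(H = 512, W = 512, n_regions = 40,
                       intensity_jitter = 15, border_blur_sigma = 1.5,
                       noise_sd = 8, n_nuclei = 25, nucleus_radius = c(4, 7),
                       n_holes = 3, hole_radius = c(3, 6),
                       background_frac = 0.1, membrane_intensity = 230,
                       seed = 1L) {
  stopifnot(n_regions >= 1, intensity_jitter >= 0, border_blur_sigma >= 0,
            noise_sd >= 0, n_nuclei >= 0, n_holes >= 0)
  spec <- list(H = H, W = W, n_regions = n_regions,
               intensity_jitter = intensity_jitter,
               border_blur_sigma = border_blur_sigma, noise_sd = noise_sd,
               n_nuclei = n_nuclei, nucleus_radius = nucleus_radius,
               n_holes = n_holes, hole_radius = hole_radius,
               background_frac = background_frac,
               membrane_intensity = membrane_intensity, seed = seed)
  class(spec) <- "MosaicSpec"
  spec
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.adjacencyPairs <- function(lab) {
  right <- cbind(as.vector(lab[, -ncol(lab)]), as.vector(lab[, -1]))
  down <- cbind(as.vector(lab[-nrow(lab), ]), as.vector(lab[-1, ]))
  pr <- rbind(right, down)
  pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
  pr <- unique(rbind(pr, pr[, 2:1]))
  pr
}

.stampDisk <- function(m, cx, cy, r, value) {
  # cx, cy 0-based; returns modified matrix
  H <- nrow(m); W <- ncol(m)
  x0 <- max(0, cx - r); x1 <- min(W - 1, cx + r)
  y0 <- max(0, cy - r); y1 <- min(H - 1, cy + r)
  for (x in x0:x1) for (y in y0:y1)
    if ((x - cx)^2 + (y - cy)^2 <= r^2) m[y + 1, x + 1] <- value
  m
}

.paintRegions <- function(gtlab, spec) {
  H <- spec$H; W <- spec$W
  n <- spec$n_regions
  pairs <- .adjacencyPairs(gtlab)
  nbrs <- split(pairs[, 2], factor(pairs[, 1], levels = 1:n))
  # background regions: mutually non-adjacent, chosen in random order
  n_bg <- round(spec$background_frac * n)
  is_bg <- logical(n)
  for (i in sample.int(n)) {
    if (sum(is_bg) >= n_bg) break
    if (!any(is_bg[nbrs[[i]]])) is_bg[i] <- TRUE
  }
  # fibre colour profiles: independent random draw per fibre, as in
  # stochastic confetti recombination -- adjacent fibres may share a
  # profile and are then distinguishable only by the membrane ridge,
  # which is the hard case the edge criteria exist for
  np <- nrow(.FIBER_PROFILES)
  idx <- sample.int(np, n, replace = TRUE)
  base <- .FIBER_PROFILES[idx, , drop = FALSE] +
    matrix(stats::rnorm(3 * n, 0, spec$intensity_jitter), n, 3)
  if (any(is_bg))
    base[is_bg, ] <- matrix(.BG_PROFILE, sum(is_bg), 3, byrow = TRUE) +
      matrix(stats::rnorm(3 * sum(is_bg), 0, 2), sum(is_bg), 3)
  base <- pmin(pmax(base, 0), 255)
  cc <- matrix(base[gtlab, 1], H, W)
  yy <- matrix(base[gtlab, 2], H, W)
  rr <- matrix(base[gtlab, 3], H, W)
  # cyan membrane ridge along region borders
  if (n > 1) {
    bmask <- cpp_boundary_mask(gtlab)
    cc[bmask] <- pmax(cc[bmask], spec$membrane_intensity)
  }
  gg <- matrix(0, H, W)
  # artifact holes: near-zero in all channels
  holes <- list()
  if (spec$n_holes > 0) {
    for (h in seq_len(spec$n_holes)) {
      r <- sample(spec$hole_radius[1]:spec$hole_radius[2], 1)
      hx <- sample(0:(W - 1), 1)
      hy <- sample(0:(H - 1), 1)
      holes[[h]] <- c(hx, hy, r)
      cc <- .stampDisk(cc, hx, hy, r, 2)
      yy <- .stampDisk(yy, hx, hy, r, 2)
      rr <- .stampDisk(rr, hx, hy, r, 2)
    }
  }
  # nuclei: green disks fully inside a single non-background region,
  # non-touching, clear of holes
  nuc_mask <- matrix(FALSE, H, W)
  centers <- matrix(numeric(0), 0, 3)
  if (spec$n_nuclei > 0) {
    max_try <- 400 * spec$n_nuclei
    tries <- 0
    while (nrow(centers) < spec$n_nuclei) {
      tries <- tries + 1
      if (tries > max_try)
        stop("infeasible nucleus placement after bounded retries")
      r <- sample(spec$nucleus_radius[1]:spec$nucleus_radius[2], 1)
      cx <- sample(r:(W - 1 - r), 1)
      cy <- sample(r:(H - 1 - r), 1)
      lab0 <- gtlab[cy + 1, cx + 1]
      if (is_bg[lab0]) next
      # whole disk inside one region (margin 2 px from the border)
      rm2 <- r + 2
      probe_x <- c(cx - rm2, cx + rm2, cx, cx, cx - r, cx + r, cx - r, cx + r)
      probe_y <- c(cy, cy, cy - rm2, cy + rm2, cy - r, cy - r, cy + r, cy + r)
      inb <- probe_x >= 0 & probe_x < W & probe_y >= 0 & probe_y < H
      if (!all(inb)) next
      if (any(gtlab[cbind(probe_y + 1, probe_x + 1)] != lab0)) next
      if (length(holes) && any(vapply(holes, function(hh)
        (hh[1] - cx)^2 + (hh[2] - cy)^2 <= (hh[3] + r + 2)^2,
        logical(1)))) next
      if (nrow(centers) > 0 &&
          any((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 <=
              (centers[, 3] + r + 4)^2)) next
      centers <- rbind(centers, c(cx, cy, r))
      gg <- .stampDisk(gg, cx, cy, r, 200)
      nuc_mask <- .stampDisk(nuc_mask, cx, cy, r, TRUE)
    }
  }
  for (h in seq_along(holes))
    gg <- .stampDisk(gg, holes[[h]][1], holes[[h]][2], holes[[h]][3], 0)
  blur <- function(m) .gblur(m, spec$border_blur_sigma)
  cc <- blur(cc); yy <- blur(yy); rr <- blur(rr); gg <- blur(gg)
  if (spec$noise_sd > 0) {
    addn <- function(m) m + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    cc <- addn(cc); yy <- addn(yy); rr <- addn(rr); gg <- addn(gg)
  }
  clip <- function(m) pmin(pmax(m, 0), 255)
  img <- MultiChannelImage(cyan = clip(cc), green = clip(gg),
                           yellow = clip(yy), red = clip(rr))
  nuc_lab <- matrix(0L, H, W)
  if (nrow(centers) > 0)
    for (i in seq_len(nrow(centers)))
      nuc_lab <- .stampDisk(nuc_lab, centers[i, 1], centers[i, 2],
                            centers[i, 3], i)
  nuclei <- new("NucleiMask", mask = nuc_mask,
                components = .measureComponents(nuc_lab))
  list(image = img, gt = LabelMap(gtlab), nuclei = nuclei)
}

#' Generate a cross-section-like confetti mosaic
#'
#' Voronoi partition of the image into \code{n_regions} cells, painted
#' with fibre colour profiles (adjacent regions never share a profile),
#' a cyan membrane ridge along borders, optional background regions and
#' artifact holes, green nuclear disks, Gaussian border blur and additive
#' noise.  Reproducible bit-for-bit from \code{spec$seed}.
#'
#' @param spec a \code{\link{mosaicSpec}}.
#' @return list with \code{image} (\linkS4class{MultiChannelImage}),
#'   \code{gt} (\linkS4class{LabelMap}) and \code{nuclei}
#'   (\linkS4class{NucleiMask}); the spec is attached as attribute
#'   \code{"spec"}.
#' @export
generateMosaic <- function(spec) {
  stopifnot(inherits(spec, "MosaicSpec"))
  out <- .withSeed(spec$seed, {
    H <- spec$H; W <- spec$W; n <- spec$n_regions
    pos <- sample.int(H * W, n)
    sy <- (pos - 1) %% H
    sx <- (pos - 1) %/% H
    best <- matrix(Inf, H, W)
    gtlab <- matrix(1L, H, W)
    ygrid <- (seq_len(H) - 1)
    xgrid <- (seq_len(W) - 1)
    for (i in seq_len(n)) {
      d2 <- outer((ygrid - sy[i])^2, (xgrid - sx[i])^2, "+")
      upd <- d2 < best
      best[upd] <- d2[upd]
      gtlab[upd] <- i
    }
    .paintRegions(gtlab, spec)
  })
  attr(out, "spec") <- spec
  out
}

#' Generate a lateral-section-like stripe mosaic
#'
#' As \code{\link{generateMosaic}} but the ground-truth regions are long
#' horizontal stripes with wavy borders, emulating the extreme aspect
#' ratio of fibres in lateral sections.  Every stripe spans the full
#' width and is at least 3 px tall.
#'
#' @param spec a \code{\link{mosaicSpec}}; \code{n_regions} is the stripe
#'   count.
#' @return As \code{\link{generateMosaic}}.
#' @export
generateLateral <- function(spec) {
  stopifnot(inherits(spec, "MosaicSpec"))
  out <- .withSeed(spec$seed, {
    H <- spec$H; W <- spec$W; n <- spec$n_regions
    x <- (seq_len(W) - 1)
    bounds <- matrix(0, max(n - 1, 0), W)
    if (n > 1) {
      amp_max <- max(1, (H / n) / 3)
      for (k in seq_len(n - 1)) {
        a1 <- stats::runif(1, amp_max / 3, amp_max)
        a2 <- stats::runif(1, 0, amp_max / 2)
        f1 <- sample(1:3, 1)
        f2 <- sample(2:5, 1)
        ph1 <- stats::runif(1, 0, 2 * pi)
        ph2 <- stats::runif(1, 0, 2 * pi)
        bounds[k, ] <- H * k / n + a1 * sin(2 * pi * f1 * x / W + ph1) +
          a2 * sin(2 * pi * f2 * x / W + ph2)
      }
      # enforce a minimum stripe height of 3 px
      for (k in seq_len(n - 1)) {
        lower <- if (k == 1) 3 else bounds[k - 1, ] + 3
        bounds[k, ] <- pmax(bounds[k, ], lower)
        bounds[k, ] <- pmin(bounds[k, ], H - 3 * (n - k))
      }
    }
    gtlab <- matrix(1L, H, W)
    if (n > 1) {
      for (k in seq_len(n - 1)) {
        below <- outer((seq_len(H) - 1), bounds[k, ], ">=")
        gtlab <- gtlab + below
      }
    }
    storage.mode(gtlab) <- "integer"
    .paintRegions(gtlab, spec)
  })
  attr(out, "spec") <- spec
  out
}
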