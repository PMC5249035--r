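# Brute-force reference implementations used as independent oracles.
# These deliberately share no code with the package internals: direct
# sorting, exhaustive window scans and double loops throughout.

oracle_percentile <- function(v, p) {
  # linear-interpolation order statistic computed by direct sorting
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_rescale <- function(m, lo_pct, hi_pct) {
  lo <- oracle_percentile(as.vector(m), lo_pct)
  hi <- oracle_percentile(as.vector(m), hi_pct)
  if (hi <= lo) return(matrix(0, nrow(m), ncol(m)))
  out <- (m - lo) / (hi - lo) * 255
  pmin(pmax(out, 0), 255)
}

oracle_median_filter <- function(m, radius) {
  H <- nrow(m); W <- ncol(m)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n - i + 1
    }
    i
  }
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    vals <- c()
    for (di in -radius:radius) for (dj in -radius:radius)
      vals <- c(vals, m[refl(i + di, H), refl(j + dj, W)])
    out[i, j] <- sort(vals)[(length(vals) + 1) / 2]
  }
  out
}

oracle_bresenham <- function(x0, y0, x1, y1) {
  # independent R implementation, canonicalized like the package contract
  if (x1 < x0 || (x1 == x0 && y1 < y0)) {
    tmp <- c(x0, y0); x0 <- x1; y0 <- y1; x1 <- tmp[1]; y1 <- tmp[2]
  }
  dx <- abs(x1 - x0); sx <- if (x0 < x1) 1 else -1
  dy <- -abs(y1 - y0); sy <- if (y0 < y1) 1 else -1
  err <- dx + dy
  pts <- matrix(c(x0, y0), 1, 2)
  while (!(x0 == x1 && y0 == y1)) {
    e2 <- 2 * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
    pts <- rbind(pts, c(x0, y0))
  }
  pts
}

oracle_line_max <- function(p, x0, y0, x1, y1) {
  pts <- oracle_bresenham(x0, y0, x1, y1)
  max(p[cbind(pts[, 2] + 1, pts[, 1] + 1)])
}

oracle_chi2 <- function(P, Q) {
  tot <- 0
  for (k in seq_along(P)) {
    s <- P[k] + Q[k]
    if (s > 0) tot <- tot + (P[k] - Q[k])^2 / s
  }
  tot / 2
}

oracle_edge_strength <- function(p, lab, i, j) {
  H <- nrow(lab); W <- ncol(lab)
  vals <- c()
  for (r in 1:H) for (cl in 1:W) {
    if (lab[r, cl] != i) next
    nb <- c(if (r > 1) lab[r - 1, cl], if (r < H) lab[r + 1, cl],
            if (cl > 1) lab[r, cl - 1], if (cl < W) lab[r, cl + 1])
    if (any(nb == j)) vals <- c(vals, p[r, cl])
  }
  mean(vals)
}

oracle_boundary_pixels <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  b <- matrix(FALSE, H, W)
  for (r in 1:H) for (cl in 1:W) {
    nb <- c(if (r > 1) lab[r - 1, cl], if (r < H) lab[r + 1, cl],
            if (cl > 1) lab[r, cl - 1], if (cl < W) lab[r, cl + 1])
    b[r, cl] <- any(nb != lab[r, cl])
  }
  b
}

oracle_boundary_recall <- function(pred, gt, d) {
  gb <- oracle_boundary_pixels(gt)
  pb <- oracle_boundary_pixels(pred)
  H <- nrow(gt); W <- ncol(gt)
  idx <- which(gb, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("no gt edges")
  hit <- 0
  for (t in seq_len(nrow(idx))) {
    r <- idx[t, 1]; cl <- idx[t, 2]
    rs <- max(1, r - d):min(H, r + d)
    cs <- max(1, cl - d):min(W, cl + d)
    if (any(pb[rs, cs])) hit <- hit + 1
  }
  hit / nrow(idx)
}

oracle_use <- function(pred, gt) {
  N <- length(pred)
  tot <- 0
  for (g in unique(as.vector(gt))) {
    gm <- gt == g
    for (s in unique(as.vector(pred[gm]))) {
      sm <- pred == s
      inside <- sum(sm & gm)
      outside <- sum(sm & !gm)
      tot <- tot + min(inside, outside)
    }
  }
  tot / N
}

oracle_dice <- function(X, Y) {
  if (sum(X) + sum(Y) == 0) return(1)
  2 * sum(X & Y) / (sum(X) + sum(Y))
}

oracle_med_dsc <- function(pred, gt) {
  gl <- sort(unique(as.vector(gt)))
  dscs <- sapply(gl, function(g) {
    gm <- gt == g
    pl <- sort(unique(as.vector(pred)))
    ov <- sapply(pl, function(s) sum(gm & pred == s))
    f <- pl[which.max(ov)]
    oracle_dice(gm, pred == f)
  })
  list(medDSC = median(dscs), dsc = dscs)
}

.adjacent_pair <- function(lab) {
  # one random 4-adjacent (directed) label pair of a label map
  H <- nrow(lab); W <- ncol(lab)
  pairs <- unique(rbind(
    cbind(as.vector(lab[, -W]), as.vector(lab[, -1])),
    cbind(as.vector(lab[-H, ]), as.vector(lab[-1, ]))))
  pairs <- rbind(pairs, pairs[, 2:1])
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs[sample(nrow(pairs), 1), ]
}

# random label map with L blobs (nearest-seed partition, connected regions)
random_label_map <- function(H, W, L) {
  pos <- sample.int(H * W, L)
  sy <- (pos - 1) %% H
  sx <- (pos - 1) %/% H
  best <- matrix(Inf, H, W)
  lab <- matrix(1L, H, W)
  for (i in seq_len(L)) {
    d2 <- outer(((1:H) - 1 - sy[i])^2, ((1:W) - 1 - sx[i])^2, "+")
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- i
  }
  lab
}
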