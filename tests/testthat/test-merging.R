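# helper: a label map of two vertical superpixels over a given image
two_sp <- function(H = 20, W = 20) {
  LabelMap(matrix(rep(c(1L, 2L), each = W / 2 * H), H, W)[, ])
}

test_that("chi-squared histogram distance follows the definition", {
  expect_equal(chi2Distance(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(chi2Distance(c(1, 0), c(0, 1)), 1)
  expect_error(chi2Distance(c(1, 0), c(1, 0, 0)), "bin")
  set.seed(60)
  for (t in 1:50) {
    P <- runif(16); P <- P / sum(P)
    Q <- runif(16); Q <- Q / sum(Q)
    expect_equal(chi2Distance(P, Q), oracle_chi2(P, Q), tolerance = 1e-12)
  }
  # empty bins contribute zero
  expect_equal(chi2Distance(c(0.5, 0.5, 0), c(0.5, 0.5, 0)), 0)
})

test_that("region distance combines the three per-channel chi2 values", {
  fx <- small_mosaic(seed = 61)
  norm <- normalizeImage(fx$image)
  edge <- edgeProbability(norm)
  sp <- runSlicMmed(norm, edge, K = 30)
  g <- buildRegionGraph(sp, norm, edge)
  expect_equal(regionDistance(g, 3, 3), 0)
  for (t in 1:20) {
    ij <- sample(length(g@sizes), 2)
    x2 <- sapply(1:3, function(ch)
      oracle_chi2(g@histograms[ij[1], ch, ], g@histograms[ij[2], ch, ]))
    expect_equal(regionDistance(g, ij[1], ij[2]), sqrt(sum(x2^2)),
                 tolerance = 1e-12)
  }
  expect_error(regionDistance(g, 1, length(g@sizes) + 5), "unknown")
  # histograms are normalized
  expect_true(all(abs(apply(g@histograms, 1:2, sum) - 1) < 1e-9))
})

test_that("edge strength is the mean border probability, directed", {
  lab <- two_sp()
  e0 <- EdgeMap(matrix(0, 20, 20))
  expect_equal(edgeStrength(e0, lab, 1, 2), 0)
  ec <- EdgeMap(matrix(0.4, 20, 20))
  expect_equal(edgeStrength(ec, lab, 1, 2), 0.4)
  set.seed(62)
  p <- matrix(runif(400), 20, 20)
  er <- EdgeMap(p)
  m <- labelMatrix(lab)
  expect_equal(edgeStrength(er, lab, 1, 2), oracle_edge_strength(p, m, 1, 2))
  expect_equal(edgeStrength(er, lab, 2, 1), oracle_edge_strength(p, m, 2, 1))
  # non-adjacent pair errors
  lab3 <- LabelMap(matrix(rep(1:3, each = 100), 10, 30))
  expect_error(edgeStrength(er, lab3, 1, 3), "not adjacent")
})

test_that("identical-colour neighbors merge only across weak edges", {
  img <- make_img(20, 20, c(cyan = 80, yellow = 120, red = 40))
  sp <- two_sp()
  merged <- mergeSuperpixels(sp, img, EdgeMap(matrix(0, 20, 20)),
                             thres_size = 1)
  expect_equal(nLabels(merged), 1)
  # same colours but an impassable border
  p <- matrix(0, 20, 20)
  p[, 10:11] <- 1
  merged2 <- mergeSuperpixels(sp, img, EdgeMap(p), thres_edge = 0.1,
                              thres_size = 1)
  expect_equal(nLabels(merged2), 2)
})

test_that("the size cap blocks bright fibres but not background", {
  img_bright <- make_img(20, 20, c(cyan = 80, yellow = 120, red = 40))
  img_dark <- make_img(20, 20, c(cyan = 3, yellow = 2, red = 2))
  sp <- two_sp()
  e0 <- EdgeMap(matrix(0, 20, 20))
  # union (400 px) exceeds thres_size (0.5 * 400 = 200 px)
  expect_equal(nLabels(mergeSuperpixels(sp, img_bright, e0,
                                        thres_size = 0.5)), 2)
  expect_equal(nLabels(mergeSuperpixels(sp, img_dark, e0,
                                        thres_size = 0.5, thres_bg = 10)), 1)
})

test_that("merging is a coarsening, terminates, and is idempotent", {
  fx <- small_mosaic(seed = 63)
  norm <- normalizeImage(fx$image)
  edge <- edgeProbability(norm)
  sp <- runSlicMmed(norm, edge, K = 60)
  merged <- mergeSuperpixels(sp, norm, edge)
  expect_lte(nLabels(merged), nLabels(sp))
  # coarsening: every input superpixel maps to exactly one output region
  spl <- split(as.vector(labelMatrix(merged)), as.vector(labelMatrix(sp)))
  expect_true(all(vapply(spl, function(v) length(unique(v)) == 1, logical(1))))
  # idempotence at the fixpoint
  again <- mergeSuperpixels(merged, norm, edge)
  expect_identical(labelMatrix(again), labelMatrix(merged))
})

test_that("merge along a path unions exactly the traversed labels", {
  lab3 <- LabelMap(matrix(rep(c(3L, 7L, 9L), each = 100), 10, 30))
  out <- mergeAlongPath(lab3, rbind(c(2, 5), c(27, 5)))
  expect_identical(sort(unique(as.vector(labelMatrix(out)))), 3L)
  # path within one region changes nothing
  out2 <- mergeAlongPath(lab3, rbind(c(1, 1), c(8, 8)))
  expect_identical(labelMatrix(out2), labelMatrix(lab3))
  expect_error(mergeAlongPath(lab3, matrix(numeric(0), 0, 2)), "empty")
  # random polylines agree with the raster-membership oracle
  set.seed(64)
  m <- random_label_map(24, 24, 8)
  lm <- LabelMap(m)
  for (t in 1:20) {
    pts <- cbind(sample(0:23, 3, TRUE), sample(0:23, 3, TRUE))
    hit <- unique(c(
      m[cbind(oracle_bresenham(pts[1, 1], pts[1, 2], pts[2, 1], pts[2, 2])[, 2] + 1,
              oracle_bresenham(pts[1, 1], pts[1, 2], pts[2, 1], pts[2, 2])[, 1] + 1)],
      m[cbind(oracle_bresenham(pts[2, 1], pts[2, 2], pts[3, 1], pts[3, 2])[, 2] + 1,
              oracle_bresenham(pts[2, 1], pts[2, 2], pts[3, 1], pts[3, 2])[, 1] + 1)]))
    out <- mergeAlongPath(lm, pts)
    om <- labelMatrix(out)
    expect_true(all(om[m %in% hit] == min(hit)))
    expect_identical(om[!(m %in% hit)], m[!(m %in% hit)])
  }
})

test_that("restoring superpixels inverts a path merge on the footprint", {
  set.seed(65)
  orig <- LabelMap(random_label_map(32, 32, 10))
  merged <- mergeAlongPath(orig, rbind(c(2, 2), c(29, 29)))
  pos <- c(2, 2)
  restored <- restoreSuperpixels(merged, orig, pos, Inf)
  # partition equality up to renaming
  a <- as.vector(labelMatrix(restored))
  b <- as.vector(labelMatrix(orig))
  expect_equal(length(unique(a)), length(unique(b)))
  expect_true(all(tapply(a, b, function(v) length(unique(v))) == 1))
  expect_true(all(tapply(b, a, function(v) length(unique(v))) == 1))
  # a never-merged region is returned unchanged
  same <- restoreSuperpixels(orig, orig, c(5, 5), Inf)
  expect_identical(labelMatrix(same), labelMatrix(orig))
  expect_error(restoreSuperpixels(merged, orig, c(40, 2)), "outside")
})

test_that("partial-radius restore composes disk and region masks", {
  orig <- LabelMap(matrix(rep(c(1L, 2L, 3L, 4L), each = 160), 16, 40))
  merged <- mergeAlongPath(orig, rbind(c(1, 8), c(38, 8)))
  r <- 6
  pos <- c(20, 8)
  out <- restoreSuperpixels(merged, orig, pos, r)
  om <- labelMatrix(out)
  mm <- labelMatrix(merged)
  oo <- labelMatrix(orig)
  for (x in 0:39) for (y in 0:15) {
    inside <- (x - 20)^2 + (y - 8)^2 <= r^2 && mm[y + 1, x + 1] == mm[9, 21]
    if (inside) {
      expect_equal(om[y + 1, x + 1] - max(mm), oo[y + 1, x + 1])
    } else {
      expect_equal(om[y + 1, x + 1], mm[y + 1, x + 1])
    }
  }
})

test_that("nuclei stamping adds one label per component", {
  seg <- LabelMap(matrix(rep(c(1L, 2L), each = 200), 20, 20))
  empty <- new("NucleiMask", mask = matrix(FALSE, 20, 20),
               components = data.frame())
  expect_identical(labelMatrix(combineWithNuclei(seg, empty)),
                   labelMatrix(seg))
  mask <- matrix(FALSE, 20, 20)
  mask[5:8, 8:13] <- TRUE  # straddles both fibre labels
  nuc <- new("NucleiMask", mask = mask, components = data.frame(label = 1))
  out <- combineWithNuclei(seg, nuc)
  om <- labelMatrix(out)
  expect_equal(nLabels(out), 3)
  expect_true(all(om[mask] == max(om)))
  expect_identical(om[!mask], labelMatrix(seg)[!mask])
  badmask <- new("NucleiMask", mask = matrix(FALSE, 10, 10),
                 components = data.frame())
  expect_error(combineWithNuclei(seg, badmask), "shape")
})
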