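test_that("centroid seeding follows the S = sqrt(N/K) grid", {
  img <- make_img(100, 100)
  st <- initCentroids(img, 25, zero_edge(100, 100))
  expect_equal(st@S, 20)
  expect_equal(nrow(st@centroids), 25)
  # uniform gradient: centroids stay exactly on the grid
  expect_setequal(st@centroids[, 4], c(10, 30, 50, 70, 90))
  expect_setequal(st@centroids[, 5], c(10, 30, 50, 70, 90))
  expect_error(initCentroids(img, 100 * 100 + 1, zero_edge(100, 100)), "K")
})

test_that("a gradient pit pulls its centroid by one pixel", {
  img <- make_img(100, 100)
  g <- matrix(1, 100, 100)
  g[10 + 1, 9 + 1] <- 0  # pit at (x=9, y=10), one left of seed (10, 10)
  st <- initCentroids(img, 25, g)
  moved <- st@centroids[st@centroids[, 5] == 10 & st@centroids[, 4] < 15, ]
  expect_equal(unname(moved[4]), 9)
  expect_equal(unname(moved[5]), 10)
  # exhaustive 3x3 argmin check for every centroid
  for (k in seq_len(nrow(st@centroids))) {
    cx <- st@centroids[k, 4]; cy <- st@centroids[k, 5]
    xs <- max(0, cx - 1):min(99, cx + 1)
    ys <- max(0, cy - 1):min(99, cy + 1)
    expect_equal(g[cy + 1, cx + 1], min(g[ys + 1, xs + 1]))
  }
})

test_that("pixel distance reproduces the D' formula", {
  # centroid and pixel colours/positions chosen so that d_c = m, d_s = S
  H <- 100; W <- 100
  planes <- list(cyan = matrix(0, H, W), yellow = matrix(0, H, W),
                 red = matrix(0, H, W))
  planes$cyan[50 + 1, 70 + 1] <- 20          # d_c = 20 = m at pixel (70, 50)
  img <- MultiChannelImage(planes)
  st <- new("SuperpixelState",
            centroids = matrix(c(0, 0, 0, 50, 50), 1), S = 20, m = 20,
            alpha = 20)
  # identical pixel: zero distance
  expect_equal(pixelDistance(st, 1, c(50, 50),
                             MultiChannelImage(cyan = matrix(0, H, W),
                                               yellow = matrix(0, H, W),
                                               red = matrix(0, H, W)),
                             zero_edge(H, W)), 0)
  # d_c = m and d_s = S: D' = sqrt(2) with no edge term
  expect_equal(pixelDistance(st, 1, c(70, 50), img, zero_edge(H, W)),
               sqrt(2))
  # with d_e = 1 and alpha = 20: D' = sqrt(22)
  expect_equal(pixelDistance(st, 1, c(70, 50), img,
                             EdgeMap(matrix(1, H, W))), sqrt(22))
})

test_that("K = 1 yields a single label covering the image", {
  img <- make_img(40, 40)
  lab <- runSlicMmed(img, zero_edge(40, 40), K = 1)
  expect_equal(nLabels(lab), 1)
  expect_true(all(labelMatrix(lab) == 1))
})

test_that("superpixels partition the image into connected regions", {
  fx <- small_mosaic(seed = 51)
  norm <- normalizeImage(fx$image)
  edge <- edgeProbability(norm)
  lab <- runSlicMmed(norm, edge, K = 60)
  m <- labelMatrix(lab)
  L <- max(m)
  expect_true(all(m >= 1))
  expect_identical(sort(unique(as.vector(m))), 1:L)
  expect_equal(sum(tabulate(m)), length(m))
  # 4-connectivity of every label
  for (l in seq_len(L)) {
    cc <- EBImage::bwlabel(EBImage::Image((m == l) * 1))
    expect_equal(max(cc), 1)
  }
})

test_that("with a zero edge map SLIC-MMED equals plain SLIC bit for bit", {
  fx <- small_mosaic(seed = 52)
  norm <- normalizeImage(fx$image)
  e0 <- zero_edge(128, 128)
  a <- runSlicMmed(norm, e0, K = 50, edgeAware = TRUE)
  b <- runSlicMmed(norm, e0, K = 50, edgeAware = FALSE)
  expect_identical(labelMatrix(a), labelMatrix(b))
})

test_that("the algorithm is deterministic", {
  fx <- small_mosaic(seed = 53)
  norm <- normalizeImage(fx$image)
  edge <- edgeProbability(norm)
  a <- runSlicMmed(norm, edge, K = 40)
  b <- runSlicMmed(norm, edge, K = 40)
  expect_identical(labelMatrix(a), labelMatrix(b))
})

test_that("a strong two-region edge is recalled perfectly at K = 50", {
  two <- make_two_region_img(64, 64)
  edge <- edgeProbability(two$img)
  lab <- runSlicMmed(two$img, edge, K = 50, alpha = 20)
  expect_equal(boundaryRecall(lab, two$gt, d = 2), 1.0)
})

test_that("missing fibre channels raise an error", {
  img <- MultiChannelImage(cyan = matrix(0, 16, 16),
                           green = matrix(0, 16, 16))
  expect_error(runSlicMmed(img, zero_edge(16, 16), K = 4),
               "missing.*yellow.*red|yellow, red")
})
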