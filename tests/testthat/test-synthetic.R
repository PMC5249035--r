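test_that("generation is reproducible bit for bit from the seed", {
  a <- small_mosaic(seed = 80)
  b <- small_mosaic(seed = 80)
  for (ch in channelNames(a$image))
    expect_identical(getPlane(a$image, ch), getPlane(b$image, ch))
  expect_identical(labelMatrix(a$gt), labelMatrix(b$gt))
  expect_identical(nucleiMaskMatrix(a$nuclei), nucleiMaskMatrix(b$nuclei))
  c <- small_mosaic(seed = 81)
  expect_false(identical(getPlane(a$image, "red"), getPlane(c$image, "red")))
})

test_that("region and nucleus counts match the spec exactly", {
  fx <- generateMosaic(mosaicSpec(H = 192, W = 192, n_regions = 20,
                                  n_nuclei = 15, nucleus_radius = c(3, 5),
                                  seed = 82))
  expect_equal(nLabels(fx$gt), 20)
  expect_true(all(labelSizes(fx$gt) > 0))
  comp <- EBImage::bwlabel(EBImage::Image(nucleiMaskMatrix(fx$nuclei) * 1))
  expect_equal(max(comp), 15)
  expect_equal(nrow(nucleiComponents(fx$nuclei)), 15)
})

test_that("noise-free, blur-free mosaics are piecewise constant off-membrane", {
  fx <- generateMosaic(mosaicSpec(H = 96, W = 96, n_regions = 5,
                                  noise_sd = 0, border_blur_sigma = 0,
                                  n_nuclei = 0, n_holes = 0,
                                  background_frac = 0, seed = 83))
  gt <- labelMatrix(fx$gt)
  b <- slicmmed:::cpp_boundary_mask(gt)
  interior <- !b
  for (ch in c("cyan", "yellow", "red")) {
    pl <- getPlane(fx$image, ch)
    per_region <- tapply(pl[interior], gt[interior], function(v)
      length(unique(v)))
    expect_true(all(per_region == 1))
  }
  # degenerate single-region mosaic: constant planes everywhere
  one <- generateMosaic(mosaicSpec(H = 48, W = 48, n_regions = 1,
                                   noise_sd = 0, border_blur_sigma = 0,
                                   n_nuclei = 0, n_holes = 0,
                                   background_frac = 0, seed = 84))
  expect_equal(length(unique(as.vector(getPlane(one$image, "red")))), 1)
  expect_equal(nLabels(one$gt), 1)
})

test_that("nuclei appear only in the green plane", {
  base <- mosaicSpec(H = 96, W = 96, n_regions = 4, noise_sd = 0,
                     border_blur_sigma = 0, n_holes = 0,
                     background_frac = 0, seed = 85)
  with_n <- generateMosaic(base)
  base0 <- base
  base0$n_nuclei <- 0
  without_n <- generateMosaic(base0)
  # same seed: identical region geometry and colours in the fibre channels
  for (ch in c("cyan", "yellow", "red"))
    expect_identical(getPlane(with_n$image, ch), getPlane(without_n$image, ch))
  expect_gt(max(getPlane(with_n$image, "green")), 150)
})

test_that("lateral mosaics are full-width stripes at least 3 px tall", {
  fx <- generateLateral(mosaicSpec(H = 128, W = 256, n_regions = 8,
                                   n_nuclei = 0, n_holes = 0, seed = 86))
  gt <- labelMatrix(fx$gt)
  expect_equal(nLabels(fx$gt), 8)
  for (l in 1:8) {
    cols <- unique(which(gt == l, arr.ind = TRUE)[, 2])
    expect_equal(length(cols), 256)  # spans the full width
    heights <- tapply(which(gt == l, arr.ind = TRUE)[, 1],
                      which(gt == l, arr.ind = TRUE)[, 2], length)
    expect_gte(min(heights), 3)
  }
  # reproducibility
  fy <- generateLateral(mosaicSpec(H = 128, W = 256, n_regions = 8,
                                   n_nuclei = 0, n_holes = 0, seed = 86))
  expect_identical(labelMatrix(fx$gt), labelMatrix(fy$gt))
})

test_that("infeasible nucleus placement errors after bounded retries", {
  expect_error(
    generateMosaic(mosaicSpec(H = 40, W = 40, n_regions = 2, n_nuclei = 60,
                              nucleus_radius = c(5, 6), seed = 87)),
    "infeasible")
})
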