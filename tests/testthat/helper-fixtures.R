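# Fixture builders shared across test files.  Everything is generated in
# code; nothing is read from disk.

make_img <- function(H = 16, W = 16, value = c(cyan = 50, yellow = 100,
                                               red = 150)) {
  planes <- lapply(value, function(v) matrix(v, H, W))
  names(planes) <- names(value)
  MultiChannelImage(planes)
}

# two vertical half-plane regions with distinct colours and a sharp border
make_two_region_img <- function(H = 32, W = 32, left = c(40, 200, 30),
                                right = c(40, 30, 200)) {
  half <- W %/% 2
  mk <- function(ch) {
    m <- matrix(left[ch], H, W)
    m[, (half + 1):W] <- right[ch]
    m
  }
  list(img = MultiChannelImage(cyan = mk(1), yellow = mk(2), red = mk(3)),
       gt = LabelMap(matrix(rep(c(1L, 2L), c(half, W - half)),
                            H, W, byrow = TRUE)))
}

zero_edge <- function(H, W) EdgeMap(matrix(0, H, W))

small_mosaic <- function(seed = 42, H = 128, W = 128, n_regions = 6,
                         n_nuclei = 3, ...) {
  generateMosaic(mosaicSpec(H = H, W = W, n_regions = n_regions,
                            n_nuclei = n_nuclei, n_holes = 1,
                            nucleus_radius = c(3, 5), seed = seed, ...))
}

# Cache for the expensive acceptance-scale computations, shared between
# the superpixel-quality and segmentation-quality acceptance tests.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_mosaics <- function() {
  if (!is.null(.acceptance_cache$mosaics)) return(.acceptance_cache$mosaics)
  .acceptance_cache$mosaics <- lapply(1:10, function(i)
    generateMosaic(mosaicSpec(seed = 1000 + i)))
  .acceptance_cache$mosaics
}

acceptance_prep <- function() {
  # normalized image, edge map and ground truth per acceptance mosaic
  if (!is.null(.acceptance_cache$prep)) return(.acceptance_cache$prep)
  .acceptance_cache$prep <- lapply(acceptance_mosaics(), function(fx) {
    norm <- normalizeImage(fx$image)
    list(norm = norm, edge = edgeProbability(norm), gt = fx$gt)
  })
  .acceptance_cache$prep
}

acceptance_sweep <- function() {
  # superpixel label maps for both modes at the three sweep K values
  if (!is.null(.acceptance_cache$sweep)) return(.acceptance_cache$sweep)
  .acceptance_cache$sweep <- lapply(acceptance_prep(), function(p) {
    out <- list()
    for (K in c(200, 400, 800)) {
      out[[paste0("mmed_", K)]] <-
        runSlicMmed(p$norm, p$edge, K = K, edgeAware = TRUE)
      out[[paste0("plain_", K)]] <-
        runSlicMmed(p$norm, p$edge, K = K, edgeAware = FALSE)
    }
    out
  })
  .acceptance_cache$sweep
}
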