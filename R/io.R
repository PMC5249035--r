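# Label-map and overlay I/O.  PNG files are 8-bit per sample, so label
# maps are stored as 16-bit values split across the red (high byte) and
# green (low byte) channels; the run-length CSV is the lossless text
# export.

#' Write a label map as a 16-bit-encoded PNG
#'
#' Labels (up to 65535) are encoded with the high byte in the red channel
#' and the low byte in the green channel.
#'
#' @param x a \linkS4class{LabelMap}.
#' @param path output PNG file.
#' @return invisibly, the path.
#' @export
exportLabelMapPNG <- function(x, path) {
  lab <- x@labels
  if (max(lab) > 65535) stop("more than 65535 labels")
  arr <- array(0, c(nrow(lab), ncol(lab), 3))
  arr[, , 1] <- (lab %/% 256) / 255
  arr[, , 2] <- (lab %% 256) / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' Read a label map written by \code{exportLabelMapPNG}
#' @param path PNG file.
#' @return A \linkS4class{LabelMap}.
#' @export
importLabelMapPNG <- function(path) {
  arr <- png::readPNG(path)
  lab <- round(arr[, , 1] * 255) * 256 + round(arr[, , 2] * 255)
  storage.mode(lab) <- "integer"
  LabelMap(lab)
}

#' Write a label map as a run-length-encoded CSV
#'
#' Column-major run-length encoding: columns \code{value}, \code{length},
#' with header rows recording the shape.  Lossless text export.
#'
#' @param x a \linkS4class{LabelMap}.
#' @param path output CSV file.
#' @return invisibly, the path.
#' @export
exportLabelMapCSV <- function(x, path) {
  lab <- as.vector(x@labels)
  r <- rle(lab)
  df <- data.frame(value = r$values, length = r$lengths)
  con <- file(path, "w")
  writeLines(sprintf("# H,%d", nrow(x@labels)), con)
  writeLines(sprintf("# W,%d", ncol(x@labels)), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a label map written by \code{exportLabelMapCSV}
#' @param path CSV file.
#' @return A \linkS4class{LabelMap}.
#' @export
importLabelMapCSV <- function(path) {
  hdr <- readLines(path, n = 2)
  H <- as.integer(sub("# H,", "", hdr[1]))
  W <- as.integer(sub("# W,", "", hdr[2]))
  df <- utils::read.csv(path, comment.char = "#")
  lab <- matrix(inverse.rle(list(values = df$value, lengths = df$length)),
                H, W)
  storage.mode(lab) <- "integer"
  LabelMap(lab)
}

#' Composite RGB rendering with optional boundary overlay
#'
#' Maps cyan to the blue+green display channels, yellow to red+green and
#' red to red, then draws label boundaries in white.
#'
#' @param img a normalized \linkS4class{MultiChannelImage}.
#' @param labels optional \linkS4class{LabelMap} whose boundaries to draw.
#' @param path optional PNG output.
#' @return the H x W x 3 RGB array in [0, 1], invisibly if written.
#' @export
overlayBoundaries <- function(img, labels = NULL, path = NULL) {
  d <- dim(img)
  z <- matrix(0, d[1], d[2])
  cc <- if ("cyan" %in% channelNames(img)) getPlane(img, "cyan") / 255 else z
  yy <- if ("yellow" %in% channelNames(img)) getPlane(img, "yellow") / 255 else z
  rr <- if ("red" %in% channelNames(img)) getPlane(img, "red") / 255 else z
  arr <- array(0, c(d[1], d[2], 3))
  arr[, , 1] <- pmin(rr + yy, 1)
  arr[, , 2] <- pmin(yy + cc, 1)
  arr[, , 3] <- pmin(cc, 1)
  if (!is.null(labels)) {
    b <- cpp_boundary_mask(labels@labels)
    for (ch in 1:3) {
      pl <- arr[, , ch]
      pl[b] <- 1
      arr[, , ch] <- pl
    }
  }
  if (!is.null(path)) {
    png::writePNG(arr, path)
    return(invisible(arr))
  }
  arr
}

#' Write the per-region table of a segmentation to CSV
#' @param labels a \linkS4class{LabelMap}.
#' @param img the normalized \linkS4class{MultiChannelImage}.
#' @param edge an \linkS4class{EdgeMap} (used for graph construction).
#' @param path output CSV.
#' @param thres_bg background threshold for the is_background flag.
#' @return invisibly, the table.
#' @export
exportRegionTable <- function(labels, img, edge, path, thres_bg = 10) {
  g <- buildRegionGraph(labels, img, edge, thres_bg = thres_bg)
  lab <- labels@labels
  mean_of <- function(ch) {
    pl <- getPlane(img, ch)
    as.numeric(tapply(as.vector(pl), as.vector(lab), mean))
  }
  df <- data.frame(label = seq_along(g@sizes), area = g@sizes,
                   mean_cyan = mean_of("cyan"),
                   mean_yellow = mean_of("yellow"),
                   mean_red = mean_of("red"),
                   is_background = g@isBackground)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
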