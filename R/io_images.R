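#' Load an RGB raster image
#'
#' Reads a PNG/JPEG/TIFF image into an `h x w x 3` integer array with values
#' 0–255 (rows increase downward). An alpha channel is dropped; a grayscale
#' image is replicated to three identical channels with a warning; 16-bit
#' images are rescaled to 0–255.
#'
#' @param path path to a decodable PNG, JPEG or TIFF file.
#' @return integer array `h x w x 3`, dimnames on the channel axis
#'   `c("R","G","B")`.
#' @export
load_rgb_image <- function(path) {
  if (!file.exists(path)) stop_validation("image file not found: %s", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop_validation("cannot read image '%s': %s", path,
                                    conditionMessage(e)))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) {
    warning(sprintf("'%s' is grayscale; replicating to 3 channels", path),
            call. = FALSE)
    a <- array(a, c(dim(a), 3L))
  }
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(a)[3] < 3L) a <- array(a[, , 1], c(dim(a)[1:2], 3L))
  if (any(dim(a)[1:2] == 0L)) stop_validation("zero-sized image: %s", path)
  # EBImage stores (x = col, y = row) in [0, 1]; convert to (row, col) 0-255
  out <- aperm(a, c(2, 1, 3))
  out <- array(as.integer(round_half_up(out * 255)), dim(out))
  dimnames(out) <- list(NULL, NULL, c("R", "G", "B"))
  out
}

# inverse of load_rgb_image's layout conversion; used by overlays and tests
save_rgb_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  a <- aperm(image, c(2, 1, 3)) / 255
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Write / read a label mask PNG
#'
#' Encodes a segment label matrix losslessly as a PNG: 0 = background,
#' pixel value = segment id. Up to 255 segments the file is plain 8-bit
#' grayscale; beyond that the 16-bit id is split across the red (high byte)
#' and green (low byte) channels. `read_label_mask` reverses either
#' encoding.
#'
#' @param labels integer matrix of labels (0 = background).
#' @param path PNG path.
#' @return `write_label_mask` returns `path` invisibly; `read_label_mask`
#'   returns the integer label matrix.
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) > 65535L) stop_validation("more than 65535 labels")
  if (max(labels) <= 255L) {
    EBImage::writeImage(EBImage::Image(t(labels) / 255), path)
  } else {
    a <- array(0, c(ncol(labels), nrow(labels), 3))
    a[, , 1] <- t(labels %/% 256L) / 255
    a[, , 2] <- t(labels %% 256L) / 255
    EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  }
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 2L) {
    matrix(as.integer(round_half_up(t(a) * 255)), dim(a)[2], dim(a)[1])
  } else {
    hi <- round_half_up(t(a[, , 1]) * 255)
    lo <- round_half_up(t(a[, , 2]) * 255)
    matrix(as.integer(hi * 256 + lo), dim(a)[2], dim(a)[1])
  }
}

# 3x5 bitmap digit font used to burn segment ids into overlays; keeping the
# rendering in-array makes overlay bytes deterministic across platforms
.digit_font <- lapply(list(
  c(7, 5, 5, 5, 7), c(2, 6, 2, 2, 7), c(7, 1, 7, 4, 7), c(7, 1, 7, 1, 7),
  c(5, 5, 7, 1, 1), c(7, 4, 7, 1, 7), c(7, 4, 7, 5, 7), c(7, 1, 1, 1, 1),
  c(7, 5, 7, 5, 7), c(7, 5, 7, 1, 7)
), function(rows) t(vapply(rows, function(r)
  as.integer(bitwAnd(r, c(4L, 2L, 1L)) > 0L), integer(3))))

burn_text <- function(image, row, col, text, rgb) {
  h <- dim(image)[1]; w <- dim(image)[2]
  for (ch in strsplit(text, "")[[1]]) {
    d <- suppressWarnings(as.integer(ch))
    if (!is.na(d)) {
      g <- .digit_font[[d + 1L]]
      for (i in 1:5) for (j in 1:3)
        if (g[i, j] == 1L) {
          r <- row + i - 1L; c <- col + j - 1L
          if (r >= 1 && r <= h && c >= 1 && c <= w) image[r, c, ] <- rgb
        }
    }
    col <- col + 4L
  }
  image
}

burn_box <- function(image, rmin, cmin, rmax, cmax, rgb) {
  h <- dim(image)[1]; w <- dim(image)[2]
  r0 <- max(1L, rmin - 1L); r1 <- min(h, rmax + 1L)
  c0 <- max(1L, cmin - 1L); c1 <- min(w, cmax + 1L)
  image[r0, c0:c1, ] <- rep(rgb, each = c1 - c0 + 1L)
  image[r1, c0:c1, ] <- rep(rgb, each = c1 - c0 + 1L)
  image[r0:r1, c0, ] <- rep(rgb, each = r1 - r0 + 1L)
  image[r0:r1, c1, ] <- rep(rgb, each = r1 - r0 + 1L)
  image
}

#' Save a segmentation overlay
#'
#' Writes the raw image with a red bounding box and the segment id burned in
#' above each retained segment — the headless analogue of the interactive
#' display panel.
#'
#' @param image an RGB image array from [load_rgb_image()] or
#'   [generate_scene()].
#' @param segments a `segment_set` from [segment_pipeline()] (or any data
#'   frame with columns `id, rmin, cmin, rmax, cmax`).
#' @param path output PNG path.
#' @param box_color integer RGB triple of the box color.
#' @export
save_overlay <- function(image, segments, path, box_color = c(255L, 0L, 0L)) {
  st <- if (inherits(segments, "segment_set")) segments$stats else segments
  out <- image
  if (!is.null(st) && nrow(st)) {
    for (i in seq_len(nrow(st))) {
      out <- burn_box(out, st$rmin[i], st$cmin[i], st$rmax[i], st$cmax[i],
                      box_color)
      out <- burn_text(out, max(1L, st$rmin[i] - 7L), st$cmin[i],
                       as.character(st$id[i]), box_color)
    }
  }
  save_rgb_image(out, path)
}

#' Write the per-segment measurement table
#'
#' One CSV row per retained segment with pixel measurements, plus millimeter
#' columns when a [make_scale()] reference is supplied. Row order follows
#' segment id order.
#'
#' @param measurements data frame from [measure_segments()].
#' @param path output CSV path.
#' @param scale optional `scale_ref` from [make_scale()]; adds `area_mm2`,
#'   `length_mm` and `width_mm` columns.
#' @return the written data frame, invisibly.
#' @export
write_measurements <- function(measurements, path, scale = NULL) {
  cols <- c("id", "area_px", "diagonal_px", "length_px", "width_px")
  missing_cols <- setdiff(cols, names(measurements))
  if (length(missing_cols))
    stop_validation("measurements lack column(s): %s",
                    paste(missing_cols, collapse = ", "))
  df <- measurements[order(measurements$id), , drop = FALSE]
  if (!is.null(scale)) df <- apply_scale(df, scale)
  keep <- intersect(c(cols, "area_mm2", "length_mm", "width_mm"), names(df))
  df <- df[, keep, drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Scatter plot of segment area against diagonal size
#'
#' The headless analogue of the interactive filter panel: area (pixels) on
#' the x axis, bounding-box diagonal (pixels) on the y axis, red vertical
#' lines at the area bounds and blue horizontal lines at the diagonal bounds.
#'
#' @param measurements data frame with `area_px` and `diagonal_px` columns.
#' @param thresholds a [segment_thresholds()] object.
#' @param path output PNG path.
#' @export
write_area_diagonal_plot <- function(measurements, thresholds, path) {
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  plot(measurements$area_px, measurements$diagonal_px,
       xlab = "segment area (pixels)", ylab = "diagonal size (pixels)",
       pch = 19, col = "grey30", main = "Segment size distribution")
  for (v in c(thresholds$area_min, thresholds$area_max))
    if (is.finite(v)) abline(v = v, col = "red", lwd = 2)
  for (v in c(thresholds$diag_min, thresholds$diag_max))
    if (is.finite(v)) abline(h = v, col = "blue", lwd = 2)
  invisible(path)
}
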