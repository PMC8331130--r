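# Length is the longest distance between two boundary-pixel centers; width
# is the extent of boundary-pixel projections onto the axis perpendicular to
# the length axis. Distances are between pixel centers, so a horizontal
# 1 x 5 run has length 4 and width 0.

#' Boundary pixels of a segment
#'
#' All segment pixels having at least one of their 8 neighbors outside the
#' segment (pixels beyond the canvas count as background), in deterministic
#' raster order.
#'
#' @param mask binary matrix holding one segment, or a `"segment_set"`.
#' @param id segment id, required when `mask` is a segment set.
#' @return two-column integer matrix of (row, col), 1-based.
#' @export
boundary_pixels <- function(mask, id = NULL) {
  if (inherits(mask, "segment_set")) {
    if (is.null(id)) stop_validation("'id' is required with a segment_set")
    mask <- matrix(as.integer(mask$labels == id), mask$h, mask$w)
  }
  b <- cpp_boundary(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  px <- which(t(b))
  w <- ncol(mask)
  cbind(row = (px - 1L) %/% w + 1L, col = (px - 1L) %% w + 1L)
}

# farthest pair among boundary points; the convex hull carries every extreme
# point, so the diameter search runs on hull vertices only. Ties go to the
# first pair in raster order.
farthest_pair <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(list(d = 0, i = 1L, j = 1L))
  hull <- if (n > 3L) {
    hidx <- sort(grDevices::chull(pts[, 2], pts[, 1]))  # keep raster order
    pts[hidx, , drop = FALSE]
  } else pts
  m <- nrow(hull)
  best <- list(d = -1, i = 1L, j = 1L)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    d <- sqrt((hull[i, 1] - hull[j, 1])^2 + (hull[i, 2] - hull[j, 2])^2)
    if (d > best$d + 1e-12) best <- list(d = d, i = i, j = j)
  }
  list(d = max(best$d, 0), p = hull[best$i, ], q = hull[best$j, ],
       hull = hull)
}

#' Measure length and width of one segment
#'
#' @param mask binary matrix holding one segment, or a `"segment_set"`.
#' @param id segment id, required when `mask` is a segment set.
#' @return list: `length_px`, `width_px`, `area_px`, `length_axis` (unit
#'   vector in (row, col) coordinates).
#' @export
measure_length_width <- function(mask, id = NULL) {
  if (inherits(mask, "segment_set")) {
    if (is.null(id)) stop_validation("'id' is required with a segment_set")
    area <- ss_area(mask, id)
    bp <- boundary_pixels(mask, id)
  } else {
    area <- sum(mask != 0)
    bp <- boundary_pixels(mask)
  }
  if (!nrow(bp)) stop_validation("empty segment")
  fp <- farthest_pair(bp)
  if (fp$d == 0)
    return(list(length_px = 0, width_px = 0, area_px = area,
                length_axis = c(0, 0)))
  axis <- c(fp$q[1] - fp$p[1], fp$q[2] - fp$p[2]) / fp$d
  perp <- c(-axis[2], axis[1])
  # projection extremes are attained on the hull
  proj <- fp$hull[, 1] * perp[1] + fp$hull[, 2] * perp[2]
  list(length_px = fp$d, width_px = max(proj) - min(proj), area_px = area,
       length_axis = axis)
}

ss_area <- function(ss, id) {
  a <- ss$stats$area[ss$stats$id == id]
  if (!length(a)) stop_validation("no segment with id %s", id)
  a
}

#' Measure every segment of a segment set
#'
#' @param ss a `"segment_set"` from [segment_pipeline()].
#' @return data frame: `id, area_px, diagonal_px, length_px, width_px`, one
#'   row per segment in id order.
#' @export
measure_segments <- function(ss) {
  if (!inherits(ss, "segment_set")) stop_validation("'ss' must be a segment_set")
  ids <- ss$stats$id
  out <- data.frame(id = ids, area_px = ss$stats$area,
                    diagonal_px = ss$stats$diagonal,
                    length_px = NA_real_, width_px = NA_real_)
  for (i in seq_along(ids)) {
    # measure on the bbox crop: boundary and hull are local to the segment
    r <- ss$stats[i, ]
    sub <- ss$labels[r$rmin:r$rmax, r$cmin:r$cmax, drop = FALSE]
    m <- measure_length_width(matrix(as.integer(sub == ids[i]),
                                     nrow(sub), ncol(sub)))
    out$length_px[i] <- m$length_px
    out$width_px[i] <- m$width_px
  }
  out
}

#' Build a physical scale from a reference object
#'
#' Any retained segment with a known physical area can calibrate the
#' pixel-to-millimeter conversion; only its total area matters, not its
#' shape. The area ratio is `ref_area_mm2 / ref_area_px`; linear
#' measurements use its square root, the unique dimensionally consistent
#' extension.
#'
#' @param ss a `"segment_set"`.
#' @param ref_id id of the reference segment.
#' @param ref_area_mm2 known physical area of the reference, in mm^2.
#' @return list of class `"scale_ref"`: `ref_segment_id`, `ref_area_px`,
#'   `ref_area_mm2`, `area_ratio` (mm^2/px), `linear_ratio` (mm/px).
#' @export
make_scale <- function(ss, ref_id, ref_area_mm2) {
  if (!is.numeric(ref_area_mm2) || ref_area_mm2 <= 0)
    stop_validation("'ref_area_mm2' must be positive")
  apx <- ss_area(ss, ref_id)
  structure(list(ref_segment_id = ref_id, ref_area_px = apx,
                 ref_area_mm2 = ref_area_mm2,
                 area_ratio = ref_area_mm2 / apx,
                 linear_ratio = sqrt(ref_area_mm2 / apx)),
            class = "scale_ref")
}

#' Convert pixel measurements to millimeters
#'
#' @param measurements data frame from [measure_segments()].
#' @param scale a `"scale_ref"` from [make_scale()].
#' @return the data frame with `area_mm2`, `length_mm`, `width_mm` appended.
#' @export
apply_scale <- function(measurements, scale) {
  if (!inherits(scale, "scale_ref")) stop_validation("'scale' must be a scale_ref")
  measurements$area_mm2 <- measurements$area_px * scale$area_ratio
  measurements$length_mm <- measurements$length_px * scale$linear_ratio
  measurements$width_mm <- measurements$width_px * scale$linear_ratio
  measurements
}
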