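# Segment sets are represented compactly as a label matrix (0 = background,
# id = segment) plus a per-segment stats data frame. Pixel sets are
# recovered on demand with segment_pixels(). All connectivity in this module
# is 8-connectivity.

make_segment_set <- function(labels, provenance = "initial", note = NULL) {
  n <- attr(labels, "n")
  if (is.null(n)) n <- max(0L, max(labels))
  st <- segset_stats(labels, n)
  st$provenance <- rep_len(provenance, nrow(st))
  st$note <- if (is.null(note)) rep(NA_character_, nrow(st)) else
    rep_len(note, nrow(st))
  structure(list(labels = labels, stats = st,
                 h = nrow(labels), w = ncol(labels)),
            class = "segment_set")
}

segset_stats <- function(labels, n) {
  if (n == 0L)
    return(data.frame(id = integer(0), area = integer(0), rmin = integer(0),
                      cmin = integer(0), rmax = integer(0), cmax = integer(0),
                      diagonal = numeric(0)))
  m <- cpp_label_stats(labels, as.integer(n))
  keep <- m[, 1] > 0L
  df <- data.frame(id = seq_len(n)[keep], area = m[keep, 1],
                   rmin = m[keep, 2], cmin = m[keep, 3],
                   rmax = m[keep, 4], cmax = m[keep, 5])
  df$diagonal <- sqrt((df$rmax - df$rmin + 1)^2 + (df$cmax - df$cmin + 1)^2)
  df
}

#' Number of segments in a segment set
#' @param ss a `"segment_set"`.
#' @return integer count of retained segments.
#' @export
segment_count <- function(ss) nrow(ss$stats)

#' Pixels of one segment
#' @param ss a `"segment_set"`.
#' @param id segment id.
#' @return two-column integer matrix of (row, col), 1-based, raster order.
#' @export
segment_pixels <- function(ss, id) {
  if (!id %in% ss$stats$id) stop_validation("no segment with id %s", id)
  px <- which(t(ss$labels) == id)  # raster order via transpose
  cbind(row = (px - 1L) %/% ss$w + 1L, col = (px - 1L) %% ss$w + 1L)
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment_set: %d segments on a %d x %d canvas\n",
              segment_count(x), x$h, x$w))
  if (segment_count(x)) {
    cat(sprintf("  area: %d .. %d px, diagonal: %.1f .. %.1f px\n",
                min(x$stats$area), max(x$stats$area),
                min(x$stats$diagonal), max(x$stats$diagonal)))
    cat("  provenance:", paste(sprintf("%s (%d)",
        names(table(x$stats$provenance)), table(x$stats$provenance)),
        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Connected components of a POI mask
#'
#' Breadth-first-search flood fill with 8-connectivity: every POI pixel is
#' assigned to exactly one segment; two pixels touching only diagonally
#' belong to the same segment. Ids are dense `1..n` in raster order of the
#' first-discovered pixel.
#'
#' @param mask binary matrix (1 = POI).
#' @return a `"segment_set"`.
#' @export
connected_components <- function(mask) {
  assert_mask(mask)
  labels <- cpp_label_bfs(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  make_segment_set(labels, provenance = "initial")
}

#' Prune segments below the lower bounds
#'
#' Permanently removes every segment whose area is below `area_min` or whose
#' bounding-box diagonal is below `diag_min`; removed pixels become
#' background and are never revisited. Surviving segments keep their ids.
#'
#' @param ss a `"segment_set"`.
#' @param thresholds a [segment_thresholds()].
#' @return the pruned `"segment_set"`.
#' @export
prune_lower <- function(ss, thresholds) {
  drop <- ss$stats$id[ss$stats$area < thresholds$area_min |
                      ss$stats$diagonal < thresholds$diag_min]
  if (length(drop)) {
    ss$labels[ss$labels %in% drop] <- 0L
    ss$stats <- ss$stats[!ss$stats$id %in% drop, , drop = FALSE]
  }
  ss
}

#' Estimate how many objects a fused region contains
#'
#' Divides the region area by the mean area of correctly segmented objects
#' and rounds half-up, with a floor of 2 (a region is only split when it is
#' suspected to hold multiple objects).
#'
#' @param region_area region area in pixels.
#' @param mean_area mean area of in-bounds segments, must be positive.
#' @return integer estimate, at least 2.
#' @export
estimate_count <- function(region_area, mean_area) {
  if (!is.numeric(mean_area) || length(mean_area) != 1L || is.na(mean_area) ||
      mean_area <= 0)
    stop_validation("'mean_area' must be a positive number")
  max(2L, as.integer(round_half_up(region_area / mean_area)))
}

# distance transform of a single-segment mask, with a 1-pixel background pad
# so segments touching the canvas edge are handled like interior ones
padded_distmap <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  d <- EBImage::imageData(EBImage::distmap(pad, metric = "euclidean"))
  d[2:(h + 1), 2:(w + 1), drop = FALSE]
}

# one marker per true peak: windowed local maxima are extended through
# equal-valued neighbors into plateaus; a plateau bordered by any strictly
# greater pixel is a ridge digitization artifact, not a peak, and is
# discarded. The marker sits at the plateau pixel nearest its centroid.
plateau_markers <- function(dist, maxima) {
  cpp_plateau_markers(dist, maxima)
}

# Prune markers by prominence (morphological dynamics): flood basins from
# the candidate markers, then repeatedly merge the basin whose peak rises
# least above the saddle it shares with a deeper neighbor, while that rise
# is below `h` (in distance units). Twin maxima split off the same ridge by
# digitization are separated by at most a couple of sqrt-integer
# quantization steps (<= ~0.25 at typical depths) and collapse into one
# basin; true object lobes rise >= ~0.5 above the contact-neck saddle even
# for flank-on-flank contact. h = 0.4 sits between the two populations
# (calibrated on synthetic tangent-pair scenes; see the methods vignette).
# Returns the basin label matrix of the significant markers.
prune_markers_by_dynamics <- function(markers, dist, mask, h = 0.4,
                                      max_basins = Inf) {
  n <- max(markers)
  if (n < 2L) {
    basins <- matrix(as.integer(mask * (n == 1L)), nrow(mask), ncol(mask))
    attr(basins, "n") <- as.integer(n)
    return(basins)
  }
  basins <- cpp_watershed(dist, markers, mask)
  peaks <- vapply(seq_len(n), function(i) dist[markers == i][1], numeric(1))
  alive <- rep(TRUE, n)
  repeat {
    if (sum(alive) < 2L) break
    saddles <- cpp_basin_saddles(basins, dist, n)
    cand <- NULL
    best_dyn <- Inf
    for (m in which(alive)) {
      nb <- which(alive & saddles[m, ] >= 0)
      nb <- nb[peaks[nb] > peaks[m] |
               (peaks[nb] == peaks[m] & nb < m)]   # defer to deeper/earlier
      if (!length(nb)) next
      s <- max(saddles[m, nb])
      dyn <- peaks[m] - s
      if (dyn < best_dyn - 1e-12) {
        best_dyn <- dyn
        cand <- list(m = m, into = nb[which.max(saddles[m, nb])])
      }
    }
    if (is.null(cand) || (best_dyn >= h && sum(alive) <= max_basins)) break
    basins[basins == cand$m] <- cand$into
    alive[cand$m] <- FALSE
  }
  renumber_segments(basins)
}

#' Split a fused segment by dynamic-search-region watershed
#'
#' Computes the Euclidean distance transform of the segment and looks for
#' markers as local maxima of the distance map over a square neighborhood
#' whose area is the current search region. The search region starts at the
#' mean area of correctly segmented objects and halves while fewer markers
#' than `target` are found, until it reduces to one pixel. A plateau of
#' equal maxima contributes a single marker at its centroid, and candidate
#' markers must be prominent: a peak rising less than 0.4 distance-units
#' above the saddle it shares with a deeper peak is a digitization artifact
#' of the distance ridge and is merged away; at most `target` basins are
#' retained (deepest first). The surviving markers seed a marker-controlled
#' watershed (priority flood of the negated distance map), whose basins
#' become the children.
#'
#' @param mask binary matrix holding a single 8-connected segment.
#' @param mean_area mean area (pixels) of correctly segmented objects.
#' @param target desired number of children, at least 2 (see
#'   [estimate_count()]).
#' @return integer label matrix of children partitioning the segment. If
#'   fewer than 2 markers are found the segment is returned unchanged as a
#'   single label with attribute `note = "unsplittable"`.
#' @export
watershed_split <- function(mask, mean_area, target) {
  assert_mask(mask)
  if (!is_count(target) || target < 2)
    stop_validation("'target' must be an integer >= 2")
  if (mean_area <= 0) stop_validation("'mean_area' must be positive")
  maskint <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  dist <- padded_distmap(mask)
  region <- mean_area
  basins <- NULL
  repeat {
    side <- max(1, round_half_up(sqrt(region)))
    radius <- max(1L, as.integer(side) %/% 2L)
    maxima <- cpp_local_maxima(dist, radius)
    markers <- plateau_markers(dist, maxima)
    # basins of prominent markers only; never more basins than estimated
    # objects (the marker count decides the number of objects)
    basins <- prune_markers_by_dynamics(markers, dist, maskint,
                                        h = 0.4, max_basins = target)
    if (attr(basins, "n") >= target || region <= 1) break
    region <- region / 2
  }
  if (attr(basins, "n") < 2L) {
    out <- maskint
    attr(out, "note") <- "unsplittable"
    return(out)
  }
  basins
}

#' Split a dented segment by boundary shrinkage
#'
#' Iteratively disables the boundary pixels (those with at least one
#' background 8-neighbor) of the segment. Peeling stops when the remnant
#' divides into two or more components, satisfies the upper bounds, or
#' vanishes. When the remnant has split, all peeled pixels are re-enabled by
#' assigning each to the geodesically nearest remnant component
#' (multi-source BFS), so the children partition the original pixel set.
#'
#' @param mask binary matrix holding a single 8-connected segment.
#' @param thresholds a [segment_thresholds()]; only the upper bounds are
#'   consulted.
#' @return integer label matrix of children. If peeling never splits the
#'   segment it is returned unchanged as a single label with attribute
#'   `note = "unsplittable"`; attribute `disabled` marks the peeled pixels.
#' @export
shrink_boundary <- function(mask, thresholds) {
  assert_mask(mask)
  work <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  unchanged <- function() {
    out <- matrix(as.integer(mask), nrow(mask), ncol(mask))
    attr(out, "note") <- "unsplittable"
    out
  }
  repeat {
    b <- cpp_boundary(work)
    nxt <- work
    nxt[b] <- 0L
    if (!any(nxt == 1L)) return(unchanged())    # remnant vanished
    comps <- cpp_label_bfs(nxt)
    n <- attr(comps, "n")
    if (n >= 2L) {
      peeled <- matrix(as.integer(mask), nrow(mask), ncol(mask))
      peeled[nxt == 1L] <- 0L                   # everything peeled so far
      out <- cpp_assign_nearest(comps, peeled)
      attr(out, "disabled") <- peeled
      return(out)
    }
    st <- segset_stats(comps, n)
    if (st$area[1] <= thresholds$area_max &&
        st$diagonal[1] <= thresholds$diag_max)
      return(unchanged())                       # shrank within bounds, no split
    work <- nxt
  }
}

#' Merge or delete undersized fragments
#'
#' Fragments produced by splitting that fall below a lower bound are grown
#' back toward their siblings: each such fragment merges with the adjacent
#' sibling sharing the longest border (count of 8-adjacent pixel pairs,
#' which for shrink-split children runs through the re-enabled disabled
#' pixels); merging repeats until the union satisfies the lower bounds. A
#' fragment with no adjacent sibling that still misses the bounds is
#' deleted.
#'
#' @param child_labels integer label matrix of sibling children (one parent).
#' @param thresholds a [segment_thresholds()]; only the lower bounds are
#'   consulted.
#' @return integer label matrix after merging/deletion (labels unrenumbered).
#' @export
expand_merge <- function(child_labels, thresholds) {
  labels <- child_labels
  nmax <- max(0L, max(labels))
  repeat {
    st <- segset_stats(labels, nmax)
    low <- st[st$area < thresholds$area_min |
              st$diagonal < thresholds$diag_min, , drop = FALSE]
    if (!nrow(low)) return(labels)
    frag <- low$id[order(low$area)][1]          # smallest fragment first
    counts <- cpp_border_counts(labels, as.integer(frag), as.integer(nmax))
    if (all(counts == 0L)) {
      labels[labels == frag] <- 0L              # isolated: delete
    } else {
      buddy <- which.max(counts)                # ties: lower id wins
      labels[labels == frag] <- as.integer(buddy)
    }
  }
}

# renumber labels densely 1..n in raster order of each segment's first pixel
renumber_segments <- function(labels) {
  v <- as.vector(t(labels))
  firsts <- v[v > 0L & !duplicated(v)]
  if (!length(firsts)) {
    out <- matrix(0L, nrow(labels), ncol(labels))
    attr(out, "n") <- 0L
    return(out)
  }
  map <- integer(max(labels))
  map[firsts] <- seq_along(firsts)
  out <- labels
  out[out > 0L] <- map[out[out > 0L]]
  attr(out, "n") <- length(firsts)
  out
}

# paste child labels (local ids within a bbox crop) into the full canvas,
# replacing parent id with fresh ids; returns updated labels + new id range
graft_children <- function(labels, crop, child_labels, next_id) {
  sel <- child_labels > 0L
  ids <- sort(unique(child_labels[sel]))
  remap <- integer(max(ids))
  remap[ids] <- next_id + seq_along(ids) - 1L
  sub <- labels[crop$r0:crop$r1, crop$c0:crop$c1, drop = FALSE]
  sub[sel] <- remap[child_labels[sel]]
  labels[crop$r0:crop$r1, crop$c0:crop$c1] <- sub
  list(labels = labels, new_ids = remap[ids])
}

#' The divide-and-combine segmentation pipeline
#'
#' Runs the full dynamic segmentation over a POI mask:
#' \enumerate{
#'   \item BFS connected components ([connected_components()]);
#'   \item permanent removal of segments below the lower bounds
#'     ([prune_lower()]);
#'   \item the mean object area is taken from segments currently inside all
#'     bounds ("correctly segmented objects"; falls back to all segments
#'     with a warning when none qualify);
#'   \item every segment above `area_max` or `diag_max` is split by
#'     [watershed_split()] with [estimate_count()] children, falling back to
#'     [shrink_boundary()] when the watershed returns it unchanged; children
#'     still above the upper bounds are processed recursively, and a segment
#'     neither method can split is retained with note `"unsplittable"`;
#'   \item undersized fragments produced by splitting are merged into their
#'     siblings or deleted ([expand_merge()]);
#'   \item ids are renumbered densely in raster order.
#' }
#'
#' @param mask binary POI matrix.
#' @param thresholds a [segment_thresholds()].
#' @return a `"segment_set"`; empty for an all-zero mask.
#' @export
segment_pipeline <- function(mask, thresholds) {
  ss <- connected_components(mask)
  ss <- prune_lower(ss, thresholds)
  if (!segment_count(ss)) return(ss)
  st <- ss$stats
  inb <- st$area >= thresholds$area_min & st$area <= thresholds$area_max &
         st$diagonal >= thresholds$diag_min & st$diagonal <= thresholds$diag_max
  if (any(inb)) {
    mean_area <- mean(st$area[inb])
  } else {
    warning("no segment lies inside the bounds; mean area taken over all segments",
            call. = FALSE)
    mean_area <- mean(st$area)
  }

  labels <- ss$labels
  prov <- stats::setNames(rep("initial", nrow(st)), st$id)
  note <- stats::setNames(rep(NA_character_, nrow(st)), st$id)
  over <- function(a, d) a > thresholds$area_max | d > thresholds$diag_max
  queue <- st$id[over(st$area, st$diagonal)]
  next_id <- max(st$id) + 1L

  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    stx <- segset_stats_one(labels, id)
    if (is.null(stx)) next
    crop <- list(r0 = max(1L, stx$rmin), r1 = min(nrow(labels), stx$rmax),
                 c0 = max(1L, stx$cmin), c1 = min(ncol(labels), stx$cmax))
    sub <- labels[crop$r0:crop$r1, crop$c0:crop$c1, drop = FALSE]
    segmask <- matrix(as.integer(sub == id), nrow(sub), ncol(sub))
    target <- estimate_count(stx$area, mean_area)
    child <- watershed_split(segmask, mean_area, target)
    method <- "watershed-split"
    if (identical(attr(child, "note"), "unsplittable")) {
      child <- shrink_boundary(segmask, thresholds)
      method <- "shrink-split"
    }
    if (identical(attr(child, "note"), "unsplittable")) {
      note[as.character(id)] <- "unsplittable"
      next
    }
    child <- expand_merge(child, thresholds)
    child <- renumber_segments(child)
    n_child <- attr(child, "n")
    if (n_child == 0L) {           # everything merged away: drop the parent
      labels[labels == id] <- 0L
      prov <- prov[names(prov) != as.character(id)]
      note <- note[names(note) != as.character(id)]
      next
    }
    if (n_child == 1L && sum(child > 0L) == stx$area) {
      note[as.character(id)] <- "unsplittable"   # split then fully re-merged
      next
    }
    labels[labels == id] <- 0L
    prov <- prov[names(prov) != as.character(id)]
    note <- note[names(note) != as.character(id)]
    grafted <- graft_children(labels, crop, child, next_id)
    labels <- grafted$labels
    for (nid in grafted$new_ids) {
      prov[as.character(nid)] <- method
      note[as.character(nid)] <- NA_character_
    }
    cst <- segset_stats(labels, max(grafted$new_ids))
    cst <- cst[cst$id %in% grafted$new_ids, , drop = FALSE]
    queue <- c(queue, cst$id[over(cst$area, cst$diagonal)])
    next_id <- max(grafted$new_ids) + 1L
  }

  # final sweep: drop any leftover fragment below the lower bounds
  fin <- segset_stats(labels, max(0L, max(labels)))
  bad <- fin$id[fin$area < thresholds$area_min |
                fin$diagonal < thresholds$diag_min]
  if (length(bad)) labels[labels %in% bad] <- 0L

  old_ids <- as.vector(t(labels))
  old_ids <- old_ids[old_ids > 0L & !duplicated(old_ids)]
  labels <- renumber_segments(labels)
  out <- make_segment_set(labels)
  out$stats$provenance <- unname(prov[as.character(old_ids)])
  out$stats$note <- unname(note[as.character(old_ids)])
  out
}

# stats row for a single id, or NULL if the id is gone
segset_stats_one <- function(labels, id) {
  px <- labels == id
  if (!any(px)) return(NULL)
  idx <- which(px, arr.ind = TRUE)
  list(area = nrow(idx), rmin = min(idx[, 1]), rmax = max(idx[, 1]),
       cmin = min(idx[, 2]), cmax = max(idx[, 2]))
}
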