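#' Segment size thresholds
#'
#' Bounds on segment area (POI pixel count) and bounding-box diagonal that
#' drive the divide-and-combine segmentation: segments below a lower bound
#' are pruned or merged away, segments above an upper bound are split.
#'
#' @param area_min,area_max lower/upper bound on area in pixels.
#' @param diag_min,diag_max lower/upper bound on the bounding-box diagonal
#'   in pixels.
#' @return An object of class `"segment_thresholds"`.
#' @examples
#' segment_thresholds(area_min = 20, area_max = 500)
#' @export
segment_thresholds <- function(area_min = 0, area_max = Inf,
                               diag_min = 0, diag_max = Inf) {
  for (nm in c("area_min", "area_max", "diag_min", "diag_max")) {
    v <- get(nm)
    if (length(v) != 1L || is.na(v) || v < 0)
      stop_validation("threshold '%s' must be a single non-negative number", nm)
  }
  if (area_min > area_max)
    stop_validation("area_min (%s) exceeds area_max (%s)", area_min, area_max)
  if (diag_min > diag_max)
    stop_validation("diag_min (%s) exceeds diag_max (%s)", diag_min, diag_max)
  structure(list(area_min = area_min, area_max = area_max,
                 diag_min = diag_min, diag_max = diag_max),
            class = "segment_thresholds")
}

#' Elliptical region of interest
#'
#' Restricts the POI mask to an ellipse; pixels whose centers fall outside
#' are excluded from the analysis. Coordinates are 0-based (row, col) with
#' rows increasing downward.
#'
#' @param center numeric length 2, (row, col) of the ellipse center.
#' @param semi_axes numeric length 2, semi-axis lengths in pixels (along the
#'   rotated row/col directions); both must be positive.
#' @param rotation rotation in radians, counter-clockwise.
#' @return An object of class `"ellipse_roi"`.
#' @export
ellipse_roi <- function(center, semi_axes, rotation = 0) {
  if (length(center) != 2L || anyNA(center))
    stop_validation("roi center must be (row, col)")
  if (length(semi_axes) != 2L || any(semi_axes <= 0))
    stop_validation("roi semi_axes must be two positive numbers")
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 rotation = as.numeric(rotation)[1]),
            class = "ellipse_roi")
}

# snap a weight to the 0.02 slider grid; warn when the input was off-grid
snap_weight <- function(w) {
  s <- round(w / 0.02) * 0.02
  s <- min(1, max(0, s))
  if (abs(s - w) > 1e-9)
    warning(sprintf("rgb_weight %.4f snapped to the 0.02 grid: %.2f", w, s),
            call. = FALSE)
  round(s, 2)
}

#' Analysis parameter set
#'
#' The full set of user decisions that defines one analysis: which color-index
#' principal component to use, which of the first two RGB PCs to blend in and
#' with what weight, the number of K-Means clusters, which clusters form the
#' POI, the segment thresholds, segments to exclude, and an optional
#' elliptical region of interest. A parameter set written with
#' [write_parameter_file()] makes a run reproducible and drives batch mode.
#'
#' @param selected_index_pc integer 1–12, color-index PC used for clustering.
#' @param rgb_pc_choice 1 or 2: which RGB PC is available for blending.
#' @param rgb_weight blend weight of the RGB PC, in \[0, 1\] on a 0.02 grid
#'   (off-grid values are snapped with a warning); 0 means the pure index PC.
#' @param k number of K-Means clusters, integer 1–10.
#' @param selected_clusters integer vector of 0-based cluster ids forming the
#'   POI (clusters are numbered by ascending mean gray value).
#' @param thresholds a [segment_thresholds()] object.
#' @param excluded_segment_ids integer vector of segment ids to drop from the
#'   outputs (the headless analogue of click-to-delete).
#' @param roi optional [ellipse_roi()].
#' @return An object of class `"parameter_set"`.
#' @examples
#' parameter_set(k = 3, selected_clusters = 0)
#' @export
parameter_set <- function(selected_index_pc = 1L,
                          rgb_pc_choice = 1L,
                          rgb_weight = 0,
                          k = 2L,
                          selected_clusters = 0L,
                          thresholds = segment_thresholds(),
                          excluded_segment_ids = integer(0),
                          roi = NULL) {
  if (!is_count(selected_index_pc) || selected_index_pc < 1 || selected_index_pc > 12)
    stop_validation("'selected_index_pc' must be an integer in 1..12")
  if (!is_count(rgb_pc_choice) || !rgb_pc_choice %in% c(1, 2))
    stop_validation("'rgb_pc_choice' must be 1 or 2")
  if (length(rgb_weight) != 1L || is.na(rgb_weight) || rgb_weight < 0 || rgb_weight > 1)
    stop_validation("'rgb_weight' must be a number in [0, 1]")
  if (!is_count(k) || k < 1 || k > 10)
    stop_validation("'k' must be an integer in 1..10")
  selected_clusters <- as.integer(selected_clusters)
  if (anyNA(selected_clusters) ||
      (length(selected_clusters) && any(selected_clusters < 0 | selected_clusters >= k)))
    stop_validation("'selected_clusters' must be 0-based ids below k = %d", k)
  if (!inherits(thresholds, "segment_thresholds"))
    stop_validation("'thresholds' must be a segment_thresholds() object")
  if (!is.null(roi) && !inherits(roi, "ellipse_roi"))
    stop_validation("'roi' must be an ellipse_roi() object or NULL")
  structure(list(selected_index_pc = as.integer(selected_index_pc),
                 rgb_pc_choice = as.integer(rgb_pc_choice),
                 rgb_weight = snap_weight(rgb_weight),
                 k = as.integer(k),
                 selected_clusters = sort(unique(selected_clusters)),
                 thresholds = thresholds,
                 excluded_segment_ids = sort(unique(as.integer(excluded_segment_ids))),
                 roi = roi),
            class = "parameter_set")
}

# JSON cannot carry Inf; open upper bounds are serialized as null
thr_to_json <- function(t) {
  lapply(unclass(t), function(v) if (is.infinite(v)) NULL else v)
}
thr_from_json <- function(x) {
  g <- function(nm, default) {
    v <- x[[nm]]
    if (is.null(v)) default else as.numeric(v)
  }
  segment_thresholds(area_min = g("area_min", 0), area_max = g("area_max", Inf),
                     diag_min = g("diag_min", 0), diag_max = g("diag_max", Inf))
}

#' Write / read a parameter file
#'
#' Parameter files are JSON; `read_parameter_file(write_parameter_file(p))`
#' reproduces `p` field-by-field. Reading validates every key and names the
#' offending key on failure, so a hand-edited file with e.g. `k = 11` is
#' rejected.
#'
#' @param params a [parameter_set()].
#' @param path file path.
#' @return `write_parameter_file` returns `path` invisibly;
#'   `read_parameter_file` returns a [parameter_set()].
#' @export
write_parameter_file <- function(params, path) {
  if (!inherits(params, "parameter_set"))
    stop_validation("'params' must be a parameter_set() object")
  x <- list(
    selected_index_pc = params$selected_index_pc,
    rgb_pc_choice = params$rgb_pc_choice,
    rgb_weight = params$rgb_weight,
    k = params$k,
    selected_clusters = I(params$selected_clusters),
    thresholds = thr_to_json(params$thresholds),
    excluded_segment_ids = I(params$excluded_segment_ids)
  )
  if (!is.null(params$roi))
    x$roi <- list(center = I(params$roi$center),
                  semi_axes = I(params$roi$semi_axes),
                  rotation = params$roi$rotation)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameter_file
#' @export
read_parameter_file <- function(path) {
  if (!file.exists(path)) stop_validation("parameter file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("selected_index_pc", "rgb_pc_choice", "rgb_weight", "k",
               "selected_clusters", "thresholds"))
    if (is.null(x[[nm]]))
      stop_validation("parameter file is missing required key '%s'", nm)
  roi <- NULL
  if (!is.null(x$roi))
    roi <- ellipse_roi(center = unlist(x$roi$center),
                       semi_axes = unlist(x$roi$semi_axes),
                       rotation = if (is.null(x$roi$rotation)) 0 else x$roi$rotation)
  parameter_set(
    selected_index_pc = x$selected_index_pc,
    rgb_pc_choice = x$rgb_pc_choice,
    rgb_weight = x$rgb_weight,
    k = x$k,
    selected_clusters = unlist(x$selected_clusters),
    thresholds = thr_from_json(as.list(x$thresholds)),
    excluded_segment_ids = if (is.null(x$excluded_segment_ids)) integer(0)
                           else unlist(x$excluded_segment_ids),
    roi = roi
  )
}
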