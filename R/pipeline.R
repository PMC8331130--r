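# Single-image and batch front ends: wire indices -> PCA -> blend -> K-Means
# -> POI mask -> divide-and-combine segmentation -> morphometry, and write
# the artifact files.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

# the shared analysis chain: image + parameters -> segment set (+ gray image)
analyze_image <- function(image, params, kmeans_seed = 0L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  h <- dim(image)[1]; w <- dim(image)[2]
  say("indices: %d x %d image", h, w)
  idx <- stage("color_indices", compute_index_stack(image))
  fm <- stage("feature_matrix", build_feature_matrix(image, idx))
  pcs_idx <- stage("pca_index", pca_block(fm, "index"))
  pcs_rgb <- stage("pca_rgb", pca_block(fm, "rgb"))
  say("pca: index evs %s", paste(signif(pcs_idx$eigenvalues, 3), collapse = " "))
  gray_idx <- stage("scale_index",
                    scale_to_gray(pc_field(pcs_idx, params$selected_index_pc, h, w)))
  gray_rgb <- stage("scale_rgb",
                    scale_to_gray(pc_field(pcs_rgb, params$rgb_pc_choice, h, w)))
  gray <- stage("combine", combine_pc(gray_rgb, gray_idx, params$rgb_weight))
  cl <- stage("kmeans", kmeans_labels(gray, params$k, seed = kmeans_seed))
  say("kmeans: k = %d, cluster means %s", cl$k,
      paste(round(cl$means, 1), collapse = " "))
  if (!length(params$selected_clusters))
    stop_validation("[clusters] 'selected_clusters' is empty")
  mask <- stage("select_clusters", select_clusters(cl, params$selected_clusters))
  if (!is.null(params$roi))
    mask <- stage("roi", apply_elliptical_roi(mask, params$roi))
  ss <- stage("segmentation", segment_pipeline(mask, params$thresholds))
  say("segmentation: %d segments", segment_count(ss))
  list(segments = ss, gray = gray, clusters = cl, mask = mask)
}

drop_segments <- function(ss, ids) {
  if (!length(ids)) return(ss)
  ss$labels[ss$labels %in% ids] <- 0L
  ss$stats <- ss$stats[!ss$stats$id %in% ids, , drop = FALSE]
  ss
}

#' Process a single image end to end
#'
#' Runs the full chain on one image and writes, into `export_dir`:
#' `overlay.png` (red boxes + ids), `labels.png` (16-bit label mask),
#' `measurements.csv`, `scatter.png` (area vs diagonal with threshold
#' lines) and `params.json` (the parameter set used, which makes the run
#' reproducible byte-for-byte).
#'
#' @param input path to a PNG/JPEG/TIFF image, or an already-loaded RGB
#'   array from [load_rgb_image()]/[generate_scene()].
#' @param export_dir output directory, created if missing.
#' @param params a [parameter_set()] or the path of a parameter file.
#' @param ref_id,ref_area_mm2 optional reference segment id and its known
#'   physical area; when both are given the measurement table gains
#'   millimeter columns.
#' @param kmeans_seed seed for the K-Means initialization.
#' @param verbose log one line per stage.
#' @return invisibly, a list: `segments`, `measurements`, `scale`, `files`.
#' @export
run_single <- function(input, export_dir, params, ref_id = NULL,
                       ref_area_mm2 = NULL, kmeans_seed = 0L,
                       verbose = FALSE) {
  if (is.character(params)) params <- read_parameter_file(params)
  if (!inherits(params, "parameter_set"))
    stop_validation("'params' must be a parameter_set or a parameter file path")
  image <- if (is.character(input)) stage("load", load_rgb_image(input))
           else input
  if (!dir.exists(export_dir)) dir.create(export_dir, recursive = TRUE)

  res <- analyze_image(image, params, kmeans_seed = kmeans_seed,
                       verbose = verbose)
  ss <- drop_segments(res$segments, params$excluded_segment_ids)
  meas <- stage("morphometry", measure_segments(ss))
  scl <- NULL
  if (!is.null(ref_id) && !is.null(ref_area_mm2))
    scl <- stage("scale", make_scale(ss, ref_id, ref_area_mm2))

  files <- file.path(export_dir, c(overlay = "overlay.png",
                                   labels = "labels.png",
                                   csv = "measurements.csv",
                                   scatter = "scatter.png",
                                   params = "params.json"))
  names(files) <- c("overlay", "labels", "csv", "scatter", "params")
  stage("overlay", save_overlay(image, ss, files["overlay"]))
  stage("labels", write_label_mask(ss$labels, files["labels"]))
  stage("csv", write_measurements(meas, files["csv"], scale = scl))
  stage("scatter", write_area_diagonal_plot(meas, params$thresholds,
                                            files["scatter"]))
  stage("params", write_parameter_file(params, files["params"]))
  invisible(list(segments = ss,
                 measurements = if (is.null(scl)) meas
                                else apply_scale(meas, scl),
                 scale = scl, files = files))
}

#' Batch-process a directory of images
#'
#' Applies one parameter file to every readable PNG/JPEG/TIFF in a
#' directory — images taken under similar conditions share the same POI and
#' threshold decisions. Per-image artifacts land in a subdirectory of
#' `export_dir` named after each file; a `summary.csv` records the segment
#' count per image. A failing image is logged and skipped, not fatal.
#' Reference scaling is unavailable in batch mode, so all measurements stay
#' in pixels.
#'
#' @param input_dir directory containing at least one readable image.
#' @param export_dir output directory.
#' @param params_file path to a JSON parameter file
#'   (see [write_parameter_file()]).
#' @param kmeans_seed seed for the K-Means initialization.
#' @param verbose log one line per stage and image.
#' @return invisibly, the summary data frame (`image`, `n_segments`,
#'   `status`).
#' @export
run_batch <- function(input_dir, export_dir, params_file, kmeans_seed = 0L,
                      verbose = FALSE) {
  if (!dir.exists(input_dir)) stop_validation("no such directory: %s", input_dir)
  imgs <- list.files(input_dir, pattern = "\\.(png|jpe?g|tiff?)$",
                     ignore.case = TRUE, full.names = TRUE)
  if (!length(imgs)) stop_validation("no readable images in %s", input_dir)
  params <- read_parameter_file(params_file)
  if (!dir.exists(export_dir)) dir.create(export_dir, recursive = TRUE)

  summary <- data.frame(image = basename(imgs), n_segments = NA_integer_,
                        status = "ok", stringsAsFactors = FALSE)
  for (i in seq_along(imgs)) {
    sub <- file.path(export_dir, tools::file_path_sans_ext(basename(imgs[i])))
    res <- tryCatch(
      run_single(imgs[i], sub, params, kmeans_seed = kmeans_seed,
                 verbose = verbose),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("batch: skipping '%s': %s", basename(imgs[i]),
                      conditionMessage(res)), call. = FALSE)
      summary$status[i] <- paste("failed:", conditionMessage(res))
    } else {
      summary$n_segments[i] <- segment_count(res$segments)
    }
  }
  write.csv(summary, file.path(export_dir, "summary.csv"), row.names = FALSE)
  invisible(summary)
}
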