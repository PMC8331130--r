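#' Build the pixel feature matrix
#'
#' Stacks the raw channels and the color-index planes into an `(h*w) x 15`
#' matrix: rows are pixels in raster order (row `k` is pixel
#' `(k %/% w, k %% w)` 0-based), columns are `R, G, B` followed by the twelve
#' index planes. Values are copied without transformation.
#'
#' @param image RGB image array.
#' @param indices index stack from [compute_index_stack()].
#' @return numeric matrix with fixed column names.
#' @export
build_feature_matrix <- function(image, indices) {
  if (!identical(dim(image)[1:2], dim(indices)[1:2]))
    stop_validation("image (%s x %s) and index stack (%s x %s) disagree",
                    dim(image)[1], dim(image)[2], dim(indices)[1], dim(indices)[2])
  d <- dim(indices)[3]
  # row-major pixel order: transpose each plane before flattening
  cols <- c(
    lapply(1:3, function(i) as.numeric(t(image[, , i]))),
    lapply(seq_len(d), function(i) as.numeric(t(indices[, , i])))
  )
  m <- do.call(cbind, cols)
  colnames(m) <- c("R", "G", "B", dimnames(indices)[[3]])
  m
}

#' Correlation-based PCA on one feature block
#'
#' Runs PCA on either the RGB block (columns 1–3) or the color-index block
#' (columns 4–15) of the feature matrix. Correlation is used instead of
#' covariance — every column is standardized to zero mean and unit variance
#' before eigen-decomposition — so the contribution of a column does not
#' depend on its scale. Zero-variance columns are dropped with a warning.
#' Eigenvector signs are fixed so each loading's largest-magnitude entry is
#' positive, making the output deterministic.
#'
#' @param feature_matrix matrix from [build_feature_matrix()], or any
#'   numeric matrix when `block = "all"`.
#' @param block `"rgb"` (columns `R,G,B`), `"index"` (the rest) or `"all"`.
#' @return list of class `"pc_scores"`: `scores` (n x p), `eigenvalues`
#'   (explained variance per component, non-increasing), `loadings`
#'   (orthonormal columns), `center`, `scale`, `block`, `dropped`.
#' @export
pca_block <- function(feature_matrix, block = c("index", "rgb", "all")) {
  block <- match.arg(block)
  cols <- switch(block,
    rgb = intersect(c("R", "G", "B"), colnames(feature_matrix)),
    index = setdiff(colnames(feature_matrix), c("R", "G", "B")),
    all = colnames(feature_matrix))
  x <- feature_matrix[, cols, drop = FALSE]
  ctr <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  dropped <- cols[sdv == 0 | !is.finite(sdv)]
  if (length(dropped)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    keep <- setdiff(cols, dropped)
    if (!length(keep))
      stop_validation("all '%s' block columns are constant; PCA is degenerate",
                      block)
    x <- x[, keep, drop = FALSE]
    ctr <- ctr[keep]; sdv <- sdv[keep]
  }
  z <- sweep(sweep(x, 2, ctr), 2, sdv, "/")
  n <- nrow(z)
  cmat <- crossprod(z) / (n - 1)          # sample correlation matrix
  eig <- eigen(cmat, symmetric = TRUE)
  ev <- eig$values
  ev[ev < 1e-10] <- 0
  vec <- eig$vectors
  for (j in seq_len(ncol(vec))) {         # sign convention
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- colnames(z)
  colnames(vec) <- paste0("PC", seq_len(ncol(vec)))
  structure(list(scores = z %*% vec, eigenvalues = ev, loadings = vec,
                 center = ctr, scale = sdv, block = block, dropped = dropped),
            class = "pc_scores")
}

#' Reshape one principal-component score column to an image field
#'
#' @param pcs a `"pc_scores"` object.
#' @param component component number (1 = largest eigenvalue).
#' @param h,w image height and width; `h * w` must equal the score rows.
#' @return numeric `h x w` matrix of scores.
#' @export
pc_field <- function(pcs, component, h, w) {
  if (component < 1 || component > ncol(pcs$scores))
    stop_validation("component %d outside 1..%d", component, ncol(pcs$scores))
  if (h * w != nrow(pcs$scores))
    stop_validation("h * w (%d) != number of pixels (%d)", h * w, nrow(pcs$scores))
  matrix(pcs$scores[, component], nrow = h, ncol = w, byrow = TRUE)
}

#' Rescale a score field to an 8-bit gray image
#'
#' Linear map of the field onto 0–255: the minimum maps to 0, the maximum to
#' 255, values are rounded half-up to integers. A constant field maps to all
#' zeros with a warning.
#'
#' @param field numeric matrix of finite values.
#' @return integer `h x w` matrix with values 0–255.
#' @export
scale_to_gray <- function(field) {
  if (!all(is.finite(field))) stop_validation("field contains non-finite values")
  rng <- range(field)
  if (rng[1] == rng[2]) {
    warning("constant score field rescaled to all-zero gray image", call. = FALSE)
    return(matrix(0L, nrow(field), ncol(field)))
  }
  g <- (field - rng[1]) / (rng[2] - rng[1]) * 255
  matrix(as.integer(round_half_up(g)), nrow(field), ncol(field))
}

#' Blend an RGB PC image with a color-index PC image
#'
#' Convex combination of the two displayed (0–255) gray images:
#' `weight * rgb_pc + (1 - weight) * index_pc`, rescaled back to 0–255.
#' Mixing operates on the rescaled gray fields rather than raw scores so that
#' neither block can dominate through scale. The weight lives on the 0.02
#' slider grid; off-grid values are snapped with a warning.
#'
#' @param rgb_pc,index_pc integer gray matrices from [scale_to_gray()] with
#'   identical dimensions.
#' @param weight RGB weight in \[0, 1\]; the index image gets `1 - weight`.
#' @return integer gray matrix 0–255.
#' @export
combine_pc <- function(rgb_pc, index_pc, weight) {
  if (!identical(dim(rgb_pc), dim(index_pc)))
    stop_validation("rgb_pc and index_pc dimensions disagree")
  weight <- snap_weight(weight)
  if (weight == 0) return(index_pc)
  if (weight == 1) return(rgb_pc)
  scale_to_gray(weight * rgb_pc + (1 - weight) * index_pc)
}
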