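# Exact weighted 1-D K-Means on distinct sorted values by dynamic
# programming: optimal clusters are contiguous in sorted order, so the
# global WCSS optimum is found over contiguous partitions. O(k m^2) with
# prefix sums, m <= 256 distinct gray values. Equal-cost partitions resolve
# to the one with the earliest break points (deterministic).
kmeans_1d_exact <- function(vals, wts, k) {
  m <- length(vals)
  W <- cumsum(wts)
  S <- cumsum(wts * vals)
  Q <- cumsum(wts * vals^2)
  css <- function(j, i) {   # within-cluster SS of vals[j..i], vectorized in j
    w <- W[i] - c(0, W)[j]
    s <- S[i] - c(0, S)[j]
    q <- Q[i] - c(0, Q)[j]
    q - s^2 / w
  }
  D <- matrix(Inf, k, m)
  B <- matrix(1L, k, m)
  D[1, ] <- Q - S^2 / W
  if (k > 1) for (g in 2:k) {
    for (i in g:m) {
      j <- g:i
      cost <- D[g - 1, j - 1] + css(j, i)
      best <- which.min(cost)           # earliest j on ties
      D[g, i] <- cost[best]
      B[g, i] <- j[best]
    }
  }
  assign <- integer(m)
  i <- m
  for (g in k:1) {
    j <- B[g, i]
    assign[j:i] <- g
    i <- j - 1L
  }
  means <- vapply(seq_len(k), function(g) weighted.mean(vals[assign == g],
                                                        wts[assign == g]),
                  numeric(1))
  list(assign = assign, means = means, wcss = max(D[k, m], 0))
}

#' Pixel-wise K-Means on a gray PC image
#'
#' One-dimensional K-Means over the 0–255 gray values of the selected (or
#' blended) PC image — the second level of POI filtering. Clustering runs on
#' the distinct gray values weighted by their pixel counts, and since
#' optimal 1-D clusters are contiguous in sorted order the global
#' within-cluster-sum-of-squares optimum is computed exactly by dynamic
#' programming; no stochastic initialization is involved, so the result is
#' bit-reproducible by construction. Cluster labels are renumbered by
#' ascending cluster mean, so label 0 is always the darkest cluster.
#'
#' @param pc_image integer gray matrix (0–255) from [scale_to_gray()] or
#'   [combine_pc()].
#' @param k number of clusters, integer 1–10; silently reduced (with a
#'   warning) to the number of distinct gray values when larger.
#' @param seed,restarts retained for interface stability; the exact solver
#'   uses no randomness, so both are ignored.
#' @return list of class `"cluster_labels"`: `labels` (`h x w` integer
#'   matrix, values `0..k-1`), `k`, `means` (ascending per-cluster mean
#'   gray), `wcss`.
#' @export
kmeans_labels <- function(pc_image, k, seed = 0L, restarts = 10L) {
  if (!is_count(k) || k < 1 || k > 10)
    stop_validation("'k' must be an integer in 1..10")
  tab <- table(as.vector(pc_image))
  vals <- as.numeric(names(tab))
  wts <- as.numeric(tab)
  if (k > length(vals)) {
    warning(sprintf("k = %d exceeds the %d distinct gray values; reduced",
                    k, length(vals)), call. = FALSE)
    k <- length(vals)
  }
  res <- kmeans_1d_exact(vals, wts, k)
  # map each pixel's gray value to its 0-based cluster id (means ascending)
  lut <- integer(256L)
  lut[vals + 1L] <- res$assign - 1L
  labels <- matrix(lut[as.vector(pc_image) + 1L],
                   nrow(pc_image), ncol(pc_image))
  structure(list(labels = labels, k = k, means = res$means, wcss = res$wcss),
            class = "cluster_labels")
}

#' Turn selected clusters into the binary POI mask
#'
#' @param clusters a `"cluster_labels"` object from [kmeans_labels()].
#' @param selected non-empty set of 0-based cluster ids.
#' @return integer `h x w` matrix with 1 for POI pixels and 0 elsewhere.
#' @export
select_clusters <- function(clusters, selected) {
  selected <- unique(as.integer(selected))
  if (!length(selected))
    stop_validation("'selected' must name at least one cluster")
  if (any(selected < 0 | selected >= clusters$k))
    stop_validation("'selected' ids must lie in 0..%d", clusters$k - 1L)
  mask <- matrix(0L, nrow(clusters$labels), ncol(clusters$labels))
  mask[clusters$labels %in% selected] <- 1L
  mask
}

#' Restrict a POI mask to an elliptical region
#'
#' Pixels whose centers fall outside the ellipse are set to background.
#' Pixel centers are at integer 0-based coordinates (row, col).
#'
#' @param mask binary POI matrix.
#' @param roi an [ellipse_roi()].
#' @return the masked binary matrix.
#' @export
apply_elliptical_roi <- function(mask, roi) {
  assert_mask(mask)
  if (!inherits(roi, "ellipse_roi")) stop_validation("'roi' must be an ellipse_roi")
  h <- nrow(mask); w <- ncol(mask)
  rr <- matrix(0:(h - 1), h, w) - roi$center[1]
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE) - roi$center[2]
  ct <- cos(roi$rotation); st <- sin(roi$rotation)
  u <- rr * ct + cc * st
  v <- -rr * st + cc * ct
  inside <- (u / roi$semi_axes[1])^2 + (v / roi$semi_axes[2])^2 <= 1
  out <- mask
  out[!inside] <- 0L
  out
}
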