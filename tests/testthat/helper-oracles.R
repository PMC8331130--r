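# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: labeling uses union-find instead of BFS,
# measurements use exhaustive pair search instead of convex hulls, K-Means
# optima come from enumerating contiguous partitions of the sorted values.

# --- union-find connected-component labeling (8-connectivity) -------------
uf_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  parent <- seq_len(h * w)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  at <- function(i, j) (j - 1L) * h + i
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] == 0) next
    for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))) {
      ni <- i + d[1]; nj <- j + d[2]
      if (ni >= 1 && ni <= h && nj >= 1 && nj <= w && mask[ni, nj] != 0)
        union(at(i, j), at(ni, nj))
    }
  }
  lab <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    if (mask[i, j] != 0) lab[i, j] <- find(at(i, j))
  lab
}

# partition signature invariant to label renumbering: pixels grouped by label
partition_signature <- function(lab) {
  px <- which(lab != 0)
  unname(sort(vapply(split(px, lab[px]),
                     function(v) paste(sort(v), collapse = ","), character(1))))
}

# --- brute-force 1-D K-Means optimum over contiguous sorted partitions ----
brute_kmeans_wcss <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  css <- function(v) sum((v - mean(v))^2)
  best <- Inf
  cuts <- utils::combn(n - 1, k - 1)
  for (ci in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, ci], n)
    tot <- 0
    for (g in seq_len(k)) tot <- tot + css(x[(b[g] + 1):b[g + 1]])
    if (tot < best) best <- tot
  }
  best
}

# --- exhaustive farthest-pair / perpendicular width -----------------------
brute_length_width <- function(pts) {
  n <- nrow(pts)
  best <- c(0, 1, 1)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d > best[1] + 1e-12) best <- c(d, i, j)
  }
  if (best[1] == 0) return(list(length = 0, width = 0))
  axis <- (pts[best[3], ] - pts[best[2], ]) / best[1]
  perp <- c(-axis[2], axis[1])
  proj <- pts[, 1] * perp[1] + pts[, 2] * perp[2]
  list(length = best[1], width = max(proj) - min(proj))
}

# --- shape builders -------------------------------------------------------
disk_mask <- function(h, w, cr, cc, r) {
  m <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    if ((i - cr)^2 + (j - cc)^2 <= r^2) m[i, j] <- 1L
  m
}

fused_disks <- function(r = 8, sep = 14) {
  h <- 2L * r + 8L
  w <- 2L * r + sep + 8L
  cr <- h / 2
  c1 <- r + 4; c2 <- c1 + sep
  m <- disk_mask(h, w, cr, c1, r) | disk_mask(h, w, cr, c2, r)
  list(mask = matrix(as.integer(m), h, w), cr = cr, c1 = c1, c2 = c2)
}

random_mask <- function(h, w, p = 0.4) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# count 8-adjacent ordered pairs between two label values, by direct loops
brute_border_count <- function(labels, a, b) {
  h <- nrow(labels); w <- ncol(labels)
  cnt <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (labels[i, j] != a) next
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ni <- i + di; nj <- j + dj
      if (ni >= 1 && ni <= h && nj >= 1 && nj <= w && labels[ni, nj] == b)
        cnt <- cnt + 1L
    }
  }
  cnt
}

# default index formulas recomputed one pixel at a time, scalar arithmetic
scalar_index <- function(name, r, g, b) {
  chans <- c(R = r, G = g, B = b)
  parts <- strsplit(name, "_")[[1]]
  cyc <- list(R = c("R", "G", "B"), G = c("G", "B", "R"), B = c("B", "R", "G"))
  xyz <- chans[cyc[[parts[2]]]]
  x <- xyz[1]; y <- xyz[2]; z <- xyz[3]
  dv <- function(n, d) if (d == 0) 0 else n / d
  unname(switch(parts[1],
         PAT = dv(x, x + y),
         DIF = 2 * x - y - z,
         ROO = dv(x, y),
         GLD = dv(x - y, x + z)))
}

# render an ellipse by evaluating the inequality per pixel, independent of
# the generator's vectorized renderer
brute_ellipse_pixels <- function(h, w, cr, cc, a, b, theta) {
  out <- NULL
  for (i in seq_len(h)) for (j in seq_len(w)) {
    dr <- i - cr; dc <- j - cc
    u <- dr * cos(theta) + dc * sin(theta)
    v <- -dr * sin(theta) + dc * cos(theta)
    if ((u / a)^2 + (v / b)^2 <= 1) out <- rbind(out, c(i, j))
  }
  out
}

# helper: a quick scene -> POI mask via the full extraction chain; the POI
# clusters are identified as every cluster other than the one dominating
# the image border (the background)
scene_poi_mask <- function(scene, k = 2, kmeans_seed = 0L) {
  img <- scene$image
  h <- dim(img)[1]; w <- dim(img)[2]
  idx <- compute_index_stack(img)
  fm <- build_feature_matrix(img, idx)
  pcs <- pca_block(fm, "index")
  gray <- scale_to_gray(pc_field(pcs, 1, h, w))
  cl <- kmeans_labels(gray, k, seed = kmeans_seed)
  border <- c(cl$labels[1, ], cl$labels[h, ], cl$labels[, 1], cl$labels[, w])
  bg <- as.integer(names(which.max(table(border))))
  select_clusters(cl, setdiff(0:(cl$k - 1L), bg))
}
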