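# Ground-truthed synthetic scenes: colored ellipse "kernels" on a
# contrasting background with controlled adjacency, specks and an optional
# reference disk. These emulate seed photographs — flat fill plus Gaussian
# pixel noise — and are the test bed for the whole pipeline.

#' Specify a synthetic scene
#'
#' @param width,height canvas size in pixels.
#' @param n_objects number of ellipse kernels.
#' @param semi_axes_mean,semi_axes_sd mean and sd (pixels) of the major and
#'   minor semi-axes; draws are truncated below at 2 px.
#' @param fill_color,background integer RGB triples; `background` also
#'   accepts the presets `"white"` (235) and `"black"` (20).
#' @param noise_sd per-pixel Gaussian noise sd added to every channel.
#' @param fraction_touching fraction of objects placed as tangent pairs
#'   (rounded to whole pairs); tangent members stay disjoint in the truth
#'   but fuse into one component in the POI mask.
#' @param n_specks number of small circular noise specks, colored like the
#'   objects; speck radius is capped so speck area stays below 20% of the
#'   smallest object.
#' @param speck_radius numeric length 2, speck radius range in pixels.
#' @param reference optional `list(radius = px, area_mm2 = known area)`
#'   reference disk.
#' @param wrinkle_amp sinusoidal boundary perturbation amplitude in pixels
#'   (0 = smooth ellipses); exercises the shrink-split path.
#' @param wrinkle_freq angular frequency of the wrinkle.
#' @param clearance minimum background gap (pixels) between non-touching
#'   objects.
#' @param seed RNG seed; fixed seed gives bit-identical scenes.
#' @return list of class `"scene_spec"`.
#' @export
scene_spec <- function(width = 400L, height = 400L, n_objects = 20L,
                       semi_axes_mean = c(9, 5), semi_axes_sd = c(0.5, 0.35),
                       fill_color = c(70L, 45L, 35L), background = "white",
                       noise_sd = 3, fraction_touching = 0,
                       n_specks = 0L, speck_radius = c(1, 2),
                       reference = NULL, wrinkle_amp = 0, wrinkle_freq = 7,
                       clearance = 3, seed = 0L) {
  if (is.character(background))
    background <- switch(match.arg(background, c("white", "black")),
                         white = c(235L, 235L, 235L), black = c(20L, 20L, 20L))
  if (n_objects < 0) stop_validation("'n_objects' must be >= 0")
  if (fraction_touching < 0 || fraction_touching > 1)
    stop_validation("'fraction_touching' must be in [0, 1]")
  if (any(fill_color < 0 | fill_color > 255) ||
      any(background < 0 | background > 255))
    stop_validation("colors must be within 0..255")
  if (!is.null(reference) &&
      (is.null(reference$radius) || is.null(reference$area_mm2)))
    stop_validation("'reference' needs elements 'radius' and 'area_mm2'")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_objects = as.integer(n_objects),
                 semi_axes_mean = semi_axes_mean, semi_axes_sd = semi_axes_sd,
                 fill_color = fill_color, background = background,
                 noise_sd = noise_sd, fraction_touching = fraction_touching,
                 n_specks = as.integer(n_specks), speck_radius = speck_radius,
                 reference = reference, wrinkle_amp = wrinkle_amp,
                 wrinkle_freq = wrinkle_freq, clearance = clearance,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# support radius of a rotated ellipse along direction (dr, dc) =
# (sin(phi), cos(phi)); matches the renderer's rotation convention, where a
# point t px from the center along phi has (u, v) = t (sin(phi + theta),
# cos(phi + theta)) in axis coordinates
ellipse_support <- function(a, b, theta, phi) {
  1 / sqrt((sin(phi + theta) / a)^2 + (cos(phi + theta) / b)^2)
}

# render one (possibly wrinkled) ellipse; returns (row, col) pixel indices
render_ellipse <- function(h, w, cr, cc, a, b, theta, amp = 0, freq = 7) {
  rad <- ceiling(a + abs(amp) + 1)
  r0 <- max(1, floor(cr - rad)); r1 <- min(h, ceiling(cr + rad))
  c0 <- max(1, floor(cc - rad)); c1 <- min(w, ceiling(cc + rad))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  rr <- rep(r0:r1, times = c1 - c0 + 1)
  cc2 <- rep(c0:c1, each = r1 - r0 + 1)
  dr <- rr - cr; dc <- cc2 - cc
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  lim <- 1
  if (amp != 0) {
    phi <- atan2(v, u)
    lim <- 1 + amp * sin(freq * phi) / min(a, b)
  }
  sel <- rho <= lim
  cbind(row = rr[sel], col = cc2[sel])
}

# normalized ellipse radius of pixels, for ownership ties in touching pairs
ellipse_rho <- function(px, cr, cc, a, b, theta) {
  dr <- px[, 1] - cr; dc <- px[, 2] - cc
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  sqrt((u / a)^2 + (v / b)^2)
}

place_attempts <- 10000L

#' Generate a ground-truthed synthetic scene
#'
#' Deterministic for a fixed seed. Objects are placed by rejection sampling
#' (up to 10,000 attempts per object, otherwise a generation error suggests
#' a larger canvas). Tangent pairs share a contact band but every pixel has
#' exactly one true owner. Truth length/width are the analytic axis lengths
#' `2a`/`2b`; when a reference disk is present, millimeter truth uses
#' `mm = px * sqrt(area_mm2 / ref_area_px)` identically.
#'
#' @param spec a [scene_spec()].
#' @return list of class `"seed_scene"`: `image` (h x w x 3 integer array),
#'   `truth` (list: `objects` data frame, `labels` truth label matrix,
#'   `count`, `reference`, `specks`), `spec`.
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop_validation("'spec' must be a scene_spec")
  with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  h <- spec$height; w <- spec$width
  n <- spec$n_objects
  labels <- matrix(0L, h, w)

  placed <- data.frame(cr = numeric(0), cc = numeric(0), rad = numeric(0))
  can_place <- function(cr, cc, rad, gap) {
    if (cr - rad < 2 || cr + rad > h - 1 || cc - rad < 2 || cc + rad > w - 1)
      return(FALSE)
    if (!nrow(placed)) return(TRUE)
    all(sqrt((placed$cr - cr)^2 + (placed$cc - cc)^2) >
          placed$rad + rad + gap)
  }
  draw_center <- function(rad) c(runif(1, rad + 2, h - rad - 1),
                                 runif(1, rad + 2, w - rad - 1))

  n_pairs <- round(spec$fraction_touching * n / 2)
  kinds <- c(rep("pair", n_pairs), rep("single", n - 2L * n_pairs))

  objects <- data.frame()
  next_lab <- 0L
  add_object <- function(cr, cc, a, b, theta, touching) {
    next_lab <<- next_lab + 1L
    px <- render_ellipse(h, w, cr, cc, a, b, theta,
                         spec$wrinkle_amp, spec$wrinkle_freq)
    owned <- px[labels[px] == 0L, , drop = FALSE]
    clash <- px[labels[px] != 0L, , drop = FALSE]
    if (nrow(clash)) {
      # contact band of a touching pair: a pixel goes to the nearer boundary
      other <- unique(labels[clash])
      for (o in other) {
        op <- objects[objects$id == o, ]
        cpx <- clash[labels[clash] == o, , drop = FALSE]
        rho_new <- ellipse_rho(cpx, cr, cc, a, b, theta)
        rho_old <- ellipse_rho(cpx, op$center_row + 1, op$center_col + 1,
                               op$semi_major, op$semi_minor, op$rotation)
        take <- cpx[rho_new < rho_old, , drop = FALSE]
        if (nrow(take)) {
          labels[take] <<- 0L
          owned <- rbind(owned, take)
        }
      }
    }
    labels[owned] <<- next_lab
    objects <<- rbind(objects, data.frame(
      id = next_lab, center_row = cr - 1, center_col = cc - 1,
      semi_major = a, semi_minor = b, rotation = theta,
      length_px = 2 * a, width_px = 2 * b, touching = touching))
    next_lab
  }
  sample_axes <- function() {
    a <- max(2, rnorm(1, spec$semi_axes_mean[1], spec$semi_axes_sd[1]))
    b <- max(2, rnorm(1, spec$semi_axes_mean[2], spec$semi_axes_sd[2]))
    c(max(a, b), min(a, b))
  }

  for (kind in kinds) {
    ax1 <- sample_axes()
    rad1 <- ax1[1] + abs(spec$wrinkle_amp)
    if (kind == "single") {
      ok <- FALSE
      for (att in seq_len(place_attempts)) {
        ctr <- draw_center(rad1)
        if (can_place(ctr[1], ctr[2], rad1, spec$clearance)) { ok <- TRUE; break }
      }
      if (!ok) stop_validation(
        "could not place all objects after %d attempts; use a larger canvas",
        place_attempts)
      theta <- runif(1, 0, pi)
      add_object(ctr[1], ctr[2], ax1[1], ax1[2], theta, FALSE)
      placed <- rbind(placed, data.frame(cr = ctr[1], cc = ctr[2], rad = rad1))
    } else {
      ax2 <- sample_axes()
      rad2 <- ax2[1] + abs(spec$wrinkle_amp)
      ok <- FALSE
      for (att in seq_len(place_attempts)) {
        # the pair needs clearance from everyone else but not from each other
        ctr <- draw_center(rad1 + 2 * rad2)
        if (!can_place(ctr[1], ctr[2], rad1 + 2 * rad2, spec$clearance)) next
        ok <- TRUE; break
      }
      if (!ok) stop_validation(
        "could not place all objects after %d attempts; use a larger canvas",
        place_attempts)
      th1 <- runif(1, 0, pi); th2 <- runif(1, 0, pi)
      phi <- runif(1, 0, 2 * pi)
      d <- ellipse_support(ax1[1], ax1[2], th1, phi) +
           ellipse_support(ax2[1], ax2[2], th2, phi + pi)
      id1 <- add_object(ctr[1], ctr[2], ax1[1], ax1[2], th1, TRUE)
      # walk the partner inward until the rendered sets become 8-adjacent
      for (step in seq(0, 6, by = 0.5)) {
        cr2 <- ctr[1] + (d - step) * sin(phi)
        cc2 <- ctr[2] + (d - step) * cos(phi)
        px2 <- render_ellipse(h, w, cr2, cc2, ax2[1], ax2[2], th2,
                              spec$wrinkle_amp, spec$wrinkle_freq)
        if (touches_label(labels, px2, id1) || step == 6) {
          add_object(cr2, cc2, ax2[1], ax2[2], th2, TRUE)
          break
        }
      }
      placed <- rbind(placed, data.frame(cr = ctr[1], cc = ctr[2],
                                         rad = rad1 + 2 * rad2))
    }
  }

  # reference disk, rendered in the object color so it lands in the POI
  reference <- NULL
  if (!is.null(spec$reference)) {
    rrad <- spec$reference$radius
    ok <- FALSE
    for (att in seq_len(place_attempts)) {
      ctr <- draw_center(rrad)
      if (can_place(ctr[1], ctr[2], rrad, spec$clearance)) { ok <- TRUE; break }
    }
    if (!ok) stop_validation(
      "could not place the reference disk; use a larger canvas")
    next_lab <- next_lab + 1L
    px <- render_ellipse(h, w, ctr[1], ctr[2], rrad, rrad, 0)
    labels[px] <- next_lab
    reference <- list(id = next_lab, center = ctr - 1, radius = rrad,
                      area_px = nrow(px), area_mm2 = spec$reference$area_mm2)
    placed <- rbind(placed, data.frame(cr = ctr[1], cc = ctr[2], rad = rrad))
  }

  # specks: small disks, area capped below 20% of the smallest object
  specks <- data.frame()
  if (spec$n_specks > 0L && nrow(objects)) {
    min_area <- min(vapply(objects$id, function(i) sum(labels == i), numeric(1)))
    rcap <- sqrt(0.2 * min_area / pi) * 0.999
    for (s in seq_len(spec$n_specks)) {
      srad <- min(runif(1, spec$speck_radius[1], spec$speck_radius[2]), rcap)
      for (att in seq_len(place_attempts)) {
        ctr <- draw_center(srad)
        if (can_place(ctr[1], ctr[2], srad, 2)) break
      }
      next_lab <- next_lab + 1L
      px <- render_ellipse(h, w, ctr[1], ctr[2], srad, srad, 0)
      labels[px] <- next_lab
      specks <- rbind(specks, data.frame(id = next_lab, radius = srad,
                                         area_px = nrow(px)))
      placed <- rbind(placed, data.frame(cr = ctr[1], cc = ctr[2], rad = srad))
    }
  }

  # recorded areas are the rendered pixel-set sizes
  if (nrow(objects))
    objects$area_px <- vapply(objects$id, function(i) sum(labels == i),
                              numeric(1))
  if (!is.null(reference)) {
    lr <- sqrt(reference$area_mm2 / reference$area_px)
    objects$length_mm <- objects$length_px * lr
    objects$width_mm <- objects$width_px * lr
    objects$area_mm2 <- objects$area_px * lr^2
  }

  img <- array(0, c(h, w, 3))
  fg <- labels != 0L
  for (ch in 1:3) {
    plane <- matrix(spec$background[ch], h, w)
    plane[fg] <- spec$fill_color[ch]
    if (spec$noise_sd > 0) plane <- plane + rnorm(h * w, 0, spec$noise_sd)
    img[, , ch] <- plane
  }
  img <- array(as.integer(pmin(255, pmax(0, round_half_up(img)))), c(h, w, 3),
               dimnames = list(NULL, NULL, c("R", "G", "B")))

  structure(list(image = img,
                 truth = list(objects = objects, labels = labels,
                              count = nrow(objects), reference = reference,
                              specks = specks),
                 spec = spec),
            class = "seed_scene")
}

# TRUE when any pixel of px is 8-adjacent to (or on) a pixel labeled `id`
touches_label <- function(labels, px, id) {
  if (!nrow(px)) return(FALSE)
  h <- nrow(labels); w <- ncol(labels)
  for (dr in -1:1) for (dc in -1:1) {
    r <- px[, 1] + dr; c <- px[, 2] + dc
    keep <- r >= 1 & r <= h & c >= 1 & c <= w
    if (any(labels[cbind(r[keep], c[keep])] == id)) return(TRUE)
  }
  FALSE
}

#' Score a segmentation against scene ground truth
#'
#' Greedy one-to-one matching of predicted segments to truth objects by
#' descending intersection-over-union, then count and measurement errors.
#'
#' @param ss a `"segment_set"` over the scene's canvas.
#' @param truth the `truth` element of a [generate_scene()] result.
#' @param measurements optional data frame from [measure_segments()]; adds
#'   per-object relative length/width errors for matched pairs.
#' @param exclude_pred_ids predicted ids to leave out (e.g. the segment
#'   matching the reference disk).
#' @return list: `count_true`, `count_pred`, `count_error`, `matches`
#'   (data frame `truth_id, pred_id, iou`), `unmatched_truth`,
#'   `unmatched_pred`, and (with measurements) `length_rel_err`,
#'   `width_rel_err` vectors aligned with `matches`.
#' @export
score_against_truth <- function(ss, truth, measurements = NULL,
                                exclude_pred_ids = integer(0)) {
  pred <- ss$labels
  if (length(exclude_pred_ids)) pred[pred %in% exclude_pred_ids] <- 0L
  tl <- truth$labels
  if (!is.null(truth$reference)) tl[tl == truth$reference$id] <- 0L
  if (nrow(truth$specks)) tl[tl %in% truth$specks$id] <- 0L

  pred_ids <- setdiff(ss$stats$id, exclude_pred_ids)
  truth_ids <- truth$objects$id
  both <- pred > 0L & tl > 0L
  inter <- if (any(both)) {
    as.data.frame(table(pred = pred[both], truth = tl[both]),
                  stringsAsFactors = FALSE)
  } else data.frame(pred = integer(0), truth = integer(0), Freq = integer(0))
  inter <- inter[inter$Freq > 0, , drop = FALSE]
  inter$pred <- as.integer(as.character(inter$pred))
  inter$truth <- as.integer(as.character(inter$truth))
  pa <- stats::setNames(ss$stats$area, ss$stats$id)
  ta <- stats::setNames(truth$objects$area_px, truth$objects$id)
  inter$iou <- inter$Freq /
    (pa[as.character(inter$pred)] + ta[as.character(inter$truth)] - inter$Freq)

  inter <- inter[order(-inter$iou, inter$truth, inter$pred), , drop = FALSE]
  used_p <- integer(0); used_t <- integer(0)
  matches <- data.frame(truth_id = integer(0), pred_id = integer(0),
                        iou = numeric(0))
  for (i in seq_len(nrow(inter))) {
    if (inter$pred[i] %in% used_p || inter$truth[i] %in% used_t) next
    matches <- rbind(matches, data.frame(truth_id = inter$truth[i],
                                         pred_id = inter$pred[i],
                                         iou = inter$iou[i]))
    used_p <- c(used_p, inter$pred[i]); used_t <- c(used_t, inter$truth[i])
  }
  out <- list(count_true = length(truth_ids),
              count_pred = length(pred_ids),
              count_error = length(pred_ids) - length(truth_ids),
              matches = matches,
              unmatched_truth = setdiff(truth_ids, matches$truth_id),
              unmatched_pred = setdiff(pred_ids, matches$pred_id))
  if (!is.null(measurements) && nrow(matches)) {
    mrow <- match(matches$pred_id, measurements$id)
    trow <- match(matches$truth_id, truth$objects$id)
    out$length_rel_err <- abs(measurements$length_px[mrow] -
                              truth$objects$length_px[trow]) /
                          truth$objects$length_px[trow]
    out$width_rel_err <- abs(measurements$width_px[mrow] -
                             truth$objects$width_px[trow]) /
                         truth$objects$width_px[trow]
  }
  out
}
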