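# Analytic ray casting against sphere / axis-aligned-box OOIs. These are the
# standard closed forms: the quadratic for spheres, the slab method for
# boxes. Only the entry distance along the ray matters; a ray starting
# inside an object hits it at distance 0 (t clamped to [0, k]).

# distance along the ray to the first intersection with one OOI, or Inf;
# vectorized over rays (origin fixed, dirs an n x 3 matrix of unit rows)
.ooi_hit_dist <- function(o, origin, dirs, k) {
  n <- nrow(dirs)
  if (o$shape == "sphere") {
    oc <- matrix(origin - o$center, nrow = n, ncol = 3, byrow = TRUE)
    b <- rowSums(dirs * oc)                      # half-b of the quadratic
    cc <- sum((origin - o$center)^2) - o$radius^2
    disc <- b^2 - cc
    t1 <- -b - sqrt(pmax(disc, 0))
    t2 <- -b + sqrt(pmax(disc, 0))
    t <- ifelse(t1 >= 0, t1, ifelse(t2 >= 0, 0, Inf))  # inside => entry at 0
    t[disc < 0] <- Inf
  } else {
    # slab method, componentwise over the three axes
    t <- rep(0, n); tfar <- rep(k, n)
    for (ax in 1:3) {
      d <- dirs[, ax]; oax <- origin[ax]
      par <- abs(d) < 1e-300
      lo <- (o$min[ax] - oax) / d
      hi <- (o$max[ax] - oax) / d
      tn <- pmin(lo, hi); tf <- pmax(lo, hi)
      tn[par] <- if (oax >= o$min[ax] && oax <= o$max[ax]) -Inf else Inf
      tf[par] <- if (oax >= o$min[ax] && oax <= o$max[ax]) Inf else -Inf
      t <- pmax(t, tn); tfar <- pmin(tfar, tf)
    }
    t[t > tfar] <- Inf
  }
  t[t > k] <- Inf
  t
}

#' First OOI hit by a gaze ray
#'
#' Intersects the gaze ray with every collidable OOI in the scene and
#' returns the one with the smallest non-negative hit distance within the
#' ray length, mirroring engine line-trace semantics ("only the first hit
#' object is returned"). Exact distance ties are broken by scene declaration
#' order. Non-collidable OOIs never occlude anything.
#'
#' @param ray A [global_gaze_ray()].
#' @param scene A [scene()].
#' @return List of class `hit_record`: `hit` (logical), and when `TRUE` also
#'   `target_name`, `impact_point` (uu) and `distance` (uu).
#' @export
first_hit <- function(ray, scene) {
  stopifnot(inherits(ray, "gaze_ray"), inherits(scene, "gaze_scene"))
  dirs <- matrix(ray$direction, nrow = 1)
  best_t <- Inf; best_name <- NA_character_
  for (o in scene$oois) {
    if (!o$collidable) next
    t <- .ooi_hit_dist(o, ray$origin, dirs, ray$length_k)
    if (t < best_t) { best_t <- t; best_name <- o$name }  # strict: order breaks ties
  }
  if (!is.finite(best_t)) {
    return(structure(list(hit = FALSE, target_name = NULL,
                          impact_point = NULL, distance = NULL),
                     class = "hit_record"))
  }
  structure(list(hit = TRUE, target_name = best_name,
                 impact_point = ray$origin + ray$direction * best_t,
                 distance = best_t),
            class = "hit_record")
}

#' @export
print.hit_record <- function(x, ...) {
  if (x$hit) {
    cat(sprintf("<hit_record> %s at distance %.3f uu\n", x$target_name, x$distance))
  } else {
    cat("<hit_record> miss\n")
  }
  invisible(x)
}

# Vectorized first-hit target names for many rays from one origin.
# dirs: n x 3 matrix of unit direction rows. Returns character vector with
# NA for misses.
cast_rays <- function(origin, dirs, scene, k = 25000) {
  n <- nrow(dirs)
  best_t <- rep(Inf, n)
  best <- rep(NA_character_, n)
  for (o in scene$oois) {
    if (!o$collidable) next
    t <- .ooi_hit_dist(o, origin, dirs, k)
    better <- t < best_t
    best_t[better] <- t[better]
    best[better] <- o$name
  }
  best
}

#' Label raw samples with their gaze target
#'
#' Runs the full per-frame geometry for a raw log: local gaze direction ->
#' yaw/pitch -> rotation of the head forward vector -> global gaze ray ->
#' first OOI hit. Adds (or overwrites) the `gaze_target` column; frames
#' whose ray misses every OOI get the label `"none"`.
#'
#' Expects the raw-log columns `gaze_x`, `gaze_y`, `gaze_z` (local frame)
#' and the head pose either as shared `head` argument or per-row columns
#' `head_x, head_y, head_z, head_yaw_deg, head_pitch_deg, head_roll_deg`.
#'
#' @param samples Data frame of raw samples.
#' @param scene A [scene()].
#' @param k Ray length in uu.
#' @param head Optional single [head_pose()] shared by all rows (fast path);
#'   otherwise per-row head columns are used.
#' @return `samples` with a `gaze_target` character column.
#' @export
label_gaze_targets <- function(samples, scene, k = 25000, head = NULL) {
  stopifnot(is.data.frame(samples), inherits(scene, "gaze_scene"))
  need <- c("gaze_x", "gaze_y", "gaze_z")
  if (!all(need %in% names(samples))) {
    stop("samples need columns gaze_x, gaze_y, gaze_z", call. = FALSE)
  }
  g <- as.matrix(samples[, need])
  nr <- sqrt(rowSums(g^2))
  ok <- is.finite(nr) & nr > 0
  gd <- g / ifelse(nr > 0, nr, 1)

  if (is.null(head)) {
    hcols <- c("head_x", "head_y", "head_z",
               "head_yaw_deg", "head_pitch_deg", "head_roll_deg")
    if (!all(hcols %in% names(samples))) {
      stop("no shared head pose given and per-row head columns are missing",
           call. = FALSE)
    }
    hp <- unique(samples[, hcols])
    if (nrow(hp) == 1L) {
      head <- head_pose(position = as.numeric(hp[1, 1:3]),
                        yaw_deg = hp[[4]][1], pitch_deg = hp[[5]][1],
                        roll_deg = hp[[6]][1])
    }
  }

  if (!is.null(head)) {
    dirs <- .world_dirs_fixed_head(gd, head)
    target <- rep(NA_character_, nrow(samples))
    target[ok] <- cast_rays(head$position, dirs[ok, , drop = FALSE], scene, k)
  } else {
    target <- rep(NA_character_, nrow(samples))
    for (i in seq_len(nrow(samples))) {
      if (!ok[i]) next
      hd <- head_pose(position = c(samples$head_x[i], samples$head_y[i], samples$head_z[i]),
                      yaw_deg = samples$head_yaw_deg[i],
                      pitch_deg = samples$head_pitch_deg[i],
                      roll_deg = samples$head_roll_deg[i])
      ang <- gaze_angles(gd[i, ])
      ray <- global_gaze_ray(hd, rotate_forward(hd, ang), k)
      hit <- first_hit(ray, scene)
      target[i] <- if (hit$hit) hit$target_name else NA_character_
    }
  }
  target[is.na(target)] <- "none"
  samples$gaze_target <- target
  samples
}

# World directions for a matrix of unit local gaze rows under one head pose.
# The yaw-then-pitch rotation about the head axes equals R_head applied to
# the fixed local->world conversion, so the whole batch is one matrix
# product.
.world_dirs_fixed_head <- function(gd, head) {
  R <- cbind(head$forward, head$right, head$up)
  conv <- cbind(gd[, 3], -gd[, 1], gd[, 2])   # local -> world at identity
  conv %*% t(R)
}
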