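# Coordinate conventions
#
# Two frames are used throughout:
#   * local (eye tracker): right-handed, z forward, x left, y up. Local gaze
#     directions are reported in this frame as unit vectors.
#   * world (engine): left-handed, x forward, y right, z up. Head poses,
#     scene geometry and gaze rays live here. Lengths are "unreal units"
#     (uu), 1 uu = 1 cm.
#
# The fixed change of frame maps a local vector (x, y, z) to the world
# vector (z, -x, y): local-forward to world-forward, local-left to
# world-minus-right, local-up to world-up.

DEG <- 180 / pi

#' Construct a 3-vector
#'
#' A plain numeric length-3 vector in either the local eye-tracker frame or
#' the world frame; units depend on context (uu for positions, unitless for
#' directions).
#'
#' @param x,y,z Finite numeric scalars.
#' @return Numeric vector `c(x, y, z)`.
#' @export
vec3 <- function(x, y, z) {
  v <- c(as.numeric(x), as.numeric(y), as.numeric(z))
  if (length(v) != 3L || any(!is.finite(v))) {
    stop("vec3 components must be three finite numbers", call. = FALSE)
  }
  v
}

vnorm <- function(v) sqrt(sum(v^2))

#' Normalize a vector to unit length
#' @param v Numeric length-3 vector with positive norm.
#' @return Unit vector in the same direction.
#' @export
normalize <- function(v) {
  n <- vnorm(v)
  if (!is.finite(n) || n <= 0) stop("cannot normalize a zero or non-finite vector", call. = FALSE)
  v / n
}

# signum with the convention sgn(0) := +1
sgn1 <- function(x) ifelse(x < 0, -1, 1)

check_vec3 <- function(v, what = "vector") {
  if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v))) {
    stop(sprintf("%s must be a finite numeric length-3 vector", what), call. = FALSE)
  }
  invisible(v)
}

# Rodrigues rotation of v about unit axis k by angle theta (radians),
# right-hand rule in the component formulas.
rotate_about <- function(v, k, theta) {
  ct <- cos(theta); st <- sin(theta)
  v * ct + cross3(k, v) * st + k * sum(k * v) * (1 - ct)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Fixed local (eye tracker) -> world change of frame.
local_to_world <- function(g) c(g[3], -g[1], g[2])
world_to_local <- function(w) c(-w[2], w[3], w[1])

#' Head pose in the world frame
#'
#' Position plus orientation of the head-mounted display. Orientation may be
#' given as a unit quaternion `c(w, x, y, z)` or as intrinsic yaw / pitch /
#' roll angles in degrees (yaw positive to the right, pitch positive up).
#' Internally the pose stores the orthonormal forward / right / up triad.
#'
#' @param position Numeric length-3, head location in uu.
#' @param quaternion Optional unit quaternion `c(w, x, y, z)`.
#' @param yaw_deg,pitch_deg,roll_deg Orientation angles, used when no
#'   quaternion is given. Defaults give the identity pose (facing world +x).
#' @return An object of class `head_pose` with fields `position`, `forward`,
#'   `right`, `up`.
#' @examples
#' head_pose()                       # identity, at the origin
#' head_pose(c(0, 0, 150), yaw_deg = 90)
#' @export
head_pose <- function(position = c(0, 0, 0), quaternion = NULL,
                      yaw_deg = 0, pitch_deg = 0, roll_deg = 0) {
  check_vec3(position, "head position")
  if (!is.null(quaternion)) {
    q <- as.numeric(quaternion)
    if (length(q) != 4L || any(!is.finite(q))) {
      stop("quaternion must be a finite numeric length-4 vector c(w, x, y, z)", call. = FALSE)
    }
    if (abs(vnorm(q) - 1) > 1e-9) {
      stop("quaternion must have unit norm (tolerance 1e-9)", call. = FALSE)
    }
    R <- quat_to_matrix(q)
  } else {
    R <- ypr_to_matrix(yaw_deg, pitch_deg, roll_deg)
  }
  pose <- list(position = position,
               forward = R[, 1], right = R[, 2], up = R[, 3])
  class(pose) <- "head_pose"
  check_triad(pose)
  pose
}

# columns are the images of world x (forward), y (right), z (up)
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = FALSE)
}

# Intrinsic yaw (about up), then pitch (about post-yaw right, positive up),
# then roll (about the resulting forward). Matches the seated, roll-free
# scenario exactly; roll is supported for completeness.
ypr_to_matrix <- function(yaw_deg, pitch_deg, roll_deg) {
  f <- c(1, 0, 0); r <- c(0, 1, 0); u <- c(0, 0, 1)
  yw <- yaw_deg / DEG; pt <- pitch_deg / DEG; rl <- roll_deg / DEG
  f1 <- rotate_about(f, u, yw); r1 <- rotate_about(r, u, yw)
  f2 <- rotate_about(f1, r1, -pt); u2 <- rotate_about(u, r1, -pt)
  r3 <- rotate_about(r1, f2, rl); u3 <- rotate_about(u2, f2, rl)
  cbind(f2, r3, u3, deparse.level = 0)
}

check_triad <- function(pose) {
  R <- cbind(pose$forward, pose$right, pose$up)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
    stop("head pose triad is not orthonormal (tolerance 1e-9)", call. = FALSE)
  }
  invisible(pose)
}

#' @export
print.head_pose <- function(x, ...) {
  cat("<head_pose> position (uu):", format(x$position), "\n")
  cat("  forward:", format(round(x$forward, 6)), "\n")
  cat("  right:  ", format(round(x$right, 6)), "\n")
  cat("  up:     ", format(round(x$up, 6)), "\n")
  invisible(x)
}

#' Yaw and pitch of a local gaze direction
#'
#' Converts a normalized gaze direction reported in the local eye-tracker
#' frame (right-handed, z forward, x left, y up) into the yaw and pitch
#' angles, in degrees, by which the head-forward vector must be rotated to
#' point along the gaze. The sign convention absorbs the change of
#' handedness between the eye-tracker and world frames: yaw is
#' `-acos(z / sqrt(x^2 + z^2)) * sgn(x)` and pitch is
#' `acos(sqrt(x^2 + z^2)) * sgn(y)` (both scaled to degrees), with
#' `sgn(0) := +1`. A purely vertical gaze (`x = z = 0`) has undefined yaw;
#' the convention `yaw = 0` is used.
#'
#' @param local_gaze Unit vector in the local frame (norm within 1e-6 of 1).
#' @return List with `yaw_deg` in \[-180, 180\] and `pitch_deg` in \[-90, 90\];
#'   both 0 when the gaze equals the local forward (0, 0, 1).
#' @examples
#' gaze_angles(c(0, 0, 1))               # straight ahead: 0, 0
#' gaze_angles(c(1, 0, 0))               # full left: yaw -90
#' gaze_angles(c(0, 1, 0) )              # straight up: pitch +90
#' @export
gaze_angles <- function(local_gaze) {
  check_vec3(local_gaze, "local gaze")
  if (abs(vnorm(local_gaze) - 1) > 1e-6) {
    stop("local gaze must be normalized (|norm - 1| <= 1e-6)", call. = FALSE)
  }
  x <- local_gaze[1]; y <- local_gaze[2]; z <- local_gaze[3]
  h <- sqrt(x^2 + z^2)
  yaw <- if (h == 0) 0 else -acos(max(-1, min(1, z / h))) * DEG * sgn1(x)
  pitch <- acos(max(-1, min(1, h))) * DEG * sgn1(y)
  list(yaw_deg = yaw, pitch_deg = pitch)
}

#' Rotate the head-forward vector by gaze yaw and pitch
#'
#' Applies the gaze angles to a head pose: the head's forward direction is
#' rotated by yaw about the head's up axis, then by pitch about the
#' (post-yaw) right axis. With the identity pose this reproduces the fixed
#' frame conversion of the local gaze vector into world coordinates.
#'
#' @param head A [head_pose()].
#' @param angles List with `yaw_deg` and `pitch_deg`, as from [gaze_angles()].
#' @return Unit direction vector in the world frame.
#' @export
rotate_forward <- function(head, angles) {
  stopifnot(inherits(head, "head_pose"))
  yw <- angles$yaw_deg / DEG
  pt <- angles$pitch_deg / DEG
  if (!is.finite(yw) || !is.finite(pt)) stop("gaze angles must be finite", call. = FALSE)
  f1 <- rotate_about(head$forward, head$up, yw)
  r1 <- rotate_about(head$right, head$up, yw)
  normalize(rotate_about(f1, r1, -pt))
}

#' Build the global gaze ray
#'
#' The gaze ray starts at the head position and extends along the rotated
#' forward direction for `k` uu, i.e. the endpoint is
#' `origin + direction * k`. `k` only bounds how far a hit may occur; it is
#' conventionally set very large (default 25000 uu) because the ray stops at
#' the first object anyway.
#'
#' @param head A [head_pose()]; its position is the ray origin.
#' @param f_rotated Unit world-frame direction, as from [rotate_forward()].
#' @param k Positive ray length in uu.
#' @return Object of class `gaze_ray` with `origin`, `direction`, `length_k`.
#' @export
global_gaze_ray <- function(head, f_rotated, k = 25000) {
  stopifnot(inherits(head, "head_pose"))
  check_vec3(f_rotated, "ray direction")
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("ray length k must be a positive number (uu)", call. = FALSE)
  }
  ray <- list(origin = head$position, direction = normalize(f_rotated), length_k = k)
  class(ray) <- "gaze_ray"
  ray
}

#' @export
print.gaze_ray <- function(x, ...) {
  cat("<gaze_ray> origin:", format(x$origin),
      " direction:", format(round(x$direction, 6)),
      " k:", x$length_k, "uu\n")
  invisible(x)
}
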