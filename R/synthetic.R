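# Synthetic VR-classroom sessions with known attention dynamics. The
# generator emulates what the logging pipeline would record on hardware:
# a ~40 samples/s per-frame log of head pose, local gaze direction and
# pupil diameters, driven by a Markov attention process over the scene's
# OOIs, with angular gaze noise and placeholder-coded invalid frames.
# Because the attended sequence and true transition counts are known, every
# downstream stage can be validated against ground truth.

#' Define a Markov attention model
#'
#' Attention moves between OOIs as a discrete Markov chain: the gaze dwells
#' on the current OOI for a random time, then jumps to another OOI chosen
#' by the transition matrix. The diagonal must be zero — a "transition" to
#' the same object is not a gaze shift. Dwell times are truncated-normal
#' (lower bound one frame), a deliberately simple two-parameter choice that
#' is not claimed to match human dwell-time distributions.
#'
#' @param states Ordered character vector of OOI names (>= 2).
#' @param transition_probs Row-stochastic matrix (rows sum to 1 within
#'   1e-9) with zero diagonal; entry \[i, j\] is the probability that a
#'   shift away from state i lands on state j.
#' @param dwell_mean_ms,dwell_sd_ms Positive scalars or per-state vectors.
#' @return Object of class `markov_attention_model`.
#' @export
markov_attention_model <- function(states, transition_probs,
                                   dwell_mean_ms = 2000, dwell_sd_ms = 1000) {
  if (length(states) < 2) stop("need at least two states", call. = FALSE)
  P <- as.matrix(transition_probs)
  if (nrow(P) != length(states) || ncol(P) != length(states)) {
    stop("transition matrix must be square over the states", call. = FALSE)
  }
  if (any(!is.finite(P) | P < 0)) stop("transition probabilities must be finite and >= 0",
                                       call. = FALSE)
  if (any(abs(rowSums(P) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (any(diag(P) != 0)) {
    stop("transition matrix diagonal must be zero (no self-transitions)", call. = FALSE)
  }
  dwell_mean_ms <- rep_len(dwell_mean_ms, length(states))
  dwell_sd_ms <- rep_len(dwell_sd_ms, length(states))
  if (any(dwell_mean_ms <= 0) || any(dwell_sd_ms <= 0)) {
    stop("dwell parameters must be positive", call. = FALSE)
  }
  dimnames(P) <- list(states, states)
  structure(list(states = states, transition_probs = P,
                 dwell_mean_ms = dwell_mean_ms, dwell_sd_ms = dwell_sd_ms),
            class = "markov_attention_model")
}

# truncated normal via rejection, falling back to the bound
rtnorm1 <- function(mean, sd, lower) {
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower) return(x)
  }
  lower
}

#' Sample a dwell-segment sequence from an attention model
#'
#' Draws alternating (OOI, dwell duration) segments from the Markov chain
#' until at least `duration_ms` is covered, then truncates the last segment
#' at the session end. Consecutive segments always differ in OOI.
#'
#' @param model A [markov_attention_model()].
#' @param duration_ms Total session duration to cover (ms).
#' @param seed Optional integer seed; the output is a pure function of
#'   (model, duration, seed).
#' @param min_dwell_ms Lower truncation bound for dwell times (default one
#'   40 FPS frame, 25 ms).
#' @return Data frame with columns `ooi`, `dwell_ms`, `t_start_ms`.
#' @export
sample_attention_sequence <- function(model, duration_ms, seed = NULL,
                                      min_dwell_ms = 25) {
  stopifnot(inherits(model, "markov_attention_model"), duration_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  n_states <- length(model$states)
  state <- sample.int(n_states, 1)
  t <- 0
  ooi <- character(0); dwell <- numeric(0); tstart <- numeric(0)
  while (t < duration_ms) {
    d <- rtnorm1(model$dwell_mean_ms[state], model$dwell_sd_ms[state], min_dwell_ms)
    ooi <- c(ooi, model$states[state])
    dwell <- c(dwell, d)
    tstart <- c(tstart, t)
    t <- t + d
    state <- sample.int(n_states, 1, prob = model$transition_probs[state, ])
  }
  over <- t - duration_ms
  dwell[length(dwell)] <- dwell[length(dwell)] - over   # truncate at session end
  data.frame(ooi = ooi, dwell_ms = dwell, t_start_ms = tstart,
             stringsAsFactors = FALSE)
}

#' Configure a synthetic session
#'
#' Bundles the study conditions of one simulated session. Defaults follow
#' the reference condition the package is validated under: a 15-minute
#' seated lecture sampled at 40 frames per second (one frame every 25 ms,
#' 36,000 frames), 1 degree of angular gaze noise, and 2.5% invalid frames.
#'
#' @param scene A [scene()]; OOI centers are the true gaze targets.
#' @param model A [markov_attention_model()] over (a subset of) the scene's
#'   analysis OOIs; default: near-uniform switching over all analysis OOIs.
#' @param duration_s Session length in seconds (default 900 = 15 min).
#' @param fps Sampling rate, frames per second (default 40).
#' @param seed Integer seed; all randomness in the session derives from it.
#' @param gaze_noise_deg Angular perturbation SD of the true gaze direction
#'   in degrees (default 1).
#' @param invalid_rate Probability that a frame's pupil fields are replaced
#'   by the -1 placeholder (default 0.025).
#' @param fixed_rate If `TRUE` (default) frames fall exactly every
#'   `1000/fps` ms, giving exactly `duration_s * fps` rows; otherwise frame
#'   intervals are exponentially jittered around the nominal period.
#' @param head Head pose of the simulated student (default: seated at the
#'   origin, eye height 150 uu, facing +x).
#' @return Object of class `session_config`.
#' @export
session_config <- function(scene = classroom_scene(),
                           model = NULL,
                           duration_s = 900, fps = 40, seed = 1,
                           gaze_noise_deg = 1, invalid_rate = 0.025,
                           fixed_rate = TRUE,
                           head = head_pose(position = c(0, 0, 150))) {
  stopifnot(inherits(scene, "gaze_scene"), duration_s > 0, fps > 0,
            gaze_noise_deg >= 0, invalid_rate >= 0, invalid_rate < 1)
  if (is.null(model)) {
    k <- length(scene$analysis_oois)
    if (k < 2) stop("default attention model needs >= 2 analysis OOIs", call. = FALSE)
    P <- matrix(1 / (k - 1), k, k); diag(P) <- 0
    model <- markov_attention_model(scene$analysis_oois, P)
  }
  if (!all(model$states %in% scene$analysis_oois)) {
    stop("model states must be analysis OOIs of the scene", call. = FALSE)
  }
  structure(list(scene = scene, model = model, duration_s = duration_s,
                 fps = fps, seed = seed, gaze_noise_deg = gaze_noise_deg,
                 invalid_rate = invalid_rate, fixed_rate = fixed_rate,
                 head = head),
            class = "session_config")
}

# perturb unit world directions (rows of n x 3 matrix) by angles theta
# (radians) about uniformly random orthogonal axes
perturb_dirs <- function(dirs, theta) {
  n <- nrow(dirs)
  if (all(theta == 0)) return(dirs)
  # orthonormal pair per row: e1 = normalize(dir x a), a not parallel to dir
  a <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  near_pole <- abs(dirs[, 3]) > 0.99
  a[near_pole, ] <- matrix(rep(c(0, 1, 0), each = sum(near_pole)), ncol = 3)
  e1 <- cbind(dirs[, 2] * a[, 3] - dirs[, 3] * a[, 2],
              dirs[, 3] * a[, 1] - dirs[, 1] * a[, 3],
              dirs[, 1] * a[, 2] - dirs[, 2] * a[, 1])
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(dirs[, 2] * e1[, 3] - dirs[, 3] * e1[, 2],
              dirs[, 3] * e1[, 1] - dirs[, 1] * e1[, 3],
              dirs[, 1] * e1[, 2] - dirs[, 2] * e1[, 1])
  phi <- stats::runif(n, 0, 2 * pi)
  off <- e1 * cos(phi) + e2 * sin(phi)
  out <- dirs * cos(theta) + off * sin(theta)
  out / sqrt(rowSums(out^2))
}

#' Synthesize a raw eye-tracking session
#'
#' Simulates the full logging pipeline for one participant: a dwell
#' sequence is drawn from the attention model; at each frame the direction
#' from the head to the attended OOI's center is perturbed by angular
#' noise, converted into the local eye-tracker frame, and logged together
#' with the head pose and pupil diameters. With probability `invalid_rate`
#' a frame's pupil fields are set to the -1 placeholder (the gaze target is
#' still computed, as on hardware, where ray casting reports a target
#' whenever a head direction exists). The returned log also carries the
#' ray-cast `gaze_target` labels computed by [label_gaze_targets()].
#'
#' @param config A [session_config()].
#' @return List with `samples` (the raw log data frame: `time_ms`,
#'   `gaze_x/y/z`, `head_*`, `pupil_left_mm`, `pupil_right_mm`,
#'   `gaze_target`), `truth` (list: `segments` dwell data frame,
#'   `true_target` per-frame attended OOI, `transition_counts` matrix) and
#'   `config`.
#' @export
synthesize_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  duration_ms <- config$duration_s * 1000
  frame_ms <- 1000 / config$fps

  segments <- sample_attention_sequence(config$model, duration_ms,
                                        seed = NULL, min_dwell_ms = frame_ms)

  if (config$fixed_rate) {
    time_ms <- seq(0, by = frame_ms, length.out = config$duration_s * config$fps)
  } else {
    gaps <- stats::rexp(ceiling(config$duration_s * config$fps * 1.5), 1 / frame_ms)
    time_ms <- cumsum(gaps)
    time_ms <- time_ms[time_ms < duration_ms]
  }
  n <- length(time_ms)

  # attended OOI per frame
  seg_end <- cumsum(segments$dwell_ms)
  idx <- findInterval(time_ms, c(0, seg_end), rightmost.closed = TRUE)
  idx[idx > nrow(segments)] <- nrow(segments)
  true_target <- segments$ooi[idx]

  # true world direction toward the attended OOI center, plus angular noise
  centers <- vapply(config$scene$oois, ooi_center, numeric(3))
  colnames(centers) <- vapply(config$scene$oois, `[[`, character(1), "name")
  tgt <- t(centers[, true_target, drop = FALSE])
  dirs <- tgt - matrix(config$head$position, n, 3, byrow = TRUE)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  theta <- stats::rnorm(n, 0, config$gaze_noise_deg) / DEG
  dirs <- perturb_dirs(dirs, theta)

  # world -> local eye-tracker frame under the head pose
  R <- cbind(config$head$forward, config$head$right, config$head$up)
  w_head <- dirs %*% R                     # head-frame components (f, r, u)
  gaze <- cbind(-w_head[, 2], w_head[, 3], w_head[, 1])  # local (x left, y up, z fwd)

  pupil_l <- round(stats::rnorm(n, 3.5, 0.3), 3)
  pupil_r <- round(stats::rnorm(n, 3.5, 0.3), 3)
  invalid <- stats::runif(n) < config$invalid_rate
  pupil_l[invalid] <- -1
  pupil_r[invalid] <- -1

  hp <- config$head
  samples <- data.frame(
    time_ms = time_ms,
    gaze_x = gaze[, 1], gaze_y = gaze[, 2], gaze_z = gaze[, 3],
    head_x = hp$position[1], head_y = hp$position[2], head_z = hp$position[3],
    head_yaw_deg = atan2(hp$forward[2], hp$forward[1]) * DEG,
    head_pitch_deg = asin(max(-1, min(1, -hp$forward[3]))) * -DEG,
    head_roll_deg = 0,
    pupil_left_mm = pupil_l,
    pupil_right_mm = pupil_r,
    stringsAsFactors = FALSE
  )
  samples <- label_gaze_targets(samples, config$scene, head = hp)

  # ground-truth transition counts between consecutive differing segments
  K <- length(config$model$states)
  counts <- matrix(0L, K, K, dimnames = list(config$model$states, config$model$states))
  if (nrow(segments) > 1) {
    for (i in seq_len(nrow(segments) - 1L)) {
      counts[segments$ooi[i], segments$ooi[i + 1L]] <-
        counts[segments$ooi[i], segments$ooi[i + 1L]] + 1L
    }
  }

  list(samples = samples,
       truth = list(segments = segments, true_target = true_target,
                    transition_counts = counts),
       config = config)
}
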