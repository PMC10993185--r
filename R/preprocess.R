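#' Read a raw eye-tracking log
#'
#' Raw logs are per-frame CSV files (comma-separated, UTF-8, header row)
#' with at least `time_ms` and, after ray casting, `gaze_target`. Optional
#' columns such as `pupil_left_mm` / `pupil_right_mm` carry validity
#' information; missing eye-tracker data is conventionally encoded with a
#' placeholder value such as -1.
#'
#' @param path CSV file path.
#' @return Data frame of raw samples.
#' @export
read_raw_log <- function(path) {
  if (!file.exists(path)) stop("raw log does not exist: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_ms" %in% names(df)) {
    stop("raw log must have a 'time_ms' column: ", path, call. = FALSE)
  }
  df
}

#' @rdname read_raw_log
#' @param samples Data frame of raw samples.
#' @export
write_raw_log <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_times <- function(time_ms) {
  if (length(time_ms) == 0) return(invisible())
  if (any(!is.finite(time_ms))) {
    stop("non-finite timestamp at row ", which(!is.finite(time_ms))[1], call. = FALSE)
  }
  d <- diff(time_ms)
  if (any(d == 0)) {
    stop("duplicated timestamp at row ", which(d == 0)[1] + 1L, call. = FALSE)
  }
  if (any(d < 0)) {
    stop("timestamps not sorted at row ", which(d < 0)[1] + 1L, call. = FALSE)
  }
  invisible()
}

#' Drop invalid samples and reduce columns
#'
#' Removes rows where any validity column equals the missing-data
#' placeholder (or is `NA`), then keeps only the columns needed downstream
#' ("dimension reduction"): `time_ms`, `gaze_target`, and any requested
#' passthrough columns. The ray-casting pipeline reports a gaze target
#' whenever a head direction exists at all, so placeholder-coded frames
#' must be excluded here — their computed targets are meaningless.
#'
#' @param samples Time-sorted data frame of raw samples.
#' @param validity_columns Character vector of columns checked against the
#'   placeholder (default: the pupil diameters, when present).
#' @param placeholder Missing-data code (default -1).
#' @param keep Extra columns to retain beyond `time_ms` and `gaze_target`.
#' @return List with `samples` (cleaned data frame) and `n_dropped`.
#' @export
clean_samples <- function(samples,
                          validity_columns = intersect(
                            c("pupil_left_mm", "pupil_right_mm"), names(samples)),
                          placeholder = -1,
                          keep = character()) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0) {
    return(list(samples = samples[, intersect(c("time_ms", "gaze_target", keep),
                                              names(samples)), drop = FALSE],
                n_dropped = 0L))
  }
  check_times(samples$time_ms)
  missing_cols <- setdiff(validity_columns, names(samples))
  if (length(missing_cols)) {
    stop("validity columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- rep(FALSE, nrow(samples))
  for (cl in validity_columns) {
    v <- samples[[cl]]
    bad <- bad | is.na(v) | v == placeholder
  }
  kept_cols <- intersect(unique(c("time_ms", "gaze_target", keep)), names(samples))
  list(samples = samples[!bad, kept_cols, drop = FALSE],
       n_dropped = sum(bad))
}

#' Extract gaze transitions from a cleaned sample log
#'
#' A gaze transition is a shift between two successive analysis OOIs, timed
#' from the last sample on the source object to the first sample on the
#' target object. Samples on objects outside the analysis set (walls,
#' scenery, misses) are not transition endpoints, but the time spent on
#' them elapses inside the enclosing transition — the maximum-duration
#' filter is what excludes such indirect shifts: a long duration means the
#' gaze wandered over non-OOI objects rather than moving directly.
#'
#' @param samples Cleaned, time-sorted data frame with `time_ms` and
#'   `gaze_target`.
#' @param analysis_oois Non-empty character vector of OOI names.
#' @param max_duration_ms Upper duration threshold in ms; longer transitions
#'   are dropped and counted. Default 1000 ms.
#' @param participant_id Carried into the output table.
#' @return Object of class `transition_table`: data frame with columns
#'   `participant`, `t_start_ms`, `duration_ms`, `source`, `target`, plus
#'   attributes `n_excluded_duration`, `max_duration_ms`.
#' @examples
#' log <- data.frame(time_ms = c(0, 25, 50, 75, 100),
#'                   gaze_target = c("A", "A", "B", "wall", "C"))
#' extract_transitions(log, c("A", "B", "C"), max_duration_ms = 60)
#' @export
extract_transitions <- function(samples, analysis_oois, max_duration_ms = 1000,
                                participant_id = "p1") {
  stopifnot(is.data.frame(samples))
  if (!all(c("time_ms", "gaze_target") %in% names(samples))) {
    stop("samples need columns time_ms and gaze_target", call. = FALSE)
  }
  if (length(analysis_oois) == 0) stop("analysis_oois must be non-empty", call. = FALSE)
  if (!is.numeric(max_duration_ms) || length(max_duration_ms) != 1L ||
      !is.finite(max_duration_ms) || max_duration_ms <= 0) {
    stop("max_duration_ms must be a positive number", call. = FALSE)
  }
  check_times(samples$time_ms)

  on_ooi <- samples$gaze_target %in% analysis_oois
  t <- samples$time_ms[on_ooi]
  tg <- samples$gaze_target[on_ooi]

  if (length(t) >= 2) {
    chg <- which(tg[-1] != tg[-length(tg)])     # index of the source sample
    t_start <- t[chg]
    duration <- t[chg + 1L] - t[chg]
    src <- tg[chg]
    dst <- tg[chg + 1L]
    ok <- duration <= max_duration_ms
  } else {
    t_start <- duration <- numeric(0)
    src <- dst <- character(0)
    ok <- logical(0)
  }

  out <- data.frame(participant = rep(participant_id, sum(ok)),
                    t_start_ms = t_start[ok],
                    duration_ms = duration[ok],
                    source = src[ok],
                    target = dst[ok],
                    stringsAsFactors = FALSE)
  structure(out,
            n_excluded_duration = sum(!ok),
            max_duration_ms = max_duration_ms,
            class = c("transition_table", "data.frame"))
}

#' Read / write a transition table
#'
#' Transition CSVs use the schema
#' `participant,t_start_ms,duration_ms,source,target`, one file per
#' participant.
#'
#' @param x A `transition_table`.
#' @param path CSV file path.
#' @export
write_transitions <- function(x, path) {
  stopifnot(inherits(x, "transition_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transitions
#' @export
read_transitions <- function(path) {
  if (!file.exists(path)) stop("transition file does not exist: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "t_start_ms", "duration_ms", "source", "target")
  if (!all(need %in% names(df))) {
    stop("transition file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$duration_ms <= 0)) stop("transition durations must be positive", call. = FALSE)
  if (any(df$source == df$target)) stop("self-transitions are not allowed", call. = FALSE)
  structure(df, n_excluded_duration = NA_integer_, max_duration_ms = NA_real_,
            class = c("transition_table", "data.frame"))
}
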