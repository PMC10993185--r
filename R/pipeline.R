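#' Run the per-participant analysis pipeline
#'
#' Orchestrates the staged pipeline for a batch of participants:
#' raw log -> (optional) ray-cast labelling -> cleaning -> transition
#' extraction -> network construction -> structural metrics. Each stage
#' writes its intermediate artifact before the next begins (cleaned CSV,
#' transitions CSV, edge-list CSV + GraphML, metrics JSON), mirroring a
#' staged design in which every step consumes the previous step's smaller
#' file. Participants are processed independently: one failure is recorded
#' in the summary and does not abort the batch.
#'
#' @param inputs Named list or character vector: participant id -> raw log
#'   CSV path. Alternatively a named list of in-memory data frames.
#' @param scene A [scene()] (or path to a scene YAML file).
#' @param output_dir Directory for per-participant artifacts (created if
#'   needed).
#' @param analysis_oois OOI names forming the network nodes; default: the
#'   scene's analysis set.
#' @param max_duration_ms Transition duration threshold (ms), default 1000.
#' @param validity_columns,placeholder Passed to [clean_samples()].
#' @param k Gaze-ray length in uu, default 25000.
#' @param groups,partitions Passed to [metrics_report()].
#' @param recast If `TRUE`, recompute `gaze_target` by ray casting even
#'   when the log already has the column.
#' @param verbose Print per-stage row counts.
#' @return Invisibly, a summary data frame with one row per participant:
#'   row counts in and out of every stage, exclusion counts, and an error
#'   message for failed participants. Written to
#'   `file.path(output_dir, "summary.csv")` as well.
#' @export
run_pipeline <- function(inputs, scene, output_dir,
                         analysis_oois = NULL,
                         max_duration_ms = 1000,
                         validity_columns = NULL, placeholder = -1,
                         k = 25000,
                         groups = NULL, partitions = NULL,
                         recast = FALSE, verbose = TRUE) {
  if (is.character(scene)) scene <- read_scene(scene)
  stopifnot(inherits(scene, "gaze_scene"))
  if (is.null(analysis_oois)) analysis_oois <- scene$analysis_oois
  if (is.character(inputs)) inputs <- as.list(inputs)
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    stop("inputs must be named by participant id", call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- lapply(names(inputs), function(pid) {
    res <- tryCatch({
      raw <- inputs[[pid]]
      if (is.character(raw)) raw <- read_raw_log(raw)
      if (recast || !"gaze_target" %in% names(raw)) {
        raw <- label_gaze_targets(raw, scene, k = k)
      }
      vcols <- if (is.null(validity_columns)) {
        intersect(c("pupil_left_mm", "pupil_right_mm"), names(raw))
      } else validity_columns

      cleaned <- clean_samples(raw, validity_columns = vcols,
                               placeholder = placeholder)
      write_raw_log(cleaned$samples,
                    file.path(output_dir, paste0(pid, "_clean.csv")))

      tab <- extract_transitions(cleaned$samples, analysis_oois,
                                 max_duration_ms = max_duration_ms,
                                 participant_id = pid)
      write_transitions(tab, file.path(output_dir, paste0(pid, "_transitions.csv")))

      net <- build_network(tab, nodes = analysis_oois)
      net$participant_id <- pid
      write_network(net, file.path(output_dir, paste0(pid, "_edges.csv")))
      write_graphml(net, file.path(output_dir, paste0(pid, ".graphml")))

      rep <- metrics_report(net, groups = groups, partitions = partitions)
      write_metrics(rep, file.path(output_dir, paste0(pid, "_metrics.json")))

      if (verbose) {
        message(sprintf(
          "[%s] raw %d -> clean %d (dropped %d) -> transitions %d (excluded %d) -> edges %d",
          pid, nrow(raw), nrow(cleaned$samples), cleaned$n_dropped,
          nrow(tab), attr(tab, "n_excluded_duration"), nrow(net$edges)))
      }
      data.frame(participant = pid,
                 n_raw = nrow(raw),
                 n_clean = nrow(cleaned$samples),
                 n_dropped = cleaned$n_dropped,
                 n_transitions = nrow(tab),
                 n_excluded_duration = attr(tab, "n_excluded_duration"),
                 n_edges = nrow(net$edges),
                 max_duration_ms = max_duration_ms,
                 error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(participant = pid, n_raw = NA_integer_, n_clean = NA_integer_,
                 n_dropped = NA_integer_, n_transitions = NA_integer_,
                 n_excluded_duration = NA_integer_, n_edges = NA_integer_,
                 max_duration_ms = max_duration_ms,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(output_dir, "summary.csv"), row.names = FALSE)
  invisible(summary)
}

#' Plot an attention network over the scene layout
#'
#' Draws the network in a top-down view of the scene: each node at its
#' OOI's (x, y) center (plotted as y right, x forward -> up), edge widths
#' proportional to transition counts. Nodes without a scene position fall
#' back to a deterministic circular layout.
#'
#' @param net An `attention_network`.
#' @param scene Optional [scene()] providing node positions.
#' @param file Optional output path (`.png` or `.svg` chosen by extension);
#'   `NULL` plots to the active device.
#' @param max_lwd Line width of the heaviest edge.
#' @return Invisibly, the node layout matrix used.
#' @export
plot_network <- function(net, scene = NULL, file = NULL, max_lwd = 8) {
  stopifnot(inherits(net, "attention_network"))
  nodes <- net$nodes
  pos <- matrix(NA_real_, length(nodes), 2, dimnames = list(nodes, c("px", "py")))
  if (!is.null(scene)) {
    for (o in scene$oois) {
      if (o$name %in% nodes) {
        ctr <- ooi_center(o)
        pos[o$name, ] <- c(ctr[2], ctr[1])   # top-down: y right, x forward/up
      }
    }
  }
  missing <- which(is.na(pos[, 1]))
  if (length(missing)) {
    span <- if (all(is.na(pos[, 1]))) 100 else max(abs(pos), na.rm = TRUE)
    ang <- 2 * pi * (seq_along(missing) - 1) / max(1, length(missing))
    pos[missing, ] <- span * cbind(cos(ang), sin(ang))
  }

  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 7, height = 7)
    else grDevices::png(file, width = 700, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::plot(pos, type = "n", asp = 1, xlab = "y (uu, right)",
                 ylab = "x (uu, forward)",
                 main = sprintf("Attention network: %s", net$participant_id))
  e <- net$edges
  if (nrow(e) > 0) {
    wmax <- max(e$weight)
    for (i in seq_len(nrow(e))) {
      p1 <- pos[e$source[i], ]; p2 <- pos[e$target[i], ]
      graphics::segments(p1[1], p1[2], p2[1], p2[2],
                         lwd = max(0.5, max_lwd * e$weight[i] / wmax),
                         col = grDevices::grey(0.4, alpha = 0.7))
    }
  }
  graphics::points(pos, pch = 21, bg = "steelblue", cex = 2.4)
  graphics::text(pos, labels = nodes, pos = 3, offset = 0.8)
  invisible(pos)
}
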