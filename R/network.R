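#' Build a weighted attention network from a transition table
#'
#' Groups transitions by ordered (source, target) pair and counts
#' occurrences; the counts become directed edge weights. One network
#' represents the gaze-based visual attention of one participant over one
#' session: nodes are OOIs, an edge weight is the total number of gaze
#' transitions from its source to its target. Supplying a node roster keeps
#' never-gazed OOIs as isolated nodes so that structural variables stay
#' comparable across participants.
#'
#' @param table A [extract_transitions()] result (or a data frame with
#'   `source`, `target` and optionally `participant` columns).
#' @param nodes Optional character vector of node names to include even
#'   when unvisited; endpoint names are always included.
#' @return Object of class `attention_network`: list with `participant_id`,
#'   `nodes` (sorted character), `edges` (data frame `source`, `target`,
#'   `weight`, sorted by source then target), `directed = TRUE` and `meta`.
#' @export
build_network <- function(table, nodes = NULL) {
  stopifnot(is.data.frame(table))
  if (!all(c("source", "target") %in% names(table))) {
    stop("transition table needs source and target columns", call. = FALSE)
  }
  if (nrow(table) > 0 && any(table$source == table$target)) {
    stop("transition table contains self-transitions", call. = FALSE)
  }
  pid <- if ("participant" %in% names(table) && nrow(table) > 0) {
    table$participant[1]
  } else "unknown"

  if (nrow(table) > 0) {
    counts <- stats::aggregate(list(weight = rep(1L, nrow(table))),
                               by = list(source = table$source, target = table$target),
                               FUN = sum)
    counts <- counts[order(counts$source, counts$target), , drop = FALSE]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(source = character(0), target = character(0),
                         weight = integer(0), stringsAsFactors = FALSE)
  }
  all_nodes <- sort(unique(c(nodes, counts$source, counts$target)))
  structure(list(participant_id = pid,
                 nodes = all_nodes,
                 edges = counts,
                 directed = TRUE,
                 meta = list(max_duration_ms = attr(table, "max_duration_ms"),
                             n_transitions = nrow(table))),
            class = "attention_network")
}

#' @export
print.attention_network <- function(x, ...) {
  cat(sprintf("<%s attention_network> participant %s: %d nodes, %d edges, total weight %d\n",
              if (x$directed) "directed" else "undirected",
              x$participant_id, length(x$nodes), nrow(x$edges),
              as.integer(sum(x$edges$weight))))
  invisible(x)
}

total_weight <- function(net) sum(net$edges$weight)

#' Collapse a directed attention network to an undirected one
#'
#' Reciprocal directed weights are summed per unordered node pair, so an
#' undirected edge weight is the total number of transitions between the
#' two OOIs in either direction. Clique analysis requires this form.
#'
#' @param net A directed `attention_network`.
#' @return An `attention_network` with `directed = FALSE`; edges hold
#'   unordered pairs with `source < target` lexicographically.
#' @export
to_undirected <- function(net) {
  stopifnot(inherits(net, "attention_network"))
  if (!net$directed) return(net)
  e <- net$edges
  if (nrow(e) > 0) {
    lo <- pmin(e$source, e$target)
    hi <- pmax(e$source, e$target)
    agg <- stats::aggregate(list(weight = e$weight),
                            by = list(source = lo, target = hi), FUN = sum)
    agg <- agg[order(agg$source, agg$target), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- e
  }
  out <- net
  out$edges <- agg
  out$directed <- FALSE
  out
}

#' Convert an attention network to an igraph graph
#'
#' Edge weights become the `weight` edge attribute; isolated nodes are
#' preserved.
#'
#' @param net An `attention_network`.
#' @return An `igraph` object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "attention_network"))
  g <- igraph::make_empty_graph(n = 0, directed = net$directed)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges) > 0) {
    idx <- rbind(match(net$edges$source, net$nodes),
                 match(net$edges$target, net$nodes))
    g <- igraph::add_edges(g, as.vector(idx), weight = net$edges$weight)
  }
  g
}

#' Serialize / deserialize an attention network
#'
#' The portable on-disk form is an edge-list CSV (`source,target,weight`,
#' sorted by source then target for byte-stable output) plus a JSON sidecar
#' (`<path>.meta.json`) holding the participant id, node roster,
#' directedness and processing metadata, so the round trip is lossless
#' including isolated nodes.
#'
#' @param net An `attention_network`.
#' @param path Edge-list CSV path; the sidecar is written next to it.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns the reconstructed `attention_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "attention_network"))
  e <- net$edges[order(net$edges$source, net$edges$target), , drop = FALSE]
  utils::write.csv(e, path, row.names = FALSE, quote = FALSE)
  meta <- list(participant_id = net$participant_id,
               nodes = as.list(net$nodes),
               directed = net$directed,
               meta = net$meta)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file does not exist: ", path, call. = FALSE)
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "weight") %in% names(e))) {
    stop("edge list must have columns source,target,weight: ", path, call. = FALSE)
  }
  if (nrow(e) > 0) {
    bad <- which(!is.finite(e$weight) | e$weight < 1 | e$weight != round(e$weight))
    if (length(bad)) {
      stop(sprintf("invalid weight at line %d of %s (weights are positive integer counts)",
                   bad[1] + 1L, path), call. = FALSE)
    }
    dup <- which(duplicated(e[, c("source", "target")]))
    if (length(dup)) {
      stop(sprintf("duplicate edge at line %d of %s", dup[1] + 1L, path), call. = FALSE)
    }
    if (any(e$source == e$target)) {
      stop("self-loop edge in ", path, call. = FALSE)
    }
  }
  e <- e[order(e$source, e$target), , drop = FALSE]
  rownames(e) <- NULL
  metapath <- paste0(path, ".meta.json")
  if (file.exists(metapath)) {
    meta <- jsonlite::read_json(metapath, simplifyVector = TRUE)
    nodes <- sort(unique(c(meta$nodes, e$source, e$target)))
    structure(list(participant_id = meta$participant_id,
                   nodes = nodes,
                   edges = e,
                   directed = isTRUE(meta$directed),
                   meta = as.list(meta$meta)),
              class = "attention_network")
  } else {
    structure(list(participant_id = "unknown",
                   nodes = sort(unique(c(e$source, e$target))),
                   edges = e,
                   directed = TRUE,
                   meta = list()),
              class = "attention_network")
  }
}

#' Export an attention network as GraphML
#'
#' Standard GraphML with a `weight` edge attribute, readable by igraph,
#' networkx, Gephi and the like.
#'
#' @param net An `attention_network`.
#' @param path Output file path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
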