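# Structural variables of gaze-based attention networks, grouped as in the
# method: centrality (strength), distribution (weighted degree centrality,
# uniformity), interconnectedness (cut sizes, maximal cliques).

#' Node strength (weighted degree centrality of a node)
#'
#' Sum of the weights of a node's incoming and outgoing edges — the total
#' gaze-transition involvement of an OOI. On an undirected network each
#' incident edge counts once.
#'
#' @param net An `attention_network`.
#' @param node Node name.
#' @return Non-negative number; 0 for an isolated node.
#' @export
strength <- function(net, node) {
  stopifnot(inherits(net, "attention_network"))
  if (!node %in% net$nodes) stop("unknown node: ", node, call. = FALSE)
  e <- net$edges
  sum(e$weight[e$source == node]) + sum(e$weight[e$target == node])
}

#' Summed strength of a group of OOIs
#'
#' Sums [strength()] over a node group. By default edges internal to the
#' group contribute at both endpoints and are therefore counted twice —
#' the literal "sum of per-node degree centralities". With
#' `exclude_internal = TRUE` only edges crossing the group boundary count
#' (each once).
#'
#' @param net An `attention_network`.
#' @param group Non-empty character vector of node names.
#' @param exclude_internal If `TRUE`, drop within-group edges.
#' @return Non-negative number.
#' @export
group_strength <- function(net, group, exclude_internal = FALSE) {
  stopifnot(inherits(net, "attention_network"))
  if (length(group) == 0) stop("group must be non-empty", call. = FALSE)
  unknown <- setdiff(group, net$nodes)
  if (length(unknown)) stop("unknown nodes: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  if (!exclude_internal) {
    return(sum(vapply(unique(group), function(n) strength(net, n), numeric(1))))
  }
  e <- net$edges
  crossing <- xor(e$source %in% group, e$target %in% group)
  sum(e$weight[crossing])
}

#' Candeloro weighted degree centrality (WDC)
#'
#' A uniformity index of a node's outgoing edge weights, following
#' Candeloro et al.'s Lorenz-curve construction. With the DC outgoing
#' weights sorted ascending, let `Fc(i)` be the cumulative weight share of
#' the i smallest edges; then
#'
#'   `WDC = 1 + 2 * sum_{i=1}^{DC-1} Fc(i)`.
#'
#' WDC ranges from 1 (all weight on one edge, maximally skewed) to DC
#' (perfectly uniform weights), and is invariant to rescaling all weights.
#' Sorting ascending is essential for comparability across participants
#' whose largest edge is not in the same position.
#'
#' @param weights Positive numeric vector of a node's outgoing edge
#'   weights, in any order (sorted internally). May also be an
#'   `attention_network` together with `node`.
#' @param node When `weights` is a network: the node whose outgoing profile
#'   to use.
#' @return WDC in `[1, DC]` where `DC = length(weights)`.
#' @examples
#' weighted_degree_centrality(c(1, 1, 1, 1))  # 4: uniform over 4 edges
#' weighted_degree_centrality(c(1, 1, 2))     # 2.5
#' @export
weighted_degree_centrality <- function(weights, node = NULL) {
  if (inherits(weights, "attention_network")) {
    net <- weights
    if (is.null(node)) stop("supply the node whose outgoing edges to use", call. = FALSE)
    if (!node %in% net$nodes) stop("unknown node: ", node, call. = FALSE)
    weights <- if (net$directed) {
      net$edges$weight[net$edges$source == node]
    } else {
      net$edges$weight[net$edges$source == node | net$edges$target == node]
    }
  }
  if (length(weights) == 0) {
    stop("node has no outgoing edges; WDC needs DC >= 1", call. = FALSE)
  }
  if (any(!is.finite(weights) | weights <= 0)) {
    stop("edge weights must be positive and finite", call. = FALSE)
  }
  w <- sort(weights)                       # ascending
  dc <- length(w)
  if (dc == 1L) return(1)
  fc <- cumsum(w) / sum(w)
  1 + 2 * sum(fc[seq_len(dc - 1L)])
}

#' Gaze uniformity index
#'
#' The negated chi-square goodness-of-fit statistic of all directed edge
#' weights against a uniform expectation (the mean weight):
#'
#'   `U = -sum_e (w_e - mean(w))^2 / mean(w)`.
#'
#' U is 0 when every edge carries the same number of transitions and grows
#' more negative the more gaze concentrates on a subset of OOI pairs. Only
#' edges present in the network enter; absent pairs are not treated as
#' zero-count categories.
#'
#' @param net An `attention_network` with at least one edge, or a positive
#'   numeric vector of edge weights.
#' @return Number `<= 0`.
#' @examples
#' uniformity(c(2, 2, 2))  # 0
#' uniformity(c(1, 3))     # -1
#' @export
uniformity <- function(net) {
  w <- if (inherits(net, "attention_network")) net$edges$weight else net
  if (length(w) == 0) stop("uniformity needs at least one edge", call. = FALSE)
  if (any(!is.finite(w) | w <= 0)) {
    stop("edge weights must be positive and finite", call. = FALSE)
  }
  m <- mean(w)
  0 - sum((w - m)^2 / m)   # 0 - x keeps the uniform case at +0
}

check_partition <- function(net, set_s, set_t) {
  if (length(set_s) == 0 || length(set_t) == 0) {
    stop("both partition sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(set_s, set_t))) {
    stop("partition sets must be disjoint", call. = FALSE)
  }
  unknown <- setdiff(c(set_s, set_t), net$nodes)
  if (length(unknown)) {
    stop("partition refers to unknown nodes: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
}

#' Cut size between two node groups
#'
#' Sum of the weights of all edges with one endpoint in `set_s` and the
#' other in `set_t` — how often the gaze crossed between the two groups.
#' On a directed network both directions are counted. The normalized
#' variant divides by the total edge weight of the network (not by group
#' volumes, as some network libraries do), answering "what share of all
#' transitions crossed between the groups?".
#'
#' @param net An `attention_network`.
#' @param set_s,set_t Disjoint, non-empty node-name vectors.
#' @return `cut_size()`: non-negative number. `normalized_cut_size()`:
#'   number in `[0, 1]`.
#' @export
cut_size <- function(net, set_s, set_t) {
  stopifnot(inherits(net, "attention_network"))
  check_partition(net, set_s, set_t)
  e <- net$edges
  crossing <- (e$source %in% set_s & e$target %in% set_t) |
              (e$source %in% set_t & e$target %in% set_s)
  sum(e$weight[crossing])
}

#' @rdname cut_size
#' @export
normalized_cut_size <- function(net, set_s, set_t) {
  tot <- total_weight(net)
  if (tot == 0) stop("normalized cut size is undefined on an edgeless network",
                     call. = FALSE)
  cut_size(net, set_s, set_t) / tot
}

#' Maximal cliques of an undirected attention network
#'
#' A clique is a set of OOIs pairwise connected by positive-weight edges —
#' at least one gaze transition exists between every pair; a maximal clique
#' cannot be extended by any further node. Isolated nodes are maximal
#' cliques of size one by definition. Directed networks must be collapsed
#' with [to_undirected()] first, since cliques ignore edge direction.
#'
#' @param unet An undirected `attention_network`.
#' @return List of character vectors (each sorted), ordered by size then
#'   lexicographically, for deterministic output.
#' @export
maximal_cliques <- function(unet) {
  stopifnot(inherits(unet, "attention_network"))
  if (unet$directed) {
    stop("cliques are defined on undirected networks; call to_undirected() first",
         call. = FALSE)
  }
  cl <- igraph::max_cliques(as_igraph(unet))
  cl <- lapply(cl, function(v) sort(names(v)))
  keys <- vapply(cl, paste, character(1), collapse = "\r")
  cl[order(lengths(cl), keys)]
}

#' Clique summary statistics
#'
#' Counts and mean sizes of the maximal cliques, reported both over all
#' maximal cliques (singletons included, per the mathematical definition)
#' and restricted to cliques of size two or more, making the treatment of
#' isolated nodes explicit.
#'
#' @param unet An undirected `attention_network` (or a clique list from
#'   [maximal_cliques()]).
#' @return List with `count`, `mean_size`, `count_size2`, `mean_size2`,
#'   `cliques`.
#' @export
clique_stats <- function(unet) {
  cl <- if (is.list(unet) && !inherits(unet, "attention_network")) unet
        else maximal_cliques(unet)
  sizes <- lengths(cl)
  big <- sizes >= 2
  list(count = length(cl),
       mean_size = if (length(cl)) mean(sizes) else NA_real_,
       count_size2 = sum(big),
       mean_size2 = if (any(big)) mean(sizes[big]) else NA_real_,
       cliques = cl)
}

#' Compute a full metrics report for one network
#'
#' Bundles the structural variables of one participant's attention network
#' into a single report: per-node strength, optional group strengths,
#' per-node WDC (for nodes with outgoing edges), uniformity, requested cut
#' sizes, and clique summaries of the undirected collapse. The report
#' records all parameters used so results are comparable across
#' participants.
#'
#' @param net A directed `attention_network`.
#' @param groups Optional named list of node-name vectors for group
#'   strengths.
#' @param partitions Optional named list of `list(s = ..., t = ...)` node
#'   partitions for cut sizes.
#' @return Object of class `metrics_report` (a nested list).
#' @export
metrics_report <- function(net, groups = NULL, partitions = NULL) {
  stopifnot(inherits(net, "attention_network"))
  node_strength <- vapply(net$nodes, function(n) strength(net, n), numeric(1))
  wdc <- lapply(net$nodes, function(n) {
    w <- net$edges$weight[net$edges$source == n]
    if (length(w)) weighted_degree_centrality(w) else NULL
  })
  names(wdc) <- net$nodes
  wdc <- Filter(Negate(is.null), wdc)

  grp <- lapply(groups, function(g) {
    list(strength = group_strength(net, g),
         strength_boundary = group_strength(net, g, exclude_internal = TRUE))
  })
  cuts <- lapply(partitions, function(p) {
    list(cut_size = cut_size(net, p$s, p$t),
         normalized_cut_size = normalized_cut_size(net, p$s, p$t))
  })
  u <- if (nrow(net$edges) > 0) uniformity(net) else NA_real_
  cs <- clique_stats(to_undirected(net))

  structure(list(
    participant_id = net$participant_id,
    parameters = list(nodes = net$nodes,
                      groups = groups,
                      partitions = partitions,
                      max_duration_ms = net$meta$max_duration_ms),
    strength = as.list(node_strength),
    group_strength = grp,
    wdc = wdc,
    uniformity = u,
    cuts = cuts,
    cliques = cs[c("count", "mean_size", "count_size2", "mean_size2")],
    clique_list = cs$cliques
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> participant %s\n", x$participant_id))
  cat("  strength:", paste(sprintf("%s=%g", names(x$strength), unlist(x$strength)),
                           collapse = " "), "\n")
  if (length(x$wdc)) {
    cat("  WDC:", paste(sprintf("%s=%.3f", names(x$wdc), unlist(x$wdc)),
                        collapse = " "), "\n")
  }
  cat(sprintf("  uniformity U = %.3f\n", x$uniformity))
  cat(sprintf("  cliques: %d (mean size %.2f); size>=2: %d (mean %.2f)\n",
              x$cliques$count, x$cliques$mean_size,
              x$cliques$count_size2, x$cliques$mean_size2))
  for (nm in names(x$cuts)) {
    cat(sprintf("  cut '%s': %g (normalized %.4f)\n", nm,
                x$cuts[[nm]]$cut_size, x$cuts[[nm]]$normalized_cut_size))
  }
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report`.
#' @param path Output JSON path.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
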