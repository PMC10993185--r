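# Independent oracles used to cross-check the implementation. These are
# deliberately written with different formulations than the package code:
# sphere hits via polyroot on the expanded quadratic, box hits via explicit
# face-plane tests, cliques via exhaustive subset enumeration.

# smallest t in [0, k] where the ray origin + t*dir meets the sphere, or Inf
oracle_sphere_dist <- function(origin, dir, center, radius, k) {
  oc <- origin - center
  roots <- polyroot(c(sum(oc^2) - radius^2, 2 * sum(dir * oc), sum(dir^2)))
  ts <- Re(roots)[abs(Im(roots)) < 1e-8]
  if (sum(oc^2) < radius^2) return(0)        # origin inside
  ts <- ts[ts >= 0 & ts <= k]
  if (length(ts) == 0) Inf else min(ts)
}

# smallest t in [0, k] where the ray meets the axis-aligned box, or Inf
oracle_box_dist <- function(origin, dir, bmin, bmax, k) {
  inside <- all(origin >= bmin & origin <= bmax)
  if (inside) return(0)
  cand <- Inf
  eps <- 1e-9
  for (ax in 1:3) {
    for (plane in c(bmin[ax], bmax[ax])) {
      if (abs(dir[ax]) < 1e-300) next
      t <- (plane - origin[ax]) / dir[ax]
      if (t < 0 || t > k) next
      p <- origin + t * dir
      others <- setdiff(1:3, ax)
      if (all(p[others] >= bmin[others] - eps & p[others] <= bmax[others] + eps)) {
        cand <- min(cand, t)
      }
    }
  }
  cand
}

# brute-force first hit: intersect with every collidable OOI, keep the
# minimum distance, break exact ties by declaration order
oracle_first_hit <- function(ray, sc) {
  best_t <- Inf; best <- NA_character_
  for (o in sc$oois) {
    if (!o$collidable) next
    t <- if (o$shape == "sphere") {
      oracle_sphere_dist(ray$origin, ray$direction, o$center, o$radius, ray$length_k)
    } else {
      oracle_box_dist(ray$origin, ray$direction, o$min, o$max, ray$length_k)
    }
    if (t < best_t) { best_t <- t; best <- o$name }
  }
  list(hit = is.finite(best_t), target_name = best, distance = best_t)
}

# all maximal cliques by exhaustive subset search (n <= 8 nodes);
# returns a canonically sorted list of sorted character vectors
oracle_maximal_cliques <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      adj[edges$source[i], edges$target[i]] <- TRUE
      adj[edges$target[i], edges$source[i]] <- TRUE
    }
  }
  is_clique <- function(idx) {
    if (length(idx) <= 1) return(TRUE)
    all(adj[idx, idx][upper.tri(diag(length(idx)))])
  }
  subsets <- lapply(seq_len(2^n - 1), function(m) which(bitwAnd(m, 2^(0:(n - 1))) > 0))
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(idx) {
    !any(vapply(setdiff(seq_len(n), idx),
                function(v) is_clique(c(idx, v)), logical(1)))
  }, cliques)
  out <- lapply(maximal, function(idx) sort(nodes[idx]))
  keys <- vapply(out, paste, character(1), collapse = "\r")
  out[order(lengths(out), keys)]
}

ooi_center_of <- function(o) if (o$shape == "sphere") o$center else (o$min + o$max) / 2

# random scene of <= max_obj spheres/boxes in front of the origin
random_scene <- function(max_obj = 10) {
  n <- sample.int(max_obj, 1)
  oois <- lapply(seq_len(n), function(i) {
    if (runif(1) < 0.5) {
      ooi(sprintf("s%d", i), "sphere",
          center = runif(3, -50, 50) + c(60, 0, 0),
          radius = runif(1, 1, 15),
          collidable = runif(1) > 0.1)
    } else {
      lo <- runif(3, -50, 50) + c(60, 0, 0)
      ooi(sprintf("b%d", i), "box", min = lo, max = lo + runif(3, 1, 25),
          collidable = runif(1) > 0.1)
    }
  })
  scene(oois)
}

# random directed attention network over n nodes
random_network <- function(n_nodes = 6, p_edge = 0.4, max_w = 9) {
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pick <- runif(nrow(pairs)) < p_edge
  e <- pairs[pick, , drop = FALSE]
  tab <- if (nrow(e) > 0) {
    e$n <- sample.int(max_w, nrow(e), replace = TRUE)
    data.frame(participant = "rnd",
               source = rep(e$source, e$n),
               target = rep(e$target, e$n),
               stringsAsFactors = FALSE)
  } else {
    data.frame(participant = character(0), source = character(0),
               target = character(0), stringsAsFactors = FALSE)
  }
  build_network(tab, nodes = nodes)
}

# fixed local->world frame conversion used by the round-trip checks
convert_local_to_world <- function(g) c(g[3], -g[1], g[2])

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    if (sqrt(sum(v^2)) > 1e-3) return(v / sqrt(sum(v^2)))
  }
}
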