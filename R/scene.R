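#' Define an object of interest (OOI)
#'
#' An OOI is a named gaze target in the virtual scene. Two shapes are
#' supported, sufficient to stand in for classroom objects: spheres
#' (center + radius) and axis-aligned boxes (componentwise min < max).
#' Non-collidable OOIs are invisible to the ray caster — the analogue of
#' disabling an object's collider so it cannot occlude tracked objects.
#'
#' @param name Unique, non-empty name.
#' @param shape `"sphere"` or `"box"`.
#' @param center,radius Sphere parameters (uu).
#' @param min,max Box corner parameters (uu).
#' @param collidable Logical; non-collidable objects are skipped by the ray
#'   caster.
#' @return Object of class `ooi`.
#' @examples
#' ooi("board", "box", min = c(500, -150, 100), max = c(510, 150, 250))
#' ooi("teacher", "sphere", center = c(450, 80, 160), radius = 30)
#' @export
ooi <- function(name, shape = c("sphere", "box"), center = NULL, radius = NULL,
                min = NULL, max = NULL, collidable = TRUE) {
  shape <- match.arg(shape)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("OOI name must be a non-empty string", call. = FALSE)
  }
  obj <- list(name = name, shape = shape, collidable = isTRUE(collidable))
  if (shape == "sphere") {
    check_vec3(center, sprintf("center of OOI '%s'", name))
    if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) || radius <= 0) {
      stop(sprintf("radius of OOI '%s' must be a positive number", name), call. = FALSE)
    }
    obj$center <- as.numeric(center); obj$radius <- as.numeric(radius)
  } else {
    check_vec3(min, sprintf("min corner of OOI '%s'", name))
    check_vec3(max, sprintf("max corner of OOI '%s'", name))
    if (!all(min < max)) {
      stop(sprintf("box OOI '%s' needs min < max componentwise", name), call. = FALSE)
    }
    obj$min <- as.numeric(min); obj$max <- as.numeric(max)
  }
  class(obj) <- "ooi"
  obj
}

ooi_center <- function(o) if (o$shape == "sphere") o$center else (o$min + o$max) / 2

#' Assemble a scene of OOIs
#'
#' A scene is the ordered list of trackable objects plus an optional subset
#' of "analysis OOIs" — the objects whose transitions enter the attention
#' network (other objects are merely trackable scenery). Declaration order
#' matters: it breaks ties when a ray hits two objects at the same distance.
#'
#' @param ... `ooi()` objects (or a single list of them).
#' @param analysis_oois Optional character vector of OOI names marking the
#'   analysis subset; defaults to all OOIs.
#' @return Object of class `gaze_scene`.
#' @export
scene <- function(..., analysis_oois = NULL) {
  oois <- list(...)
  if (length(oois) == 1L && !inherits(oois[[1L]], "ooi")) oois <- oois[[1L]]
  if (!all(vapply(oois, inherits, logical(1), "ooi"))) {
    stop("scene() expects ooi() objects", call. = FALSE)
  }
  nms <- vapply(oois, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("OOI names must be unique within a scene: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(analysis_oois)) analysis_oois <- nms
  unknown <- setdiff(analysis_oois, nms)
  if (length(unknown)) {
    stop("analysis_oois not present in scene: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(oois = oois, analysis_oois = analysis_oois), class = "gaze_scene")
}

#' @export
print.gaze_scene <- function(x, ...) {
  cat(sprintf("<gaze_scene> %d OOIs (%d in analysis set)\n",
              length(x$oois), length(x$analysis_oois)))
  for (o in x$oois) {
    geom <- if (o$shape == "sphere") {
      sprintf("center (%s) r=%g", paste(o$center, collapse = ", "), o$radius)
    } else {
      sprintf("(%s)-(%s)", paste(o$min, collapse = ", "), paste(o$max, collapse = ", "))
    }
    cat(sprintf("  %s [%s]%s %s\n", o$name, o$shape,
                if (o$collidable) "" else " (non-collidable)", geom))
  }
  invisible(x)
}

#' Read / write a scene description
#'
#' Scenes are stored as YAML with an `oois` list (`name`, `shape`, shape
#' parameters, `collidable`) and an optional `analysis_oois` name list. All
#' coordinates are in uu.
#'
#' @param path File path.
#' @return `read_scene()` returns a `gaze_scene`; `write_scene()` returns
#'   `path` invisibly.
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) stop("scene file does not exist: ", path, call. = FALSE)
  spec <- yaml::read_yaml(path)
  if (is.null(spec$oois)) stop("scene file has no 'oois' entry: ", path, call. = FALSE)
  oois <- lapply(spec$oois, function(s) {
    ooi(name = s$name, shape = s$shape,
        center = unlist(s$center), radius = s$radius,
        min = unlist(s$min), max = unlist(s$max),
        collidable = if (is.null(s$collidable)) TRUE else s$collidable)
  })
  scene(oois, analysis_oois = unlist(spec$analysis_oois))
}

#' @rdname read_scene
#' @param x A `gaze_scene`.
#' @export
write_scene <- function(x, path) {
  stopifnot(inherits(x, "gaze_scene"))
  spec <- list(
    oois = lapply(x$oois, function(o) {
      s <- list(name = o$name, shape = o$shape, collidable = o$collidable)
      if (o$shape == "sphere") {
        s$center <- as.list(o$center); s$radius <- o$radius
      } else {
        s$min <- as.list(o$min); s$max <- as.list(o$max)
      }
      s
    }),
    analysis_oois = as.list(x$analysis_oois)
  )
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' A default virtual-classroom scene
#'
#' A seated-lecture layout used as the package's reference study condition:
#' a board (box) on the front wall, a teacher (sphere) in front of it, and
#' four virtual peer learners (spheres) seated around the student. The
#' student's head sits at the origin at eye height 150 uu, facing the board
#' along +x. All six objects form the analysis set.
#'
#' @param peer_count Number of peer learners (1-4 supported positions).
#' @return A `gaze_scene`.
#' @export
classroom_scene <- function(peer_count = 4) {
  stopifnot(peer_count >= 1, peer_count <= 4)
  peers_xy <- list(c(200, -150), c(200, 150), c(50, -200), c(50, 200))
  peers <- lapply(seq_len(peer_count), function(i) {
    ooi(sprintf("peer%d", i), "sphere",
        center = c(peers_xy[[i]], 140), radius = 35)
  })
  all <- c(list(
    ooi("board", "box", min = c(590, -200, 100), max = c(610, 200, 280)),
    ooi("teacher", "sphere", center = c(500, 120, 150), radius = 40)
  ), peers)
  scene(all)
}
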