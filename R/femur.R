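# Femur data model: endosteal surface mesh + landmarks + the canonical
# anatomical frame in which the placement rules ("AP view", "lateral
# view") are stated. Frame convention: origin at the greater-trochanter
# apex, +z distal along the shaft axis, +y anterior, +x lateral
# (right-handed for a right femur; the landmark `side` flag flips +x for
# a left femur).

#' Femoral landmarks
#'
#' @param gt_apex greater-trochanter apex, length-3 mm.
#' @param head_center femoral head centre, length-3 mm.
#' @param shaft_axis_points matrix (>= 2 x 3) of points on the diaphyseal
#'   canal axis spanning at least 50 mm.
#' @param anterior_dir anterior direction (normalized on construction).
#' @param side `"R"` or `"L"`.
#' @return an object of class `fem_landmarks`.
#' @export
landmarks <- function(gt_apex, head_center, shaft_axis_points,
                      anterior_dir, side = "R") {
  gt_apex <- as.numeric(gt_apex)
  head_center <- as.numeric(head_center)
  shaft_axis_points <- as.matrix(shaft_axis_points)
  anterior_dir <- as.numeric(anterior_dir)
  if (length(gt_apex) != 3 || length(head_center) != 3 ||
      ncol(shaft_axis_points) != 3 || length(anterior_dir) != 3)
    stop_femfit("schema", "landmark fields must be 3D points (mm)")
  if (!side %in% c("R", "L"))
    stop_femfit("schema", "side must be 'R' or 'L'")
  if (vnorm(anterior_dir) < 1e-9)
    stop_femfit("schema", "anterior_dir must be non-zero")
  anterior_dir <- unitize(anterior_dir)
  if (nrow(shaft_axis_points) < 2)
    stop_femfit("schema", "need at least 2 shaft axis points")
  dir <- shaft_axis_dir(shaft_axis_points)
  span <- diff(range(shaft_axis_points %*% dir))
  if (span < 50)
    stop_femfit("schema",
                "shaft_axis_points span %.1f mm; need >= 50 mm", span)
  if (vnorm(head_center - gt_apex) < 1e-6)
    stop_femfit("schema", "head_center must differ from gt_apex")
  structure(list(gt_apex = gt_apex, head_center = head_center,
                 shaft_axis_points = shaft_axis_points,
                 anterior_dir = anterior_dir, side = side),
            class = "fem_landmarks")
}

# total-least-squares direction of the shaft axis point cloud
shaft_axis_dir <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  sv <- svd(x, nu = 0, nv = 1)
  as.numeric(sv$v[, 1])
}

#' Canonical anatomical frame from landmarks
#'
#' `z` is the total-least-squares shaft-axis direction pointing distally
#' (away from the trochanter), `y` the anterior direction orthogonalized
#' against `z`, and `x` the lateral completion (`y` cross `z`, negated
#' for a left femur).
#'
#' @param lm a [landmarks()] object.
#' @return an object of class `fem_frame` with `origin` (the GT apex) and
#'   `axes` (3x3 matrix whose columns are x, y, z).
#' @export
canonical_frame <- function(lm) {
  stopifnot(inherits(lm, "fem_landmarks"))
  z <- shaft_axis_dir(lm$shaft_axis_points)
  # orient distal: the shaft points lie distal of the trochanter
  if (sum(z * (colMeans(lm$shaft_axis_points) - lm$gt_apex)) < 0) z <- -z
  y <- lm$anterior_dir - sum(lm$anterior_dir * z) * z
  if (vnorm(y) < 1e-6)
    stop_femfit("geometry",
                "anterior_dir is parallel to the shaft axis; frame degenerate")
  y <- unitize(y)
  x <- cross3(y, z)
  if (lm$side == "L") x <- -x
  structure(list(origin = lm$gt_apex, axes = cbind(x, y, z),
                 side = lm$side),
            class = "fem_frame")
}

#' @export
print.fem_frame <- function(x, ...) {
  cat(sprintf("<fem_frame %s> origin (%.1f, %.1f, %.1f) mm\n", x$side,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Convert world points to frame coordinates (and back)
#' @param frame a `fem_frame`.
#' @param pts n x 3 matrix or length-3 vector, world mm.
#' @return coordinates in the femur frame (x lateral, y anterior,
#'   z distal), same shape as the input.
#' @export
to_frame <- function(frame, pts) {
  if (is.null(dim(pts)))
    return(as.numeric(t(frame$axes) %*% (pts - frame$origin)))
  sweep(pts, 2, frame$origin) %*% frame$axes
}

#' @rdname to_frame
#' @export
from_frame <- function(frame, pts) {
  if (is.null(dim(pts)))
    return(as.numeric(frame$axes %*% pts + frame$origin))
  sweep(pts %*% t(frame$axes), 2, frame$origin, "+")
}

frame_as_rigid <- function(frame) {
  # frame-local -> world
  rigid_transform(frame$axes, frame$origin)
}

#' Project a point into the AP or lateral view
#'
#' The AP (frontal) view drops the anteroposterior coordinate and
#' reports `(x, z)`; the lateral (sagittal) view drops the mediolateral
#' coordinate and reports `(y, z)`. Both are stated in the femur frame,
#' so the GT apex projects to the view origin.
#'
#' @param point length-3 world point, mm.
#' @param view `"AP"` or `"LATERAL"`.
#' @param frame a `fem_frame`.
#' @return length-2 view coordinates, mm.
#' @export
project <- function(point, view = c("AP", "LATERAL"), frame) {
  view <- match.arg(view)
  p <- to_frame(frame, point)
  if (view == "AP") c(x = p[1], z = p[3]) else c(y = p[2], z = p[3])
}

#' Assemble a femur model
#'
#' @param mesh watertight endosteal `fem_mesh` (world mm).
#' @param lm a [landmarks()] object.
#' @param id specimen identifier.
#' @param validate verify mesh integrity and landmark consistency.
#' @return an object of class `femur_model` with fields `mesh`,
#'   `landmarks`, `frame`, `id`.
#' @export
femur_model <- function(mesh, lm, id = "femur", validate = TRUE) {
  stopifnot(inherits(mesh, "fem_mesh"), inherits(lm, "fem_landmarks"))
  frame <- canonical_frame(lm)
  if (validate) {
    wt <- check_watertight(mesh)
    if (!wt$watertight)
      stop_femfit("integrity",
                  "endosteal mesh is not watertight: %d open edge(s), %d non-manifold",
                  wt$open_edges, wt$nonmanifold_edges)
    # landmark consistency: the GT apex must sit at (within 5 mm of) the
    # proximal extremity of the trochanteric surface. The check is scoped
    # to the mesh component nearest the apex so that a femoral head
    # component, which can legitimately rise above the GT-apex plane, does
    # not shadow it.
    V <- to_frame(frame, mesh$vertices)
    d_apex <- sqrt(V[, 1]^2 + V[, 2]^2 + V[, 3]^2)
    comp <- mesh_vertex_components(mesh)
    troch <- comp[which.min(d_apex)]
    zmin <- min(V[comp == troch, 3])
    if (zmin < -5)
      stop_femfit("integrity",
                  "gt_apex lies %.1f mm distal of the trochanteric surface's proximal extremity (limit 5 mm)",
                  -zmin)
  }
  structure(list(mesh = mesh, landmarks = lm, frame = frame, id = id),
            class = "femur_model")
}

#' @export
print.femur_model <- function(x, ...) {
  cat(sprintf("<femur_model '%s'> %d vertices, side %s\n", x$id,
              nrow(x$mesh$vertices), x$frame$side))
  invisible(x)
}

#' Read/write the landmark file
#'
#' Landmark schema (JSON or YAML by extension):
#' `{gt_apex: [x,y,z], head_center: [x,y,z], shaft_axis_points: [[...],
#' ...], anterior_dir: [x,y,z], side: "R"|"L"}`, all coordinates mm.
#'
#' @param path landmark file path.
#' @return `read_landmarks()` returns a [landmarks()] object.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop_femfit("io", "landmark file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop_femfit("schema", "landmark file must be JSON or YAML: %s", path))
  need <- c("gt_apex", "head_center", "shaft_axis_points", "anterior_dir")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    stop_femfit("schema", "landmark file missing field(s): %s",
                paste(missing, collapse = ", "))
  sap <- raw$shaft_axis_points
  if (is.list(sap)) sap <- do.call(rbind, lapply(sap, as.numeric))
  landmarks(raw$gt_apex, raw$head_center, sap, raw$anterior_dir,
            raw$side %||% "R")
}

#' @rdname read_landmarks
#' @param lm a [landmarks()] object.
#' @export
write_landmarks <- function(lm, path) {
  obj <- list(gt_apex = lm$gt_apex, head_center = lm$head_center,
              shaft_axis_points = lm$shaft_axis_points,
              anterior_dir = lm$anterior_dir, side = lm$side)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  } else {
    yaml::write_yaml(lapply(obj, function(x)
      if (is.matrix(x)) apply(x, 1, as.numeric, simplify = FALSE) else x),
      path)
  }
  invisible(path)
}

#' Load a femur model from mesh + landmark files
#'
#' @param mesh_path STL or PLY endosteal surface, mm.
#' @param landmarks_path landmark file (see [read_landmarks()]).
#' @param id specimen id (defaults to the mesh file stem).
#' @return a [femur_model()].
#' @export
load_femur <- function(mesh_path, landmarks_path, id = NULL) {
  mesh <- read_mesh(mesh_path)
  lm <- read_landmarks(landmarks_path)
  femur_model(mesh, lm,
              id = id %||% tools::file_path_sans_ext(basename(mesh_path)))
}
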