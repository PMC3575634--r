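#' Triangulated surface meshes
#'
#' Meshes are stored index-based: `vertices` is an n x 3 numeric matrix in
#' millimetres and `faces` an m x 3 integer matrix of 1-based vertex
#' indices with outward-facing counter-clockwise winding. All femur and
#' nail surfaces in the package are watertight (every edge shared by
#' exactly two faces with opposite orientation), which is what gives the
#' signed penetration depth a well-defined sign.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return an object of class `fem_mesh`.
#' @export
new_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3)
    stop_femfit("geometry", "mesh needs n x 3 vertices and m x 3 faces")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop_femfit("geometry", "face index out of range")
  structure(list(vertices = vertices, faces = faces), class = "fem_mesh")
}

#' @export
print.fem_mesh <- function(x, ...) {
  wt <- check_watertight(x)
  cat(sprintf("<fem_mesh> %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (wt$watertight) "watertight" else
                sprintf("%d open edge(s)", wt$open_edges)))
  invisible(x)
}

#' Watertightness check
#'
#' A mesh is watertight when every undirected edge is used by exactly two
#' faces and the two uses run in opposite directions (consistent outward
#' orientation). Returns the open (boundary) edge count so integrity
#' errors can name the defect.
#'
#' @param mesh a `fem_mesh`.
#' @return list with `watertight`, `open_edges`, `nonmanifold_edges`,
#'   `misoriented_edges`.
#' @export
check_watertight <- function(mesh) {
  f <- mesh$faces
  he_from <- c(f[, 1], f[, 2], f[, 3])
  he_to <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(he_from, he_to)
  hi <- pmax(he_from, he_to)
  key <- paste(lo, hi)
  cnt <- table(key)
  open_edges <- sum(cnt == 1)
  nonmanifold <- sum(cnt > 2)
  # orientation: each directed half-edge must appear exactly once
  dkey <- paste(he_from, he_to)
  mis <- sum(table(dkey) > 1)
  list(watertight = open_edges == 0 && nonmanifold == 0 && mis == 0,
       open_edges = open_edges, nonmanifold_edges = nonmanifold,
       misoriented_edges = mis)
}

#' Enclosed mesh volume
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra
#' against the origin); positive for outward-oriented watertight meshes.
#'
#' @param mesh a `fem_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  dets <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(dets) / 6
}

#' Apply a rigid transform to a mesh
#' @param mesh a `fem_mesh`.
#' @param tr a [rigid_transform()].
#' @return transformed `fem_mesh`.
#' @export
transform_mesh <- function(mesh, tr) {
  new_mesh(rigid_apply(tr, mesh$vertices), mesh$faces)
}

#' Merge two meshes into one (disjoint components)
#' @param a,b `fem_mesh` objects.
#' @return combined `fem_mesh`.
#' @export
merge_meshes <- function(a, b) {
  new_mesh(rbind(a$vertices, b$vertices),
           rbind(a$faces, b$faces + nrow(a$vertices)))
}

# Connected components over shared vertices; returns per-vertex labels
# (1-based, relabelled consecutively). Reuses the spatial linker with a
# tiny radius by feeding face-edge midpoints is overkill; a plain
# union-find over face edges is clear and fast enough.
mesh_vertex_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(x) {
    r <- x
    while (parent[r] != r) r <- parent[r]
    while (parent[x] != r) {
      nx <- parent[x]
      parent[x] <<- r
      x <- nx
    }
    r
  }
  f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    a <- find(f[i, 1])
    b <- find(f[i, 2])
    if (a != b) parent[b] <- a
    a <- find(f[i, 1])
    b <- find(f[i, 3])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Signed distance from points to a watertight mesh
#'
#' Unsigned closest distance with the sign taken from ray-crossing parity
#' containment: points inside the enclosed volume get negative values.
#'
#' @param mesh a watertight `fem_mesh`.
#' @param points n x 3 matrix of query points.
#' @return numeric vector of signed distances, mm (negative inside).
#' @export
mesh_signed_distance <- function(mesh, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  mesh_signed_distance_cpp(mesh$vertices, mesh$faces, as.matrix(points))
}

#' First-hit ray casting
#'
#' @param mesh a `fem_mesh`.
#' @param origins n x 3 matrix of ray origins.
#' @param dirs n x 3 matrix of ray directions (need not be unit; distances
#'   are reported in units of the direction norm, so pass unit vectors for
#'   millimetre distances).
#' @return vector of first-hit distances, `Inf` where a ray misses.
#' @export
mesh_ray_hits <- function(mesh, origins, dirs) {
  if (is.null(dim(origins))) origins <- matrix(origins, ncol = 3)
  if (is.null(dim(dirs))) dirs <- matrix(dirs, ncol = 3)
  if (nrow(dirs) == 1 && nrow(origins) > 1)
    dirs <- dirs[rep(1, nrow(origins)), , drop = FALSE]
  mesh_ray_hits_cpp(mesh$vertices, mesh$faces, as.matrix(origins),
                    as.matrix(dirs))
}

# Swept-tube surface builder ----------------------------------------------
#
# centers:  n x 3 station centres along the sweep axis
# xd, yd:   n x 3 local in-plane frame vectors per station
# off_x/y:  n x k local 2D cross-section offsets (mm)
# caps:     apex points (length-3) closing the start/end; NULL = open
sweep_tube <- function(centers, xd, yd, off_x, off_y,
                       apex_start = NULL, apex_end = NULL) {
  n <- nrow(centers)
  k <- ncol(off_x)
  vx <- centers[, 1] + off_x * xd[, 1] + off_y * yd[, 1]
  vy <- centers[, 2] + off_x * xd[, 2] + off_y * yd[, 2]
  vz <- centers[, 3] + off_x * xd[, 3] + off_y * yd[, 3]
  verts <- cbind(as.vector(t(vx)), as.vector(t(vy)), as.vector(t(vz)))
  idx <- function(i, j) (i - 1L) * k + ((j - 1L) %% k) + 1L

  i <- rep(seq_len(n - 1L), each = k)
  j <- rep(seq_len(k), n - 1L)
  f1 <- cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j))
  f2 <- cbind(idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j))
  faces <- rbind(f1, f2)

  nv <- nrow(verts)
  if (!is.null(apex_start)) {
    verts <- rbind(verts, apex_start)
    a0 <- nv + 1L
    j <- seq_len(k)
    faces <- rbind(faces, cbind(rep(a0, k), idx(1L, j + 1L), idx(1L, j)))
    nv <- nv + 1L
  }
  if (!is.null(apex_end)) {
    verts <- rbind(verts, apex_end)
    a1 <- nv + 1L
    j <- seq_len(k)
    faces <- rbind(faces, cbind(rep(a1, k), idx(n, j), idx(n, j + 1L)))
  }
  new_mesh(verts, faces)
}

# UV sphere, outward-oriented.
uv_sphere <- function(center, radius, n_lat = 12L, n_lon = 18L) {
  lat <- seq(0, pi, length.out = n_lat + 2L)[2:(n_lat + 1L)]
  theta <- seq(0, 2 * pi, length.out = n_lon + 1L)[seq_len(n_lon)]
  # rings from north (small polar angle) to south
  centers <- cbind(0, 0, radius * cos(lat))
  xd <- matrix(rep(c(1, 0, 0), each = length(lat)), ncol = 3)
  yd <- matrix(rep(c(0, 1, 0), each = length(lat)), ncol = 3)
  r <- radius * sin(lat)
  off_x <- outer(r, cos(theta))
  off_y <- outer(r, sin(theta))
  # sweep runs from +z pole toward -z, so z decreases: flip ring order to
  # keep the builder's outward winding convention (z increasing)
  ord <- rev(seq_along(lat))
  m <- sweep_tube(centers[ord, , drop = FALSE], xd, yd,
                  off_x[ord, , drop = FALSE], off_y[ord, , drop = FALSE],
                  apex_start = c(0, 0, -radius),
                  apex_end = c(0, 0, radius))
  new_mesh(sweep(m$vertices, 2, center, "+"), m$faces)
}
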