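# Geometric fitness metrics of a placed nail. The signed penetration
# field samples the nail shaft surface and measures the signed distance
# to the endosteal surface (negative inside the canal volume, positive
# protruding into cortex). Connected supra-threshold regions form
# impingement patches with thickness/length/location attributes, from
# which the per-specimen fitness report (parameters A-H) is assembled:
#   A  greatest impingement thickness, proximal region
#   B  average impingement patch length, proximal region
#   C  distance GT apex -> proximal patch centre
#   D  tip protrusion above the GT-apex plane
#   E  impingement thickness and length, mid-shaft
#   F  distance GT apex -> mid-shaft patch centre
#   G  maximum anterior gap between nail and inner cortex, mid-shaft
#   H  impingement patch length at the distal part of the nail

#' Signed nail-to-cortex penetration field
#'
#' @param femur a [femur_model()].
#' @param nail a [build_nail_mesh()] result.
#' @param placement a [place_nail()] result.
#' @param density nail-surface sample density, samples per mm^2.
#' @param allow_unconverged sample even when the placement did not
#'   converge.
#' @return an object of class `penetration_field`: `points` (n x 3,
#'   femur-frame mm), `depth` (signed mm, positive = into cortex),
#'   `station` (arc length along the nail axis, mm), `theta`.
#' @export
penetration_field <- function(femur, nail, placement, density = 4,
                              allow_unconverged = TRUE) {
  stopifnot(inherits(placement, "placement_result"))
  if (!placement$converged && !allow_unconverged)
    stop_femfit("geometry", "placement did not converge")
  wt <- check_watertight(femur$mesh)
  if (!wt$watertight)
    stop_femfit("integrity",
                "penetration sign undefined on a non-watertight mesh (%d open edges)",
                wt$open_edges)
  smp <- nail_surface_samples(nail$spec, density)
  pts_f <- rigid_apply(placement$transform_frame, smp$points)
  mesh_f <- transform_mesh(femur$mesh,
                           rigid_invert(frame_as_rigid(femur$frame)))
  depth <- mesh_signed_distance(mesh_f, pts_f)
  structure(list(points = pts_f, depth = depth, station = smp$station,
                 theta = smp$theta, density = density),
            class = "penetration_field")
}

#' Extract connected impingement patches
#'
#' Patches are single-linkage connected components (sample adjacency
#' within `linkage_radius`) of samples whose penetration depth exceeds
#' `threshold`.
#'
#' @param field a [penetration_field()].
#' @param threshold impingement depth threshold, mm.
#' @param linkage_radius adjacency radius for component linking, mm.
#' @return list of `impingement_patch` objects (possibly empty), ordered
#'   by centroid station; each has `points`, `depth`, `station`,
#'   `max_thickness`, `axial_length`, `centroid`, `centroid_station`,
#'   `dist_to_gt_apex`.
#' @export
extract_patches <- function(field, threshold = 0.1, linkage_radius = 2) {
  sel <- which(field$depth > threshold)
  if (length(sel) == 0) return(list())
  P <- field$points[sel, , drop = FALSE]
  lab <- link_components_cpp(P, linkage_radius)
  patches <- lapply(seq_len(max(lab)), function(l) {
    i <- which(lab == l)
    ctr <- colMeans(P[i, , drop = FALSE])
    st <- field$station[sel[i]]
    structure(list(points = P[i, , drop = FALSE],
                   depth = field$depth[sel[i]], station = st,
                   max_thickness = max(field$depth[sel[i]]),
                   axial_length = max(st) - min(st),
                   centroid = ctr, centroid_station = mean(st),
                   dist_to_gt_apex = vnorm(ctr)),
              class = "impingement_patch")
  })
  patches[order(vapply(patches, function(p) p$centroid_station, 0))]
}

#' Assign an impingement patch to a nail region
#'
#' Regions are nail-relative: proximal up to the bend station plus a
#' margin, distal the last `distal_fraction` of the inserted length,
#' middle in between. A centroid exactly on a boundary goes to the more
#' proximal region.
#'
#' @param patch an `impingement_patch`.
#' @param placement a [place_nail()] result.
#' @param spec the [nail_spec()].
#' @param boundaries list: `margin` (mm past the bend station counted as
#'   proximal) and `distal_fraction`.
#' @return `"proximal"`, `"middle"` or `"distal"`.
#' @export
classify_region <- function(patch, placement, spec,
                            boundaries = list(margin = 10,
                                              distal_fraction = 0.25)) {
  b <- modifyList(list(margin = 10, distal_fraction = 0.25), boundaries)
  s <- patch$centroid_station
  inserted <- spec$total_length - max(0, -placement$insertion_depth)
  prox_bound <- spec$bend_station + b$margin
  distal_bound <- spec$total_length - b$distal_fraction * inserted
  if (s <= prox_bound) "proximal"
  else if (s <= distal_bound) "middle"
  else "distal"
}

#' Classify the anatomical side of a patch
#'
#' The side is the 90-degree angular sector (anterior, posterior,
#' lateral, medial in the femur frame) containing the patch centroid's
#' direction from the local nail axis. A centroid exactly on a sector
#' boundary goes to the mediolateral (x) sector.
#'
#' @param patch an `impingement_patch`.
#' @param placement a [place_nail()] result.
#' @param nail the placed [build_nail_mesh()].
#' @return `"anterior"`, `"posterior"`, `"lateral"` or `"medial"`.
#' @export
classify_side <- function(patch, placement, nail) {
  axis_local <- nail_axis_eval(nail$spec, patch$centroid_station)$points[1, ]
  axis_f <- rigid_apply(placement$transform_frame, axis_local)
  v <- patch$centroid - axis_f
  if (sqrt(v[1]^2 + v[2]^2) < 1e-9)
    stop_femfit("geometry", "patch centroid lies on the nail axis")
  if (abs(v[1]) >= abs(v[2])) {
    if (v[1] > 0) "lateral" else "medial"
  } else {
    if (v[2] > 0) "anterior" else "posterior"
  }
}

#' Tip protrusion above the greater trochanter
#'
#' Length of the nail's proximal tip above the GT-apex transverse plane
#' (clamped at zero when the tip is buried).
#'
#' @param nail a [build_nail_mesh()] result.
#' @param placement a [place_nail()] result.
#' @return protrusion, mm.
#' @export
protrusion_length <- function(nail, placement) {
  tip_f <- rigid_apply(placement$transform_frame, c(0, 0, 0))
  max(0, -tip_f[3])
}

#' Maximum anterior gap in the mid-shaft region
#'
#' For stations in the middle region, the gap is the distance from the
#' nail's anterior-most surface point to the endosteal surface along the
#' anterior (+y) direction in that station's sagittal plane. Returns the
#' maximum and its station; the all-direction maximum clearance (largest
#' inside-canal sample clearance in the region) is reported alongside.
#' Stations whose ray misses the mesh are excluded with a logged note.
#'
#' @param femur a [femur_model()].
#' @param nail a [build_nail_mesh()] result.
#' @param placement a [place_nail()] result.
#' @param boundaries region boundaries as in [classify_region()].
#' @param step station spacing, mm.
#' @param field optional [penetration_field()] reused for the clearance.
#' @return list with `max_gap` (mm), `station`, `gaps` (data.frame),
#'   `max_clearance` (mm, `NA` when no field is supplied).
#' @export
max_gap_middle <- function(femur, nail, placement,
                           boundaries = list(margin = 10,
                                             distal_fraction = 0.25),
                           step = 2, field = NULL) {
  b <- modifyList(list(margin = 10, distal_fraction = 0.25), boundaries)
  spec <- nail$spec
  inserted <- spec$total_length - max(0, -placement$insertion_depth)
  s0 <- spec$bend_station + b$margin
  s1 <- spec$total_length - b$distal_fraction * inserted
  if (s1 <= s0)
    stop_femfit("geometry", "middle region is empty for this nail")
  s <- seq(s0, s1, by = step)
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  rr <- section_radius(spec, theta, s)
  ax <- nail_axis_eval(spec, s)
  # nail-local ring points; anterior-most has the largest frame y after
  # the placement spin, so transform all and take per-ring max
  k <- length(theta)
  px <- rep(ax$points[, 1], each = k) +
    as.vector(t(rr)) * cos(theta) * rep(ax$tangents[, 3], each = k)
  py <- as.vector(t(rr)) * sin(theta)
  pz <- rep(ax$points[, 3], each = k) -
    as.vector(t(rr)) * cos(theta) * rep(ax$tangents[, 1], each = k)
  pts_f <- rigid_apply(placement$transform_frame, cbind(px, py, pz))
  ring <- rep(seq_along(s), each = k)
  top_idx <- vapply(seq_along(s), function(i) {
    j <- which(ring == i)
    j[which.max(pts_f[j, 2])]
  }, 0L)
  origins <- pts_f[top_idx, , drop = FALSE]
  mesh_f <- transform_mesh(femur$mesh,
                           rigid_invert(frame_as_rigid(femur$frame)))
  gaps <- mesh_ray_hits(mesh_f, origins, c(0, 1, 0))
  miss <- !is.finite(gaps)
  if (any(miss)) {
    # a nail penetrating the anterior cortex has no anterior space at
    # that station: gap 0; rays missing from inside are excluded
    outside <- mesh_signed_distance(mesh_f,
                                    origins[miss, , drop = FALSE]) > 0
    gaps[which(miss)[outside]] <- 0
    if (any(!outside))
      femfit_log("%d mid-shaft gap ray(s) missed the mesh and were excluded",
                 sum(!outside))
  }
  ok <- is.finite(gaps)
  if (!any(ok))
    stop_femfit("geometry", "no mid-shaft gap ray hit the endosteal surface")
  imax <- which(ok)[which.max(gaps[ok])]
  clearance <- NA_real_
  if (!is.null(field)) {
    in_mid <- field$station >= s0 & field$station <= s1 & field$depth < 0
    if (any(in_mid)) clearance <- max(-field$depth[in_mid])
  }
  list(max_gap = max(gaps[ok]), station = s[imax],
       gaps = data.frame(station = s[ok], gap = gaps[ok]),
       max_clearance = clearance)
}

region_levels <- c("proximal", "middle", "distal")

#' Per-specimen geometric fitness report
#'
#' Runs the full metric chain (penetration field, patch extraction,
#' region/side classification, protrusion, anterior gap) and assembles
#' parameters A-H. Regions without any impingement patch report `NA`
#' metrics and `impinged = FALSE`. Samples within `exclude_entry_mm` of
#' the entry plane are excluded from patch extraction: crossing the
#' closed trochanteric surface at the (in reality reamed) entry portal
#' is not impingement.
#'
#' @param femur a [femur_model()].
#' @param nail a [build_nail_mesh()] result.
#' @param spec the matching [nail_spec()].
#' @param placement a [place_nail()] result.
#' @param opts list: `density` (samples/mm^2, default 4), `threshold`
#'   (mm, default 0.1), `linkage_radius` (mm, default 2),
#'   `exclude_entry_mm` (default 15), `boundaries`
#'   (see [classify_region()]), `gap_step` (mm, default 2).
#' @return an object of class `fitness_report`.
#' @export
compute_fitness <- function(femur, nail, spec, placement, opts = list()) {
  o <- modifyList(list(density = 4, threshold = 0.1, linkage_radius = 2,
                       exclude_entry_mm = 15,
                       boundaries = list(margin = 10,
                                         distal_fraction = 0.25),
                       gap_step = 2), opts)
  field <- penetration_field(femur, nail, placement, density = o$density)
  keep <- field$points[, 3] >= o$exclude_entry_mm
  field_in <- structure(list(points = field$points[keep, , drop = FALSE],
                             depth = field$depth[keep],
                             station = field$station[keep],
                             theta = field$theta[keep],
                             density = field$density),
                        class = "penetration_field")
  patches <- extract_patches(field_in, threshold = o$threshold,
                             linkage_radius = o$linkage_radius)
  regions <- vapply(patches, classify_region, "", placement = placement,
                    spec = spec, boundaries = o$boundaries)
  sides <- vapply(patches, classify_side, "", placement = placement,
                  nail = nail)

  per_region <- function(region) {
    i <- which(regions == region)
    if (length(i) == 0)
      return(list(impinged = FALSE, max_thickness = NA_real_,
                  mean_length = NA_real_, dist_to_gt = NA_real_,
                  side = NA_character_, n_patches = 0L))
    thick <- vapply(patches[i], function(p) p$max_thickness, 0)
    lens <- vapply(patches[i], function(p) p$axial_length, 0)
    main <- i[which.max(thick)]
    list(impinged = TRUE, max_thickness = max(thick),
         mean_length = mean(lens),
         dist_to_gt = patches[[main]]$dist_to_gt_apex,
         side = sides[main], n_patches = length(i))
  }
  reg <- lapply(stats::setNames(region_levels, region_levels), per_region)

  gap <- max_gap_middle(femur, nail, placement,
                        boundaries = o$boundaries, step = o$gap_step,
                        field = field_in)

  structure(list(
    femur_id = femur$id, nail_id = spec$model_id,
    A_max_thickness_proximal = reg$proximal$max_thickness,
    B_length_proximal = reg$proximal$mean_length,
    C_dist_proximal = reg$proximal$dist_to_gt,
    D_protrusion = protrusion_length(nail, placement),
    E_thickness_middle = reg$middle$max_thickness,
    E_length_middle = reg$middle$mean_length,
    F_dist_middle = reg$middle$dist_to_gt,
    G_max_gap_middle = gap$max_gap,
    G_gap_station = gap$station,
    G_max_clearance = gap$max_clearance,
    H_length_distal = reg$distal$mean_length,
    H_thickness_distal = reg$distal$max_thickness,
    impinged = vapply(reg, function(r) r$impinged, TRUE),
    side = vapply(reg, function(r) r$side, ""),
    n_patches = vapply(reg, function(r) r$n_patches, 0L),
    insertion_depth = placement$insertion_depth,
    head_center_miss = placement$head_center_miss,
    converged = placement$converged,
    opts = o[c("density", "threshold", "linkage_radius",
               "exclude_entry_mm", "gap_step")]),
    class = "fitness_report")
}

#' @export
print.fitness_report <- function(x, ...) {
  cat(sprintf("<fitness_report %s / %s>\n", x$femur_id, x$nail_id))
  cat(sprintf("  impinged: prox=%s mid=%s dist=%s; D=%.2f mm, G=%.2f mm\n",
              x$impinged[["proximal"]], x$impinged[["middle"]],
              x$impinged[["distal"]], x$D_protrusion, x$G_max_gap_middle))
  invisible(x)
}

#' Serialize / restore a fitness report
#'
#' @param report a `fitness_report`.
#' @param path JSON file path.
#' @return `read_fitness_report()` returns the restored `fitness_report`.
#' @export
write_fitness_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_fitness_report
#' @export
read_fitness_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("A_max_thickness_proximal", "B_length_proximal",
              "C_dist_proximal", "E_thickness_middle", "E_length_middle",
              "F_dist_middle", "H_length_distal", "H_thickness_distal",
              "G_max_clearance"))
    x[[f]] <- if (is.null(x[[f]])) NA_real_ else as.numeric(x[[f]])
  x$impinged <- unlist(x$impinged)
  x$side <- vapply(x$side, function(s) s %||% NA_character_, "")
  x$n_patches <- unlist(x$n_patches)
  structure(x, class = "fitness_report")
}
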