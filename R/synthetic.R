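# Seeded generator of landmarked parametric endosteal femur models.
#
# The canal is a circular-section tube swept along a sagittal-plane
# circular arc (the anterior bow), with radius tapering linearly from
# the trochanteric flare to the isthmus and constant beyond. The
# trochanteric region is closed by a flat-topped superellipse dome whose
# apex is the GT-apex landmark; the femoral head is a sphere centred at
# the point reached from the neck take-off along the neck axis. All
# landmarks are exact by construction, which is what makes downstream
# placement and metrics testable without any imaging data.

#' Parameters of one synthetic femur
#'
#' @param femur_length overall canal extent below the GT apex, mm.
#' @param isthmus_radius narrowest canal radius, mm.
#' @param isthmus_station canal-axis station of the isthmus, mm below the
#'   GT apex.
#' @param proximal_flare_radius canal radius at the trochanteric level,
#'   mm (>= isthmus radius).
#' @param anterior_bow_radius radius of the sagittal circular arc of the
#'   canal axis, mm (`Inf` = straight; finite values must exceed 200 mm).
#' @param neck_shaft_angle angle between neck axis and shaft axis,
#'   degrees (90, 160).
#' @param neck_length neck take-off to head centre, mm.
#' @param anteversion anterior tilt of the neck axis, degrees.
#' @param head_radius femoral head radius, mm.
#' @param trochanter_overhang height of the GT apex above the canal-axis
#'   origin, mm.
#' @return an object of class `femur_params`.
#' @export
femur_params <- function(femur_length = 400, isthmus_radius = 5.5,
                         isthmus_station = 200,
                         proximal_flare_radius = 14,
                         anterior_bow_radius = 900,
                         neck_shaft_angle = 129, neck_length = 50,
                         anteversion = 15, head_radius = 22,
                         trochanter_overhang = 12) {
  p <- list(femur_length = femur_length, isthmus_radius = isthmus_radius,
            isthmus_station = isthmus_station,
            proximal_flare_radius = proximal_flare_radius,
            anterior_bow_radius = anterior_bow_radius,
            neck_shaft_angle = neck_shaft_angle,
            neck_length = neck_length, anteversion = anteversion,
            head_radius = head_radius,
            trochanter_overhang = trochanter_overhang)
  lengths <- p[setdiff(names(p), c("anterior_bow_radius", "anteversion",
                                   "neck_shaft_angle"))]
  for (f in names(lengths))
    if (!is_scalar_num(p[[f]]) || p[[f]] <= 0)
      stop_femfit("invalid_spec", "femur parameter '%s' must be > 0", f)
  if (p$proximal_flare_radius < p$isthmus_radius)
    stop_femfit("invalid_spec",
                "proximal_flare_radius must be >= isthmus_radius")
  if (p$neck_shaft_angle <= 90 || p$neck_shaft_angle >= 160)
    stop_femfit("invalid_spec", "neck_shaft_angle must be in (90, 160)")
  if (!is.infinite(p$anterior_bow_radius) &&
      (!is.numeric(p$anterior_bow_radius) || p$anterior_bow_radius <= 200))
    stop_femfit("invalid_spec",
                "anterior_bow_radius must exceed 200 mm (or be Inf)")
  structure(p, class = "femur_params")
}

# canonical parameter order for population sampling / manifests
femur_param_names <- function() {
  c("femur_length", "isthmus_radius", "isthmus_station",
    "proximal_flare_radius", "anterior_bow_radius", "neck_shaft_angle",
    "neck_length", "anteversion", "head_radius", "trochanter_overhang")
}

#' Default population distributions
#'
#' Truncated-normal `(mean, sd, min, max)` per femur parameter. The
#' centres follow East-Asian morphometric literature values (e.g. mean
#' neck-shaft angle 129 deg, anterior bow radius 900 mm, isthmus radius
#' 5.5 mm); they are declared assumptions, fully overridable through
#' [population_spec()]. Bounds default to mean +/- 3 sd.
#'
#' @return named list of `c(mean, sd, min, max)` vectors.
#' @export
default_population <- function() {
  base <- list(
    femur_length = c(400, 20), isthmus_radius = c(5.5, 0.8),
    isthmus_station = c(200, 20), proximal_flare_radius = c(14, 1.5),
    anterior_bow_radius = c(900, 150), neck_shaft_angle = c(129, 5),
    neck_length = c(50, 5), anteversion = c(15, 5),
    head_radius = c(22, 1.5), trochanter_overhang = c(12, 2))
  lapply(base, function(v) c(mean = v[1], sd = v[2],
                             min = v[1] - 3 * v[2], max = v[1] + 3 * v[2]))
}

#' Cohort sampling specification
#'
#' @param n number of femurs (>= 1).
#' @param seed integer master seed; per-femur child seeds are derived
#'   from it by counter, so femur `i` is reproducible independently of
#'   the rest of the cohort.
#' @param params named overrides of [default_population()] entries; each
#'   value is `c(mean, sd)` or `c(mean, sd, min, max)`.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n, seed, params = list()) {
  if (!is_scalar_num(n) || n < 1 || n != round(n))
    stop_femfit("config", "n must be a positive integer (got %s)",
                format(n))
  if (!is_scalar_num(seed))
    stop_femfit("config", "an explicit integer seed is required")
  dist <- default_population()
  for (nm in names(params)) {
    if (!nm %in% names(dist))
      stop_femfit("config", "unknown femur parameter '%s'", nm)
    v <- as.numeric(params[[nm]])
    if (length(v) == 2) v <- c(v, v[1] - 3 * v[2], v[1] + 3 * v[2])
    if (length(v) != 4)
      stop_femfit("config", "'%s' must be (mean, sd) or (mean, sd, min, max)",
                  nm)
    names(v) <- c("mean", "sd", "min", "max")
    if (v["sd"] < 0)
      stop_femfit("config", "'%s' sd must be >= 0", nm)
    if (v["sd"] > 0 && v["min"] >= v["max"])
      stop_femfit("config", "'%s' bounds infeasible (min >= max)", nm)
    dist[[nm]] <- v
  }
  structure(list(n = as.integer(n), seed = as.integer(seed), dist = dist),
            class = "population_spec")
}

# inverse-CDF truncated-normal draw (exact, no rejection)
rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd == 0) return(mean)
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(1, plo, phi), mean, sd)
}

#' Sample a cohort of femur parameter sets
#'
#' @param spec a [population_spec()].
#' @return list of [femur_params()] objects of length `spec$n`, fully
#'   determined by `spec$seed`.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  lapply(seq_len(spec$n), function(i) {
    child <- as.integer((as.numeric(spec$seed) + i * 1000003) %%
                          2147483647)
    set.seed(child)
    vals <- lapply(spec$dist, function(d)
      rtruncnorm1(d[["mean"]], d[["sd"]], d[["min"]], d[["max"]]))
    do.call(femur_params, vals)
  })
}

# canal axis in frame coordinates: point + tangent at arc stations s,
# s = 0 at the trochanteric level (z = overhang), increasing distally
canal_axis_eval <- function(params, s) {
  h <- params$trochanter_overhang
  Lc <- params$femur_length - h
  Rb <- params$anterior_bow_radius
  if (is.infinite(Rb)) {
    n <- length(s)
    return(list(points = cbind(0, 0, h + s),
                tangents = matrix(rep(c(0, 0, 1), each = n), ncol = 3),
                arc_length = Lc))
  }
  phi0 <- asin(Lc / (2 * Rb))
  d <- sqrt(Rb^2 - (Lc / 2)^2)
  S <- 2 * Rb * phi0
  phi <- -phi0 + s / Rb
  y <- Rb * cos(phi) - d
  z <- h + Lc / 2 + Rb * sin(phi)
  list(points = cbind(0, y, z),
       tangents = cbind(0, -sin(phi), cos(phi)),
       arc_length = S)
}

# canal radius at arc station s (flare -> isthmus, constant beyond)
canal_radius <- function(params, s) {
  s_is <- params$isthmus_station - params$trochanter_overhang
  w <- pmin(1, pmax(0, s / s_is))
  params$proximal_flare_radius +
    (params$isthmus_radius - params$proximal_flare_radius) * w
}

# arc station whose z-coordinate equals `z_target` (below the GT apex)
canal_station_at_z <- function(params, z_target) {
  h <- params$trochanter_overhang
  Rb <- params$anterior_bow_radius
  if (is.infinite(Rb)) return(z_target - h)
  Lc <- params$femur_length - h
  phi0 <- asin(Lc / (2 * Rb))
  Rb * (asin((z_target - h - Lc / 2) / Rb) + phi0)
}

# depth below the GT apex of the neck take-off point on the canal axis;
# a fixed generator convention, documented so that morphometric
# re-estimation can use the same reference
NECK_BASE_DEPTH <- 40

neck_axis_dir <- function(params) {
  beta <- deg2rad(180 - params$neck_shaft_angle)
  av <- deg2rad(params$anteversion)
  c(-sin(beta) * cos(av), sin(beta) * sin(av), -cos(beta))
}

#' Build a synthetic femur model
#'
#' Realizes one parameter set as a watertight endosteal mesh (canal tube
#' plus head sphere) with exact landmarks, in the canonical frame
#' (GT apex at the origin, +z distal, +y anterior, +x lateral).
#'
#' @param params a [femur_params()] object.
#' @param id specimen id.
#' @param axial_step canal ring spacing, mm.
#' @param circumferential_samples vertices per canal ring.
#' @param dome_rings rings across the trochanteric cap.
#' @return a [femur_model()]; the generating parameters are attached as
#'   attribute `"params"`.
#' @export
build_femur <- function(params, id = "synthfem", axial_step = 3,
                        circumferential_samples = 24L, dome_rings = 8L) {
  stopifnot(inherits(params, "femur_params"))
  h <- params$trochanter_overhang
  Lc <- params$femur_length - h
  Rb <- params$anterior_bow_radius
  if (!is.infinite(Rb) && (Rb < params$femur_length / pi || 2 * Rb <= Lc))
    stop_femfit("geometry",
                "anterior_bow_radius %.0f mm is too tight for a %.0f mm femur",
                Rb, params$femur_length)
  if (NECK_BASE_DEPTH <= h)
    stop_femfit("geometry",
                "trochanter_overhang must stay above the neck take-off depth")

  probe <- canal_axis_eval(params, 0)
  S <- probe$arc_length
  s <- sort(unique(c(seq(axial_step, S, by = axial_step), S)))
  ax <- canal_axis_eval(params, s)
  rr_shaft <- canal_radius(params, s)

  # trochanteric dome: flat-topped superellipse profile, apex = GT apex
  p_exp <- 8
  zd <- h * seq_len(dome_rings) / dome_rings
  rr_dome <- params$proximal_flare_radius *
    (1 - ((h - zd) / h)^p_exp)^(1 / p_exp)
  t0 <- canal_axis_eval(params, 0)$tangents[1, ]  # arc-start orientation
  dome_pts <- cbind(0, 0, zd)
  # ring planes blend from horizontal at the apex to the arc tangent at
  # the base, so the cap stays symmetric near the apex (where the entry
  # rules read the trochanteric AP extent) and meets the shaft smoothly
  tilt0 <- atan2(t0[2], t0[3])
  tilt <- tilt0 * zd / h
  dome_tg <- cbind(0, sin(tilt), cos(tilt))
  # drop the dome ring that coincides with the arc start
  keep <- zd < h - 1e-9
  centers <- rbind(dome_pts[keep, , drop = FALSE],
                   canal_axis_eval(params, 0)$points,
                   ax$points)
  tangents <- rbind(dome_tg[keep, , drop = FALSE], t0, ax$tangents)
  radii <- c(rr_dome[keep], params$proximal_flare_radius, rr_shaft)

  k <- as.integer(circumferential_samples)
  theta <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  xd <- cbind(tangents[, 3], 0, -tangents[, 1]) /
    sqrt(tangents[, 3]^2 + tangents[, 1]^2)
  # planar y-z axis curve: x stays global lateral, y_loc = t cross x
  yd <- cbind(0, tangents[, 3], -tangents[, 2])
  off_x <- outer(radii, cos(theta))
  off_y <- outer(radii, sin(theta))
  canal <- sweep_tube(centers, xd, yd, off_x, off_y,
                      apex_start = c(0, 0, 0),
                      apex_end = ax$points[nrow(ax$points), ])

  base <- canal_axis_eval(params,
                          canal_station_at_z(params, NECK_BASE_DEPTH))$points[1, ]
  head_center <- base + params$neck_length * neck_axis_dir(params)
  head <- uv_sphere(head_center, params$head_radius, 10L, 16L)
  mesh <- merge_meshes(canal, head)

  sap <- canal_axis_eval(params, c(0.25, 0.4, 0.55, 0.7, 0.85) * S)$points
  lm <- landmarks(gt_apex = c(0, 0, 0), head_center = head_center,
                  shaft_axis_points = sap, anterior_dir = c(0, 1, 0),
                  side = "R")
  fm <- femur_model(mesh, lm, id = id)
  attr(fm, "params") <- params
  fm
}

# Kasa algebraic circle fit; returns list(center = c(a, b), radius)
fit_circle <- function(y, z) {
  A <- cbind(y, z, 1)
  b <- -(y^2 + z^2)
  coef <- qr.solve(A, b)
  ctr <- -coef[1:2] / 2
  r2 <- sum(ctr^2) - coef[3]
  list(center = ctr, radius = sqrt(max(r2, 0)))
}

#' Re-estimate generator parameters from an emitted model
#'
#' Morphometric recovery used to validate the generator: canal-axis
#' points are extracted by slicing the canal component of the mesh,
#' the anterior bow radius comes from a circle fit to those axis points
#' in the sagittal plane, the isthmus radius from the narrowest slice,
#' and the neck-shaft angle from the landmark head centre against the
#' fitted shaft axis (neck take-off at the generator's documented 40 mm
#' reference depth).
#'
#' @param femur a [femur_model()].
#' @param slice_step slice spacing, mm.
#' @return list with `anterior_bow_radius`, `isthmus_radius`,
#'   `neck_shaft_angle`, plus the extracted `axis_points` (frame mm).
#' @export
estimate_femur_params <- function(femur, slice_step = 8) {
  V <- to_frame(femur$frame, femur$mesh$vertices)
  comp <- mesh_vertex_components(femur$mesh)
  canal_comp <- comp[which.min(rowSums(V^2))]  # component at the GT apex
  Vc <- V[comp == canal_comp, , drop = FALSE]
  z0 <- min(Vc[, 3])
  z1 <- max(Vc[, 3])
  zc <- seq(z0 + 30, z1 - 15, by = slice_step)
  cent <- matrix(NA_real_, length(zc), 3)
  for (i in seq_along(zc)) {
    sel <- abs(Vc[, 3] - zc[i]) <= slice_step / 2
    if (sum(sel) < 8) next
    # a z-slice through the tilted tube catches partial rings, so a
    # vertex-mean centroid is biased; a 2D circle fit to the slice
    # boundary recovers the axis point robustly
    cf <- fit_circle(Vc[sel, 1], Vc[sel, 2])
    cent[i, ] <- c(cf$center, zc[i])
  }
  ok <- !is.na(cent[, 1])
  cent <- cent[ok, , drop = FALSE]
  zc <- zc[ok]

  fit <- fit_circle(cent[, 2], cent[, 3])
  resid_line <- sd(cent[, 2])
  bow <- if (fit$radius > 2e4 || resid_line < 0.05) Inf else fit$radius

  # isthmus = smallest perpendicular distance from the diaphyseal canal
  # wall to the recovered axis curve
  shaft <- Vc[, 3] >= z0 + 60 & Vc[, 3] <= z1 - 15
  Vs <- Vc[shaft, , drop = FALSE]
  if (is.finite(bow)) {
    dyz <- sqrt((Vs[, 2] - fit$center[1])^2 + (Vs[, 3] - fit$center[2])^2)
    isthmus <- min(sqrt(Vs[, 1]^2 + (dyz - fit$radius)^2))
  } else {
    xl <- mean(cent[, 1])
    yl <- mean(cent[, 2])
    isthmus <- min(sqrt((Vs[, 1] - xl)^2 + (Vs[, 2] - yl)^2))
  }

  base <- c(approx(zc, cent[, 1], NECK_BASE_DEPTH, rule = 2)$y,
            approx(zc, cent[, 2], NECK_BASE_DEPTH, rule = 2)$y,
            NECK_BASE_DEPTH)
  zdir <- shaft_axis_dir(cent)
  if (zdir[3] < 0) zdir <- -zdir
  hc <- to_frame(femur$frame, femur$landmarks$head_center)
  u <- unitize(hc - base)
  nsa <- rad2deg(acos(pmin(1, pmax(-1, sum(u * zdir)))))

  list(anterior_bow_radius = bow, isthmus_radius = isthmus,
       neck_shaft_angle = nsa, axis_points = cent)
}

#' Simulate a cohort of synthetic femurs
#'
#' Samples a population and builds every femur; optionally writes each
#' model (STL + landmark JSON) and a manifest CSV of the true generator
#' parameters to `out_dir`.
#'
#' @param spec a [population_spec()].
#' @param out_dir optional output directory.
#' @param ... passed to [build_femur()] (mesh resolution).
#' @return list with `femurs` (list of [femur_model()]), `params` and
#'   `manifest` (data.frame of true parameters).
#' @export
simulate_cohort <- function(spec, out_dir = NULL, ...) {
  params <- sample_population(spec)
  ids <- sprintf("femur_%03d", seq_along(params))
  femurs <- mapply(function(p, id) build_femur(p, id = id, ...), params,
                   ids, SIMPLIFY = FALSE)
  manifest <- cbind(data.frame(id = ids),
                    do.call(rbind, lapply(params, function(p)
                      as.data.frame(unclass(p)))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(femurs)) {
      write_stl(femurs[[i]]$mesh, file.path(out_dir,
                                            paste0(ids[i], ".stl")))
      write_landmarks(femurs[[i]]$landmarks,
                      file.path(out_dir, paste0(ids[i], ".json")))
    }
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  list(femurs = femurs, params = params, manifest = manifest)
}
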