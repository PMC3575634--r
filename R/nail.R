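# Parametric cephalomedullary nail geometry.
#
# Nail-local frame: origin at the proximal tip, +z toward the distal tip
# along the proximal segment, +x toward the lateral face (the side the
# flat of a PFNA-II points to), +y anterior. The mediolateral bend is a
# circular-arc transition between the straight proximal and distal
# segments so the swept surface stays manifold; the distal segment tilts
# medially (toward -x) by the bend angle.

#' Nail design specification
#'
#' Validated container for the parametric description of an
#' intramedullary nail. Prefer the design constructors
#' [make_pfna2_spec()], [make_pfna_legacy_spec()], [make_intertan_spec()];
#' `nail_spec()` builds a fully explicit (GENERIC) spec.
#'
#' @param model_id one of `"PFNA2"`, `"PFNA"`, `"INTERTAN"`, `"GENERIC"`.
#' @param total_length nail length along its axis, mm.
#' @param proximal_diameter,distal_diameter section diameters, mm
#'   (proximal >= distal; for the trapezoidal section the proximal
#'   diameter is the mediolateral width).
#' @param bend_angle mediolateral angulation between the proximal and
#'   distal segments, degrees (0 <= angle < 15).
#' @param bend_station arc-length position of the bend centre from the
#'   proximal tip, mm.
#' @param ccd_angle angle between the head-element axis and the distal
#'   nail axis, degrees (90 < angle < 180).
#' @param proximal_section `"circular"`, `"flat_lateral"` or
#'   `"trapezoidal"`.
#' @param flat_depth material removed on the lateral face, mm (flat
#'   section only).
#' @param trapezoid_ap_depth anteroposterior extent of the trapezoidal
#'   section, mm (trapezoidal section only).
#' @param trapezoid_lateral_ratio length of the lateral parallel side of
#'   the trapezoid relative to the medial side.
#' @param head_element_length length of the blade/screw corridor, mm.
#' @param head_station arc-length station where the head-element axis
#'   crosses the nail axis, mm from the proximal tip.
#' @param head_envelope_radius radius of the cylindrical head-element
#'   envelope, mm.
#' @param twin_screws logical; `TRUE` marks an integrated twin-screw
#'   corridor (InterTan-style) rather than a single blade.
#' @param bend_radius radius of the circular-arc bend transition, mm.
#' @param taper_length axial length over which the proximal section
#'   morphs into the circular distal section, mm (ends at the bend
#'   station).
#' @return an object of class `nail_spec`.
#' @export
nail_spec <- function(model_id = "GENERIC",
                      total_length,
                      proximal_diameter,
                      distal_diameter,
                      bend_angle,
                      bend_station,
                      ccd_angle,
                      proximal_section = c("circular", "flat_lateral",
                                           "trapezoidal"),
                      flat_depth = 0,
                      trapezoid_ap_depth = 0,
                      trapezoid_lateral_ratio = 0.7,
                      head_element_length = 100,
                      head_station = 45,
                      head_envelope_radius = 5.5,
                      twin_screws = FALSE,
                      bend_radius = 50,
                      taper_length = 30) {
  proximal_section <- match.arg(proximal_section)
  spec <- list(
    model_id = model_id, total_length = total_length,
    proximal_diameter = proximal_diameter,
    distal_diameter = distal_diameter, bend_angle = bend_angle,
    bend_station = bend_station, ccd_angle = ccd_angle,
    proximal_section = proximal_section, flat_depth = flat_depth,
    trapezoid_ap_depth = trapezoid_ap_depth,
    trapezoid_lateral_ratio = trapezoid_lateral_ratio,
    head_element_length = head_element_length,
    head_station = head_station,
    head_envelope_radius = head_envelope_radius,
    twin_screws = isTRUE(twin_screws), bend_radius = bend_radius,
    taper_length = taper_length)
  validate_nail_spec(spec)
  structure(spec, class = "nail_spec")
}

validate_nail_spec <- function(s) {
  num_fields <- c("total_length", "proximal_diameter", "distal_diameter",
                  "bend_angle", "bend_station", "ccd_angle", "flat_depth",
                  "trapezoid_ap_depth", "head_element_length",
                  "head_station", "head_envelope_radius", "bend_radius",
                  "taper_length")
  for (f in num_fields) {
    if (!is_scalar_num(s[[f]]))
      stop_femfit("invalid_spec", "field '%s' must be a finite number", f)
  }
  if (!(s$total_length > s$bend_station && s$bend_station > 0))
    stop_femfit("invalid_spec",
                "need total_length > bend_station > 0 (got %g, %g)",
                s$total_length, s$bend_station)
  if (!(s$proximal_diameter >= s$distal_diameter &&
        s$distal_diameter > 0))
    stop_femfit("invalid_spec",
                "need proximal_diameter >= distal_diameter > 0 (got %g, %g)",
                s$proximal_diameter, s$distal_diameter)
  if (s$bend_angle < 0 || s$bend_angle >= 15)
    stop_femfit("invalid_spec", "bend_angle must be in [0, 15) degrees")
  if (s$ccd_angle <= 90 || s$ccd_angle >= 180)
    stop_femfit("invalid_spec", "ccd_angle must be in (90, 180) degrees")
  if (s$proximal_section != "flat_lateral" && s$flat_depth != 0)
    stop_femfit("invalid_spec",
                "flat_depth must be 0 unless proximal_section is flat_lateral")
  if (s$proximal_section != "trapezoidal" && s$trapezoid_ap_depth != 0)
    stop_femfit("invalid_spec",
                "trapezoid_ap_depth must be 0 unless section is trapezoidal")
  if (s$proximal_section == "flat_lateral" && s$flat_depth <= 0)
    stop_femfit("invalid_spec", "flat_lateral section needs flat_depth > 0")
  if (s$proximal_section == "trapezoidal" && s$trapezoid_ap_depth <= 0)
    stop_femfit("invalid_spec",
                "trapezoidal section needs trapezoid_ap_depth > 0")
  if (s$head_station <= 0 || s$head_station >= s$total_length)
    stop_femfit("invalid_spec", "head_station must lie inside the nail")
  invisible(s)
}

#' @export
print.nail_spec <- function(x, ...) {
  cat(sprintf(
    "<nail_spec %s> L=%g mm, prox %g mm / dist %g mm, bend %g deg @ %g mm, CCD %g deg, section %s\n",
    x$model_id, x$total_length, x$proximal_diameter, x$distal_diameter,
    x$bend_angle, x$bend_station, x$ccd_angle, x$proximal_section))
  invisible(x)
}

#' Shipped nail design defaults
#'
#' Reads the named entry from the package's nail configuration
#' (`inst/extdata/nail_defaults.yaml`), or from `config_path` when given.
#'
#' @param model `"pfna2"`, `"pfna"` or `"intertan"`.
#' @param config_path optional alternative YAML config.
#' @return named list of default fields.
#' @export
nail_defaults <- function(model, config_path = NULL) {
  path <- config_path %||%
    system.file("extdata", "nail_defaults.yaml", package = "femfit")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg[[model]]))
    stop_femfit("config", "no nail config entry '%s' in %s", model, path)
  cfg[[model]]
}

make_design_spec <- function(model, model_id, length, distal_diameter,
                             overrides) {
  if (!is_scalar_num(length) || length <= 0)
    stop_femfit("invalid_spec", "nail length must be > 0 (got %s)",
                format(length))
  if (!is_scalar_num(distal_diameter) || distal_diameter <= 0)
    stop_femfit("invalid_spec", "distal diameter must be > 0 (got %s)",
                format(distal_diameter))
  cfg <- nail_defaults(model)
  cfg <- modifyList(cfg, overrides)
  cfg$total_length <- length
  cfg$distal_diameter <- distal_diameter
  do.call(nail_spec, c(list(model_id = model_id), cfg))
}

#' PFNA-II design specification
#'
#' Asian-variant proximal femoral nail antirotation: 5 degree
#' mediolateral bend, 16.5 mm proximal diameter, flattened lateral
#' proximal face. Length and distal diameter are per-case choices; the
#' remaining fields come from the shipped config and can be overridden.
#'
#' @param length total nail length, mm.
#' @param distal_diameter distal shaft diameter, mm.
#' @param ... config overrides (e.g. `ccd_angle = 125`).
#' @return a `nail_spec`.
#' @export
make_pfna2_spec <- function(length = 200, distal_diameter = 10, ...) {
  make_design_spec("pfna2", "PFNA2", length, distal_diameter, list(...))
}

#' Legacy PFNA design specification
#'
#' The original (non-Asian) design: 6 degree bend, 17 mm proximal
#' diameter, fully circular proximal section.
#'
#' @inheritParams make_pfna2_spec
#' @return a `nail_spec`.
#' @export
make_pfna_legacy_spec <- function(length = 200, distal_diameter = 10, ...) {
  make_design_spec("pfna", "PFNA", length, distal_diameter, list(...))
}

#' InterTan design specification
#'
#' Trapezoidal proximal cross-section with an integrated twin
#' cephalocervical screw corridor. The trapezoid dimensions are not
#' published design constants; the shipped config carries representative
#' values which every experiment records.
#'
#' @inheritParams make_pfna2_spec
#' @return a `nail_spec`.
#' @export
make_intertan_spec <- function(length = 200, distal_diameter = 10, ...) {
  make_design_spec("intertan", "INTERTAN", length, distal_diameter, list(...))
}

#' Read / write a nail spec as a YAML config entry
#'
#' @param spec a `nail_spec`.
#' @param path YAML file path.
#' @return `read_nail_spec()` returns the restored `nail_spec`.
#' @export
write_nail_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_nail_spec
#' @export
read_nail_spec <- function(path) {
  do.call(nail_spec, yaml::read_yaml(path))
}

# axis polyline ------------------------------------------------------------

# Axis point + tangent at arc-length stations s (vectorized).
# Straight proximal segment, circular-arc bend of radius `bend_radius`
# centred at `bend_station`, straight distal segment tilting medially.
nail_axis_eval <- function(spec, s) {
  b <- deg2rad(spec$bend_angle)
  if (b == 0) {
    n <- length(s)
    return(list(points = cbind(0, 0, s),
                tangents = matrix(rep(c(0, 0, 1), each = n), ncol = 3)))
  }
  Rb <- spec$bend_radius
  arc_len <- Rb * b
  s1 <- spec$bend_station - arc_len / 2
  s2 <- spec$bend_station + arc_len / 2
  if (s1 <= 0)
    stop_femfit("geometry", "bend arc extends past the proximal tip")
  px <- numeric(length(s))
  pz <- numeric(length(s))
  tx <- numeric(length(s))
  tz <- numeric(length(s))
  prox <- s <= s1
  px[prox] <- 0
  pz[prox] <- s[prox]
  tx[prox] <- 0
  tz[prox] <- 1
  arc <- s > s1 & s < s2
  al <- (s[arc] - s1) / Rb
  px[arc] <- -Rb * (1 - cos(al))
  pz[arc] <- s1 + Rb * sin(al)
  tx[arc] <- -sin(al)
  tz[arc] <- cos(al)
  dist <- s >= s2
  ex <- -Rb * (1 - cos(b))
  ez <- s1 + Rb * sin(b)
  px[dist] <- ex - sin(b) * (s[dist] - s2)
  pz[dist] <- ez + cos(b) * (s[dist] - s2)
  tx[dist] <- -sin(b)
  tz[dist] <- cos(b)
  list(points = cbind(px, 0, pz), tangents = cbind(tx, 0, tz))
}

# cross-section radius r(theta) -------------------------------------------

# radial distance of a convex polygon boundary from the origin, per angle
poly_radial <- function(theta, verts) {
  nv <- nrow(verts)
  r <- rep(Inf, length(theta))
  d <- cbind(cos(theta), sin(theta))
  for (i in seq_len(nv)) {
    a <- verts[i, ]
    bb <- verts[i %% nv + 1, ]
    e <- bb - a
    den <- d[, 1] * (-e[2]) + d[, 2] * e[1]
    # solve a + u*e = t*d ; t = (a x e) / (d x e)
    t_ <- (a[1] * (-e[2]) + a[2] * e[1]) / den
    u <- (a[1] * d[, 2] - a[2] * d[, 1]) / -den
    ok <- is.finite(t_) & t_ > 0 & u >= -1e-9 & u <= 1 + 1e-9
    r[ok] <- pmin(r[ok], t_[ok])
  }
  r
}

# proximal cross-section radius function at angles theta (theta = 0 is
# lateral +x, counter-clockwise toward anterior +y)
proximal_radius <- function(spec, theta) {
  r <- spec$proximal_diameter / 2
  switch(spec$proximal_section,
    circular = rep(r, length(theta)),
    flat_lateral = {
      xcut <- r - spec$flat_depth
      out <- rep(r, length(theta))
      ct <- cos(theta)
      cutin <- ct > 0 & (xcut / ct) < r
      out[cutin] <- xcut / ct[cutin]
      out
    },
    trapezoidal = {
      w <- spec$proximal_diameter / 2
      hm <- spec$trapezoid_ap_depth / 2
      hl <- hm * spec$trapezoid_lateral_ratio
      verts <- rbind(c(w, -hl), c(w, hl), c(-w, hm), c(-w, -hm))
      poly_radial(theta, verts)
    })
}

# full radius profile r(theta, s): proximal shape up to the taper start,
# linear morph to the circular distal radius by the bend station
section_radius <- function(spec, theta, s) {
  t0 <- spec$bend_station - spec$taper_length
  t1 <- spec$bend_station
  w <- pmin(1, pmax(0, (s - t0) / max(t1 - t0, 1e-9)))
  rp <- proximal_radius(spec, theta)
  rd <- spec$distal_diameter / 2
  outer(1 - w, rp) + outer(w, rep(rd, length(theta)))
}

# head-element axis in nail-local coordinates
head_axis_local <- function(spec) {
  b <- deg2rad(spec$bend_angle)
  g <- deg2rad(spec$ccd_angle) + b  # angle from the +z axis
  base <- nail_axis_eval(spec, spec$head_station)$points[1, ]
  list(base = base, dir = c(-sin(g), 0, cos(g)))
}

#' Build the triangulated nail surface
#'
#' Sweeps the parametric cross-section along the axis polyline. Returns a
#' watertight indexed mesh together with the axis polyline, the
#' head-element axis and a per-vertex arc-length station table.
#'
#' @param spec a [nail_spec()].
#' @param circumferential_samples vertices per cross-section ring
#'   (>= 12).
#' @param axial_step ring spacing along the axis, mm (<= 5).
#' @return an object of class `nail_mesh` with fields `surface`
#'   (`fem_mesh`), `axis` (stations + points + tangents), `head_axis`
#'   (`base`, `dir` in nail-local mm), `station` (per-vertex arc length)
#'   and `spec`.
#' @export
build_nail_mesh <- function(spec, circumferential_samples = 32L,
                            axial_step = 2) {
  stopifnot(inherits(spec, "nail_spec"))
  if (circumferential_samples < 12)
    stop_femfit("invalid_spec", "need >= 12 circumferential samples")
  if (axial_step > 5)
    stop_femfit("invalid_spec", "axial_step must be <= 5 mm")
  if (spec$proximal_section == "flat_lateral" &&
      spec$flat_depth >= spec$proximal_diameter / 2)
    stop_femfit("geometry",
                "flat_depth >= proximal radius gives a degenerate section")

  L <- spec$total_length
  s <- sort(unique(c(seq(0, L, by = axial_step), L,
                     spec$bend_station,
                     spec$bend_station - spec$taper_length)))
  s <- s[s >= 0 & s <= L]
  ax <- nail_axis_eval(spec, s)
  theta <- seq(0, 2 * pi, length.out = circumferential_samples + 1L)
  theta <- theta[-length(theta)]
  rr <- section_radius(spec, theta, s)
  off_x <- rr * matrix(cos(theta), nrow = length(s),
                       ncol = length(theta), byrow = TRUE)
  off_y <- rr * matrix(sin(theta), nrow = length(s),
                       ncol = length(theta), byrow = TRUE)
  # local frames: global +y stays anterior; x = y cross tangent
  tg <- ax$tangents
  xd <- cbind(tg[, 3], 0, -tg[, 1])
  yd <- matrix(rep(c(0, 1, 0), each = length(s)), ncol = 3)
  surf <- sweep_tube(ax$points, xd, yd, off_x, off_y,
                     apex_start = ax$points[1, ],
                     apex_end = ax$points[length(s), ])
  station <- c(rep(s, each = length(theta)), 0, L)
  structure(list(surface = surf,
                 axis = list(station = s, points = ax$points,
                             tangents = ax$tangents),
                 head_axis = head_axis_local(spec),
                 station = station,
                 spec = spec),
            class = "nail_mesh")
}

#' @export
print.nail_mesh <- function(x, ...) {
  cat(sprintf("<nail_mesh %s> %d vertices, axis length %.2f mm\n",
              x$spec$model_id, nrow(x$surface$vertices),
              max(x$axis$station)))
  invisible(x)
}

#' Sample points on the nail shaft surface
#'
#' Near-uniform sampling of the lateral (shaft) surface at a target areal
#' density; end caps are not sampled (penetration is measured against the
#' shaft, the tip is handled by the protrusion and distal-patch metrics).
#'
#' @param spec a `nail_spec`.
#' @param density target samples per mm^2.
#' @return list with `points` (n x 3, nail-local mm), `station` (arc
#'   length per sample, mm) and `theta` (section angle).
#' @export
nail_surface_samples <- function(spec, density = 4) {
  stopifnot(density > 0)
  ds <- 1 / sqrt(density)
  L <- spec$total_length
  s <- seq(ds / 2, L - ds / 2, by = ds)
  girth_proxy <- pi * spec$proximal_diameter
  k <- max(12L, as.integer(round(girth_proxy * sqrt(density))))
  theta <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  ax <- nail_axis_eval(spec, s)
  rr <- section_radius(spec, theta, s)
  tg <- ax$tangents
  xdx <- tg[, 3]
  xdz <- -tg[, 1]
  ct <- matrix(cos(theta), nrow = length(s), ncol = k, byrow = TRUE)
  st <- matrix(sin(theta), nrow = length(s), ncol = k, byrow = TRUE)
  px <- ax$points[, 1] + rr * ct * xdx
  py <- rr * st
  pz <- ax$points[, 3] + rr * ct * xdz
  list(points = cbind(as.vector(t(px)), as.vector(t(py)),
                      as.vector(t(pz))),
       station = rep(s, each = k),
       theta = rep(theta, length(s)))
}
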