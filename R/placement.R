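# Rule-based virtual nail insertion. The manufacturer rules fix the
# entry point (greater-trochanter vertex in the AP view, anterior third
# of the local trochanteric AP extent in the lateral view) and require
# the head element to pass through the femoral head centre; the two
# remaining surgical freedoms -- insertion depth along the proximal axis
# and axial rotation -- are solved by deterministic grid minimization of
# the head-centre miss distance. Cortical penetration is permitted: the
# whole point of the downstream metrics is to measure where the
# rule-compliant position conflicts with the bone.

#' Guideline entry point on the trochanter
#'
#' In the AP view the entry point sits at the GT vertex; in the lateral
#' view at the boundary between the anterior and middle thirds of the
#' local trochanteric anteroposterior extent. The point is realized on
#' the mesh surface by casting a distal ray from above the trochanter.
#'
#' @param femur a [femur_model()].
#' @param band proximal band (mm below the local apex) over which the
#'   trochanteric AP extent is measured.
#' @param tol_x half-width of the mediolateral strip used to localize
#'   the apex, mm.
#' @return length-3 world point on the mesh surface, mm. The femur-frame
#'   coordinates are attached as attribute `"frame_point"`.
#' @export
entry_point <- function(femur, band = 5, tol_x = 3) {
  fr <- femur$frame
  V <- to_frame(fr, femur$mesh$vertices)
  tx <- tol_x
  repeat {
    cand <- which(abs(V[, 1]) <= tx)
    if (length(cand) >= 10 || tx > 50) break
    tx <- tx * 2
  }
  if (length(cand) < 3)
    stop_femfit("geometry", "cannot locate the proximal trochanteric surface")
  z_top <- min(V[cand, 3])
  prox <- cand[V[cand, 3] <= z_top + band]
  y_rng <- range(V[prox, 2])
  y_star <- y_rng[1] + (2 / 3) * diff(y_rng)  # anterior-third boundary

  mesh_f <- new_mesh(V, femur$mesh$faces)
  # nudge the ray off the exact mediolateral midline so it cannot thread
  # a shared vertex column of the tessellation
  origin <- c(1e-4, y_star, z_top - 50)
  t_hit <- mesh_ray_hits(mesh_f, origin, c(0, 0, 1))
  if (!is.finite(t_hit))
    stop_femfit("geometry", "entry ray misses the proximal surface")
  p_f <- origin + c(0, 0, 1) * t_hit
  p_w <- from_frame(fr, p_f)
  attr(p_w, "frame_point") <- p_f
  p_w
}

#' Solve insertion depth and axial rotation
#'
#' Minimizes the distance from the head-element axis to the femoral head
#' centre over (depth, rotation), with the nail's proximal axis
#' constrained through the entry point along the insertion direction.
#' Deterministic: exhaustive coarse grid (default 1 mm x 1 deg), then
#' local golden-section refinement to 0.01 mm / 0.01 deg. Ties on the
#' grid break toward smaller depth, then smaller rotation.
#'
#' @param femur a [femur_model()].
#' @param nail a [build_nail_mesh()] result.
#' @param spec the matching [nail_spec()].
#' @param entry entry point (world mm), e.g. from [entry_point()].
#' @param grid list of solver controls: `depth_range` (mm, relative to
#'   the entry plane; negative = tip proud), `depth_step`, `rot_step`
#'   (deg), `refine_tol` (c(mm, deg)), `approach_angle` (deg, anterior
#'   tilt of the insertion direction away from the shaft axis).
#' @return list with `depth` (mm), `rotation` (deg), `miss` (mm).
#' @export
solve_depth_rotation <- function(femur, nail, spec, entry,
                                 grid = list()) {
  g <- modifyList(list(depth_range = c(-15, 60), depth_step = 1,
                       rot_step = 1, refine_tol = c(0.01, 0.01),
                       approach_angle = 0), grid)
  if (g$depth_range[1] >= g$depth_range[2])
    stop_femfit("geometry", "empty feasible depth range")
  fr <- femur$frame
  entry_f <- attr(entry, "frame_point") %||% to_frame(fr, entry)
  hc <- to_frame(fr, femur$landmarks$head_center)
  d_ins <- as.numeric(rot_axis(c(1, 0, 0), -g$approach_angle) %*% c(0, 0, 1))

  hb <- nail$head_axis$base
  m <- nail$head_axis$dir

  phis <- seq(-180, 180 - g$rot_step, by = g$rot_step)
  depths <- seq(g$depth_range[1], g$depth_range[2], by = g$depth_step)

  # for fixed rotation phi the squared miss is quadratic in depth:
  # |P (w0 - depth * d)|^2 with P = I - u u^T, so the whole grid reduces
  # to three coefficient vectors over phi
  cosp <- cos(deg2rad(phis))
  sinp <- sin(deg2rad(phis))
  ux <- m[1] * cosp - m[2] * sinp
  uy <- m[1] * sinp + m[2] * cosp
  uz <- rep(m[3], length(phis))
  bx <- hb[1] * cosp - hb[2] * sinp
  by <- hb[1] * sinp + hb[2] * cosp
  bz <- rep(hb[3], length(phis))
  w0x <- hc[1] - entry_f[1] - bx
  w0y <- hc[2] - entry_f[2] - by
  w0z <- hc[3] - entry_f[3] - bz
  # P v = v - (u.v) u  (u unit by construction)
  dot_ud <- ux * d_ins[1] + uy * d_ins[2] + uz * d_ins[3]
  dot_uw <- ux * w0x + uy * w0y + uz * w0z
  a <- 1 - dot_ud^2                      # |P d|^2
  bcoef <- (w0x * d_ins[1] + w0y * d_ins[2] + w0z * d_ins[3]) -
    dot_uw * dot_ud                      # (P w0) . (P d)
  cc <- (w0x^2 + w0y^2 + w0z^2) - dot_uw^2

  M <- outer(a, depths^2) - 2 * outer(bcoef, depths) + cc  # phi x depth
  M[M < 0] <- 0
  best <- which(M == min(M), arr.ind = TRUE)
  # tie-break: smallest depth, then smallest rotation
  ord <- order(depths[best[, 2]], phis[best[, 1]])
  bi <- best[ord[1], ]
  phi0 <- phis[bi[1]]
  dep0 <- depths[bi[2]]

  miss_at <- function(phi, depth) {
    cp <- cos(deg2rad(phi))
    sp <- sin(deg2rad(phi))
    u <- c(m[1] * cp - m[2] * sp, m[1] * sp + m[2] * cp, m[3])
    b <- c(hb[1] * cp - hb[2] * sp, hb[1] * sp + hb[2] * cp, hb[3])
    w <- hc - entry_f - b - depth * d_ins
    pw <- w - sum(u * w) * u
    sqrt(sum(pw^2))
  }
  best_depth_for <- function(phi) {
    cp <- cos(deg2rad(phi))
    sp <- sin(deg2rad(phi))
    u <- c(m[1] * cp - m[2] * sp, m[1] * sp + m[2] * cp, m[3])
    b <- c(hb[1] * cp - hb[2] * sp, hb[1] * sp + hb[2] * cp, hb[3])
    w0 <- hc - entry_f - b
    pd <- d_ins - sum(u * d_ins) * u
    pw <- w0 - sum(u * w0) * u
    den <- sum(pd^2)
    if (den < 1e-12) return(dep0)
    min(max(sum(pw * pd) / den, g$depth_range[1]), g$depth_range[2])
  }

  # golden-section refinement over rotation (depth optimum closed-form)
  lo <- phi0 - g$rot_step
  hi <- phi0 + g$rot_step
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- miss_at(x1, best_depth_for(x1))
  f2 <- miss_at(x2, best_depth_for(x2))
  while (hi - lo > g$refine_tol[2]) {
    if (f1 <= f2) {
      hi <- x2
      x2 <- x1
      f2 <- f1
      x1 <- hi - gr * (hi - lo)
      f1 <- miss_at(x1, best_depth_for(x1))
    } else {
      lo <- x1
      x1 <- x2
      f1 <- f2
      x2 <- lo + gr * (hi - lo)
      f2 <- miss_at(x2, best_depth_for(x2))
    }
  }
  phi_star <- if (f1 <= f2) x1 else x2
  dep_star <- best_depth_for(phi_star)
  dep_star <- round(dep_star / g$refine_tol[1]) * g$refine_tol[1]
  miss <- miss_at(phi_star, dep_star)
  if (miss > miss_at(phi0, dep0)) {  # refinement must never regress
    phi_star <- phi0
    dep_star <- dep0
    miss <- miss_at(phi0, dep0)
  }
  list(depth = dep_star, rotation = phi_star, miss = miss,
       d_ins = d_ins, entry_frame = entry_f)
}

#' Place a nail into a femur by the manufacturer rules
#'
#' @param femur a [femur_model()].
#' @param nail a [build_nail_mesh()] result.
#' @param spec the matching [nail_spec()].
#' @param opts list: `tol` (head-centre miss accepted as converged, mm,
#'   default 1), `max_miss` (mm; a best miss above this is reported as a
#'   placement failure, default 10), `entry_band` / `entry_tol_x`
#'   (passed to [entry_point()]), plus any [solve_depth_rotation()]
#'   grid controls.
#' @return an object of class `placement_result`: `transform` (nail-local
#'   to world [rigid_transform()]), `transform_frame` (nail-local to
#'   femur frame), `entry_point` (world mm), `insertion_depth` (mm below
#'   the entry plane), `rotation` (deg), `head_center_miss` (mm),
#'   `converged`.
#' @export
place_nail <- function(femur, nail, spec, opts = list()) {
  o <- modifyList(list(tol = 1, max_miss = 10, entry_band = 5,
                       entry_tol_x = 3), opts)
  entry <- entry_point(femur, band = o$entry_band, tol_x = o$entry_tol_x)
  sol <- solve_depth_rotation(femur, nail, spec, entry,
                              grid = o[intersect(names(o),
                                                 c("depth_range",
                                                   "depth_step", "rot_step",
                                                   "refine_tol",
                                                   "approach_angle"))])
  # nail-local -> femur frame: rotate +z onto the insertion direction,
  # spin by the solved axial rotation, tip at entry + depth * direction
  R_align <- if (abs(sol$d_ins[3] - 1) < 1e-12) diag(3) else {
    axis <- cross3(c(0, 0, 1), sol$d_ins)
    rot_axis(axis, rad2deg(acos(sol$d_ins[3])))
  }
  R_f <- R_align %*% rot_z(sol$rotation)
  t_f <- sol$entry_frame + sol$depth * sol$d_ins
  tr_frame <- rigid_transform(R_f, t_f)
  tr_world <- rigid_compose(frame_as_rigid(femur$frame), tr_frame)
  converged <- sol$miss <= o$tol
  if (sol$miss > o$max_miss)
    femfit_log("placement for %s/%s did not converge (best miss %.2f mm)",
               femur$id, spec$model_id, sol$miss)
  structure(list(transform = tr_world, transform_frame = tr_frame,
                 entry_point = as.numeric(entry),
                 insertion_depth = sol$depth, rotation = sol$rotation,
                 head_center_miss = sol$miss,
                 converged = converged && sol$miss <= o$max_miss),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf(
    "<placement> depth %.2f mm, rotation %.2f deg, head-centre miss %.3f mm (%s)\n",
    x$insertion_depth, x$rotation, x$head_center_miss,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
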