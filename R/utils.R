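#' @useDynLib femfit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif qnorm pnorm sd approx setNames
#'   chisq.test fisher.test t.test wilcox.test
#' @importFrom utils read.csv write.csv packageVersion modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used for reported
#' percentages and millimetre summaries (base `round()` rounds half to
#' even, which does not match conventional clinical reporting).
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop_femfit("geometry", "cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Rotation matrix about the z axis
#' @param angle_deg rotation angle in degrees (counter-clockwise about +z).
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), nrow = 3)
}

# Rotation about an arbitrary unit axis (Rodrigues).
rot_axis <- function(axis, angle_deg) {
  u <- unitize(axis)
  a <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), nrow = 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Rigid transforms
#'
#' A rigid transform is stored as a list with rotation `R` (3x3, det +1
#' unless constructed with a reflection on purpose) and translation `t`;
#' it maps points as `R %*% p + t`.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)), length(t) == 3)
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param tr a `rigid_transform`.
#' @param pts n x 3 matrix (or length-3 vector) of points.
#' @export
rigid_apply <- function(tr, pts) {
  if (is.null(dim(pts))) return(as.numeric(tr$R %*% pts + tr$t))
  sweep(pts %*% t(tr$R), 2, tr$t, "+")
}

#' @rdname rigid_transform
#' @param a,b transforms; the result applies `b` first, then `a`.
#' @export
rigid_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' @rdname rigid_transform
#' @export
rigid_invert <- function(tr) {
  rigid_transform(t(tr$R), as.numeric(-t(tr$R) %*% tr$t))
}

#' @rdname rigid_transform
#' @export
rigid_matrix44 <- function(tr) {
  m <- diag(4)
  m[1:3, 1:3] <- tr$R
  m[1:3, 4] <- tr$t
  m
}

# Random rigid transform drawn from the current RNG stream (test helper
# exported because the property suites in reverse-dependency code use it).
#' @rdname rigid_transform
#' @param translation_scale scale of the random translation, mm.
#' @export
rigid_random <- function(translation_scale = 100) {
  axis <- unitize(rnorm(3))
  rigid_transform(rot_axis(axis, runif(1, 0, 360)),
                  rnorm(3, sd = translation_scale))
}

# classed conditions -------------------------------------------------------

stop_femfit <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("femfit_", class, "_error"), "femfit_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

femfit_log <- function(fmt, ...) {
  if (isTRUE(getOption("femfit.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
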