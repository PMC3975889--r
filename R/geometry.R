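# Elementary 3D vector geometry: torsion measurement, internal-coordinate
# atom placement (NeRF) and axis rotations.  All angles are degrees.

.deg <- function(x) x * 180 / pi
.rad <- function(x) x * pi / 180

#' Wrap angles into `[0, 360)`
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into `[0, 360)`.
#' @export
wrap360 <- function(x) {
  y <- x %% 360
  y[y == 360] <- 0   # guards the x %% 360 == 360 floating-point quirk
  y
}

#' Wrap angles into `(-180, 180]`
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into `(-180, 180]`.
#' @export
wrap180 <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y == -180] <- 180
  y
}

v_norm <- function(v) sqrt(sum(v * v))
v_unit <- function(v) v / v_norm(v)
v_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Torsion angle defined by four points
#'
#' Signed dihedral angle of the chain p1-p2-p3-p4 under the IUPAC sign
#' convention (clockwise rotation of the far bond, viewed from p2 towards
#' p3, is positive), reported in `[0, 360)`.  Callers that need backbone
#' phi/psi in `(-180, 180]` wrap the result with [wrap180()].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees in `[0, 360)`.
#' @examples
#' dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)) # 90
#' dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)) # 180
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (v_norm(b1) < 1e-10 || v_norm(b2) < 1e-10 || v_norm(b3) < 1e-10) {
    stop("dihedral undefined: coincident consecutive points")
  }
  n1 <- v_cross(b1, b2)
  n2 <- v_cross(b2, b3)
  if (v_norm(n1) < 1e-10 || v_norm(n2) < 1e-10) {
    stop("dihedral undefined: collinear point triple")
  }
  b2u <- b2 / v_norm(b2)
  wrap360(.deg(atan2(sum(v_cross(n1, n2) * b2u), sum(n1 * n2))))
}

# Place atom D bonded to C given frame atoms A-B-C, the C-D bond length,
# the B-C-D angle and the A-B-C-D torsion (natural extension reference
# frame).  The torsion convention matches dihedral().
nerf_place <- function(a, b, c3, bond, angle, torsion) {
  th <- .rad(angle)
  ph <- .rad(torsion)
  bc <- v_unit(c3 - b)
  n <- v_cross(b - a, bc)
  if (v_norm(n) < 1e-10) stop("nerf_place: collinear frame atoms")
  n <- v_unit(n)
  m <- v_cross(n, bc)
  d_local <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c3 + d_local[1L] * bc + d_local[2L] * m + d_local[3L] * n
}

# Rodrigues rotation matrix about unit axis u (length-3) by ang degrees.
rotation_about_axis <- function(u, ang) {
  u <- v_unit(u)
  t <- .rad(ang)
  ct <- cos(t)
  st <- sin(t)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * (u %o% u)
}

# Rotate points (n x 3 matrix) about the axis through `origin` along `u`.
rotate_points <- function(xyz, origin, u, ang) {
  R <- rotation_about_axis(u, ang)
  sweep(sweep(xyz, 2L, origin) %*% t(R), 2L, origin, "+")
}
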