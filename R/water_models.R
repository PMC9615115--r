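#' Rigid water model templates
#'
#' Geometry, site charges and Lennard-Jones parameters of common rigid
#' water models.  The 4-site models place the negative charge on a
#' massless virtual site (M) displaced from the oxygen along the H-O-H
#' bisector; the oxygen itself is neutral and carries the LJ center.
#'
#' @param model "tip4pew" (default) or "tip3p".
#' @return A `water_template` list with fields `r_OH` (A), `theta_HOH`
#'   (degrees), `site_charges` (named: O, H1, H2, and M for 4-site
#'   models, elementary charges), `virtual_site_offset` (A along the
#'   bisector, 0 for 3-site models), `lj_sigma` (A), `lj_eps`
#'   (kcal/mol) and `name`.
#' @export
water_template <- function(model = c("tip4pew", "tip3p")) {
  model <- match.arg(model)
  tpl <- switch(model,
    tip4pew = list(name = "tip4pew", r_OH = 0.9572, theta_HOH = 104.52,
                   site_charges = c(O = 0, H1 = 0.52422, H2 = 0.52422,
                                    M = -1.04844),
                   virtual_site_offset = 0.125,
                   lj_sigma = 3.16435, lj_eps = 0.16275),
    tip3p   = list(name = "tip3p", r_OH = 0.9572, theta_HOH = 104.52,
                   site_charges = c(O = -0.834, H1 = 0.417, H2 = 0.417),
                   virtual_site_offset = 0,
                   lj_sigma = 3.1507, lj_eps = 0.1521)
  )
  structure(tpl, class = "water_template")
}

#' Local-frame site coordinates of a water template
#'
#' The oxygen sits at the origin, both hydrogens lie in the xz-plane at
#' z > 0, and the H-O-H bisector points along +z (toward the hydrogen
#' side).  The chemistry-convention molecular dipole therefore points
#' along -z (toward the oxygen).
#'
#' @param template a `water_template`.
#' @return matrix with rows O, H1, H2 (and M for 4-site models).
#' @export
water_local_sites <- function(template) {
  th <- template$theta_HOH * pi / 360  # half angle in radians
  r <- template$r_OH
  m <- rbind(O = c(0, 0, 0),
             H1 = c(r * sin(th), 0, r * cos(th)),
             H2 = c(-r * sin(th), 0, r * cos(th)))
  if (template$virtual_site_offset > 0)
    m <- rbind(m, M = c(0, 0, template$virtual_site_offset))
  m
}

#' Rotation matrix about an axis
#'
#' @param axis length-3 axis vector (need not be normalized).
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Uniformly random rotation matrices
#' @param n how many.
#' @return list of 3 x 3 rotation matrices.
#' @export
random_rotations <- function(n) {
  lapply(seq_len(n), function(i) {
    # random quaternion method
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3, 3)
  })
}

#' Place one water molecule
#'
#' @param center oxygen position (A, length 3).
#' @param orientation 3 x 3 rotation matrix applied to the local template
#'   frame (see [water_local_sites()]).
#' @param template a `water_template`.
#' @return matrix of site positions (rows O, H1, H2[, M]).
#' @export
make_water <- function(center, orientation = diag(3),
                       template = water_template()) {
  R <- as.matrix(orientation)
  stopifnot(dim(R) == c(3, 3))
  if (max(abs(crossprod(R) - diag(3))) > 1e-8) stop("orientation is not a rotation")
  loc <- water_local_sites(template)
  sweep(loc %*% t(R), 2, -as.numeric(center))
}
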