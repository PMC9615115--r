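#' Load spectroscopic-map coefficients
#'
#' The electric-field map is configuration, not code: a YAML file holds
#' the frequency, position and transition-dipole polynomials, the
#' intramolecular coupling model, the bond polarizability anisotropy and
#' the field summation cutoff, together with its literature source.  The
#' default file transcribes a published O-H map for 4-site water models.
#'
#' @param path path to a map YAML file; default is the shipped map.
#' @return a `map_coefficients` list.
#' @export
load_map_coefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "map_oh_tip4p_2013.yaml",
                        package = "chiralsfg")
  m <- yaml::read_yaml(path)
  stopifnot(length(m$freq_poly) >= 1, length(m$dipole_poly) >= 1,
            length(m$position_poly) >= 1, m$field_cutoff > 0)
  m$freq_poly <- as.numeric(m$freq_poly)
  m$position_poly <- as.numeric(m$position_poly)
  m$dipole_poly <- as.numeric(m$dipole_poly)
  structure(m, class = "map_coefficients")
}

polyval_asc <- function(coef, x) {
  # polynomial with coefficients in ascending powers
  y <- 0
  for (k in rev(seq_along(coef))) y <- y * x + coef[k]
  y
}

#' Electric field projection on one O-H bond
#'
#' Sums the Coulomb field of all charged sites of *other* molecules
#' within `cutoff` of the H atom (minimum image) and projects it on the
#' O->H unit vector.  Returned in atomic units.
#'
#' @param frame an `sfg_frame`.
#' @param topology an `sfg_topology` with charges.
#' @param o_idx,h_idx atom indices of the bond's O and H.
#' @param cutoff summation cutoff in Angstrom.
#' @return scalar field projection (a.u.).
#' @export
field_projection <- function(frame, topology, o_idx, h_idx, cutoff) {
  stopifnot(cutoff > 0)
  E <- field_projection_all(frame, topology,
                            data.frame(molecule_id = topology$molecule_id[h_idx],
                                       bond_id = 1L, o_idx = o_idx,
                                       h_idx = h_idx), cutoff)
  as.numeric(E)
}

#' Field projections for a table of O-H bonds (vectorized)
#'
#' @param frame an `sfg_frame`.
#' @param topology an `sfg_topology`.
#' @param bonds data frame as from [water_bonds()].
#' @param cutoff Angstrom.
#' @return numeric vector of projections (a.u.), one per bond row.
#' @export
field_projection_all <- function(frame, topology, bonds, cutoff) {
  xyz <- frame$xyz
  chg <- which(topology$charge != 0)
  q <- topology$charge[chg]
  mol <- topology$molecule_id[chg]
  sites <- xyz[chg, , drop = FALSE]
  a0 <- .const$bohr_A
  E <- numeric(nrow(bonds))
  for (i in seq_len(nrow(bonds))) {
    h <- xyz[bonds$h_idx[i], ]
    o <- xyz[bonds$o_idx[i], ]
    u <- min_image(matrix(h - o, 1), frame$box)
    u <- u / sqrt(sum(u^2))
    d <- min_image(sweep(sites, 2, h, "-"), frame$box)  # site - H
    r2 <- rowSums(d^2)
    keep <- mol != bonds$molecule_id[i] & r2 <= cutoff^2
    if (!any(keep)) next
    r2k <- r2[keep]
    if (any(r2k < 0.01))
      stop(sprintf("charged site within 0.1 A of H atom %d (frame t=%g)",
                   bonds$h_idx[i], frame$time))
    # field at H from charge q at displacement d (site - H): E = -q*d/r^3
    proj <- -(d[keep, , drop = FALSE] %*% t(u))[, 1]
    E[i] <- a0^2 * sum(q[keep] * proj / (r2k^1.5))
  }
  E
}

#' Map a field projection to an O-H stretch frequency
#'
#' @param E field projection(s), a.u.
#' @param coeffs a `map_coefficients`.
#' @param isotope_scale if TRUE, apply the harmonic reduced-mass ratio
#'   sqrt(mu(16O-H)/mu(18O-H)) for an 18-O substituted oscillator.
#' @return frequency (or frequencies), cm-1.
#' @export
map_frequency <- function(E, coeffs, isotope_scale = FALSE) {
  w <- polyval_asc(coeffs$freq_poly, E)
  if (isotope_scale) w <- w * isotope_ratio(coeffs)
  w
}

#' Harmonic 16O->18O frequency scale factor
#' @param coeffs a `map_coefficients` (carries the isotope masses).
#' @return scalar ratio sqrt(mu16/mu18) < 1.
#' @export
isotope_ratio <- function(coeffs = load_map_coefficients()) {
  m16 <- coeffs$isotope_mass_O[1]; m18 <- coeffs$isotope_mass_O[2]
  mh <- coeffs$mass_H
  mu16 <- m16 * mh / (m16 + mh)
  mu18 <- m18 * mh / (m18 + mh)
  sqrt(mu16 / mu18)
}

#' Transition dipole and polarizability of one O-H bond
#'
#' The transition dipole is mu'(E) * x10(w) along the bond; the
#' transition polarizability is an axially symmetric bond tensor
#' x10 * scale * (ratio * I + (1 - ratio) * u u^T), where `ratio` is the
#' transverse/parallel polarizability-derivative ratio.
#'
#' @param E field projection (a.u., scalar).
#' @param bond_unit unit vector along O->H (lab frame).
#' @param coeffs a `map_coefficients`.
#' @param omega optionally the precomputed frequency for this E.
#' @return list(`mu` 3-vector, `alpha` 3x3 symmetric matrix, `x10`).
#' @export
map_transition_moments <- function(E, bond_unit, coeffs, omega = NULL) {
  u <- bond_unit / sqrt(sum(bond_unit^2))
  if (is.null(omega)) omega <- map_frequency(E, coeffs)
  x10 <- polyval_asc(coeffs$position_poly, omega)
  mu <- polyval_asc(coeffs$dipole_poly, E) * x10 * u
  r <- coeffs$polarizability_ratio
  alpha <- coeffs$alpha_parallel_scale * x10 *
    (r * diag(3) + (1 - r) * tcrossprod(u))
  list(mu = mu, alpha = alpha, x10 = x10)
}

#' Chromophores of all water O-H bonds in a frame
#'
#' @param frame an `sfg_frame`.
#' @param topology an `sfg_topology`.
#' @param coeffs a `map_coefficients`.
#' @param molecules water molecule ids to map (default all).
#' @return list of per-bond chromophores: each a list with
#'   `molecule_id`, `bond_id`, `omega`, `E`, `x10`, `mu`, `alpha`,
#'   `position` (H position) and `bond_unit`.
#' @export
build_chromophores <- function(frame, topology, coeffs,
                               molecules = NULL) {
  bonds <- water_bonds(topology)
  if (!is.null(molecules)) bonds <- bonds[bonds$molecule_id %in% molecules, ]
  if (!nrow(bonds)) return(list())
  E <- field_projection_all(frame, topology, bonds, coeffs$field_cutoff)
  lapply(seq_len(nrow(bonds)), function(i) {
    u <- min_image(matrix(frame$xyz[bonds$h_idx[i], ] -
                            frame$xyz[bonds$o_idx[i], ], 1), frame$box)
    u <- as.numeric(u / sqrt(sum(u^2)))
    w <- map_frequency(E[i], coeffs)
    mm <- map_transition_moments(E[i], u, coeffs, omega = w)
    list(molecule_id = bonds$molecule_id[i], bond_id = bonds$bond_id[i],
         omega = w, E = E[i], x10 = mm$x10, mu = mm$mu, alpha = mm$alpha,
         position = frame$xyz[bonds$h_idx[i], ], bond_unit = u)
  })
}

#' Intramolecular exciton pair of one water molecule
#'
#' Diagonalizes the 2x2 Hamiltonian [[w1, w12], [w2, w12]] whose
#' off-diagonal coupling follows the map's intramolecular coupling
#' model, and combines the bond transition moments with the eigenvector
#' weights.  The trace is conserved: w+ + w- = w1 + w2.
#'
#' @param ch1,ch2 chromophores of the two O-H bonds of one molecule
#'   (from [build_chromophores()]).
#' @param coeffs a `map_coefficients`.
#' @return list with `omega` (length 2, ascending), `mu` (2 x 3),
#'   `alpha` (list of two 3x3), `coupling` (w12, cm-1).
#' @export
build_exciton_pair <- function(ch1, ch2, coeffs) {
  if (ch1$molecule_id != ch2$molecule_id)
    stop("chromophores belong to different molecules")
  cp <- coeffs$coupling
  w12 <- (cp$mixed_poly[1] + cp$mixed_poly[2] * (ch1$E + ch2$E)) *
    ch1$x10 * ch2$x10 + cp$offset
  w1 <- ch1$omega; w2 <- ch2$omega
  mean_w <- (w1 + w2) / 2
  s <- sqrt(((w1 - w2) / 2)^2 + w12^2)
  wm <- mean_w - s; wp <- mean_w + s
  if (w12 == 0) {
    v1 <- if (w1 <= w2) c(1, 0) else c(0, 1)
    v2 <- if (w1 <= w2) c(0, 1) else c(1, 0)
  } else {
    v2 <- c(w12, wp - w1); v2 <- v2 / sqrt(sum(v2^2))  # eigvec of wp
    v1 <- c(-v2[2], v2[1])                             # eigvec of wm
  }
  mu <- rbind(v1[1] * ch1$mu + v1[2] * ch2$mu,
              v2[1] * ch1$mu + v2[2] * ch2$mu)
  alpha <- list(v1[1] * ch1$alpha + v1[2] * ch2$alpha,
                v2[1] * ch1$alpha + v2[2] * ch2$alpha)
  list(omega = c(wm, wp), mu = mu, alpha = alpha, coupling = w12,
       molecule_id = ch1$molecule_id)
}
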