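#' System topology
#'
#' A topology is a data frame with one row per atom (including massless
#' virtual sites of 4-site water models) describing identity, partial
#' charge and the role the atom plays inside its molecule.  Virtual sites
#' carry charge but are excluded from geometric operations such as
#' Voronoi tessellation and hydrogen-bond detection.
#'
#' @param atom_name character atom names (PDB conventions).
#' @param residue_name character residue names.
#' @param residue_index integer residue numbers.
#' @param element character element symbols ("" allowed; inferred from
#'   the atom name when missing).
#' @param charge partial charges in elementary charge units.
#' @param molecule_id integer molecule identifiers; atoms of one
#'   molecule share one id.
#' @param is_water logical flag per atom.
#' @param water_site_role one of "O","H1","H2","virtual","n/a".
#' @return An object of class `sfg_topology` (a data frame).
#' @export
sfg_topology <- function(atom_name, residue_name, residue_index,
                         element = NULL, charge, molecule_id,
                         is_water, water_site_role) {
  n <- length(atom_name)
  if (is.null(element)) element <- gsub("[^A-Za-z].*$", "", substr(atom_name, 1, 1))
  top <- data.frame(
    atom_index = seq_len(n),
    atom_name = as.character(atom_name),
    residue_name = as.character(residue_name),
    residue_index = as.integer(residue_index),
    element = as.character(element),
    charge = as.numeric(charge),
    molecule_id = as.integer(molecule_id),
    is_water = as.logical(is_water),
    water_site_role = as.character(water_site_role),
    stringsAsFactors = FALSE
  )
  class(top) <- c("sfg_topology", "data.frame")
  validate_topology(top)
  top
}

validate_topology <- function(top) {
  stopifnot(is.data.frame(top))
  w <- top[top$is_water, ]
  if (nrow(w)) {
    roles <- split(w$water_site_role, w$molecule_id)
    ok <- vapply(roles, function(r)
      sum(r == "O") == 1L && sum(r == "H1") == 1L && sum(r == "H2") == 1L,
      logical(1))
    if (!all(ok))
      stop("water molecule(s) without exactly one O and two H sites: ",
           paste(names(roles)[!ok], collapse = ", "))
  }
  invisible(top)
}

#' @export
print.sfg_topology <- function(x, ...) {
  cat(sprintf("sfg_topology: %d atoms, %d molecules (%d water)\n",
              nrow(x), length(unique(x$molecule_id)),
              length(unique(x$molecule_id[x$is_water]))))
  invisible(x)
}

#' Molecule ids of water molecules in a topology
#' @param topology an `sfg_topology`.
#' @return sorted integer vector of water molecule ids.
#' @export
water_molecules <- function(topology) {
  sort(unique(topology$molecule_id[topology$is_water]))
}

#' O-H bond table of all water molecules
#'
#' @param topology an `sfg_topology`.
#' @return data frame with columns `molecule_id`, `bond_id` (1 or 2),
#'   `o_idx`, `h_idx` (atom indices), two rows per water.
#' @export
water_bonds <- function(topology) {
  w <- topology[topology$is_water & topology$water_site_role %in% c("O", "H1", "H2"), ]
  sp <- split(w, w$molecule_id)
  out <- lapply(sp, function(m) {
    o <- m$atom_index[m$water_site_role == "O"]
    data.frame(molecule_id = m$molecule_id[1], bond_id = 1:2, o_idx = o,
               h_idx = c(m$atom_index[m$water_site_role == "H1"],
                         m$atom_index[m$water_site_role == "H2"]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' A single simulation frame
#'
#' @param xyz numeric N x 3 matrix of positions in Angstrom.
#' @param box 3 x 3 matrix whose rows are the lattice vectors (Angstrom),
#'   or a length-3 vector for an orthorhombic box.
#' @param vacuum_axis which axis carries the vacuum gap ("x","y","z").
#' @param time frame time in ps.
#' @return An object of class `sfg_frame`.
#' @export
sfg_frame <- function(xyz, box, vacuum_axis = "z", time = 0) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, all(is.finite(xyz)))
  if (is.vector(box) && length(box) == 3) box <- diag(as.numeric(box))
  box <- as.matrix(box)
  stopifnot(dim(box) == c(3, 3))
  if (abs(det(box)) < 1e-9) stop("box vectors do not span a nonzero volume")
  vacuum_axis <- match.arg(vacuum_axis, c("x", "y", "z"))
  structure(list(xyz = xyz, box = box, vacuum_axis = vacuum_axis,
                 time = as.numeric(time)),
            class = "sfg_frame")
}

#' @export
print.sfg_frame <- function(x, ...) {
  cat(sprintf("sfg_frame: %d atoms, t = %g ps, box diag (%.2f, %.2f, %.2f) A\n",
              nrow(x$xyz), x$time, x$box[1, 1], x$box[2, 2], x$box[3, 3]))
  invisible(x)
}

box_is_orthorhombic <- function(box) {
  all(abs(box[upper.tri(box) | lower.tri(box)]) < 1e-10)
}

#' Minimum-image displacement vectors
#'
#' Shortest periodic displacement(s) from point(s) `a` to point(s) `b`.
#' For orthorhombic boxes the component-wise wrap is exact; for triclinic
#' boxes a search over the 27 nearest lattice images is performed.
#'
#' @param d raw displacement matrix (n x 3) `b - a`, Angstrom.
#' @param box 3 x 3 lattice-vector matrix (rows are vectors).
#' @return matrix of minimum-image displacements, same shape as `d`.
#' @export
min_image <- function(d, box) {
  d <- matrix(d, ncol = 3)
  if (box_is_orthorhombic(box)) {
    L <- diag(box)
    for (k in 1:3) d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
    return(d)
  }
  # triclinic: fractional wrap then scan neighbor images
  s <- d %*% solve(box)
  s <- s - round(s)
  d0 <- s %*% box
  best <- d0
  bn <- rowSums(best^2)
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    if (i == 0 && j == 0 && k == 0) next
    shift <- c(i, j, k) %*% box
    cand <- sweep(d0, 2, -as.numeric(shift))
    cn <- rowSums(cand^2)
    imp <- cn < bn
    best[imp, ] <- cand[imp, ]
    bn[imp] <- cn[imp]
  }
  best
}

#' Minimum-image vector between two atoms of a frame
#'
#' @param frame an `sfg_frame`.
#' @param a,b atom indices; the displacement points from `a` to `b`.
#' @return length-3 numeric vector (Angstrom).
#' @export
minimum_image_vector <- function(frame, a, b) {
  stopifnot(inherits(frame, "sfg_frame"))
  as.numeric(min_image(frame$xyz[b, , drop = FALSE] - frame$xyz[a, , drop = FALSE],
                       frame$box))
}

#' Minimum-image distances from one point to many points
#' @noRd
min_image_dist <- function(p, pts, box) {
  d <- min_image(sweep(pts, 2, p), box)
  sqrt(rowSums(d^2))
}

axis_index <- function(axis) match(axis, c("x", "y", "z"))
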