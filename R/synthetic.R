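#' Topology for a box of identical waters
#'
#' @param n number of water molecules.
#' @param template a `water_template`.
#' @param first_molecule_id id of the first water (ids increment).
#' @return an `sfg_topology`.
#' @export
water_topology <- function(n, template = water_template(),
                           first_molecule_id = 1L) {
  four <- template$virtual_site_offset > 0
  roles <- if (four) c("O", "H1", "H2", "virtual") else c("O", "H1", "H2")
  names_ <- if (four) c("O", "H1", "H2", "M") else c("O", "H1", "H2")
  elem <- if (four) c("O", "H", "H", "") else c("O", "H", "H")
  q <- template$site_charges[if (four) c("O", "H1", "H2", "M") else c("O", "H1", "H2")]
  k <- length(roles)
  resn <- if (four) "TIP4" else "HOH"
  sfg_topology(
    atom_name = rep(names_, n),
    residue_name = rep(resn, n * k),
    residue_index = rep(seq_len(n), each = k),
    element = rep(elem, n),
    charge = rep(as.numeric(q), n),
    molecule_id = rep(first_molecule_id - 1L + seq_len(n), each = k),
    is_water = TRUE,
    water_site_role = rep(roles, n)
  )
}

#' Frame from per-water centers and orientations
#' @noRd
waters_frame <- function(centers, rotations, template, box,
                         vacuum_axis = "z", time = 0) {
  xyz <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    make_water(centers[i, ], rotations[[i]], template)))
  sfg_frame(xyz, box, vacuum_axis = vacuum_axis, time = time)
}

#' Reflect a frame through a vertical mirror plane
#'
#' Reflection through the plane perpendicular to the interface:
#' `"yz"` negates x, `"xz"` negates y.  Pure sign flips are exact in
#' floating point, so applying the operation twice restores the frame
#' bit for bit.  The reflected coordinates live in the adjacent periodic
#' cell; all geometric operations are minimum-image aware, so this is
#' immaterial.  Charges and topology are unchanged; the handedness of
#' any chiral arrangement is inverted.
#'
#' @param frame an `sfg_frame` with vacuum along z.
#' @param plane "yz" (default) or "xz".
#' @return the reflected `sfg_frame`.
#' @export
build_mirror_pair <- function(frame, plane = c("yz", "xz")) {
  plane <- match.arg(plane)
  ax <- if (plane == "yz") 1L else 2L
  if (frame$vacuum_axis != "z")
    stop("mirror plane must contain the vacuum axis; only vacuum_axis='z' supported")
  xyz <- frame$xyz
  xyz[, ax] <- -xyz[, ax]
  sfg_frame(xyz, frame$box, vacuum_axis = frame$vacuum_axis, time = frame$time)
}

#' Chiral helical arrangement of water molecules
#'
#' Places `n` waters on one turn of a helix about the z axis.  Each
#' water's H-O-H bisector is tilted by `dipole_tilt` degrees away from
#' +z toward the local helix tangent, which breaks every vertical mirror
#' plane when `dipole_tilt != 0` or `pitch != 0`.  With `dipole_tilt = 0`
#' and `pitch = 0` the arrangement has explicit vertical mirror planes
#' (achiral control).  Handedness -1 is constructed as the exact
#' yz-plane reflection of handedness +1.
#'
#' @param n number of waters (>= 1).
#' @param radius helix radius (A).
#' @param pitch z rise over the full turn (A).
#' @param handedness +1 or -1.
#' @param dipole_tilt tilt of the bisector toward the tangent (degrees).
#' @param template a `water_template`.
#' @param box box edge lengths (length 3; default fits the helix with
#'   a generous vacuum gap above).
#' @return list with elements `topology` and `frames` (one frame).
#' @export
build_chiral_water_helix <- function(n = 12, radius = 5, pitch = 2,
                                     handedness = 1, dipole_tilt = 30,
                                     template = water_template(),
                                     box = NULL) {
  stopifnot(n >= 1, handedness %in% c(-1, 1))
  if (is.null(box)) {
    L <- 4 * radius + 10
    box <- c(L, L, 2 * (pitch + 10))
  }
  phi <- 2 * pi * (seq_len(n) - 1) / n
  cx <- box[1] / 2; cy <- box[2] / 2; z0 <- 5
  centers <- cbind(cx + radius * cos(phi), cy + radius * sin(phi),
                   z0 + pitch * (seq_len(n) - 1) / n)
  tilt <- dipole_tilt * pi / 180
  rots <- lapply(seq_len(n), function(k) {
    # local helix tangent (mixes azimuthal and vertical directions)
    t3 <- c(-radius * sin(phi[k]), radius * cos(phi[k]), pitch / (2 * pi))
    t3 <- t3 / sqrt(sum(t3^2))
    b <- cos(tilt) * c(0, 0, 1) + sin(tilt) * t3
    b <- b / sqrt(sum(b^2))
    u <- t3 - sum(t3 * b) * b
    if (sqrt(sum(u^2)) < 1e-8) u <- c(cos(phi[k]), sin(phi[k]), 0)
    u <- u / sqrt(sum(u^2))
    cbind(u, pracma::cross(b, u), b)  # columns: local x, y, z images
  })
  fr <- waters_frame(centers, rots, template, box)
  if (handedness < 0) fr <- build_mirror_pair(fr, "yz")
  list(topology = water_topology(n, template), frames = list(fr))
}

#' Rejection-sampled water positions in a slab
#' @noRd
sample_slab_centers <- function(n, box, z_range, min_oo = 2.4,
                                max_tries = 20000L) {
  centers <- matrix(NA_real_, n, 3)
  got <- 0L
  tries <- 0L
  boxm <- diag(box)
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " waters with min O-O ", min_oo,
           " A in the slab; enlarge the box")
    p <- c(runif(1, 0, box[1]), runif(1, 0, box[2]),
           runif(1, z_range[1], z_range[2]))
    if (got > 0L) {
      dmin <- min(min_image_dist(p, centers[seq_len(got), , drop = FALSE], boxm))
      if (dmin < min_oo) next
    }
    got <- got + 1L
    centers[got, ] <- p
  }
  centers
}

#' Water slab fixture with a vacuum gap
#'
#' Builds `n_waters` rigid waters confined to a slab occupying the lower
#' part of the box along the vacuum axis (z), leaving vacuum above.  The
#' slab thickness is set by liquid density (29.9 A^3 per water).
#' Placement uses rejection sampling with a 2.4 A minimum O-O distance
#' and uniformly random orientations; the result is bit-reproducible for
#' a given seed.  With `thermalize = TRUE` the configuration is relaxed
#' and sampled at 298 K by the built-in rigid-body Metropolis Monte
#' Carlo sampler (see [thermalize_slab()]), returning `n_frames` frames.
#'
#' @param n_waters number of waters.
#' @param box box edge lengths (A, length 3); the vacuum gap is whatever
#'   the slab does not fill along z.
#' @param thermalize logical; run the MC sampler.
#' @param seed integer seed (drives placement and, if used, MC).
#' @param template a `water_template`.
#' @param n_frames,equil_sweeps,sample_every thermalization controls
#'   passed to [thermalize_slab()].
#' @param temperature_K MC temperature (K).
#' @return list(`topology`, `frames`).
#' @export
build_slab_fixture <- function(n_waters, box = c(20, 20, 60),
                               thermalize = FALSE, seed = 1,
                               template = water_template(),
                               n_frames = 60, equil_sweeps = 4000,
                               sample_every = 50, temperature_K = 298, ...) {
  stopifnot(n_waters >= 1)
  thick <- min(n_waters * 29.9 / (box[1] * box[2]), 0.95 * box[3])
  set.seed(seed)
  centers <- sample_slab_centers(n_waters, box, c(0, thick))
  rots <- random_rotations(n_waters)
  fr <- waters_frame(centers, rots, template, box)
  top <- water_topology(n_waters, template)
  if (!thermalize) return(list(topology = top, frames = list(fr)))
  if (is.null(template$lj_eps))
    stop("thermalization requires a water template with LJ parameters; ",
         "use thermalize = FALSE or a full template")
  frames <- thermalize_slab(centers, rots, template, box, seed = seed,
                            n_frames = n_frames, equil_sweeps = equil_sweeps,
                            sample_every = sample_every,
                            temperature_K = temperature_K, ...)
  list(topology = top, frames = frames)
}

#' Idealized charged strand template
#'
#' A planar stand-in for an extended beta-strand presenting, per repeat
#' unit, a backbone carbonyl (C, O), an amide (N, H) and an ammonium-like
#' charged group (NZ with three HZ), with point charges typical of amide
#' and lysine-ammonium sites.  Carbonyl O, amide H and the ammonium
#' point down (toward the water phase).  This is a synthetic template,
#' not a protein model.
#'
#' @param n_repeats number of repeat units along x.
#' @param spacing repeat spacing (A).
#' @param charge_scale multiply all site charges (0 gives a neutral
#'   geometry-only strand).
#' @return a `template_strand` list with `sites` (data frame: name,
#'   class, x, y, z offsets, charge) and `net_charge`.
#' @export
make_template_strand <- function(n_repeats = 3, spacing = 6.8,
                                 charge_scale = 1) {
  unit <- data.frame(
    name  = c("C", "O", "N", "H", "NZ", "HZ1", "HZ2", "HZ3"),
    class = c("backbone", "backbone", "backbone", "backbone",
              "sidechain", "sidechain", "sidechain", "sidechain"),
    # offsets within a repeat unit (A); z < 0 is toward the water
    x = c(0.0, 0.0, 2.4, 2.4, 4.4, 4.4, 3.6, 5.2),
    y = c(0.0, 0.0, 0.0, 0.0, 2.8, 2.8, 3.3, 3.3),
    z = c(0.0, -1.23, 0.0, -1.01, -1.2, -2.2, -0.8, -0.8),
    # idealized amide / ammonium point charges; each repeat nets exactly +1 e
    charge = c(0.60, -0.60, -0.40, 0.40, -0.30, 1.3 / 3, 1.3 / 3, 1.3 / 3),
    stringsAsFactors = FALSE
  )
  sites <- do.call(rbind, lapply(seq_len(n_repeats), function(k) {
    u <- unit
    u$x <- u$x + (k - 1) * spacing
    u
  }))
  sites$charge <- sites$charge * charge_scale
  structure(list(sites = sites, net_charge = sum(sites$charge)),
            class = "template_strand")
}

#' Strand mimic embedded at the upper interface of a water slab
#'
#' The strand lies in a horizontal plane just below the upper water
#' surface with its interaction sites pointing into the water; waters
#' fill the slab beneath it.  If the strand carries net charge,
#' neutralizing chloride ions are placed near the slab bottom.
#'
#' @param strand a `template_strand`.
#' @param n_waters number of waters.
#' @param seed integer seed.
#' @param box box edge lengths (A).
#' @param template a `water_template`.
#' @param strand_depth depth of the strand plane below the top of the
#'   slab (A).
#' @return list(`topology`, `frames`) (single frame).
#' @export
build_template_system <- function(strand, n_waters, seed = 1,
                                  box = c(26, 26, 60),
                                  template = water_template(),
                                  strand_depth = 1.0) {
  stopifnot(inherits(strand, "template_strand"))
  set.seed(seed)
  thick <- min(n_waters * 29.9 / (box[1] * box[2]) + 4, 0.6 * box[3])
  ztop <- thick
  s <- strand$sites
  # center the strand in x,y; plane sits strand_depth below the surface
  sx <- s$x - mean(range(s$x)) + box[1] / 2
  sy <- s$y - mean(range(s$y)) + box[2] / 2
  sz <- s$z + ztop - strand_depth
  n_ion <- round(abs(strand$net_charge))
  ion_q <- if (strand$net_charge > 0) -1 else 1
  # waters below the strand plane
  centers <- sample_slab_centers(n_waters, box, c(0, ztop - strand_depth - 2.6))
  rots <- random_rotations(n_waters)
  wfr <- waters_frame(centers, rots, template, box)
  ion_xyz <- if (n_ion > 0)
    cbind(runif(n_ion, 2, box[1] - 2), runif(n_ion, 2, box[2] - 2),
          runif(n_ion, 1, 3)) else NULL
  wtop <- water_topology(n_waters, template)
  strand_top <- sfg_topology(
    atom_name = s$name, residue_name = "STR",
    residue_index = rep(seq_len(nrow(s) / 8), each = 8),
    element = substr(s$name, 1, 1),
    charge = s$charge,
    molecule_id = max(wtop$molecule_id) + 1L,
    is_water = FALSE, water_site_role = "n/a")
  tops <- list(wtop, strand_top)
  xyzs <- list(wfr$xyz, cbind(sx, sy, sz))
  if (n_ion > 0) {
    ion_top <- sfg_topology(
      atom_name = rep(if (ion_q < 0) "CL" else "NA", n_ion),
      residue_name = if (ion_q < 0) "CL" else "NA",
      residue_index = seq_len(n_ion),
      element = rep(if (ion_q < 0) "Cl" else "Na", n_ion),
      charge = rep(ion_q, n_ion),
      molecule_id = max(strand_top$molecule_id) + seq_len(n_ion),
      is_water = FALSE, water_site_role = "n/a")
    tops <- c(tops, list(ion_top))
    xyzs <- c(xyzs, list(ion_xyz))
  }
  top <- merge_topologies(tops)
  fr <- sfg_frame(do.call(rbind, xyzs), box, vacuum_axis = "z")
  list(topology = top, frames = list(fr))
}

#' Concatenate topologies, renumbering atoms and keeping molecule ids
#' @param tops list of `sfg_topology` objects (molecule ids must not clash).
#' @return a single `sfg_topology`.
#' @export
merge_topologies <- function(tops) {
  df <- do.call(rbind, lapply(tops, as.data.frame))
  if (anyDuplicated(unlist(lapply(tops, function(t) unique(t$molecule_id)))))
    stop("molecule ids clash across topologies")
  sfg_topology(df$atom_name, df$residue_name, df$residue_index, df$element,
               df$charge, df$molecule_id, df$is_water, df$water_site_role)
}

#' Combine two systems sharing one box into a single system
#'
#' Used e.g. to place a structure and its mirror image in one frame.
#' Molecule ids of the second system are shifted past those of the first.
#'
#' @param sys1,sys2 lists with `topology` and `frames` (equal frame
#'   counts and boxes).
#' @return list(`topology`, `frames`).
#' @export
merge_systems <- function(sys1, sys2) {
  t2 <- sys2$topology
  shift <- max(sys1$topology$molecule_id)
  t2$molecule_id <- t2$molecule_id + shift
  top <- merge_topologies(list(sys1$topology, t2))
  stopifnot(length(sys1$frames) == length(sys2$frames))
  frames <- Map(function(f1, f2)
    sfg_frame(rbind(f1$xyz, f2$xyz), f1$box, f1$vacuum_axis, f1$time),
    sys1$frames, sys2$frames)
  list(topology = top, frames = frames)
}
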