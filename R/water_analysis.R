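#' Point-charge dipole of a water molecule
#'
#' Classical dipole of the molecule's charged sites, sign-flipped to the
#' chemistry convention: the vector bisects the H-O-H angle and points
#' toward the oxygen (away from the hydrogens).  Units: Debye.
#'
#' @param frame an `sfg_frame`.
#' @param topology an `sfg_topology`.
#' @param molecule_id a water molecule id (vectorized).
#' @return matrix (length(molecule_id) x 3) of dipole vectors (D).
#' @export
water_dipole <- function(frame, topology, molecule_id) {
  out <- matrix(NA_real_, length(molecule_id), 3)
  for (i in seq_along(molecule_id)) {
    rows <- which(topology$molecule_id == molecule_id[i] & topology$is_water)
    if (!length(rows)) stop("not a water molecule: ", molecule_id[i])
    o <- rows[topology$water_site_role[rows] == "O"]
    rel <- min_image(frame$xyz[rows, , drop = FALSE] -
                       matrix(frame$xyz[o, ], length(rows), 3, byrow = TRUE),
                     frame$box)
    p <- colSums(rel * topology$charge[rows])  # physics convention (- to +)
    out[i, ] <- -p * .const$debye_eA           # toward the oxygen
  }
  out
}

#' Mean hydrogen bonds per water of a subset
#'
#' Average over frames and subset members of the number of H-bonds each
#' water donates plus accepts (to water or solute).
#'
#' @param frames list of `sfg_frame`s.
#' @param topology an `sfg_topology`.
#' @param subset an `sfg_subset` (members recycled if length 1).
#' @param criteria an [hbond_criteria()].
#' @param hbonds_per_frame optional precomputed list of
#'   [detect_hbonds()] results, one per frame.
#' @return mean H-bond count per water.
#' @export
mean_hbonds_per_water <- function(frames, topology, subset,
                                  criteria = hbond_criteria(),
                                  hbonds_per_frame = NULL) {
  members <- subset$members
  if (length(members) == 1L) members <- rep(members, length(frames))
  total <- 0; count <- 0
  for (f in seq_along(frames)) {
    m <- members[[f]]
    if (!length(m)) next
    hb <- if (is.null(hbonds_per_frame)) detect_hbonds(frames[[f]], topology, criteria)
          else hbonds_per_frame[[f]]
    donated <- table(factor(hb$donor_mol[hb$donor_mol %in% m], levels = m))
    accepted <- table(factor(hb$acceptor_mol[hb$acceptor_mol %in% m], levels = m))
    total <- total + sum(donated) + sum(accepted)
    count <- count + length(m)
  }
  if (count == 0) stop("subset '", subset$name, "' is empty in all frames")
  total / count
}

#' Retention times of a subset membership series
#'
#' Episodes are maximal runs of consecutive frames during which a
#' molecule belongs to the subset; the retention time is the mean
#' episode duration over all episodes of all molecules.  Episodes
#' truncated by the trajectory edges are included in the mean and
#' counted as censored.
#'
#' @param membership an `sfg_subset` sampled at uniform time spacing.
#' @param time_step frame spacing in ps (resolution of the estimate).
#' @return a `retention_record`: list with `subset`, `durations` (ps),
#'   `mean_retention` (ps), `n_episodes`, `n_censored`.
#' @export
retention_times <- function(membership, time_step = 1) {
  mem <- membership$members
  nf <- length(mem)
  mols <- sort(unique(unlist(mem)))
  if (!length(mols)) stop("empty membership: no episodes")
  durations <- numeric(0)
  censored <- 0L
  for (m in mols) {
    inset <- vapply(mem, function(s) m %in% s, logical(1))
    r <- rle(inset)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    for (k in runs) {
      durations <- c(durations, r$lengths[k] * time_step)
      if (starts[k] == 1L || ends[k] == nf) censored <- censored + 1L
    }
  }
  structure(list(subset = membership$name, durations = durations,
                 mean_retention = mean(durations),
                 n_episodes = length(durations), n_censored = censored),
            class = "retention_record")
}

#' Join per-water signal with retention time across subsets
#'
#' @param subsets character vector of subset names.
#' @param spectra named list of per-water `sfg_spectrum`s.
#' @param retention named list of `retention_record`s.
#' @param band length-2 integration band (cm-1) for the absolute area.
#' @return data frame (subset, per_water_area, mean_retention_ps) with
#'   attribute `rank_correlation` (Spearman over the rows).
#' @export
signal_vs_retention <- function(subsets, spectra, retention,
                                band = c(2800, 4000)) {
  if (!all(subsets %in% names(spectra)) || !all(subsets %in% names(retention)))
    stop("subset names missing from spectra or retention inputs")
  area <- vapply(subsets, function(s)
    band_area(spectra[[s]], band[1], band[2], "absolute"), numeric(1))
  ret <- vapply(subsets, function(s) retention[[s]]$mean_retention, numeric(1))
  out <- data.frame(subset = subsets, per_water_area = area,
                    mean_retention_ps = ret, row.names = NULL)
  attr(out, "rank_correlation") <-
    if (nrow(out) >= 3) cor(area, ret, method = "spearman") else NA_real_
  out
}

#' Interface height of a frame
#'
#' Mean vacuum-axis coordinate of the top decile of water oxygens: a
#' robust density-based proxy for the water surface.
#'
#' @param frame an `sfg_frame`.
#' @param topology an `sfg_topology`.
#' @return scalar coordinate (A) along the vacuum axis.
#' @export
interface_height <- function(frame, topology) {
  ax <- axis_index(frame$vacuum_axis)
  oz <- frame$xyz[topology$is_water & topology$water_site_role == "O", ax]
  mean(sort(oz, decreasing = TRUE)[seq_len(max(1, ceiling(length(oz) / 10)))])
}

#' Accumulate water dipoles on an interfacial-plane grid
#'
#' Each water's dipole vector is added to the grid cell containing its
#' oxygen's in-plane coordinates, restricted to oxygens within
#' `depth_range` below the interface, summed over frames.
#'
#' @param frames list of `sfg_frame`s.
#' @param topology an `sfg_topology`.
#' @param resolution cell edge (A), default 1.
#' @param depth_range depths below the interface to include (A,
#'   length 2).
#' @return a `dipole_grid`: list with `vec` (nx x ny x 3 array of dipole
#'   vector sums, D), `occupancy` (nx x ny counts), `resolution`,
#'   `origin`, `axes`, `depth_range`, `n_frames`.
#' @export
dipole_grid <- function(frames, topology, resolution = 1,
                        depth_range = c(0, 14)) {
  stopifnot(resolution > 0)
  ax <- axis_index(frames[[1]]$vacuum_axis)
  plane <- setdiff(1:3, ax)
  L <- diag(frames[[1]]$box)[plane]
  nx <- ceiling(L[1] / resolution); ny <- ceiling(L[2] / resolution)
  vec <- array(0, c(nx, ny, 3))
  occ <- matrix(0L, nx, ny)
  wmol <- water_molecules(topology)
  orow <- vapply(wmol, function(m)
    which(topology$molecule_id == m & topology$water_site_role == "O"),
    integer(1))
  for (fr in frames) {
    zs <- interface_height(fr, topology)
    depth <- zs - fr$xyz[orow, ax]
    keep <- depth >= depth_range[1] & depth <= depth_range[2]
    if (!any(keep)) next
    mu <- water_dipole(fr, topology, wmol[keep])
    xy <- fr$xyz[orow[keep], plane, drop = FALSE]
    xy <- xy - floor(xy / matrix(L, nrow(xy), 2, byrow = TRUE)) *
      matrix(L, nrow(xy), 2, byrow = TRUE)  # wrap into the box
    ix <- pmin(nx, floor(xy[, 1] / resolution) + 1L)
    iy <- pmin(ny, floor(xy[, 2] / resolution) + 1L)
    for (k in seq_along(ix)) {
      vec[ix[k], iy[k], ] <- vec[ix[k], iy[k], ] + mu[k, ]
      occ[ix[k], iy[k]] <- occ[ix[k], iy[k]] + 1L
    }
  }
  structure(list(vec = vec, occupancy = occ, resolution = resolution,
                 origin = c(0, 0), axes = c("x", "y", "z")[plane],
                 depth_range = depth_range, n_frames = length(frames)),
            class = "dipole_grid")
}

grid_cell_centers <- function(grid) {
  nx <- dim(grid$vec)[1]; ny <- dim(grid$vec)[2]
  list(x = grid$origin[1] + (seq_len(nx) - 0.5) * grid$resolution,
       y = grid$origin[2] + (seq_len(ny) - 0.5) * grid$resolution)
}

#' Annulus profile of a dipole grid
#'
#' Magnitude of the vector sum of cell dipole vectors whose centers fall
#' in concentric rings about `center`, reported both for the in-plane
#' components and for the full 3-vector sum.
#'
#' @param grid a `dipole_grid`.
#' @param center in-plane center (length 2, A).
#' @param ring_width ring width (A), default 1.
#' @return data frame: `r_lo`, `r_hi`, `n_cells`, `mag_inplane`,
#'   `mag_3d`.
#' @export
annulus_dipole_profile <- function(grid, center, ring_width = 1) {
  stopifnot(ring_width > 0)
  cc <- grid_cell_centers(grid)
  if (center[1] < 0 || center[1] > max(cc$x) + grid$resolution / 2 ||
      center[2] < 0 || center[2] > max(cc$y) + grid$resolution / 2)
    stop("center lies outside the grid")
  dx <- outer(cc$x - center[1], rep(1, length(cc$y)))
  dy <- outer(rep(1, length(cc$x)), cc$y - center[2])
  r <- sqrt(dx^2 + dy^2)
  ring <- floor(r / ring_width)
  rings <- sort(unique(as.integer(ring)))
  out <- lapply(rings, function(k) {
    sel <- which(ring == k, arr.ind = TRUE)
    v <- c(0, 0, 0)
    for (r in seq_len(nrow(sel)))
      v <- v + grid$vec[sel[r, 1], sel[r, 2], ]
    data.frame(r_lo = k * ring_width, r_hi = (k + 1) * ring_width,
               n_cells = nrow(sel),
               mag_inplane = sqrt(sum(v[1:2]^2)), mag_3d = sqrt(sum(v^2)))
  })
  do.call(rbind, out)
}

#' Mirror-asymmetry score of a dipole grid
#'
#' Root-mean-square difference between the dipole field and its mirror
#' image across a vertical plane (in-plane component perpendicular to
#' the plane negated), over cells occupied on both sides.  Zero for a
#' mirror-symmetric field.
#'
#' @param grid a `dipole_grid`.
#' @param plane "xz" (mirror across y) or "yz" (mirror across x).
#' @param plane_coord coordinate of the plane along the mirrored axis
#'   (A); must align with a cell boundary or center.
#' @return scalar score (D).
#' @export
mirror_asymmetry_score <- function(grid, plane = c("yz", "xz"),
                                   plane_coord) {
  plane <- match.arg(plane)
  ax <- if (plane == "yz") 1L else 2L  # mirrored in-plane axis
  cc <- grid_cell_centers(grid)
  n <- dim(grid$vec)[ax]
  centers <- if (ax == 1L) cc$x else cc$y
  # mirror cell index: center maps to 2*plane_coord - center
  mi <- round((2 * plane_coord - grid$origin[ax]) / grid$resolution + 1 -
                seq_len(n))
  if (max(abs((2 * plane_coord - centers) -
              (grid$origin[ax] + (mi - 0.5) * grid$resolution))) > 1e-6)
    stop("plane_coord does not align with the grid")
  acc <- 0; m <- 0L
  nx <- dim(grid$vec)[1]; ny <- dim(grid$vec)[2]
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    ij_m <- if (ax == 1L) c(mi[i], j) else c(i, mi[j])
    if (ij_m[1] < 1 || ij_m[1] > nx || ij_m[2] < 1 || ij_m[2] > ny) next
    if (grid$occupancy[i, j] == 0 || grid$occupancy[ij_m[1], ij_m[2]] == 0) next
    v <- grid$vec[i, j, ]
    w <- grid$vec[ij_m[1], ij_m[2], ]
    w[ax] <- -w[ax]  # mirrored field flips the perpendicular component
    acc <- acc + sum((v - w)^2)
    m <- m + 1L
  }
  if (m == 0L) stop("no occupied mirror-paired cells")
  sqrt(acc / (3 * m))
}

#' Fraction of subset waters with a dangling O-H
#'
#' A water counts when at least one of its O-H bonds points within
#' `angle_max` of the vacuum-side normal and that H donates no hydrogen
#' bond.  Pooled over frames.
#'
#' @param frames list of `sfg_frame`s.
#' @param topology an `sfg_topology`.
#' @param subset an `sfg_subset` (members recycled if length 1).
#' @param angle_max maximum angle to the vacuum normal (degrees).
#' @param criteria an [hbond_criteria()].
#' @return fraction in [0, 1].
#' @export
dangling_oh_fraction <- function(frames, topology, subset, angle_max = 60,
                                 criteria = hbond_criteria()) {
  members <- subset$members
  if (length(members) == 1L) members <- rep(members, length(frames))
  bonds <- water_bonds(topology)
  hit <- 0; tot <- 0
  for (f in seq_along(frames)) {
    m <- members[[f]]
    if (!length(m)) next
    fr <- frames[[f]]
    ax <- axis_index(fr$vacuum_axis)
    hb <- detect_hbonds(fr, topology, criteria)
    donating_h <- unique(hb$h)
    for (w in m) {
      b <- bonds[bonds$molecule_id == w, ]
      dangle <- FALSE
      for (r in seq_len(nrow(b))) {
        if (b$h_idx[r] %in% donating_h) next
        v <- minimum_image_vector(fr, b$o_idx[r], b$h_idx[r])
        cosang <- v[ax] / sqrt(sum(v^2))  # vacuum at +axis
        if (cosang > cos(angle_max * pi / 180)) { dangle <- TRUE; break }
      }
      hit <- hit + dangle
      tot <- tot + 1
    }
  }
  if (tot == 0) stop("subset empty in all frames")
  hit / tot
}
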