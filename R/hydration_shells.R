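#' Voronoi face-sharing neighbors under periodic boundaries
#'
#' Tessellates the atomic centers of all real atoms (virtual sites are
#' excluded) and returns the pairs whose Voronoi cells share a face.
#' Periodic images are taken into account, so the relation is defined on
#' the torus.
#'
#' @param frame an `sfg_frame`.
#' @param topology an `sfg_topology`.
#' @param jitter if > 0, add deterministic uniform jitter of this
#'   amplitude (A) to break exact degeneracies (logged via `message`).
#' @param jitter_seed seed for the jitter.
#' @return an `sfg_neighbors` object: list with `pairs` (2-column matrix
#'   of atom indices, i < j) and `adjacency` (list of neighbor index
#'   vectors per atom; empty for virtual sites).
#' @export
voronoi_neighbors <- function(frame, topology, jitter = 0, jitter_seed = 42) {
  real <- which(topology$water_site_role != "virtual")
  pos <- frame$xyz[real, , drop = FALSE]
  if (jitter > 0) {
    message("applying ", jitter, " A jitter to break tessellation degeneracies")
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(jitter_seed)
    pos <- pos + matrix(runif(length(pos), -jitter, jitter), ncol = 3)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  pr <- voronoi_pairs_cpp(pos, frame$box)
  pairs <- cbind(real[pr[, 1]], real[pr[, 2]])
  adj <- vector("list", nrow(topology))
  for (k in seq_len(nrow(topology))) adj[[k]] <- integer(0)
  if (nrow(pairs)) {
    sp1 <- split(pairs[, 2], pairs[, 1])
    sp2 <- split(pairs[, 1], pairs[, 2])
    for (nm in names(sp1)) adj[[as.integer(nm)]] <- c(adj[[as.integer(nm)]], sp1[[nm]])
    for (nm in names(sp2)) adj[[as.integer(nm)]] <- c(adj[[as.integer(nm)]], sp2[[nm]])
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  structure(list(pairs = pairs, adjacency = adj), class = "sfg_neighbors")
}

.solute_atoms <- function(topology, ion_residues = c("CL", "NA", "K", "BR", "I")) {
  which(!topology$is_water & !(toupper(topology$residue_name) %in% ion_residues))
}

#' First and second hydration shells from a neighbor map
#'
#' First shell: waters with at least one atom whose Voronoi cell touches
#' a solute atom's cell.  Second shell: waters touching a first-shell
#' water, excluding the first shell.  Ions are not solute.
#'
#' @param neighbors an `sfg_neighbors`.
#' @param topology an `sfg_topology`.
#' @return list(`first_shell`, `second_shell`) of water molecule ids.
#' @export
assign_shells <- function(neighbors, topology) {
  solute <- .solute_atoms(topology)
  if (!length(solute)) stop("no solute present: shells are undefined")
  sol_nb <- unique(unlist(neighbors$adjacency[solute]))
  first <- sort(unique(topology$molecule_id[sol_nb[topology$is_water[sol_nb]]]))
  first_atoms <- which(topology$molecule_id %in% first & topology$is_water &
                         topology$water_site_role != "virtual")
  f_nb <- unique(unlist(neighbors$adjacency[first_atoms]))
  second <- sort(setdiff(
    unique(topology$molecule_id[f_nb[topology$is_water[f_nb]]]), first))
  list(first_shell = first, second_shell = second)
}

#' Classify solute atoms as backbone or side chain
#'
#' @param topology an `sfg_topology`.
#' @param backbone_names atom names counted as backbone.
#' @return character vector over atoms: "backbone", "sidechain" or NA
#'   for non-solute atoms.  Errors if a solute atom matches neither
#'   class (the backbone list plus the complement must cover them).
#' @export
classify_solute_atoms <- function(topology,
                                  backbone_names = c("C", "O", "N", "H", "HN",
                                                     "CA", "HA", "OXT")) {
  out <- rep(NA_character_, nrow(topology))
  sol <- .solute_atoms(topology)
  nm <- toupper(topology$atom_name[sol])
  out[sol] <- ifelse(nm %in% toupper(backbone_names), "backbone", "sidechain")
  out
}

#' Split the first shell into backbone and side-chain regions
#'
#' A water belongs to the backbone region if any of its atoms touches a
#' backbone-class solute atom, and to the side-chain region likewise;
#' the two regions deliberately overlap (a water touching both classes
#' is in both), so together they cover the first shell.
#'
#' @param first_shell water molecule ids of the first shell.
#' @param neighbors an `sfg_neighbors`.
#' @param topology an `sfg_topology`.
#' @param solute_class optional per-atom class from
#'   [classify_solute_atoms()].
#' @return list(`backbone_region`, `sidechain_region`).
#' @export
split_backbone_sidechain <- function(first_shell, neighbors, topology,
                                     solute_class = NULL) {
  if (is.null(solute_class)) solute_class <- classify_solute_atoms(topology)
  sol <- .solute_atoms(topology)
  if (anyNA(solute_class[sol]))
    stop("unlabeled solute atoms: ",
         paste(topology$atom_name[sol[is.na(solute_class[sol])]], collapse = ", "))
  touch_region <- function(cls) {
    atoms <- which(!is.na(solute_class) & solute_class == cls)
    nb <- unique(unlist(neighbors$adjacency[atoms]))
    mols <- unique(topology$molecule_id[nb[topology$is_water[nb]]])
    sort(intersect(mols, first_shell))
  }
  list(backbone_region = touch_region("backbone"),
       sidechain_region = touch_region("sidechain"))
}

#' Hydrogen-bond geometric criteria
#'
#' @param heavy_distance_max maximum donor-heavy to acceptor-heavy
#'   distance (A, exclusive).
#' @param angle_min minimum donor-heavy--H...acceptor angle at the H
#'   (degrees; 180 = linear).
#' @param strong_H_to_O_max H-to-acceptor distance at or below which a
#'   bond counts as "strong" (A).
#' @return an `hbond_criteria` list.
#' @export
hbond_criteria <- function(heavy_distance_max = 3.5, angle_min = 135,
                           strong_H_to_O_max = 1.6) {
  stopifnot(heavy_distance_max > 0, angle_min > 0, angle_min <= 180,
            strong_H_to_O_max > 0)
  structure(list(heavy_distance_max = heavy_distance_max,
                 angle_min = angle_min,
                 strong_H_to_O_max = strong_H_to_O_max),
            class = "hbond_criteria")
}

#' Donor (heavy, H) pairs of a topology
#'
#' Water O-H bonds from the site roles; solute N-H and O-H pairs by a
#' covalent-distance rule (H within 1.25 A of the heavy atom, minimum
#' image).
#' @noRd
donor_pairs <- function(frame, topology) {
  wb <- water_bonds(topology)
  dp <- data.frame(heavy = wb$o_idx, h = wb$h_idx)
  sol <- .solute_atoms(topology)
  hs <- sol[topology$element[sol] == "H" | grepl("^H", topology$atom_name[sol])]
  heav <- sol[topology$element[sol] %in% c("N", "O") |
                grepl("^[NO]", topology$atom_name[sol])]
  if (length(hs) && length(heav)) {
    for (h in hs) {
      d <- min_image_dist(frame$xyz[h, ], frame$xyz[heav, , drop = FALSE],
                          frame$box)
      k <- which(d < 1.25)
      if (length(k))
        dp <- rbind(dp, data.frame(heavy = heav[which.min(d)], h = h))
    }
  }
  dp
}

acceptor_atoms <- function(topology) {
  w <- which((topology$is_water & topology$water_site_role == "O") |
               (!topology$is_water &
                  (topology$element %in% c("N", "O") |
                     grepl("^[NO]", topology$atom_name)) &
                  !(toupper(topology$residue_name) %in% c("CL", "NA", "K"))))
  w
}

#' Detect hydrogen bonds in a frame
#'
#' A donor-heavy/H pair and an acceptor heavy atom form an H-bond when
#' the heavy-heavy minimum-image distance is below
#' `criteria$heavy_distance_max` and the donor-heavy--H...acceptor angle
#' at the H exceeds `criteria$angle_min`.
#'
#' @param frame an `sfg_frame`.
#' @param topology an `sfg_topology`.
#' @param criteria an [hbond_criteria()].
#' @return data frame: `donor_heavy`, `h`, `acceptor` (atom indices),
#'   `d_heavy`, `d_HA` (A), `angle` (degrees), `donor_mol`,
#'   `acceptor_mol`.
#' @export
detect_hbonds <- function(frame, topology, criteria = hbond_criteria()) {
  dp <- donor_pairs(frame, topology)
  acc <- acceptor_atoms(topology)
  xyz <- frame$xyz
  box <- frame$box
  out <- vector("list", nrow(dp))
  for (i in seq_len(nrow(dp))) {
    Dh <- dp$heavy[i]; H <- dp$h[i]
    a_ok <- acc[acc != Dh]
    d <- min_image_dist(xyz[Dh, ], xyz[a_ok, , drop = FALSE], box)
    cand <- which(d < criteria$heavy_distance_max)
    if (!length(cand)) next
    a_c <- a_ok[cand]
    # angle at the H: donor-heavy -- H ... acceptor
    v1 <- as.numeric(min_image(matrix(xyz[Dh, ] - xyz[H, ], 1), box))
    v2 <- min_image(xyz[a_c, , drop = FALSE] -
                      matrix(xyz[H, ], length(cand), 3, byrow = TRUE), box)
    cosang <- as.numeric(v2 %*% v1) /
      (sqrt(sum(v1^2)) * sqrt(rowSums(v2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    keep <- ang > criteria$angle_min
    if (!any(keep)) next
    out[[i]] <- data.frame(donor_heavy = Dh, h = H, acceptor = a_c[keep],
                           d_heavy = d[cand][keep],
                           d_HA = sqrt(rowSums(v2[keep, , drop = FALSE]^2)),
                           angle = ang[keep])
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(donor_heavy = integer(0), h = integer(0),
                      acceptor = integer(0), d_heavy = numeric(0),
                      d_HA = numeric(0), angle = numeric(0))
  out$donor_mol <- topology$molecule_id[out$donor_heavy]
  out$acceptor_mol <- topology$molecule_id[out$acceptor]
  rownames(out) <- NULL
  out
}

#' Role of solute interaction sites
#'
#' Atom-name rules mapping solute atoms to the interaction classes of
#' the first-shell taxonomy: backbone carbonyl oxygen (`CO_O`), amide
#' nitrogen/hydrogen (`amide_N`, `amide_H`), ammonium nitrogen/hydrogen
#' (`NH3_N`, `NH3_H`) or `other`.
#'
#' @param topology an `sfg_topology`.
#' @return character vector over atoms (NA for non-solute).
#' @export
solute_site_roles <- function(topology) {
  out <- rep(NA_character_, nrow(topology))
  sol <- .solute_atoms(topology)
  nm <- toupper(topology$atom_name[sol])
  out[sol] <- "other"
  out[sol][nm == "O"] <- "CO_O"
  out[sol][nm == "N"] <- "amide_N"
  out[sol][nm %in% c("H", "HN")] <- "amide_H"
  out[sol][nm == "NZ"] <- "NH3_N"
  out[sol][grepl("^HZ", nm)] <- "NH3_H"
  out
}

#' First-shell hydrogen-bond taxonomy
#'
#' Populates the water subsets used for the subset spectra: waters
#' donating to backbone carbonyls (`hb_to_CO`, with the short-bond
#' subset `strong_hb_CO`), waters accepting from amide N-H (`hb_to_NH`),
#' waters accepting from side-chain ammonium N-H (`hb_to_NH3`), and the
#' near-but-not-H-bonded complements of the backbone and side-chain
#' regions (`backbone_no_hb`, `sidechain_no_hb`).
#'
#' @param first_shell,second_shell shell molecule ids.
#' @param hbonds output of [detect_hbonds()] for the same frame.
#' @param backbone_region,sidechain_region region molecule ids.
#' @param topology an `sfg_topology`.
#' @param criteria an [hbond_criteria()].
#' @return a `shell_assignment` list of molecule-id sets.
#' @export
classify_first_shell <- function(first_shell, second_shell, hbonds,
                                 backbone_region, sidechain_region,
                                 topology, criteria = hbond_criteria()) {
  roles <- solute_site_roles(topology)
  is_w <- topology$is_water
  # water donating to solute carbonyl O
  don_CO <- hbonds[is_w[hbonds$donor_heavy] &
                     !is.na(roles[hbonds$acceptor]) &
                     roles[hbonds$acceptor] == "CO_O", ]
  hb_to_CO <- sort(intersect(unique(don_CO$donor_mol), first_shell))
  strong_hb_CO <- sort(intersect(
    unique(don_CO$donor_mol[don_CO$d_HA <= criteria$strong_H_to_O_max]),
    hb_to_CO))
  acc_from <- function(role) {
    b <- hbonds[!is.na(roles[hbonds$h]) & roles[hbonds$h] == role &
                  is_w[hbonds$acceptor], ]
    sort(intersect(unique(b$acceptor_mol), first_shell))
  }
  hb_to_NH <- acc_from("amide_H")
  hb_to_NH3 <- acc_from("NH3_H")
  # any H-bond with the solute, either direction
  sol_hb <- hbonds[(is_w[hbonds$donor_heavy] & !is_w[hbonds$acceptor]) |
                     (!is_w[hbonds$donor_heavy] & is_w[hbonds$acceptor]), ]
  w_hb <- unique(c(sol_hb$donor_mol[is_w[sol_hb$donor_heavy]],
                   sol_hb$acceptor_mol[is_w[sol_hb$acceptor]]))
  structure(list(
    first_shell = first_shell, second_shell = second_shell,
    backbone_region = backbone_region, sidechain_region = sidechain_region,
    hb_to_CO = hb_to_CO, hb_to_NH = hb_to_NH, hb_to_NH3 = hb_to_NH3,
    strong_hb_CO = strong_hb_CO,
    backbone_no_hb = sort(setdiff(backbone_region, w_hb)),
    sidechain_no_hb = sort(setdiff(sidechain_region, w_hb))),
    class = "shell_assignment")
}
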