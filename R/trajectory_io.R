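#' Default water-detection and charge configuration
#'
#' @param water_residues residue names treated as water.
#' @param charge_table named charge table ("tip4pew", "tip3p",
#'   "strand_mimic") used for atoms whose topology carries no charge,
#'   or NULL to require charges in the file.
#' @param vacuum_axis axis of the vacuum gap.
#' @return a list of configuration values.
#' @export
io_config <- function(water_residues = c("HOH", "WAT", "TIP4", "TIP3", "SOL"),
                      charge_table = "tip4pew", vacuum_axis = "z") {
  list(water_residues = water_residues, charge_table = charge_table,
       vacuum_axis = vacuum_axis)
}

#' Load a named charge table shipped with the package
#'
#' Tables are plain TSV files (columns residue, atom, charge) under
#' `inst/extdata`.  "tip4pew" and "tip3p" carry the water-model charges;
#' "strand_mimic" carries the synthetic strand template charges.
#'
#' @param name table name or a path to a TSV file.
#' @return data frame with columns `residue`, `atom`, `charge`.
#' @export
load_charge_table <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0("charges_", name, ".tsv"),
                package = "chiralsfg")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown charge table: ", name)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

.water_role <- function(atom_name) {
  a <- toupper(atom_name)
  ifelse(grepl("^O", a), "O",
    ifelse(a %in% c("H1", "HW1") | grepl("^H.*1$", a), "H1",
      ifelse(a %in% c("H2", "HW2") | grepl("^H.*2$", a), "H2",
        ifelse(grepl("^(M|EP|MW)", a), "virtual", "n/a"))))
}

#' Build an `sfg_topology` from parsed atom records
#' @noRd
topology_from_records <- function(atom_name, residue_name, residue_index,
                                  element, charge, config) {
  is_water <- residue_name %in% config$water_residues
  role <- ifelse(is_water, .water_role(atom_name), "n/a")
  # one molecule per (residue name, residue number) pair, in file order
  key <- paste(residue_name, residue_index)
  molecule_id <- as.integer(factor(key, levels = unique(key)))
  if (all(is.na(charge)) || all(charge == 0 | is.na(charge))) {
    if (is.null(config$charge_table))
      stop("charges required: topology carries none and no charge table is configured")
    tab <- load_charge_table(config$charge_table)
    # water charges always resolvable from the water tables
    wt <- load_charge_table(if (any(grepl("TIP3|HOH|SOL|WAT",
                                          residue_name[is_water])) &&
                                 !any(grepl("TIP4", residue_name[is_water])))
                              "tip3p" else "tip4pew")
    tab <- rbind(tab, wt)
    m <- match(paste(residue_name, toupper(atom_name)),
               paste(tab$residue, toupper(tab$atom)))
    charge <- tab$charge[m]
    # waters with unmatched file-specific atom names: match by site role
    wrole <- role
    need <- is.na(charge) & is_water
    if (any(need)) {
      wmap <- c(O = "O", H1 = "H1", H2 = "H2", virtual = "M")
      m2 <- match(wmap[wrole[need]], wt$atom)
      charge[need] <- wt$charge[m2]
    }
    if (anyNA(charge))
      stop("charges required: no table entry for atoms ",
           paste(unique(paste(residue_name, atom_name)[is.na(charge)]),
                 collapse = ", "))
  }
  sfg_topology(atom_name, residue_name, residue_index, element, charge,
               molecule_id, is_water, role)
}

parse_cryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(NULL)
  v <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                    substr(cl[1], 25, 33)))
  diag(v)
}

#' Read a topology and trajectory
#'
#' Supported topology formats: PDB (via bio3d) and GRO.  Supported
#' trajectories: DCD (via bio3d), multi-model PDB, or none (the
#' coordinates of the topology file become the single frame).  Water
#' molecules are detected by residue name; partial charges come from the
#' file when present (GRO never carries them) or from the configured
#' charge table.
#'
#' @param topology_path path to a PDB or GRO file.
#' @param trajectory_path optional path to a DCD or multi-model PDB.
#' @param config see [io_config()].
#' @return list(`topology`, `frames`): frames in file order with
#'   nondecreasing time stamps.
#' @export
read_system <- function(topology_path, trajectory_path = NULL,
                        config = io_config()) {
  if (!file.exists(topology_path)) stop("no such file: ", topology_path)
  ext <- tolower(tools::file_ext(topology_path))
  if (ext == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(topology_path, multi = TRUE),
                    error = function(e) stop("format error reading PDB '",
                                             topology_path, "': ",
                                             conditionMessage(e)))
    a <- pdb$atom
    top <- topology_from_records(trimws(a$elety), trimws(a$resid),
                                 a$resno, trimws(a$elesy),
                                 rep(NA_real_, nrow(a)), config)
    box <- parse_cryst1(readLines(topology_path, warn = FALSE))
    if (is.null(box)) stop("format error: PDB lacks a CRYST1 record (box required)")
    nat <- nrow(a)
    xyz <- pdb$xyz
    nmod <- nrow(as.matrix(xyz))
    frames <- lapply(seq_len(nmod), function(i)
      sfg_frame(matrix(as.matrix(xyz)[i, ], ncol = 3, byrow = TRUE), box,
                vacuum_axis = config$vacuum_axis, time = i - 1))
  } else if (ext == "gro") {
    g <- read_gro(topology_path)
    top <- topology_from_records(g$atom_name, g$residue_name,
                                 g$residue_index, NULL, NA, config)
    frames <- list(sfg_frame(g$xyz, g$box, vacuum_axis = config$vacuum_axis))
  } else stop("unsupported topology format: .", ext)

  if (!is.null(trajectory_path)) {
    if (!file.exists(trajectory_path)) stop("no such file: ", trajectory_path)
    text <- tolower(tools::file_ext(trajectory_path))
    if (text == "dcd") {
      tr <- bio3d::read.dcd(trajectory_path, cell = FALSE, verbose = FALSE)
      box <- frames[[1]]$box
      frames <- lapply(seq_len(nrow(tr)), function(i)
        sfg_frame(matrix(tr[i, ], ncol = 3, byrow = TRUE), box,
                  vacuum_axis = config$vacuum_axis, time = i - 1))
    } else if (text == "pdb") {
      sub <- read_system(trajectory_path, NULL, config)
      frames <- sub$frames
    } else stop("unsupported trajectory format: .", text)
    if (any(vapply(frames, function(f) nrow(f$xyz), 1) != nrow(top)))
      stop("trajectory atom count does not match topology")
  }
  list(topology = top, frames = frames)
}

#' Minimal GRO reader (fixed-width Gromos87 coordinates, nm -> A)
#' @noRd
read_gro <- function(path) {
  ln <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(ln[2])))
  if (is.na(n) || length(ln) < n + 3) stop("format error in GRO file: ", path)
  body <- ln[3:(2 + n)]
  residue_index <- as.integer(substr(body, 1, 5))
  residue_name <- trimws(substr(body, 6, 10))
  atom_name <- trimws(substr(body, 11, 15))
  xyz <- 10 * cbind(as.numeric(substr(body, 21, 28)),
                    as.numeric(substr(body, 29, 36)),
                    as.numeric(substr(body, 37, 44)))
  bv <- as.numeric(strsplit(trimws(ln[n + 3]), "\\s+")[[1]]) * 10
  box <- if (length(bv) >= 9)
    matrix(c(bv[1], bv[4], bv[5], bv[6], bv[2], bv[7], bv[8], bv[9], bv[3]),
           3, 3, byrow = TRUE) else diag(bv[1:3])
  list(atom_name = atom_name, residue_name = residue_name,
       residue_index = residue_index, xyz = xyz, box = box)
}

#' Write a system as a (multi-model) PDB file
#'
#' Writes a CRYST1 record and one MODEL per frame; coordinate precision
#' is the PDB fixed format (1e-3 A).
#'
#' @param topology an `sfg_topology`.
#' @param frames list of `sfg_frame`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_system <- function(topology, frames, path) {
  b <- frames[[1]]$box
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    b[1, 1], b[2, 2], b[3, 3], 90, 90, 90), con)
  nm <- topology$atom_name
  nm4 <- ifelse(nchar(nm) < 4, paste0(" ", substr(paste0(nm, "   "), 1, 3)),
                substr(nm, 1, 4))
  for (i in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    xyz <- frames[[i]]$xyz
    writeLines(sprintf(
      "ATOM  %5d %s %-4s%5d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (topology$atom_index - 1) %% 99999 + 1, nm4,
      substr(topology$residue_name, 1, 4),
      (topology$residue_index - 1) %% 9999 + 1,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, topology$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a spectrum as a TSV table
#'
#' Columns: `frequency_cm1`, `re_chi`, `im_chi`, `subset`.  Values are
#' written with full double precision so a re-read is bit-exact.
#'
#' @param result an `sfg_spectrum` (see [accumulate_spectrum()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(result, path) {
  stopifnot(inherits(result, "sfg_spectrum"))
  if (length(result$frequency_grid) == 0)
    warning("writing an empty spectrum (header only)")
  df <- data.frame(frequency_cm1 = result$frequency_grid,
                   re_chi = Re(result$chi_values),
                   im_chi = Im(result$chi_values),
                   subset = rep(result$subset_name,
                                length(result$frequency_grid)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("frequency_cm1\tre_chi\tim_chi\tsubset", con)
  if (nrow(df))
    writeLines(sprintf("%s\t%s\t%s\t%s",
                       format(df$frequency_cm1, digits = 17, trim = TRUE),
                       format(df$re_chi, digits = 17, trim = TRUE),
                       format(df$im_chi, digits = 17, trim = TRUE),
                       df$subset), con)
  invisible(path)
}

#' Re-read a spectrum table written by [write_spectrum_table()]
#' @param path path to the TSV file.
#' @return an `sfg_spectrum` (metadata fields restored where stored).
#' @export
read_spectrum_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("numeric", "numeric", "numeric",
                                  "character"))
  new_spectrum(df$frequency_cm1, complex(real = df$re_chi,
                                         imaginary = df$im_chi),
               tensor_element = NA_character_,
               subset_name = if (nrow(df)) df$subset[1] else NA_character_,
               n_frames = NA_integer_, mean_subset_size = NA_real_)
}
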