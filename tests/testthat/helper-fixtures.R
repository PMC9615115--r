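# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

helix_sys <- function() fixture("helix", function()
  build_chiral_water_helix(n = 10, radius = 5, pitch = 2, dipole_tilt = 30))

# small strand-mimic system with waters under the strand
template_sys <- function() fixture("template", function() {
  strand <- make_template_strand(n_repeats = 2)
  build_template_system(strand, n_waters = 48, seed = 11, box = c(22, 22, 50))
})

all_subset <- function(sys)
  sfg_subset("all_water", list(water_molecules(sys$topology)))

narrow_grid <- seq(3000, 3800, by = 4)

spectrum_of <- function(sys, element = "zyx", subset = NULL, ...) {
  if (is.null(subset)) subset <- all_subset(sys)
  accumulate_spectrum(sys$frames, sys$topology, subset, element = element,
                      grid = narrow_grid, ...)
}

# chain construction: solute atom and single-file waters along x in a
# periodic box; Voronoi cells are slabs so shell structure is exact
chain_system <- function(n_waters = 5, spacing = 3, box_yz = 8) {
  box <- c(spacing * (n_waters + 1), box_yz, box_yz)
  tpl <- water_template("tip3p")
  centers <- cbind(spacing * (seq_len(n_waters) + 0.5), box_yz / 2, box_yz / 2)
  # bisector along +y so all atoms of a water share its x coordinate
  rot <- rotation_about(c(1, 0, 0), -90)
  wfr <- do.call(rbind, lapply(seq_len(n_waters), function(i)
    make_water(centers[i, ], rot, tpl)))
  solute <- sfg_topology("C1", "LIG", 1, "C", 0, n_waters + 1L, FALSE, "n/a")
  top <- merge_topologies(list(water_topology(n_waters, tpl), solute))
  fr <- sfg_frame(rbind(wfr, c(spacing * 0.5, box_yz / 2, box_yz / 2)), box)
  list(topology = top, frames = list(fr))
}
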