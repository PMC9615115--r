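#' Thermalize a rigid-water slab by Metropolis Monte Carlo
#'
#' Samples the NVT ensemble of rigid waters at `temperature_K` with
#' single-molecule translation + rotation moves.  The pair potential is
#' the water model's O-O Lennard-Jones term plus Coulomb interactions of
#' all charged sites, with a molecule-based (O-O) minimum-image cutoff.
#' Orthorhombic boxes only.  The sampler is deterministic for a given
#' seed and independent of R's RNG state.
#'
#' Rigid-body Monte Carlo samples the same equilibrium ensemble a
#' thermostatted MD run would; one "sweep" is one attempted move per
#' molecule, and frames are taken at fixed sweep intervals after an
#' equilibration period.
#'
#' @param centers n x 3 matrix of initial oxygen positions (A).
#' @param rotations list of n 3x3 orientation matrices.
#' @param template a `water_template` (must carry LJ parameters).
#' @param box orthorhombic box edge lengths (length 3, A).
#' @param seed integer seed.
#' @param n_frames number of frames to return.
#' @param equil_sweeps equilibration sweeps before sampling.
#' @param sample_every sweeps between samples.
#' @param temperature_K temperature (K).
#' @param cutoff O-O cutoff (A); must be below half the smallest box
#'   edge.
#' @param max_trans,max_rot_deg move amplitudes.
#' @return list of `sfg_frame`s (time stamped by sample index).
#' @export
thermalize_slab <- function(centers, rotations, template = water_template(),
                            box = c(20, 20, 60), seed = 1,
                            n_frames = 60, equil_sweeps = 4000,
                            sample_every = 50, temperature_K = 298,
                            cutoff = 9, max_trans = 0.2, max_rot_deg = 20) {
  centers <- as.matrix(centers)
  if (cutoff > min(box) / 2)
    stop("cutoff exceeds half the smallest box edge")
  loc <- water_local_sites(template)
  qs <- template$site_charges
  charged <- names(qs)[qs != 0]
  sites <- cbind(loc[charged, , drop = FALSE], qs[charged])
  rotm <- do.call(rbind, lapply(rotations, function(R) as.numeric(t(R))))
  res <- mc_water_cpp(centers, rotm, sites, template$lj_sigma,
                      template$lj_eps, box, cutoff, temperature_K,
                      as.integer(equil_sweeps), as.integer(n_frames),
                      as.integer(sample_every), max_trans, max_rot_deg,
                      as.integer(seed %% .Machine$integer.max))
  frames <- lapply(seq_along(res$frames), function(i) {
    fr <- res$frames[[i]]
    rots <- lapply(seq_len(nrow(fr$centers)), function(j)
      matrix(fr$rotations[j, ], 3, 3, byrow = TRUE))
    f <- waters_frame(fr$centers, rots, template, box, time = i - 1)
    f
  })
  attr(frames, "energies") <- res$energies
  attr(frames, "acceptance") <- res$acceptance
  frames
}
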