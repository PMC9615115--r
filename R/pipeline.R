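#' Assemble a run configuration
#'
#' @param input either list(topology=, trajectory=) file paths, or
#'   list(fixture = "helix"|"slab"|"template", ...) parameters for the
#'   synthetic generators, or a preloaded list(topology=, frames=).
#' @param output_dir output directory (created if needed).
#' @param map_file optional map-coefficient file path.
#' @param criteria an [hbond_criteria()].
#' @param grid frequency grid (cm-1).
#' @param lineshape,width line-shape settings.
#' @param element tensor element for the main spectra.
#' @param seed integer seed recorded in outputs and used for fixtures.
#' @param shell_stride compute Voronoi shells every this many frames
#'   (shell membership is reused within a stride window).
#' @param time_step frame spacing (ps) for retention analysis.
#' @return a `run_config` list.
#' @export
run_config <- function(input, output_dir, map_file = NULL,
                       criteria = hbond_criteria(),
                       grid = seq(2800, 4000, by = 1),
                       lineshape = "lorentzian", width = 5,
                       element = "zyx", seed = 1, shell_stride = 1,
                       time_step = 1) {
  cfg <- list(input = input, output_dir = output_dir, map_file = map_file,
              criteria = criteria, grid = grid, lineshape = lineshape,
              width = width, element = element, seed = seed,
              shell_stride = shell_stride, time_step = time_step)
  for (p in list(cfg$input$topology, cfg$input$trajectory, map_file))
    if (is.character(p) && !all(file.exists(p)))
      stop("missing input file: ", p)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[setdiff(names(cfg), "output_dir")],
                              auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

load_config_input <- function(cfg) {
  inp <- cfg$input
  if (!is.null(inp$frames)) return(inp)
  if (!is.null(inp$topology) && is.character(inp$topology))
    return(read_system(inp$topology, inp$trajectory))
  fixture <- match.arg(inp$fixture, c("helix", "slab", "template"))
  switch(fixture,
    helix = do.call(build_chiral_water_helix,
                    inp[intersect(names(inp),
                                  names(formals(build_chiral_water_helix)))]),
    slab = do.call(build_slab_fixture,
                   c(list(seed = cfg$seed),
                     inp[intersect(names(inp),
                                   setdiff(names(formals(build_slab_fixture)),
                                           "seed"))])),
    template = {
      strand <- make_template_strand(
        n_repeats = if (is.null(inp$n_repeats)) 3 else inp$n_repeats)
      build_template_system(strand,
                            n_waters = if (is.null(inp$n_waters)) 150
                                       else inp$n_waters,
                            seed = cfg$seed)
    })
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full hydration-shell spectrum analysis
#'
#' Produces, under `output_dir`: chiral spectra of all water, the first
#' and second hydration shells and the H-bond taxonomy subsets (absolute
#' and per-water), per-frame shell membership tables, an H-bond count
#' summary, subset retention times, the interfacial dipole grid with its
#' annulus profile, and a JSON manifest carrying the configuration hash.
#' Shell-dependent outputs require a solute; for pure-water systems the
#' taxonomy stages are skipped and noted in the manifest.
#'
#' @param cfg a [run_config()].
#' @return the manifest (list), invisibly; written as `manifest.json`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  coeffs <- load_map_coefficients(cfg$map_file)
  sys <- load_config_input(cfg)
  top <- sys$topology
  frames <- sys$frames
  outputs <- character(0)
  stage <- "setup"
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   n_frames = length(frames), n_atoms = nrow(top),
                   package_version = as.character(utils::packageVersion("chiralsfg")))
  tryCatch({
    all_w <- water_molecules(top)
    subsets <- list(all_water = sfg_subset("all_water", list(all_w)))
    has_solute <- length(.solute_atoms(top)) > 0

    if (has_solute) {
      stage <- "shells"
      idx <- unique(c(seq(1, length(frames), by = cfg$shell_stride)))
      assign_cache <- vector("list", length(frames))
      memb_rows <- list()
      for (f in seq_along(frames)) {
        src <- idx[findInterval(f, idx)]
        if (is.null(assign_cache[[src]])) {
          nb <- voronoi_neighbors(frames[[src]], top)
          sh <- assign_shells(nb, top)
          reg <- split_backbone_sidechain(sh$first_shell, nb, top)
          hb <- detect_hbonds(frames[[src]], top, cfg$criteria)
          assign_cache[[src]] <- classify_first_shell(
            sh$first_shell, sh$second_shell, hb, reg$backbone_region,
            reg$sidechain_region, top, cfg$criteria)
        }
        assign_cache[[f]] <- assign_cache[[src]]
        a <- assign_cache[[f]]
        for (nm in names(a))
          if (length(a[[nm]]))
            memb_rows[[length(memb_rows) + 1L]] <-
              data.frame(frame = f, label = nm, molecule_id = a[[nm]])
      }
      memb <- do.call(rbind, memb_rows)
      outputs <- c(outputs, write_tsv(memb, file.path(cfg$output_dir,
                                                      "shell_membership.tsv")))
      taxonomy <- c("first_shell", "second_shell", "backbone_region",
                    "sidechain_region", "hb_to_CO", "hb_to_NH", "hb_to_NH3",
                    "strong_hb_CO", "backbone_no_hb", "sidechain_no_hb")
      for (nm in taxonomy)
        subsets[[nm]] <- sfg_subset(nm, lapply(assign_cache, `[[`, nm))
      subsets$rest <- sfg_subset("rest", lapply(assign_cache, function(a)
        setdiff(all_w, c(a$first_shell, a$second_shell))))
    }

    stage <- "spectra"
    spec_abs <- list(); spec_pw <- list()
    for (nm in names(subsets)) {
      s <- accumulate_spectrum(frames, top, subsets[[nm]],
                               element = cfg$element, grid = cfg$grid,
                               lineshape = cfg$lineshape, width = cfg$width,
                               coeffs = coeffs)
      spec_abs[[nm]] <- s
      outputs <- c(outputs, write_spectrum_table(
        s, file.path(cfg$output_dir, paste0("spectrum_", nm, ".tsv"))))
      if (s$mean_subset_size > 0) {
        spec_pw[[nm]] <- normalize_per_water(s)
        outputs <- c(outputs, write_spectrum_table(
          spec_pw[[nm]],
          file.path(cfg$output_dir, paste0("spectrum_", nm, "_per_water.tsv"))))
      }
    }

    stage <- "hbond_summary"
    hb_rows <- lapply(names(subsets), function(nm) {
      ok <- any(vapply(subsets[[nm]]$members, length, 1L) > 0)
      data.frame(subset = nm,
                 mean_hbonds = if (ok)
                   mean_hbonds_per_water(frames, top, subsets[[nm]],
                                         cfg$criteria) else NA_real_)
    })
    outputs <- c(outputs, write_tsv(do.call(rbind, hb_rows),
                                    file.path(cfg$output_dir,
                                              "hbond_summary.tsv")))

    stage <- "retention"
    ret <- list()
    ret_rows <- list()
    for (nm in names(subsets)) {
      mem <- subsets[[nm]]$members
      if (length(mem) == 1L)
        mem <- rep(mem, length(frames))
      if (!length(unlist(mem))) next
      ret[[nm]] <- retention_times(sfg_subset(nm, mem), cfg$time_step)
      ret_rows[[nm]] <- data.frame(subset = nm,
                                   mean_retention_ps = ret[[nm]]$mean_retention,
                                   n_episodes = ret[[nm]]$n_episodes,
                                   n_censored = ret[[nm]]$n_censored)
    }
    outputs <- c(outputs, write_tsv(do.call(rbind, ret_rows),
                                    file.path(cfg$output_dir, "retention.tsv")))

    stage <- "dipole_grid"
    grid <- dipole_grid(frames, top)
    gdf <- expand.grid(ix = seq_len(dim(grid$vec)[1]),
                       iy = seq_len(dim(grid$vec)[2]))
    cc <- grid_cell_centers(grid)
    gdf <- data.frame(x = cc$x[gdf$ix], y = cc$y[gdf$iy],
                      vx = as.numeric(grid$vec[, , 1]),
                      vy = as.numeric(grid$vec[, , 2]),
                      vz = as.numeric(grid$vec[, , 3]),
                      occupancy = as.integer(grid$occupancy))
    outputs <- c(outputs, write_tsv(gdf, file.path(cfg$output_dir,
                                                   "dipole_grid.tsv")))
    center <- if (length(.solute_atoms(top))) {
      plane <- setdiff(1:3, axis_index(frames[[1]]$vacuum_axis))
      colMeans(frames[[1]]$xyz[.solute_atoms(top), plane, drop = FALSE])
    } else diag(frames[[1]]$box)[1:2] / 2
    ann <- annulus_dipole_profile(grid, center)
    outputs <- c(outputs, write_tsv(ann, file.path(cfg$output_dir,
                                                   "annulus_profile.tsv")))
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         " (partial outputs retained in ", cfg$output_dir, ")")
  })
  manifest$outputs <- basename(outputs)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
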