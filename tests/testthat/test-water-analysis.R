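test_that("water dipole follows the bisector-toward-oxygen convention", {
  tpl <- water_template("tip4pew")
  top <- water_topology(1, tpl)
  fr <- sfg_frame(make_water(c(10, 10, 10), diag(3), tpl), c(20, 20, 20))
  mu <- water_dipole(fr, top, 1L)
  # identity orientation: hydrogens at +z, so the dipole points along -z
  expect_equal(mu[1, 1:2], c(0, 0), tolerance = 1e-12)
  expect_lt(mu[1, 3], 0)
  # magnitude vs direct site-charge sum: TIP4P-Ew gives ~2.32 D
  loc <- water_local_sites(tpl)
  p <- colSums(loc * tpl$site_charges[rownames(loc)]) * 4.803204544
  expect_equal(sqrt(sum(mu^2)), sqrt(sum(p^2)), tolerance = 1e-12)
  expect_equal(sqrt(sum(mu^2)), 2.32, tolerance = 0.005)
  # equivariance under rotation
  set.seed(3)
  R <- random_rotations(1)[[1]]
  fr2 <- sfg_frame(make_water(c(10, 10, 10), R, tpl), c(20, 20, 20))
  mu2 <- water_dipole(fr2, top, 1L)
  expect_equal(as.numeric(mu2), as.numeric(R %*% mu[1, ]), tolerance = 1e-10)
})

test_that("hydrogen-bond counts: isolated water, dimer, and an enumerated cluster", {
  tpl <- water_template("tip3p")
  top1 <- water_topology(1, tpl)
  fr1 <- sfg_frame(make_water(c(10, 10, 10), diag(3), tpl), c(30, 30, 30))
  sub1 <- sfg_subset("w", list(1L))
  expect_equal(mean_hbonds_per_water(list(fr1), top1, sub1), 0)
  # dimer: donor has 1 (donated), acceptor has 1 (accepted)
  top2 <- water_topology(2, tpl)
  w1 <- make_water(c(10, 10, 10), diag(3), tpl)
  u <- (w1["H1", ] - w1["O", ]) / tpl$r_OH
  w2 <- make_water(c(10, 10, 10) + 2.8 * u, rotation_about(c(1, 0, 0), 90), tpl)
  fr2 <- sfg_frame(rbind(w1, w2), c(30, 30, 30))
  expect_equal(mean_hbonds_per_water(list(fr2), top2,
                                     sfg_subset("d", list(1L))), 1)
  expect_equal(mean_hbonds_per_water(list(fr2), top2,
                                     sfg_subset("a", list(2L))), 1)
  expect_equal(mean_hbonds_per_water(list(fr2), top2,
                                     sfg_subset("b", list(1:2))), 1)
  # small thermal cluster vs hand enumeration from the bond list
  sys <- build_slab_fixture(12, box = c(10, 10, 28), seed = 19)
  hb <- detect_hbonds(sys$frames[[1]], sys$topology)
  counts <- integer(12)
  for (r in seq_len(nrow(hb))) {
    counts[hb$donor_mol[r]] <- counts[hb$donor_mol[r]] + 1L
    counts[hb$acceptor_mol[r]] <- counts[hb$acceptor_mol[r]] + 1L
  }
  expect_equal(mean_hbonds_per_water(sys$frames, sys$topology,
                                     sfg_subset("all", list(1:12))),
               mean(counts))
})

test_that("retention episodes follow run lengths, with censoring flags", {
  always <- sfg_subset("s", rep(list(7L), 100))
  r <- retention_times(always, time_step = 1)
  expect_equal(r$mean_retention, 100)
  expect_equal(r$n_episodes, 1)
  expect_equal(r$n_censored, 1)
  alt <- sfg_subset("s", rep(list(3L, integer(0)), 50))
  r2 <- retention_times(alt, time_step = 1)
  expect_equal(r2$mean_retention, 1)
  expect_equal(r2$n_episodes, 50)
  # random membership vs an independent run-length oracle
  set.seed(12)
  nf <- 60
  mem <- lapply(seq_len(nf), function(i) which(runif(5) < 0.4))
  r3 <- retention_times(sfg_subset("s", mem), time_step = 2)
  durs <- c()
  for (m in 1:5) {
    run <- 0
    for (f in seq_len(nf)) {
      if (m %in% mem[[f]]) run <- run + 1
      else if (run > 0) { durs <- c(durs, run * 2); run <- 0 }
    }
    if (run > 0) durs <- c(durs, run * 2)
  }
  expect_equal(sort(r3$durations), sort(durs))
  expect_equal(r3$mean_retention, mean(durs))
  expect_error(retention_times(sfg_subset("s", list(integer(0)))), "empty")
})

test_that("signal/retention join reports a rank correlation of 1 for a
           monotone construction", {
  mk <- function(amp, nm) chiralsfg:::new_spectrum(
    seq(2800, 4000, 10), complex(real = 0,
                                 imaginary = amp * exp(-(seq(2800, 4000, 10)
                                                         - 3400)^2 / 5000)),
    "zyx", nm, 1L, 1, per_water = TRUE)
  spectra <- list(a = mk(1, "a"), b = mk(2, "b"), c = mk(3, "c"))
  retn <- list(a = list(mean_retention = 2), b = list(mean_retention = 5),
               c = list(mean_retention = 11))
  tab <- signal_vs_retention(c("a", "b", "c"), spectra, retn)
  expect_equal(attr(tab, "rank_correlation"), 1)
  expect_equal(nrow(tab), 3)
  # identical inputs give identical rows
  tab2 <- signal_vs_retention(c("a", "a"), spectra, retn)
  expect_equal(tab2$per_water_area[1], tab2$per_water_area[2])
  expect_error(signal_vs_retention(c("a", "zz"), spectra, retn), "missing")
})

test_that("dipole grid bins by oxygen cell and conserves the total dipole", {
  tpl <- water_template("tip4pew")
  top <- water_topology(1, tpl)
  fr <- sfg_frame(make_water(c(5.4, 7.2, 10), diag(3), tpl), c(12, 12, 30))
  frames <- rep(list(fr), 10)
  g <- dipole_grid(frames, top, resolution = 1, depth_range = c(-20, 20))
  expect_equal(sum(g$occupancy), 10)
  expect_equal(g$occupancy[6, 8], 10L)
  mu <- water_dipole(fr, top, 1L)
  expect_equal(g$vec[6, 8, ], 10 * as.numeric(mu), tolerance = 1e-10)
  # conservation: grid total equals the sum of all per-water dipoles
  sys <- build_slab_fixture(20, box = c(12, 12, 30), seed = 44)
  g2 <- dipole_grid(sys$frames, sys$topology, 1, c(-100, 100))
  tot <- colSums(water_dipole(sys$frames[[1]], sys$topology, 1:20))
  expect_equal(apply(g2$vec, 3, sum), as.numeric(tot), tolerance = 1e-9)
  # random frames vs a direct binning oracle
  occ_ref <- matrix(0L, 12, 12)
  vec_ref <- array(0, c(12, 12, 3))
  orow <- which(sys$topology$water_site_role == "O")
  for (w in 1:20) {
    xy <- sys$frames[[1]]$xyz[orow[w], 1:2] %% 12
    i <- floor(xy[1]) + 1; j <- floor(xy[2]) + 1
    occ_ref[i, j] <- occ_ref[i, j] + 1L
    vec_ref[i, j, ] <- vec_ref[i, j, ] +
      water_dipole(sys$frames[[1]], sys$topology, w)
  }
  expect_equal(g2$occupancy, occ_ref)
  expect_equal(g2$vec, vec_ref, tolerance = 1e-10)
})

test_that("mirror-paired waters give an antisymmetric in-plane dipole field", {
  tpl <- water_template("tip4pew")
  top <- water_topology(2, tpl)
  set.seed(6)
  R <- random_rotations(1)[[1]]
  w1 <- make_water(c(3.5, 5.5, 8), R, tpl)
  m <- build_mirror_pair(sfg_frame(w1, c(12, 12, 24)), "yz")
  fr <- sfg_frame(rbind(w1, m$xyz), c(12, 12, 24))
  g <- dipole_grid(list(fr), top, 1, c(-50, 50))
  occ <- which(g$occupancy > 0, arr.ind = TRUE)
  expect_equal(nrow(occ), 2)
  v1 <- g$vec[occ[1, 1], occ[1, 2], ]
  v2 <- g$vec[occ[2, 1], occ[2, 2], ]
  expect_equal(v1[1], -v2[1], tolerance = 1e-10)  # x component flips
  expect_equal(v1[2], v2[2], tolerance = 1e-10)
  expect_equal(v1[3], v2[3], tolerance = 1e-10)
})

test_that("annulus profile sums rings correctly and cancels symmetric fields", {
  g <- structure(list(vec = array(0, c(20, 20, 3)),
                      occupancy = matrix(1L, 20, 20), resolution = 1,
                      origin = c(0, 0), axes = c("x", "y"),
                      depth_range = c(0, 14), n_frames = 1),
                 class = "dipole_grid")
  # single nonzero cell at radius ~5 from the center
  center <- c(10, 10)
  g1 <- g
  g1$vec[16, 10, ] <- c(1, 2, 2)   # cell center (15.5, 9.5): r = 5.523
  ann <- annulus_dipole_profile(g1, center, 1)
  expect_equal(ann$mag_3d[ann$r_lo == 5], 3)
  expect_equal(ann$mag_inplane[ann$r_lo == 5], sqrt(5))
  expect_equal(sum(ann$mag_3d), 3)
  # radially symmetric inward-pointing field cancels ring by ring
  g2 <- g
  cc <- chiralsfg:::grid_cell_centers(g2)
  for (i in 1:20) for (j in 1:20) {
    d <- c(cc$x[i], cc$y[j]) - center
    r <- sqrt(sum(d^2))
    if (r > 1e-9) g2$vec[i, j, ] <- c(-d / r, 0)
  }
  ann2 <- annulus_dipole_profile(g2, center, 1)
  expect_lt(max(ann2$mag_inplane), 1e-9)
  # random grid vs a direct per-cell oracle for one ring
  set.seed(10)
  g3 <- g
  g3$vec <- array(rnorm(20 * 20 * 3), c(20, 20, 3))
  ann3 <- annulus_dipole_profile(g3, center, 2)
  ref <- c(0, 0, 0)
  for (i in 1:20) for (j in 1:20) {
    r <- sqrt(sum((c(cc$x[i], cc$y[j]) - center)^2))
    if (r >= 2 && r < 4) ref <- ref + g3$vec[i, j, ]
  }
  expect_equal(ann3$mag_3d[ann3$r_lo == 2], sqrt(sum(ref^2)), tolerance = 1e-10)
  expect_error(annulus_dipole_profile(g, c(50, 50), 1), "outside")
})

test_that("mirror asymmetry score is zero for symmetric fields and exact
           for antisymmetric ones", {
  g <- structure(list(vec = array(0, c(10, 10, 3)),
                      occupancy = matrix(1L, 10, 10), resolution = 1,
                      origin = c(0, 0), axes = c("x", "y"),
                      depth_range = c(0, 14), n_frames = 1),
                 class = "dipole_grid")
  set.seed(15)
  half <- array(rnorm(5 * 10 * 3), c(5, 10, 3))
  gs <- g
  for (i in 1:5) for (j in 1:10) {
    v <- half[i, j, ]
    gs$vec[i, j, ] <- v
    vm <- v; vm[1] <- -v[1]
    gs$vec[11 - i, j, ] <- vm  # mirror across x = 5
  }
  expect_equal(mirror_asymmetry_score(gs, "yz", 5), 0, tolerance = 1e-12)
  # field equal to its own mirror negation: score = RMS of twice the field
  ga <- g
  for (i in 1:5) for (j in 1:10) {
    v <- half[i, j, ]
    ga$vec[i, j, ] <- v
    vm <- v; vm[1] <- -v[1]
    ga$vec[11 - i, j, ] <- -vm
  }
  # both halves carry the doubled difference, so the mean square is
  # 2 * sum((2 half)^2) over the 100 cells
  ref <- sqrt(2 * sum((2 * half)^2) / (3 * 100))
  expect_equal(mirror_asymmetry_score(ga, "yz", 5), ref, tolerance = 1e-12)
  # random field vs the direct per-cell formula
  gr <- g
  gr$vec <- array(rnorm(300), c(10, 10, 3))
  acc <- 0
  for (i in 1:10) for (j in 1:10) {
    v <- gr$vec[i, j, ]
    w <- gr$vec[11 - i, j, ]; w[1] <- -w[1]
    acc <- acc + sum((v - w)^2)
  }
  expect_equal(mirror_asymmetry_score(gr, "yz", 5), sqrt(acc / 300),
               tolerance = 1e-12)
})

test_that("dangling O-H detection counts undonated vacuum-pointing bonds", {
  tpl <- water_template("tip3p")
  # ten isolated waters: orientations chosen so exactly three have an
  # O-H within 30 degrees of +z; none donate (far apart)
  n <- 10
  top <- water_topology(n, tpl)
  rots <- c(
    lapply(1:3, function(k) rotation_about(c(0, 1, 0),
                                           -tpl$theta_HOH / 2 + (k - 1) * 5)),
    lapply(4:10, function(k) rotation_about(c(0, 1, 0), 150 + k))
  )
  centers <- cbind(seq(5, 50, by = 5), 30, 30)
  xyz <- do.call(rbind, lapply(seq_len(n), function(i)
    make_water(centers[i, ], rots[[i]], tpl)))
  fr <- sfg_frame(xyz, c(60, 60, 60))
  sub <- sfg_subset("all", list(1:n))
  frac <- dangling_oh_fraction(list(fr), top, sub, angle_max = 30)
  expect_equal(frac, 0.3)
  # a fully donating water is never counted
  top2 <- water_topology(2, tpl)
  w1 <- make_water(c(10, 10, 10), rotation_about(c(0, 1, 0), -tpl$theta_HOH / 2),
                   tpl)
  u <- (w1["H1", ] - w1["O", ]) / tpl$r_OH   # points near +z
  w2 <- make_water(c(10, 10, 10) + 2.8 * u, rotation_about(c(1, 0, 0), 90), tpl)
  fr2 <- sfg_frame(rbind(w1, w2), c(30, 30, 30))
  hb <- detect_hbonds(fr2, top2)
  expect_true(1 %in% hb$donor_mol)
  expect_equal(dangling_oh_fraction(list(fr2), top2,
                                    sfg_subset("w", list(1L)), 30), 0)
})
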