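test_that("two atoms in a periodic box are mutual Voronoi neighbors", {
  pr <- chiralsfg:::voronoi_pairs_cpp(rbind(c(1, 1, 1), c(6, 4, 2)),
                                      diag(c(10, 10, 10)))
  expect_equal(pr, matrix(c(1L, 2L), 1))
})

test_that("a simple cubic lattice has exactly 6 face-sharing neighbors", {
  a <- 3; n <- 3
  pts <- as.matrix(expand.grid(x = (0:(n - 1)) * a, y = (0:(n - 1)) * a,
                               z = (0:(n - 1)) * a))
  pr <- chiralsfg:::voronoi_pairs_cpp(pts, diag(rep(n * a, 3)))
  deg <- tabulate(c(pr[, 1], pr[, 2]), nbins = nrow(pts))
  expect_true(all(deg == 6))
})

test_that("random points match the frozen independent tessellation oracle", {
  pts <- as.matrix(read.table(test_path("fixtures",
                                        "voronoi_points_synthetic.tsv"),
                              header = TRUE))
  pr <- chiralsfg:::voronoi_pairs_cpp(pts, diag(c(10, 10, 10)))
  oracle <- read.table(test_path("fixtures", "voronoi_pairs_synthetic.tsv"),
                       header = TRUE)
  expect_setequal(paste(pr[, 1], pr[, 2]), paste(oracle$i, oracle$j))
})

test_that("coincident atoms raise a degeneracy error", {
  expect_error(chiralsfg:::voronoi_pairs_cpp(rbind(c(1, 1, 1), c(1, 1, 1)),
                                             diag(c(10, 10, 10))),
               "coincident")
})

test_that("neighbor map is symmetric with no self-neighbors, and is
           invariant under rigid rotation of the frame", {
  sys <- template_sys()
  nb <- voronoi_neighbors(sys$frames[[1]], sys$topology)
  for (i in seq_along(nb$adjacency)) {
    expect_false(i %in% nb$adjacency[[i]])
    for (j in nb$adjacency[[i]]) expect_true(i %in% nb$adjacency[[j]])
  }
  # rotate the whole frame 90 degrees about z (box is square in x,y)
  fr <- sys$frames[[1]]
  L <- diag(fr$box)
  xyz <- fr$xyz
  rot <- cbind(L[2] / 2 + (xyz[, 2] - L[2] / 2) * 0 - (xyz[, 2] - L[2] / 2),
               xyz[, 1], xyz[, 3])
  rot[, 1] <- L[1] - xyz[, 2]
  rot[, 2] <- xyz[, 1]
  nb2 <- voronoi_neighbors(sfg_frame(rot, fr$box, fr$vacuum_axis), sys$topology)
  expect_identical(nb$pairs, nb2$pairs)
})

test_that("constructed chain recovers first and second shells exactly", {
  sys <- chain_system(n_waters = 5)
  nb <- voronoi_neighbors(sys$frames[[1]], sys$topology)
  sh <- assign_shells(nb, sys$topology)
  expect_equal(sh$first_shell, c(1L, 5L))
  expect_equal(sh$second_shell, c(2L, 4L))
  # water 3 is beyond two layers: in neither shell
  expect_false(3L %in% c(sh$first_shell, sh$second_shell))
})

test_that("shell assignment matches a brute-force neighbor-of-neighbor oracle", {
  sys <- template_sys()
  top <- sys$topology
  nb <- voronoi_neighbors(sys$frames[[1]], top)
  sh <- assign_shells(nb, top)
  # oracle: plain set algebra on the pair list
  pairs <- nb$pairs
  touching <- function(atom_set) {
    hit <- c(pairs[pairs[, 1] %in% atom_set, 2],
             pairs[pairs[, 2] %in% atom_set, 1])
    unique(hit)
  }
  solute <- which(!top$is_water &
                    !(toupper(top$residue_name) %in% c("CL", "NA", "K")))
  first_ref <- sort(unique(top$molecule_id[intersect(touching(solute),
                                                     which(top$is_water))]))
  fs_atoms <- which(top$molecule_id %in% first_ref & top$is_water &
                      top$water_site_role != "virtual")
  second_ref <- sort(setdiff(
    unique(top$molecule_id[intersect(touching(fs_atoms), which(top$is_water))]),
    first_ref))
  expect_identical(sh$first_shell, first_ref)
  expect_identical(sh$second_shell, second_ref)
  expect_length(intersect(sh$first_shell, sh$second_shell), 0)
  expect_error(assign_shells(nb, water_topology(3)), "no solute")
})

test_that("backbone/side-chain regions overlap and cover the first shell", {
  sys <- template_sys()
  top <- sys$topology
  nb <- voronoi_neighbors(sys$frames[[1]], top)
  sh <- assign_shells(nb, top)
  reg <- split_backbone_sidechain(sh$first_shell, nb, top)
  expect_true(all(sh$first_shell %in%
                    union(reg$backbone_region, reg$sidechain_region)))
  expect_gte(length(reg$backbone_region) + length(reg$sidechain_region),
             length(sh$first_shell))
})

test_that("hydrogen-bond criteria accept and reject the canonical geometries", {
  # two waters: donor O-H pointing at acceptor O, linear, O-O 2.8 A
  tpl <- water_template("tip3p")
  top <- water_topology(2, tpl)
  th <- tpl$theta_HOH * pi / 360
  # bond O->H1 points along +x after rotating bisector (z) onto the
  # H1 direction; simpler: place acceptor along the O->H1 direction
  w1 <- make_water(c(10, 10, 10), diag(3), tpl)
  u <- (w1["H1", ] - w1["O", ]) / tpl$r_OH
  place <- function(d_oo) {
    w2 <- make_water(c(10, 10, 10) + d_oo * u,
                     rotation_about(c(1, 0, 0), 90), tpl)
    sfg_frame(rbind(w1, w2), c(30, 30, 30))
  }
  hb <- detect_hbonds(place(2.8), top)
  expect_equal(nrow(hb[hb$donor_mol == 1 & hb$acceptor_mol == 2, ]), 1)
  expect_equal(hb$angle[1], 180, tolerance = 1e-6)
  # distance fails
  hb2 <- detect_hbonds(place(3.6), top)
  expect_equal(nrow(hb2), 0)
  # angle fails: put the acceptor 120 degrees off the O-H axis at 2.8 A
  v <- rotation_about(c(0, 1, 0), 115) %*% u  # angle at H will be ~120
  w3 <- make_water(c(10, 10, 10) + as.numeric(2.8 * v),
                   rotation_about(c(1, 0, 0), 90), tpl)
  fr3 <- sfg_frame(rbind(w1, w3), c(30, 30, 30))
  hb3 <- detect_hbonds(fr3, top)
  expect_equal(nrow(hb3[hb3$donor_mol == 1 & hb3$acceptor_mol == 2 &
                          hb3$h == 2, ]), 0)
})

test_that("H-bond set shrinks monotonically as criteria tighten", {
  sys <- build_slab_fixture(30, box = c(14, 14, 35), seed = 8)
  fr <- sys$frames[[1]]
  key <- function(hb) paste(hb$h, hb$acceptor)
  loose <- detect_hbonds(fr, sys$topology, hbond_criteria(3.5, 135))
  tight_d <- detect_hbonds(fr, sys$topology, hbond_criteria(3.0, 135))
  tight_a <- detect_hbonds(fr, sys$topology, hbond_criteria(3.5, 155))
  expect_true(all(key(tight_d) %in% key(loose)))
  expect_true(all(key(tight_a) %in% key(loose)))
})

test_that("first-shell taxonomy matches a brute-force classification", {
  sys <- template_sys()
  top <- sys$topology
  fr <- sys$frames[[1]]
  crit <- hbond_criteria()
  nb <- voronoi_neighbors(fr, top)
  sh <- assign_shells(nb, top)
  reg <- split_backbone_sidechain(sh$first_shell, nb, top)
  hb <- detect_hbonds(fr, top, crit)
  cls <- classify_first_shell(sh$first_shell, sh$second_shell, hb,
                              reg$backbone_region, reg$sidechain_region,
                              top, crit)
  expect_true(all(cls$strong_hb_CO %in% cls$hb_to_CO))
  expect_true(all(cls$backbone_region %in%
                    union(union(cls$hb_to_CO, cls$hb_to_NH), cls$backbone_no_hb)
                  | cls$backbone_region %in% cls$hb_to_NH3))
  # brute force per-water reclassification
  roles <- solute_site_roles(top)
  for (w in sh$first_shell) {
    don <- hb[hb$donor_mol == w, ]
    acc <- hb[hb$acceptor_mol == w, ]
    ref_co <- any(!is.na(roles[don$acceptor]) & roles[don$acceptor] == "CO_O")
    expect_equal(w %in% cls$hb_to_CO, ref_co)
    ref_nh <- any(!is.na(roles[acc$h]) & roles[acc$h] == "amide_H")
    expect_equal(w %in% cls$hb_to_NH, ref_nh)
    ref_nh3 <- any(!is.na(roles[acc$h]) & roles[acc$h] == "NH3_H")
    expect_equal(w %in% cls$hb_to_NH3, ref_nh3)
    any_sol <- any(!top$is_water[don$acceptor]) || any(!top$is_water[acc$h])
    expect_equal(w %in% cls$backbone_no_hb,
                 (w %in% reg$backbone_region) && !any_sol)
    expect_equal(w %in% cls$sidechain_no_hb,
                 (w %in% reg$sidechain_region) && !any_sol)
  }
})

test_that("a water donating a short H-bond to C=O lands in the strong subset", {
  # constructed geometry: water H 1.5 A from a lone carbonyl oxygen
  tpl <- water_template("tip4pew")
  wtop <- water_topology(1, tpl)
  co_top <- sfg_topology(c("C", "O"), "STR", 1, c("C", "O"),
                         c(0.5973, -0.5679), 2L, FALSE, "n/a")
  top <- merge_topologies(list(wtop, co_top))
  w <- make_water(c(10, 10, 10), diag(3), tpl)
  u <- (w["H1", ] - w["O", ]) / tpl$r_OH
  o_pos <- w["H1", ] + 1.5 * u
  c_pos <- o_pos + 1.23 * u
  fr <- sfg_frame(rbind(w, c_pos, o_pos), c(25, 25, 25))
  crit <- hbond_criteria()
  hb <- detect_hbonds(fr, top, crit)
  cls <- classify_first_shell(1L, integer(0), hb, 1L, integer(0), top, crit)
  expect_equal(cls$hb_to_CO, 1L)
  expect_equal(cls$strong_hb_CO, 1L)
  expect_length(cls$backbone_no_hb, 0)
})
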