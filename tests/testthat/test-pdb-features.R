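# Structural descriptors from raw coordinates: analytic limits,
# partition identities, brute-force equivalence, rigid-motion invariance.

test_that("parse_pdb round-trips synthetic structures and rejects bad input", {
  s <- build_backbone(list(c("helix", 15), c("coil", 5)), seed = 3)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, tf)
  s2 <- parse_pdb(tf, "A")
  expect_equal(nrow(s2$residues), 20)
  expect_identical(chain_sequence(s2), chain_sequence(s))
  expect_equal(atom_coords <- as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_match(s2$experiment, "X-RAY")

  expect_error(parse_pdb(tf, "Z"), "chain 'Z' not found")
  expect_error(parse_pdb(file.path(tempdir(), "nope.pdb"), "A"),
               "not found")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    X", "END"), empty)
  expect_error(parse_pdb(empty, "A"), "ATOM")
})

test_that("parse_pdb selects the requested chain and best altloc", {
  # hand-written two-chain file with an altloc pair
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HEADER    TEST",
    "EXPDTA    X-RAY DIFFRACTION",
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.70 11.00           C",
    "ATOM      3  CA  GLY B   1       5.000   0.000   0.000  1.00 12.00           C",
    "END"), tf)
  sa <- parse_pdb(tf, "A")
  expect_equal(nrow(sa$atoms), 1)
  expect_equal(sa$atoms$x, 1.0)  # higher-occupancy altloc kept
  sb <- parse_pdb(tf, "B")
  expect_identical(sb$residues$aa, "G")
})

test_that("isolated and well-separated atoms match analytic SASA", {
  s1 <- single_atom_structure()
  a <- compute_sasa(s1)
  expect_lt(abs(a - 4 * pi * (1.7 + 1.4)^2) / (4 * pi * (1.7 + 1.4)^2),
            0.02)
  # two atoms 100 A apart: no occlusion
  s2 <- toy_structure(data.frame(resi = c(1, 2), name = c("CA", "CA"),
                                 x = c(0, 100), y = 0, z = 0,
                                 element = "C"))
  expect_equal(sum(compute_sasa(s2)), 2 * a, tolerance = 1e-9)
})

test_that("a fully caged atom has zero SASA and depth equal to cage gap", {
  s <- caged_structure(shell_radius = 2.0, n_shell = 80)
  sasa <- compute_sasa(s)
  expect_equal(sasa[1], 0)
  # oracle: verify every quadrature point of the centre atom is occluded
  pts <- crfcleave:::sphere_points(960) * (1.7 + 1.4)
  shell <- as.matrix(s$atoms[-1, c("x", "y", "z")])
  mind <- apply(pts, 1, function(p)
    min(sqrt(colSums((t(shell) - p)^2))))
  expect_true(all(mind < 1.7 + 1.4))
  dp <- depth_index(s, sasa)
  expect_equal(dp$atom[1], 2.0, tolerance = 1e-9)  # gap to exposed shell
  expect_true(all(dp$atom[-1] == 0))
})

test_that("SASA is invariant under rigid motion", {
  s <- mixed_structure()
  base <- sum(compute_sasa(s, n_points = 480))
  s2 <- s
  xyz <- crfcleave:::random_rigid_motion(
    as.matrix(s$atoms[, c("x", "y", "z")]), seed = 9)
  s2$atoms[, c("x", "y", "z")] <- xyz
  expect_equal(sum(compute_sasa(s2, n_points = 480)), base,
               tolerance = 0.01)
})

test_that("residue accessibility categories partition the total", {
  s <- mixed_structure()
  sasa <- compute_sasa(s, n_points = 480)
  acc <- residue_accessibility(s, sasa)
  expect_true(all(abs(acc$sasa_all - acc$sasa_main - acc$sasa_side)
                  < 1e-6))
  expect_true(all(acc$sasa_all >= 0))
  # direct atom-partition oracle for one residue
  at <- s$atoms
  r5 <- which(at$resi == 5)
  main <- at$name[r5] %in% c("N", "CA", "C", "O", "OXT") &
    !(at$aa[r5] == "G" & at$name[r5] == "CA")
  expect_equal(acc$sasa_main[5], sum(sasa[r5][main]), tolerance = 1e-9)
  expect_equal(acc$sasa_side[5], sum(sasa[r5][!main]), tolerance = 1e-9)
  # relative values are percentages of the residue reference area
  expect_equal(acc$rel_all[5],
               100 * acc$sasa_all[5] /
                 crfcleave:::MAX_ASA[s$residues$aa[5]],
               ignore_attr = TRUE)
  # glycine convention: CA counts as side chain
  g <- build_backbone(list(c("coil", 5)), sequence = "GGGGG", seed = 1)
  gs <- compute_sasa(g, n_points = 480)
  gacc <- residue_accessibility(g, gs)
  ca3 <- g$atoms$resi == 3 & g$atoms$name == "CA"
  expect_gte(gacc$sasa_side[3], gs[ca3])
})

test_that("ideal helix is assigned H with (phi, psi) near (-57, -47)", {
  # all-Ala so every amide can donate (prolines have no N-H)
  s <- build_backbone(list(c("helix", 20)),
                      sequence = strrep("A", 20), seed = 1)
  tor <- backbone_torsions(s)
  interior <- 3:18
  expect_true(all(abs(tor$phi[interior] - (-57)) < 2))
  expect_true(all(abs(tor$psi[interior] - (-47)) < 2))
  expect_true(is.na(tor$phi[1]))
  expect_true(is.na(tor$psi[20]))
  ss <- assign_secondary_structure(s)
  expect_true(all(ss$ss3[interior] == "H"))
  # oracle: the i -> i+4 Kabsch-Sander energies are below -0.5
  bb <- crfcleave:::backbone_coords(s)
  cont <- crfcleave:::chain_continuity(bb)
  H <- crfcleave:::imputed_amide_h(bb, cont, s$residues$aa)
  for (i in 3:14) {
    j <- i + 4
    r_on <- sqrt(sum((bb$O[i, ] - bb$N[j, ])^2))
    r_ch <- sqrt(sum((bb$C[i, ] - H[j, ])^2))
    r_oh <- sqrt(sum((bb$O[i, ] - H[j, ])^2))
    r_cn <- sqrt(sum((bb$C[i, ] - bb$N[j, ])^2))
    e <- 0.084 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn) * 332
    expect_lt(e, -0.5)
  }
})

test_that("antiparallel strand pair is assigned E; short chains are coil", {
  sp <- build_sheet_pair(6, seed = 1)
  ss <- assign_secondary_structure(sp)
  n <- 6
  expect_gte(sum(ss$ss3[1:n] == "E"), 2)
  expect_gte(sum(ss$ss3[(n + 1):(2 * n)] == "E"), 2)
  expect_false(any(ss$ss3 == "H"))

  tiny <- build_backbone(list(c("coil", 2)), seed = 1)
  expect_true(all(assign_secondary_structure(tiny)$ss3 == "L"))
})

test_that("torsions are missing across chain breaks and for degenerate geometry", {
  sp <- build_sheet_pair(6, seed = 1)  # spatial jump between residues 6/7
  tor <- backbone_torsions(sp)
  expect_true(is.na(tor$psi[6]))
  expect_true(is.na(tor$phi[7]))
  # collinear atoms -> undefined dihedral with warning
  expect_warning(
    d <- crfcleave:::dihedral_angle(c(0, 0, 0), c(1, 0, 0),
                                    c(2, 0, 0), c(3, 0, 0)),
    "collinear")
  expect_true(is.na(d))
})

test_that("half-sphere exposure matches a brute-force oracle and its identity", {
  s <- mixed_structure()
  hse <- half_sphere_exposure(s)
  expect_true(all(hse$hseau + hse$hsead == hse$cn))
  # brute-force CA double loop with half-plane test (HSE-A directions)
  bb <- crfcleave:::backbone_coords(s)
  n <- nrow(s$residues)
  for (i in c(1, 7, 15, 20, n)) {
    cn <- 0; up <- 0
    if (i > 1 && i < n) {
      d <- 2 * bb$CA[i, ] - bb$CA[i - 1, ] - bb$CA[i + 1, ]
    } else {
      cb <- crfcleave:::virtual_cbeta(bb$N[i, ], bb$CA[i, ], bb$C[i, ])
      d <- cb - bb$CA[i, ]
    }
    for (j in seq_len(n)) {
      if (j == i) next
      v <- bb$CA[j, ] - bb$CA[i, ]
      if (sqrt(sum(v^2)) <= 13) {
        cn <- cn + 1
        if (sum(v * d) > 0) up <- up + 1
      }
    }
    expect_equal(hse$cn[i], cn)
    expect_equal(hse$hseau[i], up)
  }
  # single residue: all zero
  s1 <- single_atom_structure()
  h1 <- half_sphere_exposure(s1)
  expect_true(all(unlist(h1[1, -1]) == 0))
})

test_that("protrusion index matches closed form and brute force", {
  s1 <- single_atom_structure()
  cx <- protrusion_index(s1)
  v_s <- 4 / 3 * pi * 1000
  expect_equal(cx$atom, (v_s - 20.1) / 20.1)
  # dense lattice: cx -> 0 once occupied volume saturates the sphere
  g <- expand.grid(x = seq(-9, 9, by = 1.5), y = seq(-9, 9, by = 1.5),
                   z = seq(-9, 9, by = 1.5))
  dense <- toy_structure(data.frame(resi = 1, name = "CA", x = g$x,
                                    y = g$y, z = g$z, element = "C"))
  cxd <- protrusion_index(dense)
  centre <- which(g$x == 0 & g$y == 0 & g$z == 0)
  expect_equal(cxd$atom[centre], 0)
  # brute-force neighbour-count formula on a random cluster
  set.seed(4)
  pts <- matrix(stats::rnorm(3 * 40, sd = 6), ncol = 3)
  rs <- toy_structure(data.frame(resi = 1, name = "CA", x = pts[, 1],
                                 y = pts[, 2], z = pts[, 3],
                                 element = "C"))
  cxr <- protrusion_index(rs)
  for (i in c(1, 10, 40)) {
    n_in <- sum(sqrt(colSums((t(pts) - pts[i, ])^2)) <= 10)
    v_int <- min(n_in * 20.1, v_s)
    expect_equal(cxr$atom[i], (v_s - v_int) / v_int)
  }
})

test_that("hydrogen-bond counts are symmetric and fire in helices", {
  s <- build_backbone(list(c("helix", 16)), seed = 2)
  hb <- hydrogen_bond_counts(s)
  expect_true(all(hb$hbonds[4:13] >= 1))
  far <- toy_structure(data.frame(resi = c(1, 2), name = c("N", "O"),
                                  x = c(0, 50), y = 0, z = 0,
                                  element = c("N", "O")))
  expect_true(all(hydrogen_bond_counts(far)$hbonds == 0))
  # a close N...O pair increments both residues (backbone pairs of
  # sequence separation < 2 are excluded, so use residues 1 and 3)
  near <- toy_structure(data.frame(resi = c(1L, 2L, 3L),
                                   name = c("N", "CA", "O"),
                                   x = c(0, 20, 3), y = 0, z = 0,
                                   element = c("N", "C", "O")),
                        aa = c("A", "A", "A"))
  expect_equal(hydrogen_bond_counts(near)$hbonds, c(1L, 0L, 1L))
})

test_that("B-factor mean and packing match direct computation", {
  at <- data.frame(resi = 1, name = c("N", "CA", "C"),
                   x = c(0, 1, 2), y = 0, z = 0,
                   element = c("N", "C", "C"), bfactor = c(10, 20, 30))
  s <- toy_structure(at)
  bp <- bfactor_and_packing(s)
  expect_equal(bp$bfactor_mean, 20)
  expect_equal(bp$packing, 3 / (4 / 3 * pi * 8^3))
  # brute force on a random fixture
  s2 <- mixed_structure()
  bp2 <- bfactor_and_packing(s2)
  xyz <- as.matrix(s2$atoms[, c("x", "y", "z")])
  for (i in c(3, 17)) {
    cen <- colMeans(xyz[s2$atoms$resi == i, , drop = FALSE])
    k <- sum(sqrt(colSums((t(xyz) - cen)^2)) <= 8)
    expect_equal(bp2$packing[i], k / (4 / 3 * pi * 8^3))
  }
})

test_that("descriptors other than B-factor are rigid-motion invariant", {
  s <- cached("invariance_small",
              build_backbone(list(c("helix", 8), c("coil", 4)), seed = 6))
  d1 <- residue_descriptors(s, n_points = 480)
  s2 <- s
  s2$atoms[, c("x", "y", "z")] <- crfcleave:::random_rigid_motion(
    as.matrix(s$atoms[, c("x", "y", "z")]), seed = 13)
  d2 <- residue_descriptors(s2, n_points = 480)
  exact <- c("cn", "hseau", "hsead", "hsebu", "hsebd", "hbonds",
             "packing", "cx", "ss3_H", "ss3_E", "ss3_L")
  for (f in exact) expect_equal(d2[[f]], d1[[f]], info = f)
  for (f in c("phi", "psi", "dpx")) {
    expect_equal(d2[[f]], d1[[f]], tolerance = 1e-4, info = f)
  }
  expect_equal(d2$sasa_all, d1$sasa_all, tolerance = 0.05)
})

test_that("dpx matches a direct O(n^2) oracle on a small fixture", {
  s <- mixed_structure()
  sasa <- compute_sasa(s, n_points = 480)
  dp <- depth_index(s, sasa)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  exposed <- which(sasa > 0)
  for (i in seq(1, nrow(xyz), by = 13)) {
    want <- if (sasa[i] > 0) 0 else
      min(sqrt(colSums((t(xyz[exposed, , drop = FALSE]) - xyz[i, ])^2)))
    expect_equal(dp$atom[i], want, tolerance = 1e-9)
  }
})
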