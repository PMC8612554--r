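test_that("distance series match static and constructed geometries", {
  atoms <- data.frame(serial = 1:2, atom_name = c("P1", "P2"),
                      residue_name = "XX", residue_index = 1:2,
                      segment = "OTHER", element = "C")
  top <- topology(atoms)
  coords <- array(0, c(3, 2, 3))
  coords[, 2, 1] <- 7.8
  tr <- trajectory(coords, top)
  ds <- distance_series(tr, distance_definition("d", list(1L, "P1"),
                                                list(2L, "P2")))
  expect_equal(ds$mean, 7.8)
  expect_equal(ds$sd, 0)
  expect_equal(sum(ds$histogram$density) * 0.2, 1, tolerance = 1e-9)
  expect_error(distance_series(tr, distance_definition(
    "bad", list(1L, "P1"), list(9L, "XX"))), "resolve")
})

test_that("noisy two-atom distance SD matches a Monte-Carlo oracle", {
  atoms <- data.frame(serial = 1:2, atom_name = c("P1", "P2"),
                      residue_name = "XX", residue_index = 1:2,
                      segment = "OTHER", element = "C")
  top <- topology(atoms)
  n <- 20000
  sd0 <- 0.5
  set.seed(10)
  coords <- array(stats::rnorm(n * 2 * 3, sd = sd0), c(n, 2, 3))
  coords[, 2, 1] <- coords[, 2, 1] + 8
  tr <- trajectory(coords, top)
  ds <- distance_series(tr, distance_definition("d", list(1L, "P1"),
                                                list(2L, "P2")))
  set.seed(11)
  mc <- sqrt(rowSums((matrix(stats::rnorm(n * 3, sd = sd0), n) -
                        (matrix(stats::rnorm(n * 3, sd = sd0), n) +
                           matrix(rep(c(8, 0, 0), each = n), n)))^2))
  expect_equal(ds$sd, stats::sd(mc), tolerance = 0.05)
})

test_that("pocket frame orients front-positive and rejects degeneracies", {
  toy <- make_toy()
  sel <- toy$selections
  fr <- toy$reference
  pf <- pocket_frame(fr, toy$topology, sel$pocket_residues,
                     sel$plane_atoms, sel$front_markers)
  ifm <- resolve_selection(toy$topology, sel$front_markers)
  fm_mid <- colMeans(fr[ifm, , drop = FALSE])
  expect_gt(sum((fm_mid - pf$plane_origin) * pf$normal), 0)
  ibm <- resolve_selection(toy$topology,
                           list(list(15L, "C1'"), list(30L, "C1'")))
  bm_mid <- colMeans(fr[ibm, , drop = FALSE])
  expect_lt(sum((bm_mid - pf$plane_origin) * pf$normal), 0)
  # colinear plane atoms
  bad <- fr
  ip <- resolve_selection(toy$topology, sel$plane_atoms)
  bad[ip[3], ] <- bad[ip[1], ] + 2 * (bad[ip[2], ] - bad[ip[1], ])
  expect_error(pocket_frame(bad, toy$topology, sel$pocket_residues,
                            sel$plane_atoms, sel$front_markers), "colinear")
  # front marker in the plane
  bad2 <- fr
  for (i in ifm) bad2[i, 1] <- 0   # x = 0 lies in the bisecting plane
  expect_error(pocket_frame(bad2, toy$topology, sel$pocket_residues,
                            sel$plane_atoms, sel$front_markers),
               "orientation")
})

test_that("r and z are invariant under global rigid transforms", {
  toy <- make_toy()
  sel <- toy$selections
  sim <- simulate_bound_trajectory(toy, occupancy_program(), 5, seed = 3)
  cv0 <- cv_trace(sim$trajectory, ligand_residues = 100L,
                  pocket_residues = sel$pocket_residues,
                  plane_atoms = sel$plane_atoms,
                  front_markers = sel$front_markers)
  tf <- random_rigid_transform(77)
  coords <- sim$trajectory$coords
  for (f in seq_len(dim(coords)[1])) {
    m <- coords[f, , ]
    coords[f, , ] <- apply_rigid(m, tf)
  }
  tr2 <- trajectory(coords, toy$topology)
  cv1 <- cv_trace(tr2, ligand_residues = 100L,
                  pocket_residues = sel$pocket_residues,
                  plane_atoms = sel$plane_atoms,
                  front_markers = sel$front_markers)
  expect_equal(cv1$r, cv0$r, tolerance = 1e-9)
  expect_equal(cv1$z, cv0$z, tolerance = 1e-9)
})

test_that("theta angle handles coplanar, orthogonal and random bases", {
  toy <- make_toy()
  top <- toy$topology
  sel <- toy$selections
  fr <- toy$reference
  # plates are parallel planes in the reference -> 0 degrees
  th0 <- theta_angle(fr, top, list(sel$plates$G5, sel$plates$C16),
                     list(sel$plates$G11))
  expect_equal(th0, 0, tolerance = 1e-9)
  # rotate G11 ring by 90 degrees about x through its center -> 90 degrees
  i11 <- resolve_selection(top, sel$plates$G11)
  ctr <- colMeans(fr[i11, , drop = FALSE])
  d <- sweep(fr[i11, , drop = FALSE], 2, ctr)
  fr90 <- fr
  fr90[i11, ] <- sweep(cbind(d[, 1], -d[, 3], d[, 2]), 2, ctr, "+")
  th90 <- theta_angle(fr90, top, list(sel$plates$G5, sel$plates$C16),
                      list(sel$plates$G11))
  expect_equal(th90, 90, tolerance = 1e-9)
  # random orientations: equals the brute-force pairwise average
  set.seed(12)
  groups <- list(sel$plates$G5, sel$plates$C16, sel$plates$G11)
  frr <- fr
  for (g in groups) {
    ig <- resolve_selection(top, g)
    tf <- random_rigid_transform(sample.int(1e6, 1))
    ctr <- colMeans(frr[ig, , drop = FALSE])
    frr[ig, ] <- sweep(sweep(frr[ig, , drop = FALSE], 2, ctr) %*% t(tf$R),
                       2, ctr, "+")
  }
  th <- theta_angle(frr, top, list(groups[[1]], groups[[2]]),
                    list(groups[[3]]))
  brute <- mean(vapply(1:2, function(i) {
    n1 <- fit_plane(frr[resolve_selection(top, groups[[i]]), ])$normal
    n2 <- fit_plane(frr[resolve_selection(top, groups[[3]]), ])$normal
    acos(min(1, abs(sum(n1 * n2)))) * 180 / pi
  }, numeric(1)))
  expect_equal(th, brute, tolerance = 1e-9)
})

test_that("CV density maps normalize, localize peaks and break ties low", {
  # all frames identical -> single occupied bin
  dm <- cv_density_map(rep(2, 50), rep(3, 50), bins = 11)
  expect_equal(sum(dm$density), 1, tolerance = 1e-12)
  expect_equal(sum(dm$density > 0), 1L)
  # mixture of two Gaussians: peak lands within one bin of the heavier mean
  set.seed(9)
  n <- 20000
  pick <- stats::runif(n) < 0.7
  x <- ifelse(pick, stats::rnorm(n, 13.5, 0.3), stats::rnorm(n, 14.5, 0.3))
  y <- ifelse(pick, stats::rnorm(n, 27.5, 2), stats::rnorm(n, 80.5, 2))
  dm2 <- cv_density_map(x, y, bins = 40)
  bw_x <- diff(dm2$x_mid[1:2])
  bw_y <- diff(dm2$y_mid[1:2])
  expect_lt(abs(dm2$peak[1] - 13.5), 1.5 * bw_x)
  expect_lt(abs(dm2$peak[2] - 27.5), 1.5 * bw_y)
})

test_that("grid densities conserve mass, overflow and smooth correctly", {
  atoms <- data.frame(serial = 1L, atom_name = "MG", residue_name = "MG",
                      residue_index = 1L, segment = "ION", element = "MG")
  top <- topology(atoms)
  coords <- array(rep(c(1.1, 2.2, 3.3), each = 10), c(10, 1, 3))
  tr <- trajectory(coords, top)
  gd <- grid_density(tr, 1L, spacing = 0.5)
  expect_equal(sum(gd$counts > 0), 1L)
  expect_equal(max(gd$counts), 10)
  expect_equal(sum(gd$counts) + gd$overflow, 10 * 1)
  # explicit small grid forces overflow but conserves the tally
  gd2 <- grid_density(tr, 1L, spacing = 0.5, origin = c(10, 10, 10),
                      dims = c(4L, 4L, 4L))
  expect_equal(sum(gd2$counts) + gd2$overflow, 10)
  expect_equal(gd2$overflow, 10)
  # smoothing conserves mass and lowers the peak
  gs <- grid_density(tr, 1L, spacing = 0.5, smoothing_sd = 1)
  expect_equal(sum(gs$counts), sum(gd$counts), tolerance = 1e-9)
  expect_lt(max(gs$counts), max(gd$counts))
  expect_error(grid_density(tr, integer(0)), "empty")
})

test_that("site occupancy recovers programs and matches density peaks", {
  sites <- data.frame(label = c("M2", "far"), x = c(0, 50), y = c(0, 0),
                      z = c(0, 0))
  sim <- simulate_ion_occupancy(sites[1, ], c(M2 = 1), n_ions = 1,
                                n_frames = 200, seed = 2, noise_sd = 0.3)
  occ <- site_occupancy(sim$trajectory, 1L, sites, radius = 2)
  expect_equal(occ$occupancy[occ$label == "M2"], 1)
  expect_equal(occ$occupancy[occ$label == "far"], 0)
  # programmed 0.8: recovered within the 99% binomial interval, and the
  # density peak sits within one voxel of the site
  n <- 5000
  sim2 <- simulate_ion_occupancy(sites[1, ], c(M2 = 0.8), n_ions = 1,
                                 n_frames = n, seed = 13, noise_sd = 0.3)
  occ2 <- site_occupancy(sim2$trajectory, 1L, sites[1, ], radius = 2,
                         spacing = 0.5)
  ci <- binom_interval_99(0.8, n)
  expect_gt(occ2$occupancy, ci[1])
  expect_lt(occ2$occupancy, ci[2])
  expect_lt(occ2$nearest_peak_distance, 0.5)
})
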