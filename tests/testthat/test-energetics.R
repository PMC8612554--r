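test_that("Coulomb term matches closed form and brute-force double loop", {
  cfg <- energetics_config()
  # one +1/-1 pair at k_C / 100 A -> exactly -100 kcal/mol
  e <- coulomb_inter(matrix(0, 1, 3), 1, matrix(c(3.320636, 0, 0), 1), -1,
                     cfg)
  expect_equal(e, -100, tolerance = 1e-9)
  expect_equal(coulomb_inter(matrix(0, 1, 3), 1,
                             matrix(c(5, 0, 0), 1), 0, cfg), 0)
  set.seed(2)
  for (k in 1:20) {
    na <- 50
    nb <- 40
    A <- matrix(stats::runif(na * 3, 0, 10), na)
    B <- matrix(stats::runif(nb * 3, 12, 22), nb)
    qa <- stats::rnorm(na)
    qb <- stats::rnorm(nb)
    brute <- 0
    for (i in 1:na) for (j in 1:nb)
      brute <- brute + qa[i] * qb[j] / sqrt(sum((A[i, ] - B[j, ])^2))
    brute <- brute * cfg$coulomb_constant
    expect_equal(coulomb_inter(A, qa, B, qb, cfg), brute, tolerance = 1e-9)
  }
  expect_error(coulomb_inter(matrix(0, 1, 3), 1, matrix(0, 1, 3), 1, cfg),
               "singular")
})

test_that("Lennard-Jones term has its minimum at Rij and decays", {
  cfg <- energetics_config()
  # pair at r = Rij -> exactly -eps_ij
  e <- lj_inter(matrix(0, 1, 3), 1.9, 0.1,
                matrix(c(3.8, 0, 0), 1), 1.9, 0.4, cfg)
  expect_equal(e, -sqrt(0.1 * 0.4), tolerance = 1e-12)
  e_far <- lj_inter(matrix(0, 1, 3), 1.9, 0.1,
                    matrix(c(380, 0, 0), 1), 1.9, 0.4, cfg)
  expect_lt(abs(e_far), 1e-9)
  set.seed(3)
  for (k in 1:10) {
    na <- 30
    nb <- 25
    A <- matrix(stats::runif(na * 3, 0, 8), na)
    B <- matrix(stats::runif(nb * 3, 10, 18), nb)
    rA <- stats::runif(na, 1, 2)
    rB <- stats::runif(nb, 1, 2)
    eA <- stats::runif(na, 0.02, 0.3)
    eB <- stats::runif(nb, 0.02, 0.3)
    brute <- 0
    for (i in 1:na) for (j in 1:nb) {
      r <- sqrt(sum((A[i, ] - B[j, ])^2))
      rij <- rA[i] + rB[j]
      eij <- sqrt(eA[i] * eB[j])
      brute <- brute + eij * ((rij / r)^12 - 2 * (rij / r)^6)
    }
    expect_equal(lj_inter(A, rA, eA, B, rB, eB, cfg), brute,
                 tolerance = 1e-9)
  }
})

test_that("SASA matches the isolated-sphere closed form and a quadrature
           oracle for two overlapping spheres", {
  cfg <- energetics_config()
  s1 <- sasa(matrix(0, 1, 3), 1.6, cfg)
  expect_equal(s1$total, 4 * pi * 3^2, tolerance = 0.005 * 4 * pi * 9)
  # atom fully inside a much larger sphere
  s2 <- sasa(rbind(c(0, 0, 0), c(0.5, 0, 0)), c(1.0, 8.0), cfg)
  expect_equal(s2$per_atom[1], 0)
  # two equal overlapping spheres: exact spherical-cap formula
  r <- 1.6 + 1.4
  d <- 2.5
  cap_area <- 2 * pi * r * (r - d / 2)       # buried cap per sphere
  exact <- 2 * (4 * pi * r^2 - cap_area)
  s3 <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.6, 1.6), cfg)
  expect_equal(s3$total, exact, tolerance = 0.01 * exact)
})

test_that("the nonpolar model applies gamma * SASA + beta", {
  cfg <- energetics_config()
  expect_equal(nonpolar_term(0, cfg), 0.92)
  expect_equal(nonpolar_term(1000, cfg), 6.34)
  # binding difference with identical SASAs: the constant survives once
  expect_equal(nonpolar_term(500, cfg) - nonpolar_term(500, cfg) -
                 nonpolar_term(500, cfg), -nonpolar_term(500, cfg))
  s <- 500
  dg <- (cfg$gamma_np * s + cfg$beta_np) -
    (cfg$gamma_np * s + cfg$beta_np) - (cfg$gamma_np * 0 + cfg$beta_np)
  expect_equal(dg, -0.92)
})

test_that("PB solver reproduces the Born ion within 5% at 0.4 A spacing", {
  exact <- -166.0318 * (1 - 1 / 80) / 2.0
  cfg <- energetics_config(pb_grid_spacing = 0.4)
  e <- as.numeric(solve_pb(matrix(c(0.13, 0.07, -0.11), 1), 1.0, 2.0, cfg))
  expect_lt(abs(e - exact) / abs(exact), 0.05)
  # all charges zero -> 0
  expect_equal(as.numeric(solve_pb(matrix(0, 1, 3), 0, 2.0, cfg)), 0)
})

test_that("Born-ion error decreases monotonically under grid refinement", {
  exact <- -166.0318 * (1 - 1 / 80) / 2.0
  errs <- vapply(c(0.8, 0.4, 0.2), function(h) {
    cfg <- energetics_config(pb_grid_spacing = h)
    e <- as.numeric(solve_pb(matrix(c(0.13, 0.07, -0.11), 1), 1.0, 2.0,
                             cfg))
    abs(e - exact) / abs(exact)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("pb_delta behaves in the non-interacting and superposition limits", {
  cfg <- energetics_config(pb_grid_spacing = 0.4)
  # uncharged ligand far from a charged receptor contributes ~0
  coords <- rbind(c(0, 0, 0), c(25, 0, 0))
  d0 <- pb_delta(coords, c(1, 0), c(2, 2), 1L, 2L, cfg)
  expect_lt(abs(d0), 1.5)
  # two distant Born ions: complex energy ~ sum of individual energies
  e_two <- as.numeric(solve_pb(coords, c(1, 1), c(2, 2), cfg))
  e_one <- as.numeric(solve_pb(matrix(0, 1, 3), 1, 2, cfg))
  inter <- -332.0636 * (1 - 1 / 80) / 25   # screened cross term
  expect_lt(abs(e_two - (2 * e_one + inter)) / abs(e_two), 0.05)
  # desolvation opposes the Coulomb attraction of a complementary pair
  pair <- rbind(c(0, 0, 0), c(4, 0, 0))
  dpol <- pb_delta(pair, c(1, -1), c(2, 2), 1L, 2L, cfg)
  ele <- coulomb_inter(pair[1, , drop = FALSE], 1, pair[2, , drop = FALSE],
                       -1, cfg)
  expect_lt(ele, 0)
  expect_gt(dpol, 0)
})

test_that("entropy terms satisfy QHO limits and a thermodynamic identity", {
  cfg <- energetics_config()
  # frozen mode: S_vib -> 0 at high frequency
  hi <- entropy_terms(50000, 300, c(500, 600, 700), cfg)
  expect_lt(hi$TS_vib, 1e-6)
  # classical limit: S_vib -> R (1 - ln x) as x -> 0
  T <- cfg$temperature
  x <- 0.01
  nu <- x * T / 1.43877688
  lo <- entropy_terms(nu, 300, c(500, 600, 700), cfg)
  s_classical <- 1.9872e-3 * (1 - log(x))
  expect_equal(lo$S_vib, s_classical, tolerance = 0.01 * s_classical)
  # S = d/dT [kT ln q] for one QHO mode, by numeric differentiation
  qho_free <- function(nu, temp) {
    xx <- 1.43877688 * nu / temp
    -1.9872e-3 * temp * (-log(1 - exp(-xx)))  # -kT ln q (zero-point off)
  }
  dT <- 0.01
  s_numeric <- -(qho_free(100, T + dT) - qho_free(100, T - dT)) / (2 * dT)
  mid <- entropy_terms(100, 300, c(500, 600, 700), cfg)
  expect_equal(mid$S_vib, s_numeric, tolerance = 1e-6)
  expect_error(entropy_terms(c(100, -5), 300, c(1, 1, 1), cfg), "positive")
})

test_that("MM-PBSA assembly reproduces printed-component arithmetic", {
  comp <- data.frame(dE_ele = -32.93, dE_vdW = -32.42, dG_pol = 33.77,
                     dG_nonpol = -3.32)
  s <- mmpbsa_summary(comp, TdS = -16.17)
  expect_equal(energy_term(s, "dH"), -34.90, tolerance = 1e-9)
  expect_equal(energy_term(s, "dG_bind"), -18.73, tolerance = 1e-9)
  # assembly identities
  expect_equal(energy_term(s, "dH"),
               sum(s$mean[match(c("dE_ele", "dE_vdW", "dG_pol",
                                  "dG_nonpol"), s$term)]),
               tolerance = 1e-9)
  expect_equal(energy_term(s, "dG_bind"),
               energy_term(s, "dH") - energy_term(s, "TdS"),
               tolerance = 1e-9)
  # all-zero inputs give all-zero outputs
  z <- mmpbsa_summary(data.frame(dE_ele = 0, dE_vdW = 0, dG_pol = 0,
                                 dG_nonpol = 0), 0)
  expect_true(all(z$mean == 0))
  # SEM over eight synthetic replicates equals SD / sqrt(8)
  set.seed(4)
  reps <- lapply(1:8, function(i)
    data.frame(dE_ele = stats::rnorm(1, -30), dE_vdW = -32, dG_pol = 33,
               dG_nonpol = -3.3))
  s8 <- mmpbsa_summary(reps, TdS = rep(-16, 8))
  vals <- vapply(reps, function(df) df$dE_ele, numeric(1))
  expect_equal(s8$sem[s8$term == "dE_ele"], stats::sd(vals) / sqrt(8),
               tolerance = 1e-12)
  expect_error(mmpbsa_summary(list(), -16), "replicate")
})

test_that("per-residue decomposition is exactly additive for pairwise terms", {
  toy <- make_toy()
  top <- toy$topology
  at <- top$atoms
  dec <- per_residue_decomposition(top, toy$reference)
  ir <- which(at$segment == "RNA")
  il <- which(at$segment == "LIGAND")
  cfg <- energetics_config()
  tot_e <- coulomb_inter(toy$reference[ir, ], at$charge[ir],
                         toy$reference[il, ], at$charge[il], cfg)
  tot_v <- lj_inter(toy$reference[ir, ], at$lj_rmin_half[ir],
                    at$lj_epsilon[ir], toy$reference[il, ],
                    at$lj_rmin_half[il], at$lj_epsilon[il], cfg)
  expect_equal(sum(dec$dE_ele), tot_e, tolerance = 1e-6)
  expect_equal(sum(dec$dE_vdW), tot_v, tolerance = 1e-6)
  # nonpolar shares sum to the binding SASA term
  s_c <- sasa(toy$reference, at$pb_radius, cfg)$total
  s_r <- sasa(toy$reference[ir, ], at$pb_radius[ir], cfg)$total
  s_l <- sasa(toy$reference[il, ], at$pb_radius[il], cfg)$total
  dnp <- nonpolar_term(s_c, cfg) - nonpolar_term(s_r, cfg) -
    nonpolar_term(s_l, cfg)
  expect_equal(sum(dec$dG_nonpol), dnp, tolerance = 1e-6)
  # each residue share equals an independent single-residue calculation
  for (ri in c(6L, 15L)) {
    ires <- which(at$residue_index == ri & at$segment == "RNA")
    e_res <- coulomb_inter(toy$reference[ires, , drop = FALSE],
                           at$charge[ires], toy$reference[il, ],
                           at$charge[il], cfg)
    expect_equal(dec$dE_ele[dec$residue_index == ri & !is.na(
      dec$residue_index)], e_res, tolerance = 1e-9)
  }
  # a residue with all-zero charges contributes nothing electrostatic
  top0 <- top
  top0$atoms$charge[top0$atoms$residue_index == 6L] <- 0
  dec0 <- per_residue_decomposition(top0, toy$reference)
  expect_equal(dec0$dE_ele[dec0$residue_index == 6L &
                             !is.na(dec0$residue_index)], 0)
  # identical contribution vectors correlate perfectly
  expect_equal(stats::cor(dec$total, dec$total), 1)
})

test_that("RT ln KD reproduces experimental binding free energies", {
  expect_equal(round(dg_from_kd(2.05e-9, 300), 2), -11.93)
  expect_equal(round(dg_from_kd(35.10e-9, 300), 2), -10.23)
  expect_equal(dg_from_kd(1.0, 300), 0)
  expect_error(dg_from_kd(-1), "positive")
})
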