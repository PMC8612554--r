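test_that("toy pocket geometry satisfies its construction targets", {
  toy <- make_toy()
  sel <- toy$selections
  tr <- single_frame_traj(toy)
  expect_equal(distance_series(tr, sel$distances$d_15_30)$mean,
               toy$spec$door_back_width, tolerance = 1e-6)
  expect_equal(distance_series(tr, sel$distances$d_5_11)$mean,
               toy$spec$door_front_width, tolerance = 1e-6)
  # plate centers sit at half the plate gap above/below the ligand plane
  for (base in names(sel$plates)) {
    st <- stacking_summary(tr, sel$ligand_ring, sel$plates[[base]])
    expect_equal(st$in_fraction, 1)
    expect_equal(st$mean_vertical_distance_in, toy$spec$plate_gap / 2,
                 tolerance = 1e-6)
  }
  # all hydrogen bonds formed in the reference structure
  occ <- hbond_occupancy(tr, sel$hbonds)
  expect_equal(occ$occupancy, rep(1, 3))
  # infeasible door width
  expect_error(build_toy_complex(toy_pocket_spec(door_back_width = 2)),
               "infeasible")
})

test_that("same seed gives identical toy trajectories and hill logs", {
  toy <- make_toy()
  s1 <- simulate_bound_trajectory(toy, occupancy_program(), 50, seed = 9)
  s2 <- simulate_bound_trajectory(toy, occupancy_program(), 50, seed = 9)
  expect_identical(s1$trajectory$coords, s2$trajectory$coords)
  expect_identical(s1$states, s2$states)
  r1 <- simulate_wt_metadynamics(toy_potential_spec(),
                                 metadynamics_params(), 2000, seed = 4)
  r2 <- simulate_wt_metadynamics(toy_potential_spec(),
                                 metadynamics_params(), 2000, seed = 4)
  expect_identical(r1$trace$r, r2$trace$r)
  expect_identical(r1$hills, r2$hills)
})

test_that("degenerate occupancy programs give exact occupancies", {
  toy <- make_toy()
  sel <- toy$selections
  all_on <- occupancy_program(
    stacking_in_fraction = c(G5 = 1, G11 = 1, C16 = 1),
    hbond_occupancy = c(U6 = 1, C15 = 1, A29 = 1),
    positional_noise_sd = 0)
  sim <- simulate_bound_trajectory(toy, all_on, 40, seed = 2)
  st <- stacking_summary(sim$trajectory, sel$ligand_ring, sel$plates$G5)
  expect_equal(st$in_fraction, 1)
  off <- occupancy_program(
    stacking_in_fraction = c(G5 = 0, G11 = 1, C16 = 1),
    hbond_occupancy = c(U6 = 0, C15 = 0, A29 = 0),
    positional_noise_sd = 0)
  sim0 <- simulate_bound_trajectory(toy, off, 40, seed = 2)
  expect_equal(hbond_occupancy(sim0$trajectory, sel$hbonds)$occupancy,
               rep(0, 3))
  st0 <- stacking_summary(sim0$trajectory, sel$ligand_ring, sel$plates$G5)
  expect_equal(st0$in_fraction, 0)
  expect_true(is.na(st0$mean_vertical_distance_in))
  expect_equal(st0$n_in, 0L)
})

test_that("Markov-programmed occupancies are recovered from the state log", {
  toy <- make_toy()
  prog <- occupancy_program(
    stacking_in_fraction = c(G5 = 0.70, G11 = 0.95, C16 = 0.9),
    hbond_occupancy = c(U6 = 0.70, C15 = 0.85, A29 = 0.8))
  n <- 5000L
  sim <- simulate_bound_trajectory(toy, prog, n, seed = 21)
  s <- prog$state_switch_probability
  for (chk in list(c("stack_G5", 0.70), c("hbond_U6", 0.70),
                   c("hbond_C15", 0.85))) {
    p <- as.numeric(chk[2])
    ci <- markov_interval_99(p, n, s)
    obs <- mean(sim$states[[chk[1]]])
    expect_gt(obs, ci[1])
    expect_lt(obs, ci[2])
  }
})

test_that("ion-site occupancy simulation matches its program", {
  sites <- data.frame(label = c("M2", "M3"), x = c(0, 8), y = c(0, 0),
                      z = c(0, 0))
  # degenerate: occupancy 1, no noise -> always exactly at the site
  sim1 <- simulate_ion_occupancy(sites[1, ], c(M2 = 1), n_ions = 1,
                                 n_frames = 20, seed = 1, noise_sd = 0)
  expect_true(all(abs(sweep(matrix(sim1$trajectory$coords, ncol = 3), 2,
                            c(0, 0, 0))) < 1e-12))
  # occupancy 0 with a box that excludes the site
  box <- rbind(c(20, 20, 20), c(40, 40, 40))
  sim0 <- simulate_ion_occupancy(sites[1, ], c(M2 = 0), n_ions = 1,
                                 n_frames = 50, seed = 2, box = box)
  d <- sqrt(rowSums(matrix(sim0$trajectory$coords, ncol = 3)^2))
  expect_true(all(d > 1))
  # programmed 0.8 recovered within the 99% binomial interval
  sim <- simulate_ion_occupancy(sites, c(M2 = 0.8, M3 = 0.05), n_ions = 1,
                                n_frames = 5000, seed = 3)
  obs <- mean(sim$states[, 1] == "M2")
  ci <- binom_interval_99(0.8, 5000)
  expect_gt(obs, ci[1])
  expect_lt(obs, ci[2])
  # overlapping sites warn
  close_sites <- data.frame(label = c("A", "B"), x = c(0, 0.1), y = 0, z = 0)
  expect_warning(simulate_ion_occupancy(close_sites, c(A = 0.5, B = 0.2),
                                        n_frames = 2, seed = 1), "overlap")
})

test_that("an unbiased particle in a deep well stays bound", {
  pot <- toy_potential_spec(well_depth = 8, kT = 0.3)
  params <- metadynamics_params(deposit_interval = 100000L)
  run <- simulate_wt_metadynamics(pot, params, n_steps = 20000, seed = 6)
  expect_equal(nrow(run$hills), 0L)
  expect_lt(max(run$trace$r), 9)
})

test_that("well-tempered hill heights are non-increasing at a fixed CV", {
  run <- simulate_wt_metadynamics(toy_potential_spec(),
                                  metadynamics_params(deposit_interval = 200),
                                  n_steps = 60000, seed = 8)
  h <- run$hills
  expect_gt(nrow(h), 50)
  # reconstruct the bias at fixed CV values as hills accumulate: the
  # well-tempered deposit height at any fixed value must be non-increasing
  w <- run$params$gaussian_width
  gamma_fac <- (run$params$bias_factor - 1) * run$potential$kT
  for (s0 in c(0.5, 2, 4, 8)) {
    vb <- cumsum(h$height * exp(-(s0 - h$center)^2 / (2 * w^2)))
    hyp <- run$params$initial_height * exp(-c(0, vb[-length(vb)]) /
                                             gamma_fac)
    expect_true(all(diff(hyp) <= 1e-12))
  }
  # heights never exceed the initial height
  expect_true(all(h$height <= run$params$initial_height + 1e-12))
})

test_that("a divergent integration step is caught", {
  pot <- toy_potential_spec(wall_k = 1e6)
  params <- metadynamics_params(timestep = 5)
  expect_error(simulate_wt_metadynamics(pot, params, n_steps = 5000,
                                        seed = 1, start = c(12, 0)),
               "divergent")
})

test_that("the analytic toy-potential gradient matches finite differences", {
  pot <- toy_potential_spec()
  set.seed(17)
  for (k in 1:50) {
    x <- stats::runif(1, -9, 9)
    y <- stats::runif(1, -9, 9)
    ev <- pocketdyn:::toy_potential_eval(pot, x, y)
    h <- 1e-6
    gx <- (pocketdyn:::toy_potential_eval(pot, x + h, y)$V -
             pocketdyn:::toy_potential_eval(pot, x - h, y)$V) / (2 * h)
    gy <- (pocketdyn:::toy_potential_eval(pot, x, y + h)$V -
             pocketdyn:::toy_potential_eval(pot, x, y - h)$V) / (2 * h)
    expect_equal(ev$gx, gx, tolerance = 1e-4)
    expect_equal(ev$gy, gy, tolerance = 1e-4)
  }
})

test_that("1D well-tempered bias reconstructs the double-well free energy", {
  dw <- double_well_potential(barrier = 3, x0 = 1.5)
  run <- simulate_wt_metadynamics_1d(
    dw$V, dw$dV, metadynamics_params(deposit_interval = 250),
    n_steps = 200000, seed = 3, range = c(-3.5, 3.5))
  fe <- reconstruct_free_energy(run)
  sampled <- fe$s >= -2.6 & fe$s <= 2.6
  ref <- dw$V(fe$s[sampled])
  est <- fe$F[sampled]
  est <- est - mean(est) + mean(ref - min(ref))
  rms <- sqrt(mean((est - (ref - min(ref)))^2))
  expect_lt(rms, 0.5)
  # cross-check the designed landscape against a Boltzmann histogram of a
  # long unbiased run at a reduced barrier (brute-force oracle)
  dw2 <- double_well_potential(barrier = 1.2, x0 = 1.5)
  set.seed(5)
  kT <- 0.596
  dt <- 0.005
  nstep <- 150000L
  x <- -1.5
  xs <- numeric(nstep)
  noise <- stats::rnorm(nstep, sd = sqrt(2 * dt))
  for (i in seq_len(nstep)) {
    x <- x - (dw2$dV(x) / kT) * dt + noise[i]
    xs[i] <- x
  }
  hs <- graphics::hist(xs, breaks = seq(-4, 4, by = 0.25), plot = FALSE)
  keep <- hs$density > 0.02
  f_emp <- -kT * log(hs$density[keep])
  f_ref <- dw2$V(hs$mids[keep])
  f_emp <- f_emp - mean(f_emp) + mean(f_ref)
  expect_lt(sqrt(mean((f_emp - f_ref)^2)), 0.35)
})
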