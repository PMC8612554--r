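# Synthetic-data module: a rigid toy binding pocket with two stacking plates
# and in-plane hydrogen-bond partners, trajectories with programmed discrete
# states (Markov switching), ion-site occupancy trajectories, and a
# well-tempered metadynamics toy simulator with two escape channels.

TOY_RING_RADIUS <- 1.4       # ligand ring circumradius, A
TOY_RING_ECC <- 1.15         # x-elongation; breaks principal-axis degeneracy
TOY_BASE_RADIUS <- 1.15      # pseudo-base ring radius, A
TOY_OUT_DISPLACEMENT <- 4.0  # lateral shift of an unstacked plate, A
TOY_BROKEN_DISTANCE <- 4.5   # donor-acceptor distance of a broken H-bond, A

#' Specification of the toy binding pocket
#'
#' Defaults mirror the geometry of a six-nucleotide riboswitch pocket:
#' 3.4 A plate separation (aromatic stacking distance), a ~12 A front door
#' (C1'-C1' across G5/G11) and a ~7.5 A back door (C1'-C1' across C15/C30),
#' and 2.9 A in-plane hydrogen bonds.
#'
#' @param plate_gap vertical distance between the two stacking plates, A.
#' @param door_front_width target d_5-11 marker distance, A.
#' @param door_back_width target d_15-30 marker distance, A.
#' @param hbond_distance donor-acceptor distance of a formed bond, A.
#' @param ring_atom_count number of ligand ring atoms (>= 3).
#' @param seed integer seed stored with the spec.
#' @export
toy_pocket_spec <- function(plate_gap = 3.4, door_front_width = 12.0,
                            door_back_width = 7.5, hbond_distance = 2.9,
                            ring_atom_count = 6L, seed = 1L) {
  stopifnot(plate_gap > 0, door_front_width > 0, door_back_width > 0,
            hbond_distance > 0, ring_atom_count >= 3L)
  structure(list(plate_gap = plate_gap,
                 door_front_width = door_front_width,
                 door_back_width = door_back_width,
                 hbond_distance = hbond_distance,
                 ring_atom_count = as.integer(ring_atom_count),
                 seed = as.integer(seed)),
            class = "toy_pocket_spec")
}

ring_points <- function(center, radius, n, plane = "z", ecc_x = 1) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  if (plane == "z") {         # ring in a z = const plane
    cbind(center[1] + radius * ecc_x * cos(ang),
          center[2] + radius * sin(ang),
          center[3] + 0 * ang)
  } else {                    # ring in an x = const plane (orthogonal base)
    cbind(center[1] + 0 * ang,
          center[2] + radius * ecc_x * cos(ang),
          center[3] + radius * sin(ang))
  }
}

#' Build the rigid toy aptamer-ligand complex
#'
#' Constructs a planar ligand ring at the origin, a "G11" stacking plate at
#' +plate_gap/2 above the ligand plane and "G5"/"C16" plates below, in-plane
#' hydrogen-bond partner pseudo-bases "U6", "C15" and "A29" at
#' `hbond_distance`, and marker C1' atoms placed so that the back-door
#' (C15-C30) and front-door (G5-G11) C1' distances equal the configured
#' widths exactly.  The pocket-bisecting plane of the reference structure is
#' the x = 0 plane with the front at x > 0.  All atoms carry parameters from
#' the bundled toy table.
#'
#' @param spec a [toy_pocket_spec()]
#' @return list of class `toy_complex`: `topology` (parameterized),
#'   `reference` (n_atoms x 3 matrix), `spec`, and `selections` (see
#'   [toy_selections()]).
#' @export
build_toy_complex <- function(spec = toy_pocket_spec()) {
  stopifnot(inherits(spec, "toy_pocket_spec"))
  if (spec$door_back_width < 2 * TOY_RING_RADIUS ||
      spec$door_front_width < 2 * TOY_RING_RADIUS)
    stop("build_toy_complex: door width smaller than the ligand ring ",
         "diameter is geometrically infeasible")
  hb <- spec$hbond_distance
  gap2 <- spec$plate_gap / 2
  dfw2 <- spec$door_front_width / 2
  dbw2 <- spec$door_back_width / 2
  rows <- list()
  coords <- list()
  add <- function(resn, resi, names, elements, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      atom_name = names, residue_name = resn, residue_index = resi,
      element = elements, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
  }
  n <- spec$ring_atom_count
  # ligand ring (heavy) + three donor N atoms with their hydrogens
  add("LIG", 100L, paste0("L", seq_len(n)), rep("C", n),
      ring_points(c(0, 0, 0), TOY_RING_RADIUS, n, ecc_x = TOY_RING_ECC))
  donor_dirs <- list(U6 = c(0, 1, 0), C15 = c(0, -1, 0),
                     A29 = c(cos(210 * pi / 180), sin(210 * pi / 180), 0))
  dmat <- do.call(rbind, donor_dirs)
  add("LIG", 100L, c("D1", "D2", "D3"), rep("N", 3),
      TOY_RING_RADIUS * dmat)
  add("LIG", 100L, c("HD1", "HD2", "HD3"), rep("H", 3),
      (TOY_RING_RADIUS + 1.0) * dmat)
  # stacking plates: G11 above, G5 and C16 below
  add("G", 11L, paste0("R", 1:6), rep("C", 6),
      ring_points(c(0, 0, gap2), TOY_BASE_RADIUS, 6))
  add("G", 11L, "C1'", "C", matrix(c(3.0, 1.0, dfw2), 1))
  add("G", 5L, paste0("R", 1:6), rep("C", 6),
      ring_points(c(-1.2, 0, -gap2), TOY_BASE_RADIUS, 6))
  add("G", 5L, "C1'", "C", matrix(c(3.0, 1.0, -dfw2), 1))
  add("C", 16L, paste0("R", 1:6), rep("C", 6),
      ring_points(c(1.2, 0, -gap2), TOY_BASE_RADIUS, 6))
  add("C", 16L, "C1'", "C", matrix(c(2.0, -3.0, -2.0), 1))
  # in-plane hydrogen-bond partners: acceptor at hbond_distance from donor
  acc_r <- TOY_RING_RADIUS + hb
  add("U", 6L, "O4", "O", matrix(acc_r * donor_dirs$U6, 1))
  add("U", 6L, paste0("R", 1:6), rep("C", 6),
      ring_points((acc_r + 1.6) * donor_dirs$U6, TOY_BASE_RADIUS, 6))
  add("U", 6L, "C1'", "C", matrix(c(0, 7.5, 0.8), 1))
  add("C", 15L, "O2", "O", matrix(acc_r * donor_dirs$C15, 1))
  add("C", 15L, paste0("R", 1:6), rep("C", 6),
      ring_points((acc_r + 1.6) * donor_dirs$C15, TOY_BASE_RADIUS, 6))
  add("C", 15L, "C4", "C", matrix(c(0, -(acc_r + 3.2), 0), 1))
  add("C", 15L, "C1'", "C", matrix(c(-3.0, -4.0, -dbw2), 1))
  add("A", 29L, "N1", "N", matrix(acc_r * donor_dirs$A29, 1))
  add("A", 29L, paste0("R", 1:6), rep("C", 6),
      ring_points((acc_r + 1.6) * donor_dirs$A29, TOY_BASE_RADIUS, 6))
  add("A", 29L, "C1'", "C", matrix(c(-4.0, -2.0, 1.5), 1))
  # back-door partner C30 and plane atom carrier A10
  add("C", 30L, paste0("R", 1:6), rep("C", 6),
      ring_points(c(-2.0, -3.5, 1.0), TOY_BASE_RADIUS, 6))
  add("C", 30L, "C1'", "C", matrix(c(-3.0, -4.0, dbw2), 1))
  add("A", 10L, "C1'", "C", matrix(c(0, 2.0, 4.0), 1))
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$segment <- ifelse(atoms$residue_name == "LIG", "LIGAND", "RNA")
  ref <- do.call(rbind, coords)
  colnames(ref) <- c("x", "y", "z")
  top <- topology(atoms)
  top <- attach_parameters(top, toy_parameter_table())
  out <- list(topology = top, reference = ref, spec = spec)
  out$selections <- toy_selections(out)
  class(out) <- "toy_complex"
  out
}

#' @export
print.toy_complex <- function(x, ...) {
  cat(sprintf("toy_complex: %d atoms, plate gap %.2f A, doors %.1f/%.1f A\n",
              n_atoms(x$topology), x$spec$plate_gap,
              x$spec$door_front_width, x$spec$door_back_width))
  invisible(x)
}

#' Standard selections for the toy complex
#'
#' Returns the named atom selections the analysis modules need: ligand ring,
#' stacking plates, H-bond definitions, pocket residues, bisecting-plane
#' atoms, front markers and the named door distances.
#' @param toy a `toy_complex` (the `selections` field is also stored there).
#' @export
toy_selections <- function(toy) {
  n <- toy$spec$ring_atom_count
  pair <- function(resi, name) list(resi, name)
  ring_sel <- function(resi, nm = paste0("R", 1:6))
    lapply(nm, function(a) pair(resi, a))
  list(
    ligand_ring = lapply(paste0("L", seq_len(n)),
                         function(a) pair(100L, a)),
    plates = list(G5 = ring_sel(5L), G11 = ring_sel(11L),
                  C16 = ring_sel(16L)),
    hbonds = list(
      U6 = hbond_definition(pair(100L, "D1"), pair(100L, "HD1"),
                            pair(6L, "O4"), label = "D1-U6:O4"),
      C15 = hbond_definition(pair(100L, "D2"), pair(100L, "HD2"),
                             pair(15L, "O2"), label = "D2-C15:O2"),
      A29 = hbond_definition(pair(100L, "D3"), pair(100L, "HD3"),
                             pair(29L, "N1"), label = "D3-A29:N1")),
    pocket_residues = c(5L, 6L, 11L, 15L, 16L, 30L),
    plane_atoms = list(pair(6L, "C1'"), pair(10L, "C1'"), pair(15L, "C4")),
    front_markers = list(pair(5L, "C1'"), pair(11L, "C1'")),
    distances = list(
      d_15_30 = distance_definition("d_15-30", pair(15L, "C1'"),
                                    pair(30L, "C1'")),
      d_5_11 = distance_definition("d_5-11", pair(5L, "C1'"),
                                   pair(11L, "C1'"))),
    ligand_residue = 100L)
}

#' Bundled toy force-field parameter table
#'
#' Per-element charges, AMBER-style Lennard-Jones parameters and PARSE-like
#' PB radii for every atom name used by [build_toy_complex()].
#' @return data.frame in [read_parameter_table()] layout.
#' @export
toy_parameter_table <- function() {
  by_element <- function(el) {
    switch(el,
           C = c(0.05, 1.908, 0.086, 1.70),
           N = c(-0.30, 1.824, 0.170, 1.50),
           O = c(-0.40, 1.661, 0.210, 1.40),
           H = c(0.25, 0.600, 0.0157, 1.00))
  }
  n_max <- 24L
  atoms <- rbind(
    data.frame(residue_name = "LIG",
               atom_name = c(paste0("L", seq_len(n_max)),
                             "D1", "D2", "D3", "HD1", "HD2", "HD3"),
               element = c(rep("C", n_max), rep("N", 3), rep("H", 3)),
               stringsAsFactors = FALSE),
    data.frame(residue_name = rep(c("G", "C", "U", "A"), each = 9),
               atom_name = rep(c(paste0("R", 1:6), "C1'", "C4", "O4"), 4),
               element = rep(c(rep("C", 6), "C", "C", "O"), 4),
               stringsAsFactors = FALSE),
    data.frame(residue_name = c("C", "U", "A", "A"),
               atom_name = c("O2", "O2", "N1", "N6"),
               element = c("O", "O", "N", "N"), stringsAsFactors = FALSE))
  atoms <- atoms[!duplicated(paste(atoms$residue_name, atoms$atom_name)), ]
  p <- t(vapply(atoms$element, by_element, numeric(4)))
  # donor N on the ligand carries a positive partial charge
  donor <- atoms$residue_name == "LIG" & atoms$atom_name %in%
    c("D1", "D2", "D3")
  p[donor, 1] <- 0.30
  data.frame(residue_name = atoms$residue_name, atom_name = atoms$atom_name,
             charge_e = p[, 1], rmin_half_A = p[, 2], epsilon_kcal = p[, 3],
             pb_radius_A = p[, 4], stringsAsFactors = FALSE, row.names = NULL)
}

#' PARSE-like default PB radii by element
#' @return named numeric vector, Angstrom.
#' @export
parse_like_radii <- function() {
  c(C = 1.70, N = 1.50, O = 1.40, H = 1.00, P = 1.85, S = 1.85,
    MG = 1.45, MN = 1.45, "NA" = 1.85, K = 2.27, CL = 2.27)
}

#' Programmed statistical structure of a synthetic bound trajectory
#'
#' @param stacking_in_fraction named probabilities for the plates
#'   (`G5`, `G11`, `C16`): stationary fraction of frames in the "in" state.
#' @param hbond_occupancy named probabilities for the bonds
#'   (`U6`, `C15`, `A29`).
#' @param positional_noise_sd Gaussian positional noise per coordinate, A.
#' @param state_switch_probability Markov switching scale in (0, 1]; 1 gives
#'   i.i.d. frames, smaller values give autocorrelated states.  The lag-1
#'   state autocorrelation is `1 - state_switch_probability`.
#' @param c15_orthogonal_fraction stationary fraction of frames with the C15
#'   pseudo-base rotated into the orthogonal orientation.
#' @export
occupancy_program <- function(stacking_in_fraction =
                                c(G5 = 0.95, G11 = 0.98, C16 = 0.97),
                              hbond_occupancy =
                                c(U6 = 0.85, C15 = 0.9, A29 = 0.88),
                              positional_noise_sd = 0.1,
                              state_switch_probability = 0.5,
                              c15_orthogonal_fraction = 0) {
  probs <- c(stacking_in_fraction, hbond_occupancy,
             c15_orthogonal_fraction)
  stopifnot(all(probs >= 0 & probs <= 1),
            state_switch_probability > 0, state_switch_probability <= 1,
            positional_noise_sd >= 0)
  structure(list(stacking_in_fraction = stacking_in_fraction,
                 hbond_occupancy = hbond_occupancy,
                 positional_noise_sd = positional_noise_sd,
                 state_switch_probability = state_switch_probability,
                 c15_orthogonal_fraction = c15_orthogonal_fraction),
            class = "occupancy_program")
}

# Two-state Markov chain with stationary P(on) = p and switching scale s:
# P(on->off) = s (1 - p), P(off->on) = s p.  Lag-1 autocorrelation 1 - s.
simulate_markov_chain <- function(p, s, n) {
  if (p == 0) return(rep(FALSE, n))
  if (p == 1) return(rep(TRUE, n))
  state <- logical(n)
  state[1] <- stats::runif(1) < p
  u <- stats::runif(n - 1)
  p_on_off <- s * (1 - p)
  p_off_on <- s * p
  for (i in seq_len(n - 1)) {
    state[i + 1] <- if (state[i]) u[i] >= p_on_off else u[i] < p_off_on
  }
  state
}

#' Simulate a bound-state trajectory with programmed discrete states
#'
#' Each frame is the rigid reference structure plus Gaussian positional
#' noise, with discrete states switched by two-state Markov chains whose
#' stationary occupancies equal the programmed probabilities: a plate that is
#' "out" is displaced laterally beyond the stacking rectangle; a broken
#' hydrogen bond has its acceptor moved beyond the distance cutoff; the C15
#' pseudo-base can flip into an orthogonal orientation.  The ground-truth
#' per-frame state log is returned for parameter-recovery tests.
#'
#' @param toy a `toy_complex` from [build_toy_complex()]
#' @param program an [occupancy_program()]
#' @param n_frames number of frames (>= 1)
#' @param seed integer seed
#' @return list with `trajectory` (a [trajectory()]) and `states`
#'   (data.frame: frame, stack_G5, stack_G11, stack_C16, hbond_U6,
#'   hbond_C15, hbond_A29, c15_orthogonal).
#' @export
simulate_bound_trajectory <- function(toy, program = occupancy_program(),
                                      n_frames = 1000L, seed = 1L) {
  stopifnot(inherits(toy, "toy_complex"), n_frames >= 1)
  set.seed(seed)
  top <- toy$topology
  ref <- toy$reference
  na <- nrow(ref)
  s <- program$state_switch_probability
  chains <- list(
    stack_G5 = simulate_markov_chain(program$stacking_in_fraction[["G5"]],
                                     s, n_frames),
    stack_G11 = simulate_markov_chain(program$stacking_in_fraction[["G11"]],
                                      s, n_frames),
    stack_C16 = simulate_markov_chain(program$stacking_in_fraction[["C16"]],
                                      s, n_frames),
    hbond_U6 = simulate_markov_chain(program$hbond_occupancy[["U6"]],
                                     s, n_frames),
    hbond_C15 = simulate_markov_chain(program$hbond_occupancy[["C15"]],
                                      s, n_frames),
    hbond_A29 = simulate_markov_chain(program$hbond_occupancy[["A29"]],
                                      s, n_frames),
    c15_orthogonal = simulate_markov_chain(program$c15_orthogonal_fraction,
                                           s, n_frames))
  at <- top$atoms
  plate_rings <- list(
    stack_G5 = which(at$residue_index == 5L & at$atom_name %in%
                       paste0("R", 1:6)),
    stack_G11 = which(at$residue_index == 11L & at$atom_name %in%
                        paste0("R", 1:6)),
    stack_C16 = which(at$residue_index == 16L & at$atom_name %in%
                        paste0("R", 1:6)))
  plate_dirs <- list(stack_G5 = c(-1, 0, 0), stack_G11 = c(1, 0, 0),
                     stack_C16 = c(1, 0, 0))
  donor_dirs <- list(hbond_U6 = c(0, 1, 0), hbond_C15 = c(0, -1, 0),
                     hbond_A29 = c(cos(210 * pi / 180),
                                   sin(210 * pi / 180), 0))
  acceptors <- list(
    hbond_U6 = which(at$residue_index == 6L & at$atom_name == "O4"),
    hbond_C15 = which(at$residue_index == 15L & at$atom_name == "O2"),
    hbond_A29 = which(at$residue_index == 29L & at$atom_name == "N1"))
  c15_ring <- which(at$residue_index == 15L & at$atom_name %in%
                      paste0("R", 1:6))
  c15_center <- colMeans(ref[c15_ring, , drop = FALSE])
  shift <- TOY_BROKEN_DISTANCE - toy$spec$hbond_distance
  coords <- array(NA_real_, c(n_frames, na, 3))
  for (f in seq_len(n_frames)) {
    fr <- ref
    for (nm in names(plate_rings)) {
      if (!chains[[nm]][f])
        fr[plate_rings[[nm]], ] <- sweep(fr[plate_rings[[nm]], ,
                                            drop = FALSE], 2,
                                         TOY_OUT_DISPLACEMENT *
                                           plate_dirs[[nm]], "+")
    }
    for (nm in names(acceptors)) {
      if (!chains[[nm]][f])
        fr[acceptors[[nm]], ] <- fr[acceptors[[nm]], ] +
          shift * donor_dirs[[nm]]
    }
    if (chains$c15_orthogonal[f]) {
      # rotate the C15 ring 90 degrees about the x axis through its center
      d <- sweep(fr[c15_ring, , drop = FALSE], 2, c15_center)
      fr[c15_ring, ] <- sweep(cbind(d[, 1], -d[, 3], d[, 2]), 2,
                              c15_center, "+")
    }
    if (program$positional_noise_sd > 0)
      fr <- fr + stats::rnorm(length(fr), sd = program$positional_noise_sd)
    coords[f, , ] <- fr
  }
  states <- data.frame(frame = seq_len(n_frames),
                       do.call(cbind, lapply(chains, as.logical)))
  list(trajectory = trajectory(coords, top), states = states)
}

#' Simulate an ion-occupancy trajectory
#'
#' Each ion, independently per frame, sits at one of the reference sites
#' (plus Gaussian noise) with the programmed probability, or else in bulk
#' (uniform in a box).
#'
#' @param sites reference sites (data.frame with `label`, `x`, `y`, `z`)
#' @param occupancies named per-site probabilities (sum <= 1 per ion);
#'   remainder is bulk.
#' @param n_ions number of ions
#' @param n_frames number of frames
#' @param seed integer seed
#' @param noise_sd positional noise around a site, A (default 0.3)
#' @param box 2 x 3 matrix (rows lo/hi) of the bulk box; default sites
#'   bounding box + 10 A.
#' @return list with `trajectory` (ion-only) and `states` (n_frames x
#'   n_ions matrix of site labels or `"bulk"`).
#' @export
simulate_ion_occupancy <- function(sites, occupancies, n_ions = 1L,
                                   n_frames = 1000L, seed = 1L,
                                   noise_sd = 0.3, box = NULL) {
  stopifnot(nrow(sites) >= 1L, sum(occupancies) <= 1 + 1e-12)
  set.seed(seed)
  sp <- site_positions(sites)
  occupancies <- occupancies[match(sites$label, names(occupancies))]
  occupancies[is.na(occupancies)] <- 0
  if (nrow(sp) > 1L) {
    d <- as.matrix(stats::dist(sp))
    diag(d) <- Inf
    if (min(d) < 2 * noise_sd)
      warning("simulate_ion_occupancy: sites closer than 2x noise sd overlap")
  }
  if (is.null(box)) {
    lo <- apply(sp, 2, min) - 10
    hi <- apply(sp, 2, max) + 10
    box <- rbind(lo, hi)
  }
  atoms <- data.frame(serial = seq_len(n_ions), atom_name = "MG",
                      residue_name = "MG",
                      residue_index = 200L + seq_len(n_ions),
                      segment = "ION", element = "MG",
                      stringsAsFactors = FALSE)
  top <- topology(atoms)
  p_bulk <- 1 - sum(occupancies)
  labels <- c(sites$label, "bulk")
  probs <- c(as.numeric(occupancies), p_bulk)
  coords <- array(NA_real_, c(n_frames, n_ions, 3))
  states <- matrix(NA_character_, n_frames, n_ions)
  for (f in seq_len(n_frames)) {
    for (i in seq_len(n_ions)) {
      k <- sample.int(length(probs), 1L, prob = probs)
      states[f, i] <- labels[k]
      if (k <= nrow(sp)) {
        coords[f, i, ] <- sp[k, ] + stats::rnorm(3, sd = noise_sd)
      } else {
        coords[f, i, ] <- stats::runif(3, box[1, ], box[2, ])
      }
    }
  }
  list(trajectory = trajectory(coords, top), states = states)
}

#' Toy two-channel escape potential
#'
#' A radial bound well at the origin, a barrier ring crossed by two angular
#' channels (front along +x, back along -x) with independent barrier
#' heights, high side walls elsewhere on the ring, and a soft harmonic outer
#' wall that keeps the particle near the pocket.  The channel axis is x, so
#' the signed channel coordinate z of a 2D position is its x component.
#'
#' @param well_depth bound-well depth, kcal/mol
#' @param front_barrier,back_barrier channel barrier heights, kcal/mol
#' @param side_barrier ring height away from the channels, kcal/mol
#' @param channel_half_angle angular half-width of each channel, degrees
#' @param kT thermal energy, kcal/mol (default 0.596, i.e. 300 K)
#' @param well_sd radial width of the well, A
#' @param barrier_radius radius of the barrier ring, A
#' @param barrier_sd radial width of the barrier, A
#' @param wall_radius onset of the soft outer wall, A
#' @param wall_k harmonic wall constant, kcal/mol/A^2
#' @export
toy_potential_spec <- function(well_depth = 5, front_barrier = 3,
                               back_barrier = 5, side_barrier = 12,
                               channel_half_angle = 30, kT = 0.596,
                               well_sd = 1.5, barrier_radius = 4,
                               barrier_sd = 2.0, wall_radius = 11,
                               wall_k = 2) {
  stopifnot(front_barrier > 0, back_barrier > 0, kT > 0)
  structure(list(well_depth = well_depth, front_barrier = front_barrier,
                 back_barrier = back_barrier, side_barrier = side_barrier,
                 channel_half_angle = channel_half_angle, kT = kT,
                 well_sd = well_sd, barrier_radius = barrier_radius,
                 barrier_sd = barrier_sd, wall_radius = wall_radius,
                 wall_k = wall_k), class = "toy_potential_spec")
}

# potential energy and analytic gradient of the 2D toy landscape
toy_potential_eval <- function(pot, x, y) {
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  sg <- pot$channel_half_angle * pi / 180
  ef <- exp(-th^2 / (2 * sg^2))
  eb <- exp(-(pi - abs(th))^2 / (2 * sg^2))
  B <- pot$side_barrier - (pot$side_barrier - pot$front_barrier) * ef -
    (pot$side_barrier - pot$back_barrier) * eb
  dB <- (pot$side_barrier - pot$front_barrier) * (th / sg^2) * ef -
    (pot$side_barrier - pot$back_barrier) *
    ((pi - abs(th)) / sg^2) * sign(th) * eb
  g <- exp(-(r - pot$barrier_radius)^2 / (2 * pot$barrier_sd^2))
  dg <- -((r - pot$barrier_radius) / pot$barrier_sd^2) * g
  # radial window: the angular channel structure (and its torque) vanishes
  # smoothly at the pocket center
  a2 <- pot$well_sd^2
  tw <- r^2 / (r^2 + a2)
  dtw <- 2 * a2 * r / (r^2 + a2)^2
  well <- -pot$well_depth * exp(-r^2 / (2 * pot$well_sd^2))
  dwell <- pot$well_depth * (r / pot$well_sd^2) *
    exp(-r^2 / (2 * pot$well_sd^2))
  over <- pmax(r - pot$wall_radius, 0)
  wall <- 0.5 * pot$wall_k * over^2
  dwall <- pot$wall_k * over
  V <- well + B * g * tw + wall
  dV_dr <- dwell + B * (dg * tw + g * dtw) + dwall
  dV_dth <- dB * g * tw
  if (r < 1e-9) {
    gx <- 0
    gy <- 0
  } else {
    gx <- dV_dr * (x / r) - dV_dth * (y / r^2)
    gy <- dV_dr * (y / r) + dV_dth * (x / r^2)
  }
  list(V = V, gx = gx, gy = gy, r = r)
}

#' Integration / biasing parameters of the toy metadynamics simulator
#'
#' Defaults follow the well-tempered settings used throughout: 0.5 A
#' Gaussian width, 1.2 kcal/mol initial hill height, bias factor 15.  The
#' deposit interval (500 steps) and the overdamped Langevin timestep and
#' diffusion constant are simulator choices; the timestep keeps the step
#' standard deviation at one fifth of the hill width.
#'
#' @param gaussian_width hill width, A
#' @param initial_height initial hill height, kcal/mol
#' @param bias_factor well-tempered bias factor (> 1), dimensionless
#' @param deposit_interval steps between hill deposits
#' @param timestep Langevin timestep, ps
#' @param diffusion diffusion constant, A^2/ps
#' @export
metadynamics_params <- function(gaussian_width = 0.5, initial_height = 1.2,
                                bias_factor = 15, deposit_interval = 500L,
                                timestep = 0.005, diffusion = 1.0) {
  stopifnot(gaussian_width > 0, initial_height > 0, bias_factor > 1,
            deposit_interval >= 1, timestep > 0, diffusion > 0)
  structure(list(gaussian_width = gaussian_width,
                 initial_height = initial_height,
                 bias_factor = bias_factor,
                 deposit_interval = as.integer(deposit_interval),
                 timestep = timestep, diffusion = diffusion),
            class = "metadynamics_params")
}

# linear interpolation of a tabulated function and its derivative
bias_grid_new <- function(lo, hi, spacing) {
  x <- seq(lo, hi, by = spacing)
  list(x = x, lo = lo, spacing = spacing, v = numeric(length(x)),
       dv = numeric(length(x)))
}

bias_grid_lookup <- function(grid, s) {
  i <- (s - grid$lo) / grid$spacing
  i0 <- floor(i)
  f <- i - i0
  i0 <- as.integer(i0) + 1L
  n <- length(grid$x)
  i0 <- min(max(i0, 1L), n - 1L)
  f <- min(max(f, 0), 1)
  c(v = (1 - f) * grid$v[i0] + f * grid$v[i0 + 1L],
    dv = (1 - f) * grid$dv[i0] + f * grid$dv[i0 + 1L])
}

bias_grid_deposit <- function(grid, center, width, height) {
  u <- (grid$x - center) / width
  g <- height * exp(-u^2 / 2)
  grid$v <- grid$v + g
  grid$dv <- grid$dv - (u / width) * g
  grid
}

#' Well-tempered metadynamics of a particle in the two-channel toy potential
#'
#' Overdamped Langevin (Euler-Maruyama) dynamics of a 2D particle, with a
#' history-dependent bias acting on the collective variable r = distance
#' from the origin.  Every `deposit_interval` steps a Gaussian hill of width
#' `gaussian_width` is added at the current r with height
#' `initial_height * exp(-V_bias(r) / ((bias_factor - 1) kT))`.
#'
#' @param potential a [toy_potential_spec()]
#' @param params a [metadynamics_params()]
#' @param n_steps number of integration steps
#' @param seed integer seed
#' @param start 2-vector initial position (default origin = bound state)
#' @return list of class `metad_run`: `trace` (a CV trace with r and the
#'   channel coordinate z = x), `hills` (data.frame step/center/width/
#'   height), `bias` (final bias grid), `xy` (n x 2 positions).
#' @export
simulate_wt_metadynamics <- function(potential = toy_potential_spec(),
                                     params = metadynamics_params(),
                                     n_steps = 20000L, seed = 1L,
                                     start = c(0, 0)) {
  stopifnot(inherits(potential, "toy_potential_spec"),
            inherits(params, "metadynamics_params"))
  set.seed(seed)
  dt <- params$timestep
  D <- params$diffusion
  kT <- potential$kT
  mob <- D / kT
  noise_sd <- sqrt(2 * D * dt)
  max_step <- 5 * params$gaussian_width
  grid <- bias_grid_new(0, potential$wall_radius + 8,
                        params$gaussian_width / 10)
  gamma_fac <- (params$bias_factor - 1) * kT
  x <- start[1]
  y <- start[2]
  xs <- numeric(n_steps)
  ys <- numeric(n_steps)
  rs <- numeric(n_steps)
  hills <- vector("list", n_steps %/% params$deposit_interval + 1L)
  nh <- 0L
  nx <- stats::rnorm(n_steps, sd = noise_sd)
  ny <- stats::rnorm(n_steps, sd = noise_sd)
  for (s in seq_len(n_steps)) {
    ev <- toy_potential_eval(potential, x, y)
    r <- ev$r
    gx <- ev$gx
    gy <- ev$gy
    if (r > 1e-9) {
      b <- bias_grid_lookup(grid, r)
      gx <- gx + b[["dv"]] * (x / r)
      gy <- gy + b[["dv"]] * (y / r)
    }
    dx <- -mob * gx * dt + nx[s]
    dy <- -mob * gy * dt + ny[s]
    if (abs(dx) > max_step || abs(dy) > max_step)
      stop("simulate_wt_metadynamics: divergent integration step; ",
           "reduce the timestep")
    x <- x + dx
    y <- y + dy
    xs[s] <- x
    ys[s] <- y
    rs[s] <- sqrt(x^2 + y^2)
    if (s %% params$deposit_interval == 0L) {
      vb <- bias_grid_lookup(grid, rs[s])[["v"]]
      h <- params$initial_height * exp(-vb / gamma_fac)
      grid <- bias_grid_deposit(grid, rs[s], params$gaussian_width, h)
      nh <- nh + 1L
      hills[[nh]] <- c(step = s, center = rs[s],
                       width = params$gaussian_width, height = h)
    }
  }
  hills <- if (nh > 0) as.data.frame(do.call(rbind, hills[seq_len(nh)]))
           else data.frame(step = numeric(), center = numeric(),
                           width = numeric(), height = numeric())
  structure(list(trace = new_cv_trace(rs, xs, times = dt * seq_len(n_steps)),
                 hills = hills, bias = grid, xy = cbind(xs, ys),
                 potential = potential, params = params),
            class = "metad_run")
}

#' Well-tempered metadynamics on a 1D potential
#'
#' Used for free-energy reconstruction checks: after a long run the
#' converged bias satisfies
#' `F(x) = -(bias_factor / (bias_factor - 1)) V_bias(x) + const`.
#'
#' @param V,dV potential and derivative functions of x (kcal/mol, per A)
#' @param params a [metadynamics_params()]
#' @param n_steps number of steps
#' @param seed integer seed
#' @param kT thermal energy, kcal/mol
#' @param start initial x
#' @param range 2-vector biasing/grid range
#' @return list of class `metad_run_1d`: `x` (trace), `hills`, `bias`.
#' @export
simulate_wt_metadynamics_1d <- function(V, dV,
                                        params = metadynamics_params(),
                                        n_steps = 100000L, seed = 1L,
                                        kT = 0.596, start = -1.5,
                                        range = c(-4, 4)) {
  set.seed(seed)
  dt <- params$timestep
  D <- params$diffusion
  mob <- D / kT
  noise_sd <- sqrt(2 * D * dt)
  max_step <- 5 * params$gaussian_width
  grid <- bias_grid_new(range[1], range[2], params$gaussian_width / 10)
  gamma_fac <- (params$bias_factor - 1) * kT
  x <- start
  xs <- numeric(n_steps)
  hills <- vector("list", n_steps %/% params$deposit_interval + 1L)
  nh <- 0L
  nx <- stats::rnorm(n_steps, sd = noise_sd)
  for (s in seq_len(n_steps)) {
    b <- bias_grid_lookup(grid, x)
    dx <- -mob * (dV(x) + b[["dv"]]) * dt + nx[s]
    if (abs(dx) > max_step)
      stop("simulate_wt_metadynamics_1d: divergent integration step; ",
           "reduce the timestep")
    x <- x + dx
    x <- min(max(x, range[1]), range[2])
    xs[s] <- x
    if (s %% params$deposit_interval == 0L) {
      vb <- bias_grid_lookup(grid, x)[["v"]]
      h <- params$initial_height * exp(-vb / gamma_fac)
      grid <- bias_grid_deposit(grid, x, params$gaussian_width, h)
      nh <- nh + 1L
      hills[[nh]] <- c(step = s, center = x,
                       width = params$gaussian_width, height = h)
    }
  }
  hills <- as.data.frame(do.call(rbind, hills[seq_len(nh)]))
  structure(list(x = xs, hills = hills, bias = grid, params = params,
                 kT = kT), class = "metad_run_1d")
}

#' Reconstruct the free energy from a well-tempered bias
#'
#' `F(s) = -(gamma / (gamma - 1)) V_bias(s)`, shifted to zero minimum.
#' @param run a `metad_run` or `metad_run_1d`
#' @return data.frame with `s` (CV value) and `F` (kcal/mol)
#' @export
reconstruct_free_energy <- function(run) {
  gam <- run$params$bias_factor
  fe <- -(gam / (gam - 1)) * run$bias$v
  data.frame(s = run$bias$x, F = fe - min(fe))
}

#' Symmetric double-well potential
#'
#' `V(x) = barrier ((x/x0)^2 - 1)^2`: minima at +-x0, barrier height
#' `barrier` at x = 0.
#' @param barrier barrier height, kcal/mol
#' @param x0 well position, A
#' @return list with functions `V` and `dV`
#' @export
double_well_potential <- function(barrier = 3, x0 = 1.5) {
  list(V = function(x) barrier * ((x / x0)^2 - 1)^2,
       dV = function(x) barrier * 4 * x * ((x / x0)^2 - 1) / x0^2,
       barrier = barrier, x0 = x0)
}
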