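# MM-PBSA end-state energetics: gas-phase Coulomb and Lennard-Jones
# cross terms, finite-difference Poisson-Boltzmann polar solvation,
# SASA-based nonpolar solvation, quasi-harmonic/QHO entropy terms,
# assembly of the binding free energy, and per-nucleotide decomposition.

COULOMB_K <- 332.0636      # kcal A / (mol e^2), AMBER convention
R_GAS_KCAL <- 1.9872e-3    # kcal / (mol K)

#' Energetics configuration
#'
#' Defaults follow common MM-PBSA practice for nucleic-acid complexes:
#' dielectrics 1/80, 0.4 A PB grid with 5000 linear iterations, a 1.4 A
#' solvent probe, and the nonpolar model gamma * SASA + beta with
#' gamma = 0.00542 kcal/mol/A^2 and beta = 0.92 kcal/mol.
#'
#' @param coulomb_constant kcal A/(mol e^2)
#' @param eps_solute,eps_solvent solute/solvent dielectric constants
#' @param pb_grid_spacing PB grid spacing, A
#' @param pb_iterations fixed number of linear SOR iterations
#' @param pb_relaxation SOR over-relaxation factor
#' @param pb_padding grid padding beyond the molecule, A; `NULL` auto-sizes
#'   to 30% of the molecular extent (with a probe-dependent floor).
#' @param probe_radius solvent probe radius, A
#' @param gamma_np,beta_np nonpolar surface coefficients (kcal/mol/A^2,
#'   kcal/mol)
#' @param temperature K
#' @param sasa_sphere_points sphere points per atom for SASA
#' @export
energetics_config <- function(coulomb_constant = COULOMB_K,
                              eps_solute = 1, eps_solvent = 80,
                              pb_grid_spacing = 0.4, pb_iterations = 5000L,
                              pb_relaxation = 1.9, pb_padding = NULL,
                              probe_radius = 1.4, gamma_np = 0.00542,
                              beta_np = 0.92, temperature = 300,
                              sasa_sphere_points = 960L) {
  stopifnot(pb_grid_spacing > 0, eps_solvent > eps_solute, eps_solute >= 1)
  structure(list(coulomb_constant = coulomb_constant,
                 eps_solute = eps_solute, eps_solvent = eps_solvent,
                 pb_grid_spacing = pb_grid_spacing,
                 pb_iterations = as.integer(pb_iterations),
                 pb_relaxation = pb_relaxation, pb_padding = pb_padding,
                 probe_radius = probe_radius, gamma_np = gamma_np,
                 beta_np = beta_np, temperature = temperature,
                 sasa_sphere_points = as.integer(sasa_sphere_points)),
            class = "energetics_config")
}

cross_distances <- function(coordsA, coordsB) {
  a2 <- rowSums(coordsA^2)
  b2 <- rowSums(coordsB^2)
  d2 <- outer(a2, b2, "+") - 2 * coordsA %*% t(coordsB)
  sqrt(pmax(d2, 0))
}

#' Intermolecular Coulomb energy (no cutoff)
#'
#' `k_C sum_i sum_j q_i q_j / r_ij` over all cross pairs.
#' @param coordsA,coordsB n x 3 coordinate matrices
#' @param chargesA,chargesB partial charges, e
#' @param config an [energetics_config()]
#' @return kcal/mol
#' @export
coulomb_inter <- function(coordsA, chargesA, coordsB, chargesB,
                          config = energetics_config()) {
  r <- cross_distances(as.matrix(coordsA), as.matrix(coordsB))
  if (any(r < 1e-6))
    stop("coulomb_inter: atom pair at near-zero distance (singularity)")
  config$coulomb_constant * sum(outer(chargesA, chargesB) / r)
}

#' Intermolecular Lennard-Jones energy (no cutoff)
#'
#' 12-6 form in Rmin/epsilon parameters with Lorentz-Berthelot combination:
#' `eps_ij [ (R_ij/r)^12 - 2 (R_ij/r)^6 ]`, `R_ij = Rmin/2_i + Rmin/2_j`,
#' `eps_ij = sqrt(eps_i eps_j)`.
#' @param coordsA,coordsB n x 3 coordinate matrices
#' @param rmin_halfA,rmin_halfB Rmin/2 per atom, A
#' @param epsA,epsB epsilon per atom, kcal/mol
#' @param config an [energetics_config()]
#' @return kcal/mol
#' @export
lj_inter <- function(coordsA, rmin_halfA, epsA, coordsB, rmin_halfB, epsB,
                     config = energetics_config()) {
  r <- cross_distances(as.matrix(coordsA), as.matrix(coordsB))
  if (any(r < 1e-6))
    stop("lj_inter: atom pair at near-zero distance (singularity)")
  rij <- outer(rmin_halfA, rmin_halfB, "+")
  eij <- sqrt(outer(epsA, epsB))
  sr6 <- (rij / r)^6
  sum(eij * (sr6^2 - 2 * sr6))
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (sphere-point method)
#'
#' Shrake-Rupley style: each atom's probe-inflated sphere is sampled with a
#' deterministic Fibonacci point set; points inside any neighbour's inflated
#' sphere are buried.
#'
#' @param coords n x 3 coordinate matrix
#' @param radii atomic radii, A (probe added internally)
#' @param config an [energetics_config()] (probe radius, point count)
#' @return list with `total` (A^2) and `per_atom` (A^2 vector)
#' @export
sasa <- function(coords, radii, config = energetics_config()) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(radii) == n, all(radii > 0))
  probe <- config$probe_radius
  pts <- fibonacci_sphere(config$sasa_sphere_points)
  rr <- radii + probe
  per_atom <- numeric(n)
  if (n > 1) {
    d <- as.matrix(stats::dist(coords))
  } else {
    d <- matrix(0, 1, 1)
  }
  for (i in seq_len(n)) {
    sp <- sweep(pts * rr[i], 2, coords[i, ], "+")
    nbr <- which(d[i, ] < rr[i] + rr & seq_len(n) != i)
    acc <- rep(TRUE, nrow(sp))
    for (j in nbr) {
      dj2 <- rowSums(sweep(sp, 2, coords[j, ])^2)
      acc <- acc & dj2 > rr[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * rr[i]^2 * mean(acc)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Nonpolar solvation term
#'
#' `gamma * SASA + beta`.
#' @param sasa_total total SASA, A^2
#' @param config an [energetics_config()]
#' @return kcal/mol
#' @export
nonpolar_term <- function(sasa_total, config = energetics_config()) {
  stopifnot(sasa_total >= 0)
  config$gamma_np * sasa_total + config$beta_np
}

sphere_offsets <- function(radius_vox) {
  h <- ceiling(radius_vox)
  g <- expand.grid(i = -h:h, j = -h:h, k = -h:h)
  keep <- g$i^2 + g$j^2 + g$k^2 <= radius_vox^2
  as.matrix(g[keep, , drop = FALSE])
}

pb_make_grid <- function(coords, radii, config) {
  h <- config$pb_grid_spacing
  lo <- apply(coords - radii, 2, min)
  hi <- apply(coords + radii, 2, max)
  extent <- max(hi - lo)
  pad <- config$pb_padding
  if (is.null(pad)) pad <- max(0.3 * extent, config$probe_radius + 2.0)
  lo <- lo - pad
  hi <- hi + pad
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  list(origin = lo, dims = dims, h = h)
}

pb_solute_mask <- function(coords, radii, grid, config, fdist = NULL) {
  h <- grid$h
  dims <- grid$dims
  mask <- array(FALSE, dims)
  infl <- radii + config$probe_radius
  for (a in seq_len(nrow(coords))) {
    r <- infl[a]
    c0 <- (coords[a, ] - grid$origin) / h
    i0 <- pmax(1L, as.integer(floor(c0 - r / h)) + 1L)
    i1 <- pmin(dims, as.integer(ceiling(c0 + r / h)) + 1L)
    if (any(i0 > i1)) next
    xi <- (i0[1]:i1[1]) - 1
    yi <- (i0[2]:i1[2]) - 1
    zi <- (i0[3]:i1[3]) - 1
    dx2 <- (xi * h + grid$origin[1] - coords[a, 1])^2
    dy2 <- (yi * h + grid$origin[2] - coords[a, 2])^2
    dz2 <- (zi * h + grid$origin[3] - coords[a, 3])^2
    sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <-
      mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] | sub
  }
  # erode the probe-inflated mask back: any node within the probe radius of
  # solvent-accessible space is solvent (on-grid molecular surface).  The
  # discrete erosion is made conservative (over-reaching by half a voxel
  # diagonal) and unioned with the exact van der Waals region so that convex
  # parts of the surface sit exactly at the atom-sphere boundary.
  solvent0 <- !mask
  off <- sphere_offsets((config$probe_radius + h * sqrt(3) / 2) / h)
  near_solvent <- dilate_mask(as.logical(solvent0), as.integer(dims), off)
  solute <- mask & !array(near_solvent, dims)
  if (is.null(fdist)) fdist <- pb_atom_distance(coords, radii, grid)
  solute | (fdist <= 0)
}

trilinear_spread <- function(coords, charges, grid) {
  h <- grid$h
  dims <- grid$dims
  src <- array(0, dims)
  for (a in seq_len(nrow(coords))) {
    c0 <- (coords[a, ] - grid$origin) / h
    i0 <- floor(c0)
    f <- c0 - i0
    i0 <- as.integer(i0) + 1L
    if (any(i0 < 1L) || any(i0 + 1L > dims))
      stop("solve_pb: atom outside grid; enlarge padding")
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      src[i0[1] + dx, i0[2] + dy, i0[3] + dz] <-
        src[i0[1] + dx, i0[2] + dy, i0[3] + dz] + w * charges[a]
    }
  }
  src
}

trilinear_gather <- function(coords, phi, grid) {
  h <- grid$h
  dims <- grid$dims
  vapply(seq_len(nrow(coords)), function(a) {
    c0 <- (coords[a, ] - grid$origin) / h
    i0 <- floor(c0)
    f <- c0 - i0
    i0 <- as.integer(i0) + 1L
    val <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      val <- val + w * phi[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    val
  }, numeric(1))
}

boundary_potential <- function(grid, coords, charges, eps) {
  dims <- grid$dims
  h <- grid$h
  phi <- array(0, dims)
  bnd <- array(FALSE, dims)
  bnd[c(1, dims[1]), , ] <- TRUE
  bnd[, c(1, dims[2]), ] <- TRUE
  bnd[, , c(1, dims[3])] <- TRUE
  idx <- which(bnd, arr.ind = TRUE)
  pos <- sweep((idx - 1) * h, 2, grid$origin, "+")
  for (a in seq_len(nrow(coords))) {
    d <- sqrt(rowSums(sweep(pos, 2, coords[a, ])^2))
    d[d < h] <- h
    phi[bnd] <- phi[bnd] + charges[a] / (eps * d)
  }
  list(phi = phi, fixed = bnd)
}

# signed distance from each grid node to the nearest atom vdW sphere
pb_atom_distance <- function(coords, radii, grid) {
  dims <- grid$dims
  h <- grid$h
  xs <- grid$origin[1] + (seq_len(dims[1]) - 1) * h
  ys <- grid$origin[2] + (seq_len(dims[2]) - 1) * h
  zs <- grid$origin[3] + (seq_len(dims[3]) - 1) * h
  fd <- array(Inf, dims)
  radii <- rep_len(radii, nrow(coords))
  for (a in seq_len(nrow(coords))) {
    d <- sqrt(outer(outer((xs - coords[a, 1])^2, (ys - coords[a, 2])^2,
                          "+"), (zs - coords[a, 3])^2, "+")) - radii[a]
    fd <- pmin(fd, d)
  }
  fd
}

solve_poisson_grid <- function(coords, charges, faces, grid, config,
                               eps_boundary) {
  bp <- boundary_potential(grid, coords, charges, eps_boundary)
  src_q <- trilinear_spread(coords, charges, grid)
  src <- 4 * pi * src_q / grid$h
  phi_vec <- as.double(bp$phi)
  res <- sor_poisson(phi_vec, faces$ex, faces$ey, faces$ez,
                     as.double(src), as.logical(bp$fixed),
                     as.integer(grid$dims), config$pb_relaxation,
                     config$pb_iterations, 100L)
  list(phi = array(phi_vec, grid$dims), residuals = res)
}

#' Polar solvation energy by finite-difference Poisson-Boltzmann
#'
#' Linear PB at zero salt (i.e. the Poisson equation) on a cubic grid:
#' trilinear charge spreading, a molecular-surface (probe-rolled on-grid)
#' dielectric map, a fixed number of SOR sweeps, Dirichlet boundary set to
#' the solvent-screened Coulomb potential, and the reaction-field energy
#' `1/2 sum q_i (phi - phi_vacuum)` with the homogeneous reference solved on
#' the same grid so the grid self-energy cancels.
#'
#' @param coords n x 3 coordinates, A
#' @param charges partial charges, e
#' @param radii PB radii, A
#' @param config an [energetics_config()]
#' @param grid optional explicit grid (list origin/dims/h)
#' @return polar solvation energy, kcal/mol, with attributes `residuals`
#'   (max-update history) and `grid`.
#' @export
solve_pb <- function(coords, charges, radii, config = energetics_config(),
                     grid = NULL) {
  coords <- as.matrix(coords)
  if (all(charges == 0)) return(structure(0, residuals = numeric(),
                                          grid = grid))
  if (is.null(grid)) grid <- pb_make_grid(coords, radii, config)
  radii <- rep_len(radii, nrow(coords))
  fdist <- pb_atom_distance(coords, radii, grid)
  solute <- pb_solute_mask(coords, radii, grid, config, fdist = fdist)
  faces_het <- pb_setup_faces(as.logical(solute), as.double(fdist),
                              as.integer(grid$dims), config$eps_solute,
                              config$eps_solvent)
  het <- solve_poisson_grid(coords, charges, faces_het, grid, config,
                            eps_boundary = config$eps_solvent)
  faces_hom <- pb_setup_faces(as.logical(array(FALSE, grid$dims)),
                              as.double(fdist), as.integer(grid$dims),
                              config$eps_solute, config$eps_solute)
  hom <- solve_poisson_grid(coords, charges, faces_hom, grid, config,
                            eps_boundary = config$eps_solute)
  nres <- length(het$residuals)
  if (nres >= 2 && het$residuals[nres] > het$residuals[1])
    warning("solve_pb: residual growth; solution may not have converged")
  phi_rf <- het$phi - hom$phi
  e <- 0.5 * config$coulomb_constant *
    sum(charges * trilinear_gather(coords, phi_rf, grid))
  structure(e, residuals = het$residuals, grid = grid)
}

#' Polar solvation change on binding
#'
#' `solve_pb(complex) - solve_pb(receptor) - solve_pb(ligand)`, each state
#' on its own auto-sized grid with identical spacing (single-trajectory
#' protocol: shared atoms keep identical coordinates).
#'
#' @param coords complex coordinates (n x 3)
#' @param charges,radii per-atom parameters of the complex
#' @param receptor_idx,ligand_idx index vectors partitioning the atoms
#' @param config an [energetics_config()]
#' @return kcal/mol
#' @export
pb_delta <- function(coords, charges, radii, receptor_idx, ligand_idx,
                     config = energetics_config()) {
  coords <- as.matrix(coords)
  ec <- solve_pb(coords, charges, radii, config)
  er <- solve_pb(coords[receptor_idx, , drop = FALSE],
                 charges[receptor_idx], radii[receptor_idx], config)
  el <- solve_pb(coords[ligand_idx, , drop = FALSE],
                 charges[ligand_idx], radii[ligand_idx], config)
  as.numeric(ec) - as.numeric(er) - as.numeric(el)
}

#' Entropy terms from normal-mode frequencies
#'
#' Vibrational entropy sums quantum-harmonic-oscillator contributions over
#' the supplied (positive) frequencies; translational entropy is
#' Sackur-Tetrode at 1 atm; rotational entropy is the classical rigid rotor
#' from the principal moments of inertia.
#'
#' @param frequencies normal-mode frequencies, cm^-1 (all > 0; drop zero and
#'   imaginary modes before calling)
#' @param mass molecular mass, amu
#' @param principal_moments 3 principal moments of inertia, amu A^2
#' @param config an [energetics_config()] (temperature)
#' @param symmetry_number rotational symmetry number (default 1)
#' @return list with `TS_vib`, `TS_trans`, `TS_rot`, `TS_total` (kcal/mol)
#'   and the corresponding entropies `S_*` (kcal/mol/K)
#' @export
entropy_terms <- function(frequencies, mass, principal_moments,
                          config = energetics_config(),
                          symmetry_number = 1) {
  if (any(frequencies <= 0))
    stop("entropy_terms: frequencies must be positive")
  T <- config$temperature
  hc_over_k <- 1.43877688          # cm K
  x <- hc_over_k * frequencies / T # hbar omega / kT per mode
  s_vib <- R_GAS_KCAL * sum(x / (exp(x) - 1) - log(1 - exp(-x)))
  # Sackur-Tetrode, 1 atm
  kB <- 1.380649e-23
  hP <- 6.62607015e-34
  amu <- 1.66053906660e-27
  m <- mass * amu
  P <- 101325
  q_trans <- (2 * pi * m * kB * T / hP^2)^1.5 * kB * T / P
  s_trans <- R_GAS_KCAL * (log(q_trans) + 2.5)
  # rigid rotor (nonlinear)
  I <- principal_moments * amu * 1e-20    # kg m^2
  theta <- (hP / (2 * pi))^2 / (2 * I * kB)
  s_rot <- R_GAS_KCAL *
    (log(sqrt(pi) / symmetry_number * sqrt(prod(T / theta))) + 1.5)
  list(TS_vib = T * s_vib, TS_trans = T * s_trans, TS_rot = T * s_rot,
       TS_total = T * (s_vib + s_trans + s_rot),
       S_vib = s_vib, S_trans = s_trans, S_rot = s_rot)
}

#' Assemble MM-PBSA binding free energy with replicate statistics
#'
#' Per replicate, frame-wise components are averaged; across replicates the
#' mean and SEM (SD / sqrt(n)) are reported.  The enthalpy is the sum of the
#' four enthalpic components and the binding free energy is
#' `dG_bind = dH - TdS`.
#'
#' @param components list with one element per replicate, each a data.frame
#'   (rows = frames) with columns `dE_ele`, `dE_vdW`, `dG_pol`, `dG_nonpol`.
#' @param TdS numeric vector of T*dS per replicate (kcal/mol); recycled if
#'   length 1.
#' @param config an [energetics_config()]
#' @return object of class `energy_components`: data.frame with one row per
#'   term (`dE_ele`, `dE_vdW`, `dG_pol`, `dG_nonpol`, `dH`, `TdS`,
#'   `dG_bind`) and columns `mean`, `sem`, `n`.
#' @export
mmpbsa_summary <- function(components, TdS,
                           config = energetics_config()) {
  if (is.data.frame(components)) components <- list(components)
  n_rep <- length(components)
  if (n_rep < 1L) stop("mmpbsa_summary: need at least one replicate")
  terms <- c("dE_ele", "dE_vdW", "dG_pol", "dG_nonpol")
  rep_means <- t(vapply(components, function(df) {
    if (nrow(df) == 0L) stop("mmpbsa_summary: replicate with zero frames")
    miss <- setdiff(terms, names(df))
    if (length(miss) > 0L)
      stop("mmpbsa_summary: missing components: ",
           paste(miss, collapse = ", "))
    colMeans(df[, terms, drop = FALSE])
  }, numeric(4)))
  TdS <- rep_len(as.numeric(TdS), n_rep)
  dH <- rowSums(rep_means)
  dG <- dH - TdS
  all_terms <- cbind(rep_means, dH = dH, TdS = TdS, dG_bind = dG)
  sem <- function(v) if (n_rep > 1) stats::sd(v) / sqrt(n_rep) else NA_real_
  out <- data.frame(term = colnames(all_terms),
                    mean = colMeans(all_terms),
                    sem = apply(all_terms, 2, sem),
                    n = n_rep, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("energy_components", "data.frame")
  out
}

#' Extract a term from an energy-components table
#' @param x `energy_components` object
#' @param term term name (e.g. `"dG_bind"`)
#' @export
energy_term <- function(x, term) x$mean[match(term, x$term)]

#' Per-residue decomposition of the enthalpic binding components
#'
#' Electrostatic and van der Waals terms are decomposed exactly by pairwise
#' assignment: each receptor residue receives the sum of its cross pairs
#' with the ligand, so per-residue sums reproduce the totals.  The nonpolar
#' term is decomposed through per-atom SASA differences (complex minus
#' separated states) scaled by gamma; the `beta - ...` constant of the
#' nonpolar model is assigned to the ligand row.  Optionally the polar PB
#' term is decomposed by charge annihilation (zero one residue's charges and
#' re-solve), an approximation that does not sum exactly to the total.
#'
#' @param top parameterized complex [topology()]
#' @param coords single frame (n x 3) or frame array (n_frames x n x 3);
#'   frames are averaged.
#' @param config an [energetics_config()]
#' @param include_pol also decompose dG_pol by charge annihilation (slow)
#' @return data.frame: `residue_index`, `residue_name`, `dE_ele`, `dE_vdW`,
#'   `dG_nonpol`, (`dG_pol`,) `total`; the ligand appears as its own row.
#' @export
per_residue_decomposition <- function(top, coords,
                                      config = energetics_config(),
                                      include_pol = FALSE) {
  if (length(dim(coords)) == 3L) {
    frames <- lapply(seq_len(dim(coords)[1]), function(f) {
      m <- coords[f, , , drop = FALSE]
      dim(m) <- dim(m)[2:3]
      m
    })
  } else {
    frames <- list(as.matrix(coords))
  }
  at <- top$atoms
  il <- which(at$segment == "LIGAND")
  ir <- which(at$segment == "RNA")
  if (length(il) == 0L || length(ir) == 0L)
    stop("per_residue_decomposition: need LIGAND and RNA segments")
  res_idx <- sort(unique(at$residue_index[ir]))
  acc <- NULL
  for (fr in frames) {
    r <- cross_distances(fr[ir, , drop = FALSE], fr[il, , drop = FALSE])
    qq <- outer(at$charge[ir], at$charge[il])
    ele_pair <- config$coulomb_constant * qq / r
    rij <- outer(at$lj_rmin_half[ir], at$lj_rmin_half[il], "+")
    eij <- sqrt(outer(at$lj_epsilon[ir], at$lj_epsilon[il]))
    sr6 <- (rij / r)^6
    vdw_pair <- eij * (sr6^2 - 2 * sr6)
    ele_res <- vapply(res_idx, function(ri)
      sum(ele_pair[at$residue_index[ir] == ri, , drop = FALSE]),
      numeric(1))
    vdw_res <- vapply(res_idx, function(ri)
      sum(vdw_pair[at$residue_index[ir] == ri, , drop = FALSE]),
      numeric(1))
    # nonpolar via per-atom SASA differences
    radii <- at$pb_radius
    s_cplx <- sasa(fr, radii, config)$per_atom
    s_rec <- sasa(fr[ir, , drop = FALSE], radii[ir], config)$per_atom
    s_lig <- sasa(fr[il, , drop = FALSE], radii[il], config)$per_atom
    dsasa <- numeric(nrow(at))
    dsasa[ir] <- s_cplx[ir] - s_rec
    dsasa[il] <- s_cplx[il] - s_lig
    np_res <- vapply(res_idx, function(ri)
      config$gamma_np * sum(dsasa[at$residue_index == ri &
                                    at$segment == "RNA"]), numeric(1))
    np_lig <- config$gamma_np * sum(dsasa[il]) - config$beta_np
    row <- cbind(dE_ele = c(ele_res, sum(ele_pair) - sum(ele_res)),
                 dE_vdW = c(vdw_res, sum(vdw_pair) - sum(vdw_res)),
                 dG_nonpol = c(np_res, np_lig))
    acc <- if (is.null(acc)) row else acc + row
  }
  acc <- acc / length(frames)
  out <- data.frame(residue_index = c(res_idx, NA),
                    residue_name = c(at$residue_name[
                      match(res_idx, at$residue_index)], "LIG"),
                    acc, stringsAsFactors = FALSE, row.names = NULL)
  if (include_pol) {
    radii <- at$pb_radius
    pol_res <- numeric(nrow(out))
    fr <- frames[[1]]
    full <- pb_delta(fr, at$charge, radii, ir, il, config)
    for (k in seq_along(res_idx)) {
      q0 <- at$charge
      q0[at$residue_index == res_idx[k] & at$segment == "RNA"] <- 0
      pol_res[k] <- full - pb_delta(fr, q0, radii, ir, il, config)
    }
    q0 <- at$charge
    q0[il] <- 0
    pol_res[length(pol_res)] <- full - pb_delta(fr, q0, radii, ir, il,
                                                config)
    out$dG_pol <- pol_res
  }
  out$total <- rowSums(out[, intersect(c("dE_ele", "dE_vdW", "dG_nonpol",
                                         "dG_pol"), names(out))])
  out
}

#' Binding free energy from a dissociation constant
#'
#' `dG = R T ln(KD)` with R = 1.9872e-3 kcal/(mol K).
#' @param kd dissociation constant, molar (> 0)
#' @param temperature K (default 300)
#' @return kcal/mol
#' @export
dg_from_kd <- function(kd, temperature = 300) {
  if (any(kd <= 0)) stop("dg_from_kd: kd must be positive")
  R_GAS_KCAL * temperature * log(kd)
}
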