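# Pocket geometry: named distances, pocket frame (center + bisecting plane),
# (r, z) and Theta collective variables, 2D CV density maps, 3D grid
# densities and reference-site occupancies.

#' Define a named interatomic distance
#'
#' @param label e.g. `"d_15-30"`
#' @param a,b `(residue_index, atom_name)` pairs; must differ.
#' @export
distance_definition <- function(label, a, b) {
  if (identical(a, b)) stop("distance_definition: A and B must differ")
  structure(list(label = label, a = a, b = b), class = "distance_definition")
}

#' Per-frame distance series with summary statistics
#'
#' @param traj a [trajectory()]
#' @param def a [distance_definition()]
#' @param bin_width histogram bin width, Angstrom (default 0.2); the
#'   histogram is normalized to unit area.
#' @return list with `label`, `series`, `times`, `mean`, `sd`, `histogram`
#'   (data.frame mid/density).
#' @export
distance_series <- function(traj, def, bin_width = 0.2) {
  ia <- resolve_atom(traj$topology, def$a[[1]], def$a[[2]])
  ib <- resolve_atom(traj$topology, def$b[[1]], def$b[[2]])
  dxyz <- traj$coords[, ia, , drop = FALSE] - traj$coords[, ib, , drop = FALSE]
  d <- sqrt(rowSums(matrix(dxyz, nrow = n_frames(traj))^2))
  lo <- floor(min(d) / bin_width) * bin_width - 1e-9
  nb <- max(1L, as.integer(ceiling((max(d) - lo) / bin_width))) + 1L
  breaks <- lo + (0:nb) * bin_width
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(label = def$label, series = d, times = traj$times,
       mean = mean(d), sd = stats::sd(d),
       histogram = data.frame(mid = h$mids, density = h$density))
}

#' Pocket frame: center, bisecting plane and front-positive normal
#'
#' The pocket center is the geometric center of the heavy atoms of the
#' pocket-lining residues.  The bisecting plane passes through three named
#' atoms; its unit normal is the z-axis, with sign fixed so that the midpoint
#' of the front-marker atoms has z > 0 (the "front" of the pocket).
#'
#' @param frame n_atoms x 3 coordinate matrix
#' @param top the matching [topology()]
#' @param pocket_residues author residue indices lining the pocket
#' @param plane_atoms selection of exactly 3 atoms defining the plane
#' @param front_markers selection of atoms whose midpoint defines "front"
#' @return list of class `pocket_frame`: `pocket_center`, `plane_origin`
#'   (centroid of the plane atoms), `normal`.
#' @export
pocket_frame <- function(frame, top, pocket_residues, plane_atoms,
                         front_markers) {
  ip <- resolve_selection(top, plane_atoms)
  if (length(ip) != 3L) stop("pocket_frame: plane_atoms must name 3 atoms")
  p <- frame[ip, , drop = FALSE]
  v1 <- p[2, ] - p[1, ]
  v2 <- p[3, ] - p[1, ]
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-9 * max(sqrt(sum(v1^2)) * sqrt(sum(v2^2)), 1e-12))
    stop("pocket_frame: plane atoms are colinear")
  nrm <- nrm / nn
  origin <- colMeans(p)
  ih <- heavy_atoms_of(top, pocket_residues)
  if (length(ih) == 0L) stop("pocket_frame: no heavy atoms in pocket residues")
  center <- colMeans(frame[ih, , drop = FALSE])
  im <- resolve_selection(top, front_markers)
  mz <- sum((colMeans(frame[im, , drop = FALSE]) - origin) * nrm)
  if (abs(mz) < 1e-9)
    stop("pocket_frame: front marker lies in the bisecting plane; ",
         "supply an explicit orientation")
  if (mz < 0) nrm <- -nrm
  structure(list(pocket_center = center, plane_origin = origin,
                 normal = nrm), class = "pocket_frame")
}

#' (r, z) collective-variable trace of the ligand over a trajectory
#'
#' r is the distance from the ligand geometric center (heavy atoms) to the
#' pocket center; z is the signed coordinate of the ligand center along the
#' bisecting-plane normal.  The pocket frame is recomputed every frame (the
#' analysis is in the aptamer's moving frame).
#'
#' @param traj a [trajectory()]
#' @param ligand_residues author residue indices of the ligand (heavy atoms
#'   define its center); alternatively pass `ligand_sel` directly.
#' @param pocket_residues,plane_atoms,front_markers as in [pocket_frame()]
#' @param ligand_sel optional explicit atom selection for the ligand center.
#' @return object of class `cv_trace`: data.frame-like list with `r`, `z`,
#'   `times`.
#' @export
cv_trace <- function(traj, ligand_residues = NULL, pocket_residues,
                     plane_atoms, front_markers, ligand_sel = NULL) {
  top <- traj$topology
  il <- if (!is.null(ligand_sel)) resolve_selection(top, ligand_sel)
        else heavy_atoms_of(top, ligand_residues)
  if (length(il) == 0L) stop("cv_trace: empty ligand selection")
  nf <- n_frames(traj)
  r <- numeric(nf)
  z <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    pf <- pocket_frame(fr, top, pocket_residues, plane_atoms, front_markers)
    lc <- colMeans(fr[il, , drop = FALSE])
    r[f] <- sqrt(sum((lc - pf$pocket_center)^2))
    z[f] <- sum((lc - pf$plane_origin) * pf$normal)
  }
  new_cv_trace(r, z, traj$times)
}

#' Construct a CV trace directly
#' @param r,z numeric vectors (equal length); r >= 0.
#' @param times frame times, ps.
#' @export
new_cv_trace <- function(r, z, times = seq_along(r) - 1) {
  stopifnot(length(r) == length(z), length(r) == length(times), all(r >= 0))
  structure(list(r = as.numeric(r), z = as.numeric(z),
                 times = as.numeric(times)), class = "cv_trace")
}

#' @export
print.cv_trace <- function(x, ...) {
  cat(sprintf("cv_trace: %d frames, r in [%.2f, %.2f] A, z in [%.2f, %.2f] A\n",
              length(x$r), min(x$r), max(x$r), min(x$z), max(x$z)))
  invisible(x)
}

#' Average inter-plane angle Theta between two groups of nucleobases
#'
#' Fits a least-squares plane to each base's ring atoms and returns the mean
#' over all cross-group pairs of the acute angle between plane normals
#' (range 0..90 degrees).
#'
#' @param frame n_atoms x 3 coordinate matrix
#' @param top the matching [topology()]
#' @param group1,group2 lists of selections, one per base (each a list of
#'   `(residue_index, atom_name)` pairs resolving to >= 3 ring atoms).
#' @return angle in degrees
#' @export
theta_angle <- function(frame, top, group1, group2) {
  norm1 <- lapply(group1, function(sel)
    fit_plane(frame[resolve_selection(top, sel), , drop = FALSE])$normal)
  norm2 <- lapply(group2, function(sel)
    fit_plane(frame[resolve_selection(top, sel), , drop = FALSE])$normal)
  angs <- outer(seq_along(norm1), seq_along(norm2),
                Vectorize(function(i, j) {
                  c <- abs(sum(norm1[[i]] * norm2[[j]]))
                  acos(pmin(1, c)) * 180 / pi
                }))
  mean(angs)
}

#' 2D density map over two collective-variable series
#'
#' Histogram normalized to unit mass.  The peak is the center of the maximum
#' bin; ties are broken by lowest x then lowest y bin.
#'
#' @param x,y numeric series of equal length
#' @param bins number of bins per axis (default 50), or a list
#'   `list(x = breaks, y = breaks)` of explicit break vectors.
#' @return list with `x_mid`, `y_mid`, `density` (matrix, rows = x bins),
#'   `peak` (c(x, y) bin centers).
#' @export
cv_density_map <- function(x, y, bins = 50) {
  stopifnot(length(x) == length(y))
  if (is.list(bins)) {
    bx <- bins$x
    by <- bins$y
  } else {
    pad <- function(v) {
      r <- range(v)
      if (diff(r) == 0) r <- r + c(-0.5, 0.5)
      seq(r[1] - 1e-9, r[2] + 1e-9, length.out = bins + 1L)
    }
    bx <- pad(x)
    by <- pad(y)
  }
  ix <- findInterval(x, bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, by, rightmost.closed = TRUE, all.inside = TRUE)
  dens <- matrix(0, length(bx) - 1L, length(by) - 1L)
  for (k in seq_along(ix)) dens[ix[k], iy[k]] <- dens[ix[k], iy[k]] + 1
  dens <- dens / sum(dens)
  xm <- (bx[-1] + bx[-length(bx)]) / 2
  ym <- (by[-1] + by[-length(by)]) / 2
  mx <- max(dens)
  hits <- which(dens == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  peak <- c(xm[hits[1, 1]], ym[hits[1, 2]])
  list(x_mid = xm, y_mid = ym, density = dens, peak = peak)
}

gaussian_kernel_1d <- function(sd_vox) {
  half <- max(1L, ceiling(4 * sd_vox))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sd_vox^2))
  k / sum(k)
}

convolve_axis <- function(arr, kernel, axis) {
  # full zero-padded convolution along one axis; output grows by the kernel
  # overhang so that total mass is conserved exactly
  half <- (length(kernel) - 1L) %/% 2L
  d <- dim(arr)
  dn <- d
  dn[axis] <- d[axis] + 2L * half
  out <- array(0, dn)
  idx <- function(n) seq_len(n)
  for (o in seq_along(kernel)) {
    w <- kernel[o]
    if (w == 0) next
    src <- idx(d[axis])
    dst <- src + (o - 1L)
    sl_src <- list(idx(dn[1]), idx(dn[2]), idx(dn[3]))
    sl_dst <- sl_src
    sl_src[[axis]] <- src
    sl_dst[[axis]] <- dst
    pre <- list(idx(d[1]), idx(d[2]), idx(d[3]))
    pre[[axis]] <- src
    out[sl_dst[[1]], sl_dst[[2]], sl_dst[[3]]] <-
      out[sl_dst[[1]], sl_dst[[2]], sl_dst[[3]]] +
      w * arr[pre[[1]], pre[[2]], pre[[3]]]
  }
  out
}

#' 3D spatial density of selected atoms on a regular grid
#'
#' Counts selected-atom positions per voxel over all frames.  Positions that
#' fall outside the grid are dropped and tallied in `overflow`, so that
#' `sum(counts) + overflow == n_frames * n_particles`.
#'
#' @param traj a [trajectory()]
#' @param selection atom selection ([resolve_selection()] input) or integer
#'   atom indices.
#' @param spacing voxel edge, Angstrom (default 0.5)
#' @param smoothing_sd optional Gaussian smoothing, Angstrom (0 = none).
#'   Smoothing expands the grid by the kernel half-width so that total mass
#'   is conserved.
#' @param origin,dims optional explicit grid (origin = corner node, dims =
#'   voxel counts); default auto-sizes to the bounding box + 3 A padding.
#' @return object of class `grid_density`: `origin`, `spacing`, `counts`
#'   (3D array), `overflow`, `n_frames`, `n_particles`.
#' @export
grid_density <- function(traj, selection, spacing = 0.5, smoothing_sd = 0,
                         origin = NULL, dims = NULL) {
  isel <- if (is.numeric(selection)) as.integer(selection)
          else resolve_selection(traj$topology, selection)
  if (length(isel) == 0L) stop("grid_density: empty selection")
  nf <- n_frames(traj)
  pos <- matrix(aperm(traj$coords[, isel, , drop = FALSE], c(2, 1, 3)),
                ncol = 3)
  if (is.null(origin) || is.null(dims)) {
    lo <- apply(pos, 2, min) - 3
    hi <- apply(pos, 2, max) + 3
    origin <- lo
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  }
  iv <- floor(sweep(pos, 2, origin) / spacing) + 1L
  inside <- iv[, 1] >= 1L & iv[, 1] <= dims[1] &
            iv[, 2] >= 1L & iv[, 2] <= dims[2] &
            iv[, 3] >= 1L & iv[, 3] <= dims[3]
  counts <- array(0, dims)
  if (any(inside)) {
    lin <- (iv[inside, 3] - 1L) * dims[1] * dims[2] +
           (iv[inside, 2] - 1L) * dims[1] + iv[inside, 1]
    tab <- tabulate(lin, nbins = prod(dims))
    counts[] <- tab
  }
  overflow <- sum(!inside)
  if (smoothing_sd > 0) {
    k <- gaussian_kernel_1d(smoothing_sd / spacing)
    half <- (length(k) - 1L) %/% 2L
    for (ax in 1:3) counts <- convolve_axis(counts, k, ax)
    origin <- origin - half * spacing
  }
  structure(list(origin = origin, spacing = spacing, counts = counts,
                 overflow = overflow, n_frames = nf,
                 n_particles = length(isel)),
            class = "grid_density")
}

#' @export
print.grid_density <- function(x, ...) {
  cat(sprintf("grid_density: %s voxels @ %.2f A, mass %.4g (+%d overflow)\n",
              paste(dim(x$counts), collapse = "x"), x$spacing,
              sum(x$counts), x$overflow))
  invisible(x)
}

#' Local density peaks (26-neighbor maxima)
#'
#' @param density a [grid_density()]
#' @param threshold_frac keep peaks above this fraction of the global
#'   maximum (default 0.5).
#' @return matrix of peak positions (voxel centers), one row per peak,
#'   ordered by decreasing density.
#' @export
density_peaks <- function(density, threshold_frac = 0.5) {
  cnt <- density$counts
  d <- dim(cnt)
  thr <- threshold_frac * max(cnt)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- cnt
  is_max <- array(TRUE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- pad[(2:(d[1] + 1L)) + dx, (2:(d[2] + 1L)) + dy,
              (2:(d[3] + 1L)) + dz]
    is_max <- is_max & (cnt >= nb)
  }
  sel <- which(is_max & cnt >= thr & cnt > 0, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(matrix(numeric(), 0, 3))
  vals <- cnt[sel]
  sel <- sel[order(-vals), , drop = FALSE]
  sweep((sel - 0.5) * density$spacing, 2, density$origin, "+")
}

#' Per-site occupancy of reference sites by selected atoms
#'
#' For each reference site, the fraction of frames in which at least one
#' selected atom lies within `radius`; also reports the distance from the
#' site to the nearest density peak (see [density_peaks()]).
#'
#' @param traj a [trajectory()]
#' @param selection atom selection or integer indices
#' @param sites reference sites (data.frame with `label`, `x`, `y`, `z`)
#' @param radius occupancy radius, Angstrom (default 2)
#' @param spacing grid spacing for the peak analysis (default 0.5)
#' @param threshold_frac peak threshold (default 0.5)
#' @return data.frame: `label`, `x`, `y`, `z`, `occupancy`,
#'   `nearest_peak_distance`.
#' @export
site_occupancy <- function(traj, selection, sites, radius = 2.0,
                           spacing = 0.5, threshold_frac = 0.5) {
  if (nrow(sites) == 0L) stop("site_occupancy: sites must be non-empty")
  isel <- if (is.numeric(selection)) as.integer(selection)
          else resolve_selection(traj$topology, selection)
  nf <- n_frames(traj)
  sp <- site_positions(sites)
  occ <- numeric(nrow(sp))
  for (s in seq_len(nrow(sp))) {
    hit <- logical(nf)
    for (f in seq_len(nf)) {
      fr <- traj$coords[f, isel, , drop = FALSE]
      dim(fr) <- c(length(isel), 3)
      d2 <- rowSums(sweep(fr, 2, sp[s, ])^2)
      hit[f] <- any(d2 <= radius^2)
    }
    occ[s] <- mean(hit)
  }
  dens <- grid_density(traj, isel, spacing = spacing)
  pk <- density_peaks(dens, threshold_frac = threshold_frac)
  npd <- vapply(seq_len(nrow(sp)), function(s) {
    if (nrow(pk) == 0L) return(NA_real_)
    min(sqrt(rowSums(sweep(pk, 2, sp[s, ])^2)))
  }, numeric(1))
  data.frame(label = sites$label, x = sp[, 1], y = sp[, 2], z = sp[, 3],
             occupancy = occ, nearest_peak_distance = npd,
             stringsAsFactors = FALSE, row.names = NULL)
}
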