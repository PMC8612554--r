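# Geometric classification of base stacking (rectangle-projection metric)
# and hydrogen bonds, with occupancy summaries over trajectories.

#' Resolve an atom by author residue index and atom name
#'
#' @param top a [topology()]
#' @param residue_index 1-based author residue number
#' @param atom_name atom name string
#' @return integer row index into `top$atoms`
#' @export
resolve_atom <- function(top, residue_index, atom_name) {
  i <- which(top$atoms$residue_index == residue_index &
               top$atoms$atom_name == atom_name)
  if (length(i) != 1L)
    stop(sprintf("cannot resolve atom (%s, %s) in topology",
                 residue_index, atom_name))
  i
}

#' Resolve a list of (residue_index, atom_name) pairs
#' @param top a [topology()]
#' @param sel list of 2-element vectors/lists `(residue_index, atom_name)`,
#'   or a data.frame with columns `residue_index`, `atom_name`.
#' @return integer vector of atom row indices
#' @export
resolve_selection <- function(top, sel) {
  if (is.data.frame(sel)) {
    return(vapply(seq_len(nrow(sel)), function(i)
      resolve_atom(top, sel$residue_index[i], sel$atom_name[i]), integer(1)))
  }
  vapply(sel, function(p)
    resolve_atom(top, as.integer(p[[1]]), as.character(p[[2]])), integer(1))
}

#' Indices of the heavy (non-hydrogen) atoms of given residues
#' @param top a [topology()]
#' @param residue_indices author residue numbers
#' @export
heavy_atoms_of <- function(top, residue_indices) {
  which(top$atoms$residue_index %in% residue_indices &
          top$atoms$element != "H")
}

#' Least-squares plane through a set of points
#'
#' @param points n x 3 matrix, n >= 3, not colinear.
#' @param reference_up optional 3-vector; the normal is flipped so that
#'   `normal . reference_up >= 0`.
#' @return list with `normal` (unit 3-vector), `centroid`, and `axes`
#'   (3 x 2 matrix of in-plane principal axes, ordered by decreasing spread).
#' @export
fit_plane <- function(points, reference_up = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("fit_plane: need at least 3 points")
  ctr <- colMeans(points)
  d <- sweep(points, 2, ctr)
  sv <- svd(d)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("fit_plane: points are colinear or degenerate")
  normal <- sv$v[, 3]
  if (!is.null(reference_up) && sum(normal * reference_up) < 0)
    normal <- -normal
  list(normal = normal, centroid = ctr, axes = sv$v[, 1:2, drop = FALSE])
}

#' Classify the stacking state of a nucleobase against the ligand rings
#'
#' Fits the ligand-ring plane, projects the ligand ring atoms into it, draws
#' the bounding rectangle in the in-plane principal-axis frame expanded by
#' `margin` on every side, and tests whether the projection of the base-ring
#' geometric center falls inside ("in") or outside ("out").  A projection
#' exactly on the rectangle edge counts as "in".
#'
#' @param ligand_ring n x 3 matrix of ligand ring-atom coordinates (n >= 3).
#' @param base_ring m x 3 matrix of base ring-atom coordinates.
#' @param margin rectangle expansion per side, Angstrom (default 0.5).
#' @return list with `flag` ("in"/"out") and `vertical_distance` (Angstrom,
#'   unsigned distance of the base center from the ligand plane).
#' @export
stacking_state <- function(ligand_ring, base_ring, margin = 0.5) {
  ligand_ring <- as.matrix(ligand_ring)
  base_ring <- as.matrix(base_ring)
  pl <- fit_plane(ligand_ring)
  d <- sweep(ligand_ring, 2, pl$centroid)
  uv <- d %*% pl$axes                      # in-plane coordinates of ring atoms
  lo <- apply(uv, 2, min) - margin
  hi <- apply(uv, 2, max) + margin
  bc <- colMeans(base_ring)
  bd <- bc - pl$centroid
  buv <- as.vector(bd %*% pl$axes)
  inside <- buv[1] >= lo[1] && buv[1] <= hi[1] &&
            buv[2] >= lo[2] && buv[2] <= hi[2]
  vdist <- abs(sum(bd * pl$normal))
  list(flag = if (inside) "in" else "out", vertical_distance = vdist)
}

#' Rectangle corners used by the stacking metric
#'
#' Returns the 4 corners (in 3D) of the margin-expanded rectangle around the
#' projected ligand ring atoms.  Exposed for visual checking and for
#' independent point-in-polygon verification.
#' @inheritParams stacking_state
#' @export
stacking_rectangle <- function(ligand_ring, margin = 0.5) {
  pl <- fit_plane(as.matrix(ligand_ring))
  d <- sweep(as.matrix(ligand_ring), 2, pl$centroid)
  uv <- d %*% pl$axes
  lo <- apply(uv, 2, min) - margin
  hi <- apply(uv, 2, max) + margin
  corners_uv <- rbind(c(lo[1], lo[2]), c(hi[1], lo[2]),
                      c(hi[1], hi[2]), c(lo[1], hi[2]))
  corners <- sweep(corners_uv %*% t(pl$axes), 2, pl$centroid, "+")
  list(corners = corners, corners_uv = corners_uv, plane = pl)
}

#' Per-trajectory stacking summary (in-fraction and vertical distance)
#'
#' Applies [stacking_state()] to every frame.  `mean_vertical_distance_in` is
#' averaged over "in" frames only, and is `NA` (with `n_in = 0`) when no
#' frame is "in".
#'
#' @param traj a [trajectory()]
#' @param ligand_ring_sel selection (see [resolve_selection()]) of the ligand
#'   ring atoms.
#' @param base_sel selection of the nucleobase ring atoms.
#' @param margin rectangle margin, Angstrom.
#' @return list of class `stacking_result`: per-frame `flag`,
#'   `vertical_distance`, and summary fields `in_fraction`,
#'   `mean_vertical_distance_in`, `n_in`, `n_frames`.
#' @export
stacking_summary <- function(traj, ligand_ring_sel, base_sel, margin = 0.5) {
  nf <- n_frames(traj)
  if (nf < 1L) stop("stacking_summary: empty trajectory")
  il <- resolve_selection(traj$topology, ligand_ring_sel)
  ib <- resolve_selection(traj$topology, base_sel)
  flags <- character(nf)
  vdist <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    st <- stacking_state(fr[il, , drop = FALSE], fr[ib, , drop = FALSE],
                         margin = margin)
    flags[f] <- st$flag
    vdist[f] <- st$vertical_distance
  }
  n_in <- sum(flags == "in")
  structure(list(flag = flags, vertical_distance = vdist,
                 in_fraction = n_in / nf,
                 mean_vertical_distance_in =
                   if (n_in > 0) mean(vdist[flags == "in"]) else NA_real_,
                 n_in = n_in, n_frames = nf),
            class = "stacking_result")
}

#' @export
print.stacking_result <- function(x, ...) {
  cat(sprintf("stacking: in-fraction %.3f (%d/%d frames), mean vertical %s A\n",
              x$in_fraction, x$n_in, x$n_frames,
              if (is.na(x$mean_vertical_distance_in)) "NA"
              else sprintf("%.2f", x$mean_vertical_distance_in)))
  invisible(x)
}

#' Define a hydrogen bond
#'
#' @param donor,hydrogen,acceptor `(residue_index, atom_name)` pairs.
#' @param distance_cutoff donor-acceptor cutoff, Angstrom (default 3.5).
#' @param angle_cutoff donor-H-acceptor cutoff, degrees (default 120).
#' @param label optional label.
#' @return object of class `hbond_definition`
#' @export
hbond_definition <- function(donor, hydrogen, acceptor,
                             distance_cutoff = 3.5, angle_cutoff = 120,
                             label = NULL) {
  stopifnot(distance_cutoff > 0, angle_cutoff > 0)
  if (identical(donor, acceptor))
    stop("hbond_definition: donor and acceptor must differ")
  if (is.null(label))
    label <- sprintf("%s:%s-%s:%s", donor[[1]], donor[[2]],
                     acceptor[[1]], acceptor[[2]])
  structure(list(donor = donor, hydrogen = hydrogen, acceptor = acceptor,
                 distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff, label = label),
            class = "hbond_definition")
}

#' Group alternative hydrogen bonds that count as one
#'
#' Mirrors occupancy-table rows that list two acceptors for the same bond
#' (e.g. "O6 / N7"): the group is formed in a frame if any member is formed.
#' @param ... [hbond_definition()] objects
#' @param label group label
#' @export
hbond_group <- function(..., label = NULL) {
  defs <- list(...)
  if (length(defs) == 1L && is.list(defs[[1]]) &&
      !inherits(defs[[1]], "hbond_definition")) defs <- defs[[1]]
  stopifnot(length(defs) >= 1L,
            all(vapply(defs, inherits, logical(1), "hbond_definition")))
  if (is.null(label))
    label <- paste(vapply(defs, `[[`, character(1), "label"),
                   collapse = " / ")
  structure(list(defs = defs, label = label), class = "hbond_group")
}

angle_deg <- function(a, b, c) {
  # interior angle at b, degrees
  v1 <- a - b
  v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Is a hydrogen bond present in one frame?
#'
#' Formed iff donor-acceptor distance < `distance_cutoff` and donor-H-acceptor
#' angle > `angle_cutoff` (strict inequalities).
#'
#' @param frame n_atoms x 3 coordinate matrix
#' @param top the matching [topology()]
#' @param def an [hbond_definition()]
#' @return logical
#' @export
hbond_present <- function(frame, top, def) {
  id <- resolve_atom(top, def$donor[[1]], def$donor[[2]])
  ih <- resolve_atom(top, def$hydrogen[[1]], def$hydrogen[[2]])
  ia <- resolve_atom(top, def$acceptor[[1]], def$acceptor[[2]])
  d <- sqrt(sum((frame[id, ] - frame[ia, ])^2))
  if (d >= def$distance_cutoff) return(FALSE)
  angle_deg(frame[id, ], frame[ih, ], frame[ia, ]) > def$angle_cutoff
}

#' Hydrogen-bond occupancies over a trajectory
#'
#' @param traj a [trajectory()]
#' @param defs list of [hbond_definition()] and/or [hbond_group()] objects.
#' @return data.frame with columns `label`, `occupancy`, `n_formed`,
#'   `n_frames`.
#' @export
hbond_occupancy <- function(traj, defs) {
  if (length(defs) == 0L) stop("hbond_occupancy: defs must be non-empty")
  if (inherits(defs, "hbond_definition") || inherits(defs, "hbond_group"))
    defs <- list(defs)
  nf <- n_frames(traj)
  top <- traj$topology
  rows <- lapply(defs, function(def) {
    members <- if (inherits(def, "hbond_group")) def$defs else list(def)
    formed <- logical(nf)
    for (f in seq_len(nf)) {
      fr <- get_frame(traj, f)
      formed[f] <- any(vapply(members, function(m)
        hbond_present(fr, top, m), logical(1)))
    }
    data.frame(label = def$label, occupancy = mean(formed),
               n_formed = sum(formed), n_frames = nf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
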