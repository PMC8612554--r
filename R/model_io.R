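#' @useDynLib pocketdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

STANDARD_NUCLEOTIDES <- c("A", "U", "G", "C",
                          "RA", "RU", "RG", "RC",
                          "ADE", "URA", "GUA", "CYT",
                          "A3", "A5", "U3", "U5", "G3", "G5", "C3", "C5")

COMMON_ION_RESNAMES <- c("MG", "MN", "NA", "K", "CL", "ZN", "CA", "NA+", "K+",
                         "CL-", "MG2", "SOD", "POT", "CLA")

#' Construct a topology
#'
#' A topology is the static description of the molecular system: one row per
#' atom with residue identity, segment assignment and (optionally) per-atom
#' force-field parameters.  Residue indexing is 1-based author numbering as it
#' appears in the source structure (G5, C15, ...).
#'
#' @param atoms data.frame with at least columns `serial`, `atom_name`,
#'   `residue_name`, `residue_index`, `segment`, `element`.  Parameter columns
#'   `charge`, `lj_rmin_half`, `lj_epsilon`, `pb_radius` are added as `NA`
#'   when absent (populate them with [attach_parameters()]).
#' @return Object of class `topology` with elements `atoms` and a derived
#'   `residues` table (`residue_index`, `residue_name`, `segment`).
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  needed <- c("serial", "atom_name", "residue_name", "residue_index",
              "segment", "element")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0L)
    stop("topology: missing atom columns: ", paste(missing, collapse = ", "))
  for (col in c("charge", "lj_rmin_half", "lj_epsilon", "pb_radius"))
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (!all(atoms$segment %in% c("RNA", "LIGAND", "ION", "OTHER")))
    stop("topology: segment must be one of RNA, LIGAND, ION, OTHER")
  key <- paste(atoms$residue_index, atoms$atom_name)
  if (anyDuplicated(key))
    stop("topology: duplicated (residue_index, atom_name): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  ok <- is.na(atoms$pb_radius) | atoms$pb_radius >= 0
  if (!all(ok)) stop("topology: pb_radius must be >= 0")
  ok <- is.na(atoms$lj_epsilon) | atoms$lj_epsilon >= 0
  if (!all(ok)) stop("topology: lj_epsilon must be >= 0")
  rownames(atoms) <- NULL
  res <- unique(atoms[, c("residue_index", "residue_name", "segment")])
  rownames(res) <- NULL
  structure(list(atoms = atoms, residues = res), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  seg <- table(x$atoms$segment)
  cat(sprintf("topology: %d atoms, %d residues (%s)\n",
              nrow(x$atoms), nrow(x$residues),
              paste(sprintf("%s %d", names(seg), seg), collapse = ", ")))
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Construct a trajectory
#'
#' @param coords numeric array `n_frames x n_atoms x 3`, Angstrom.
#' @param topology a [topology()].
#' @param times frame times in ps (strictly increasing); defaults to
#'   `0, 10, 20, ...` mirroring a 10 ps save cadence.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(coords, topology, times = NULL) {
  stopifnot(inherits(topology, "topology"))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("trajectory: coords must be an n_frames x n_atoms x 3 array")
  if (dim(coords)[2] != n_atoms(topology))
    stop(sprintf("trajectory: coords have %d atoms but topology has %d",
                 dim(coords)[2], n_atoms(topology)))
  nf <- dim(coords)[1]
  if (is.null(times)) times <- seq(0, by = 10, length.out = nf)
  if (length(times) != nf) stop("trajectory: length(times) != n_frames")
  if (nf > 1L && any(diff(times) <= 0))
    stop("trajectory: times must be strictly increasing")
  structure(list(coords = coords, times = as.numeric(times),
                 topology = topology),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms (t = %g..%g ps)\n",
              n_frames(x), dim(x$coords)[2], x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()]
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an n_atoms x 3 matrix
#' @param traj a [trajectory()]
#' @param i frame index (1-based)
#' @export
get_frame <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

guess_element <- function(atom_name, pdb_element = "") {
  el <- toupper(trimws(pdb_element))
  if (nzchar(el)) return(el)
  nm <- gsub("[^A-Za-z]", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  if (two %in% c("MG", "MN", "CL", "NA", "ZN", "BR", "FE")) return(two)
  toupper(substr(nm, 1, 1))
}

assign_segment <- function(residue_name, record_type, ligand_resnames) {
  rn <- toupper(trimws(residue_name))
  ifelse(rn %in% toupper(ligand_resnames), "LIGAND",
         ifelse(rn %in% STANDARD_NUCLEOTIDES, "RNA",
                ifelse(rn %in% COMMON_ION_RESNAMES, "ION", "OTHER")))
}

# Pre-scan raw PDB lines for the error contracts that the reader promises:
# per-model atom-count consistency, insertion codes, unparseable coordinates.
prescan_pdb_lines <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("read_structure: no ATOM/HETATM records found")
  icode <- substr(lines[is_atom], 27, 27)
  if (any(icode != " " & icode != "")) {
    bad <- which(is_atom)[which(icode != " " & icode != "")[1]]
    stop(sprintf("read_structure: insertion code on line %d is not supported",
                 bad))
  }
  for (ln in which(is_atom)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[ln], 31, 38),
                                         substr(lines[ln], 39, 46),
                                         substr(lines[ln], 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("read_structure: unparseable coordinate field on line %d",
                   ln))
  }
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    model_id <- cumsum(grepl("^MODEL", lines))
    counts <- table(model_id[is_atom])
    if (length(unique(as.integer(counts))) > 1L) {
      ref <- as.integer(counts[1])
      bad <- names(counts)[which(as.integer(counts) != ref)[1]]
      stop(sprintf(paste0("read_structure: model %s has %d atoms but model ",
                          "1 has %d"),
                   bad, as.integer(counts[bad]), ref))
    }
  }
  invisible(TRUE)
}

#' Read a (multi-model) PDB structure into a trajectory
#'
#' Each MODEL block becomes one frame; a file without MODEL records yields a
#' single-frame trajectory.  HETATM ions get segment `ION`, residues named in
#' `ligand_resnames` get `LIGAND`, standard nucleotides get `RNA`, everything
#' else `OTHER`.  Only the first alternate location of an atom is kept;
#' insertion codes are rejected with an error.
#'
#' @param input path to a PDB file, or a character vector of PDB lines.
#' @param ligand_resnames residue name(s) identifying the ligand (explicit
#'   configuration, no heuristics).
#' @param times optional frame times (ps); default 10 ps cadence.
#' @return A [trajectory()].
#' @export
read_structure <- function(input, ligand_resnames = character(), times = NULL) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
  }
  prescan_pdb_lines(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  # first altloc only
  if (!is.null(at$alt)) {
    keep <- !duplicated(paste(at$chain, at$resno, at$resid, at$elety))
    if (!all(keep)) {
      at <- at[keep, , drop = FALSE]
      pdb$xyz <- pdb$xyz[, as.vector(t(cbind((which(keep) - 1) * 3 + 1,
                                             (which(keep) - 1) * 3 + 2,
                                             (which(keep) - 1) * 3 + 3))),
                         drop = FALSE]
    }
  }
  elem <- mapply(guess_element, at$elety,
                 if (is.null(at$elesy)) "" else at$elesy,
                 USE.NAMES = FALSE)
  seg <- assign_segment(at$resid, at$type, ligand_resnames)
  seg[at$type == "HETATM" & toupper(trimws(at$resid)) %in%
        COMMON_ION_RESNAMES] <- "ION"
  seg[toupper(trimws(at$resid)) %in% toupper(ligand_resnames)] <- "LIGAND"
  atoms <- data.frame(serial = at$eleno,
                      atom_name = trimws(at$elety),
                      residue_name = trimws(at$resid),
                      residue_index = at$resno,
                      segment = seg,
                      element = elem,
                      stringsAsFactors = FALSE)
  top <- topology(atoms)
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(atoms)
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  trajectory(coords, top, times = times)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [trajectory()]
#' @param file destination path
#' @return `file`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, file) {
  at <- traj$topology$atoms
  nf <- n_frames(traj)
  xyz <- matrix(NA_real_, nf, 3L * nrow(at))
  for (f in seq_len(nf)) xyz[f, ] <- as.vector(t(get_frame(traj, f)))
  type <- ifelse(at$segment %in% c("ION", "LIGAND", "OTHER") &
                   !(at$residue_name %in% STANDARD_NUCLEOTIDES),
                 "HETATM", "ATOM")
  bio3d::write.pdb(file = file, xyz = xyz, type = type,
                   resno = at$residue_index, resid = at$residue_name,
                   eleno = at$serial, elety = at$atom_name,
                   chain = "A", elesy = at$element)
  invisible(file)
}

#' Read a parameter table
#'
#' The table is a TSV with header columns `residue_name`, `atom_name`,
#' `charge_e`, `rmin_half_A`, `epsilon_kcal`, `pb_radius_A`.
#'
#' @param input path or character lines.
#' @return data.frame.
#' @export
read_parameter_table <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    tab <- utils::read.table(input, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(text = paste(input, collapse = "\n"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  }
  needed <- c("residue_name", "atom_name", "charge_e", "rmin_half_A",
              "epsilon_kcal", "pb_radius_A")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L)
    stop("read_parameter_table: missing columns: ",
         paste(missing, collapse = ", "))
  tab
}

#' Attach per-atom force-field parameters to a topology
#'
#' Populates charge, Lennard-Jones (Rmin/2, epsilon) and PB radius for every
#' atom from a `(residue_name, atom_name)`-keyed table.  All atoms must be
#' matched; otherwise an error lists every unmatched atom.
#'
#' @param top a [topology()]
#' @param table data.frame from [read_parameter_table()] (or equivalent).
#' @return The parameterized topology, with attribute `net_charge`: named
#'   vector of the net charge of each segment.
#' @export
attach_parameters <- function(top, table) {
  stopifnot(inherits(top, "topology"))
  key_top <- paste(top$atoms$residue_name, top$atoms$atom_name)
  key_tab <- paste(table$residue_name, table$atom_name)
  idx <- match(key_top, key_tab)
  if (anyNA(idx)) {
    bad <- unique(key_top[is.na(idx)])
    stop("attach_parameters: no parameters for (residue, atom): ",
         paste(bad, collapse = "; "))
  }
  top$atoms$charge <- table$charge_e[idx]
  top$atoms$lj_rmin_half <- table$rmin_half_A[idx]
  top$atoms$lj_epsilon <- table$epsilon_kcal[idx]
  top$atoms$pb_radius <- table$pb_radius_A[idx]
  out <- topology(top$atoms)
  attr(out, "net_charge") <- tapply(out$atoms$charge, out$atoms$segment, sum)
  out
}

#' Export a topology's parameters back to a table
#'
#' Inverse of [attach_parameters()]: one row per unique
#' `(residue_name, atom_name)` pair.
#' @param top parameterized [topology()]
#' @return data.frame in [read_parameter_table()] layout.
#' @export
parameter_table <- function(top) {
  a <- top$atoms
  tab <- data.frame(residue_name = a$residue_name, atom_name = a$atom_name,
                    charge_e = a$charge, rmin_half_A = a$lj_rmin_half,
                    epsilon_kcal = a$lj_epsilon, pb_radius_A = a$pb_radius,
                    stringsAsFactors = FALSE)
  tab[!duplicated(paste(tab$residue_name, tab$atom_name)), , drop = FALSE]
}

#' Read reference metal/ligand sites from PDB HETATM records
#'
#' @param input path or character lines containing HETATM records.
#' @param element_filter element symbol to keep (e.g. `"MN"`, `"MG"`);
#'   matched case-insensitively against the element column, falling back to
#'   the residue name.
#' @param labels optional labels; default `M1`, `M2`, ... in file order.
#' @return data.frame of class `reference_sites` with columns
#'   `label`, `x`, `y`, `z`, `source`.
#' @export
read_reference_sites <- function(input, element_filter, labels = NULL) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input)
    src <- input
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
    src <- "<text>"
  }
  het <- lines[grepl("^HETATM", lines)]
  if (length(het) == 0L) {
    out <- data.frame(label = character(), x = numeric(), y = numeric(),
                      z = numeric(), source = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("reference_sites", "data.frame")
    return(out)
  }
  elem <- toupper(trimws(substr(het, 77, 78)))
  resn <- toupper(trimws(substr(het, 18, 20)))
  elem[elem == ""] <- resn[elem == ""]
  keep <- elem == toupper(element_filter)
  het <- het[keep]
  if (length(het) == 0L) {
    out <- data.frame(label = character(), x = numeric(), y = numeric(),
                      z = numeric(), source = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("reference_sites", "data.frame")
    return(out)
  }
  xyz <- t(vapply(het, function(l)
    as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))),
    numeric(3)))
  if (is.null(labels)) labels <- paste0("M", seq_len(length(het)))
  if (anyDuplicated(labels)) stop("read_reference_sites: labels not unique")
  out <- data.frame(label = labels,
                    x = if (length(het)) unname(xyz[, 1]) else numeric(),
                    y = if (length(het)) unname(xyz[, 2]) else numeric(),
                    z = if (length(het)) unname(xyz[, 3]) else numeric(),
                    source = rep(src, length(het)),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("reference_sites", "data.frame")
  out
}

#' Write reference sites as PDB HETATM records
#' @param sites data.frame from [read_reference_sites()] or with the same
#'   columns; `element` controls the residue/element fields.
#' @param file destination path
#' @param element element symbol (default `"MN"`)
#' @export
write_reference_sites <- function(sites, file, element = "MN") {
  lines <- sprintf(
    "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(sites)), toupper(element), toupper(element),
    seq_len(nrow(sites)), sites$x, sites$y, sites$z, toupper(element))
  writeLines(c(lines, "END"), file)
  invisible(file)
}

site_positions <- function(sites) {
  m <- as.matrix(sites[, c("x", "y", "z")])
  rownames(m) <- sites$label
  m
}

#' Write a 3D grid density in OpenDX format
#'
#' Scalar regular grid, z index varying fastest (standard DX ordering).
#'
#' @param density a `grid_density` object (see [grid_density()]), or any list
#'   with `origin`, `spacing`, `counts`.
#' @param file destination path
#' @export
write_dx <- function(density, file) {
  cnt <- density$counts
  d <- dim(cnt)
  # DX order: x slowest, z fastest -> index [i,j,k] with k fastest
  vals <- cnt[cbind(rep(seq_len(d[1]), each = d[2] * d[3]),
                    rep(rep(seq_len(d[2]), each = d[3]), times = d[1]),
                    rep(seq_len(d[3]), times = d[1] * d[2]))]
  con <- file(file, "w")
  on.exit(close(con))
  h <- density$spacing
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            density$origin[1], density$origin[2], density$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", h),
    sprintf("delta 0.000000 %.6f 0.000000", h),
    sprintf("delta 0.000000 0.000000 %.6f", h),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))), con)
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.10g %.10g %.10g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (length(vals) > n3)
    writeLines(paste(sprintf("%.10g", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(file)
}

#' Read an OpenDX grid written by [write_dx()]
#' @param file path
#' @return list with `origin`, `spacing`, `counts` (3D array).
#' @export
read_dx <- function(file) {
  lines <- readLines(file)
  cl <- grep("class gridpositions counts", lines, value = TRUE)[1]
  d <- as.integer(strsplit(trimws(sub(".*counts", "", cl)), "\\s+")[[1]])
  ol <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", ol)), "\\s+")[[1]])
  dl <- grep("^delta", lines, value = TRUE)
  deltas <- lapply(dl, function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]]))
  spacing <- deltas[[1]][1]
  start <- grep("data follows", lines)[1] + 1L
  end <- grep("^attribute", lines)[1] - 1L
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  stopifnot(length(vals) == prod(d))
  cnt <- array(NA_real_, d)
  cnt[cbind(rep(seq_len(d[1]), each = d[2] * d[3]),
            rep(rep(seq_len(d[2]), each = d[3]), times = d[1]),
            rep(seq_len(d[3]), times = d[1] * d[2]))] <- vals
  list(origin = origin, spacing = spacing, counts = cnt)
}

#' Write a result table as TSV
#' @param x data.frame
#' @param file destination path
#' @export
write_result_tsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a TSV result table
#' @param file path
#' @export
read_result_tsv <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, seed and package/R versions of a run so that
#' every output file is regenerable from the manifest alone.
#'
#' @param config list (configuration echo)
#' @param seed integer seed used
#' @param file destination path (JSON)
#' @param extra optional named list of additional fields (e.g. timings)
#' @export
write_run_manifest <- function(config, seed, file, extra = list()) {
  manifest <- c(list(
    package = "pocketdyn",
    package_version = as.character(utils::packageVersion("pocketdyn")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config), extra)
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}
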