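# Domain containers (topology / frame / trajectory) and readers/writers for
# the plain-text structure formats the rest of the package consumes.

#' Boltzmann constant in kcal mol^-1 K^-1
#' @export
KB_KCAL <- 0.0019872041

# Conversion: 1 kcal/mol = 418.4 amu A^2 ps^-2 (accelerations and thermal
# velocities are computed in A, ps, amu from energies in kcal/mol).
KCAL_TO_AMU_A2_PS2 <- 418.4

# Atomic masses (amu) by element symbol; enough for protein/nucleotide toys.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  MG = 24.305, "NA" = 22.990, CL = 35.453, K = 39.098, ZN = 65.38, CA = 40.078,
  FE = 55.845, X = 12.011
)

# Bondi van der Waals radii (A) used by the surface-area calculator.
.bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
  MG = 1.73, "NA" = 2.27, CL = 1.75, K = 2.75, ZN = 1.39, CA = 2.31, FE = 2.00
)

# Residue-template charge classes: side chains carrying a formal charge at
# physiological pH, plus GTP phosphates.  Everything else is neutral.
.charge_class_templates <- list(
  cation = c("LYS", "ARG", "HIP"),
  anion  = c("ASP", "GLU", "GTP")
)

element_mass <- function(element) {
  el <- toupper(element)
  m <- .element_masses[el]
  m[is.na(m)] <- .element_masses[["X"]]
  unname(m)
}

charge_class_for <- function(residue_name) {
  rn <- toupper(residue_name)
  cls <- rep("neutral", length(rn))
  cls[rn %in% .charge_class_templates$cation] <- "cation"
  cls[rn %in% .charge_class_templates$anion] <- "anion"
  known <- rn %in% c(
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HIP",
    "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR",
    "VAL", "GTP", "HOH", "WAT", "MG", "NA", "CL", "BEA"
  )
  if (any(!known)) {
    warning("unknown residue template(s) ", paste(unique(rn[!known]), collapse = ", "),
            "; charge_class set to neutral", call. = FALSE)
  }
  cls
}

#' Build a topology from an atom table
#'
#' A topology is the static half of a trajectory: one row of atom metadata per
#' atom (in file order) plus an optional bond list.  Residue numbering is kept
#' exactly as supplied (1-based PDB numbers in user-facing output).
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `residue_name`, `residue_number`, and optionally `chain`, `mass`,
#'   `charge_class`, `het`.  Missing optional columns are filled from
#'   element/residue templates.
#' @param bonds optional two-column integer matrix of 1-based atom indices.
#' @return object of class `topology`
#' @export
topology <- function(atoms, bonds = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  required <- c("serial", "name", "element", "residue_name", "residue_number")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  if (!"mass" %in% names(atoms)) atoms$mass <- element_mass(atoms$element)
  if (!"charge_class" %in% names(atoms)) {
    atoms$charge_class <- charge_class_for(atoms$residue_name)
  }
  if (!"het" %in% names(atoms)) atoms$het <- FALSE
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    stop("all atom masses must be positive and finite")
  }
  if (any(!nzchar(atoms$element))) stop("all atoms need a non-empty element symbol")
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1L) || any(bonds > nrow(atoms))) {
      stop("bond indices out of range")
    }
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, bonds = bonds), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, %d bonds\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$residue_number))),
              if (is.null(x$bonds)) 0L else nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms in a topology
#' @param topology a [topology()]
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' Assemble a trajectory
#'
#' Frames are stored bio3d-style as an `n_frames x 3N` coordinate matrix in
#' Angstrom (columns x1, y1, z1, x2, ...), which keeps whole-ensemble
#' operations vectorised.
#'
#' @param topology a [topology()]
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns
#' @param time optional per-frame times (ps)
#' @param frame_stride ps between stored frames (metadata only)
#' @return object of class `trajectory`
#' @export
trajectory <- function(topology, xyz, time = NULL, frame_stride = NA_real_) {
  stopifnot(inherits(topology, "topology"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(topology)) {
    stop("coordinate columns (", ncol(xyz), ") do not match 3 x atom count (",
         3L * n_atoms(topology), ")")
  }
  if (nrow(xyz) < 1L) stop("a trajectory needs at least one frame")
  if (any(!is.finite(xyz))) stop("non-finite coordinates in trajectory")
  if (is.null(time)) time <- seq_len(nrow(xyz)) - 1
  structure(list(topology = topology, xyz = xyz, time = as.numeric(time),
                 frame_stride = frame_stride),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms\n", nrow(x$xyz), n_atoms(x$topology)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()]
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame as an N x 3 coordinate matrix
#' @param traj a [trajectory()]
#' @param i frame index (1-based)
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Concatenate trajectories sharing a topology
#'
#' Used to pool independent replicas into one combined ensemble before
#' post-processing.
#' @param ... trajectories with identical atom counts
#' @export
concatenate_trajectories <- function(...) {
  trajs <- list(...)
  if (length(trajs) == 1L && is.list(trajs[[1]]) && !inherits(trajs[[1]], "trajectory")) {
    trajs <- trajs[[1]]
  }
  stopifnot(length(trajs) >= 1, all(vapply(trajs, inherits, TRUE, "trajectory")))
  nat <- vapply(trajs, function(t) n_atoms(t$topology), integer(1))
  if (length(unique(nat)) != 1L) stop("atom counts differ between trajectories")
  trajectory(trajs[[1]]$topology,
             do.call(rbind, lapply(trajs, function(t) t$xyz)),
             time = unlist(lapply(trajs, function(t) t$time)),
             frame_stride = trajs[[1]]$frame_stride)
}

# ---- PDB ----------------------------------------------------------------

#' Read a (multi-model) PDB file into a topology + trajectory
#'
#' Parsing is delegated to [bio3d::read.pdb()]; this wrapper pre-validates
#' the ATOM/HETATM blocks (fixed-width layout, consistent atom counts across
#' MODELs) so malformed files fail with a line-level diagnostic, and maps the
#' result onto the package's containers.  HETATM records (e.g. GTP, MG, NA)
#' are retained and flagged via the `het` column.
#'
#' @param path PDB file path
#' @return list with elements `topology` and `trajectory`
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  atom_idx <- which(is_atom)
  bad_len <- atom_idx[nchar(lines[atom_idx]) < 54]
  if (length(bad_len) > 0) {
    stop("malformed ATOM/HETATM line ", bad_len[1], " in ", path,
         " (shorter than the fixed-width coordinate fields)")
  }
  coord_txt <- substr(lines[atom_idx], 31, 54)
  coord_ok <- grepl("^[ 0-9+.eE-]+$", coord_txt)
  if (any(!coord_ok)) {
    stop("malformed ATOM/HETATM line ", atom_idx[which(!coord_ok)[1]], " in ",
         path, " (non-numeric coordinate field)")
  }
  # per-MODEL atom counts must agree
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1) {
    model_of <- findInterval(atom_idx, model_starts)
    counts <- tabulate(model_of, nbins = length(model_starts))
    if (length(unique(counts[counts > 0])) > 1) {
      stop("inconsistent atom count across MODELs in ", path, ": ",
           paste(counts, collapse = ", "))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                     substr(trimws(at$elety), 1, 1), trimws(at$elesy)),
    residue_name = at$resid,
    residue_number = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  topo <- topology(atoms)
  xyz <- unclass(pdb$xyz)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  list(topology = topo, trajectory = trajectory(topo, xyz))
}

#' Write a topology + frames as a (multi-model) PDB file
#'
#' Round-trips through [read_pdb()] to PDB precision (1e-3 A on coordinates,
#' residue numbering exact).  Coordinates with magnitude >= 10000 A overflow
#' the fixed-width field and raise an error.
#'
#' @param topology a [topology()]
#' @param xyz frame matrix (`n_frames x 3N`) or single N x 3 frame
#' @param path output file
#' @export
write_pdb <- function(topology, xyz, path) {
  if (is.matrix(xyz) && ncol(xyz) == 3 && nrow(xyz) == n_atoms(topology) &&
      3 * n_atoms(topology) != 3) {
    xyz <- matrix(t(xyz), nrow = 1)
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1) stop("at least one frame required")
  if (any(abs(xyz) >= 10000)) {
    stop("coordinate magnitude >= 10000 A overflows the PDB format field")
  }
  a <- topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- nrow(xyz) > 1
  for (f in seq_len(nrow(xyz))) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    recname <- ifelse(a$het, "HETATM", "ATOM  ")
    # PDB v3.3 fixed-width ATOM record; atom names width-4 left-padded like bio3d
    nm <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
    writeLines(sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       recname, a$serial, nm, a$residue_name, a$chain,
                       a$residue_number, m[, 1], m[, 2], m[, 3], 1, 0,
                       toupper(a$element)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- XYZ ----------------------------------------------------------------

#' Read an XYZ frame series against a known topology
#'
#' Standard XYZ blocks (atom count line, comment line, one `sym x y z` line
#' per atom).  A comment of the form `t=<ps>` sets the frame time.
#'
#' @param path XYZ file
#' @param topology the matching [topology()]
#' @return a [trajectory()]
#' @export
read_xyz_trajectory <- function(path, topology) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  nat <- n_atoms(topology)
  frames <- list()
  times <- numeric(0)
  i <- 1L
  while (i <= length(lines)) {
    cnt <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(cnt)) stop("expected an atom-count line at line ", i)
    if (cnt != nat) {
      stop("frame at line ", i, " has ", cnt, " atoms but topology has ", nat)
    }
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("t=([0-9.eE+-]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else length(frames))
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    if (any(lengths(parts) < 4)) {
      stop("malformed coordinate line in frame starting at line ", i)
    }
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(co))) stop("non-numeric coordinate in frame starting at line ", i)
    frames[[length(frames) + 1L]] <- as.numeric(t(co))
    i <- i + 2L + nat
  }
  if (length(frames) == 0) stop("no frames in ", path)
  trajectory(topology, do.call(rbind, frames), time = times)
}

#' Write a trajectory in XYZ format with `t=<ps>` comments
#' @param traj a [trajectory()]
#' @param path output file
#' @export
write_xyz_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  el <- traj$topology$atoms$element
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f)
    writeLines(c(as.character(length(el)), sprintf("t=%.6g", traj$time[f]),
                 sprintf("%-3s %14.8f %14.8f %14.8f", el, m[, 1], m[, 2], m[, 3])), con)
  }
  invisible(path)
}

# ---- boost logs ---------------------------------------------------------

#' Read a boost-potential log table
#'
#' Delimited (comma or tab) table with mandatory header columns
#' `step, V, dV, E, k`; energies in kcal/mol.
#'
#' @param path log file
#' @return data.frame of boost records (possibly 0 rows)
#' @export
read_boost_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1, warn = FALSE)
  if (length(first) == 0 || !nzchar(trimws(first))) {
    return(data.frame(step = integer(0), V = numeric(0), dV = numeric(0),
                      E = numeric(0), k = numeric(0)))
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, strip.white = TRUE,
                           colClasses = "character")
  needed <- c("step", "V", "dV", "E", "k")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("boost log is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- tab[needed]
  for (cn in needed) {
    v <- suppressWarnings(as.numeric(out[[cn]]))
    if (any(is.na(v) & nzchar(trimws(out[[cn]])))) {
      stop("non-numeric value in column '", cn, "' at row ",
           which(is.na(v))[1], " of ", path)
    }
    out[[cn]] <- v
  }
  out$step <- as.integer(out$step)
  out
}

#' Write a boost log table (tab-delimited, header `step V dV E k`)
#' @param records data.frame with columns step, V, dV, E, k
#' @param path output file
#' @export
write_boost_log <- function(records, path) {
  utils::write.table(records[c("step", "V", "dV", "E", "k")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- selections ---------------------------------------------------------

#' Atom selection specification
#'
#' @param mode one of `"calpha"`, `"heavy"`, `"all"`, `"residue_range"`,
#'   `"named_atoms"`
#' @param residues closed residue-number interval(s): a vector of residue
#'   numbers or `c(lo, hi)` pairs via [seq()]; intervals are inclusive on
#'   both ends (the field's convention for switch-domain ranges, e.g. 37-50)
#' @param atoms character vector of atom names (for `named_atoms`, or to
#'   restrict any other mode)
#' @export
selection <- function(mode = c("calpha", "heavy", "all", "residue_range", "named_atoms"),
                      residues = NULL, atoms = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, residues = residues, atoms = atoms),
            class = "selection")
}

#' Resolve a selection to 1-based atom indices on a topology
#' @param topology a [topology()]
#' @param sel a [selection()] (or NULL for all atoms)
#' @export
resolve_selection <- function(topology, sel = NULL) {
  a <- topology$atoms
  if (is.null(sel)) return(seq_len(nrow(a)))
  stopifnot(inherits(sel, "selection"))
  keep <- switch(sel$mode,
    calpha = trimws(a$name) == "CA" & !a$het,
    heavy = toupper(a$element) != "H",
    all = rep(TRUE, nrow(a)),
    residue_range = rep(TRUE, nrow(a)),
    named_atoms = rep(TRUE, nrow(a))
  )
  if (!is.null(sel$residues)) keep <- keep & a$residue_number %in% sel$residues
  if (!is.null(sel$atoms)) keep <- keep & trimws(a$name) %in% sel$atoms
  idx <- which(keep)
  if (length(idx) == 0) stop("selection resolves to zero atoms")
  idx
}

# column indices into an n x 3N coordinate matrix for given atom indices
xyz_cols <- function(atom_idx) {
  as.vector(rbind(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx))
}
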