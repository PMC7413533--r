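#' Molecular structure container
#'
#' A `structure3d` holds an ordered atom table in the style of a PDB file:
#' one row per atom with serial number, atom name, residue name, chain
#' identifier, author residue number, Cartesian coordinates in Angstrom and
#' an element symbol. Residue numbering is author numbering from the input,
#' 1-based and never renumbered, so residues can be addressed the way the
#' structural literature does (e.g. A71 on each protein chain).
#'
#' @param atoms data.frame with columns `eleno` (integer serial), `elety`
#'   (atom name, e.g. `"CA"`, `"OP1"`), `resid` (residue name, e.g. `"ALA"`,
#'   `"DT"`), `chain` (single character), `resno` (integer residue number),
#'   `x`, `y`, `z` (Angstrom) and `elesy` (element symbol).
#' @param source free-text identifier of where the atoms came from.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms, source = "constructed") {
  required <- c("eleno", "elety", "resid", "chain", "resno", "x", "y", "z", "elesy")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[, required]
  atoms$eleno <- as.integer(atoms$eleno)
  atoms$resno <- as.integer(atoms$resno)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom-name) triple: ",
         key[anyDuplicated(key)][1L])
  rownames(atoms) <- NULL
  out <- list(atoms = atoms, source = source)
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, chains {%s} (source: %s)\n",
              nrow(x$atoms), paste(sort(unique(x$atoms$chain)), collapse = ","),
              x$source))
  invisible(x)
}

#' Number of atoms of a structure
#' @param structure a `structure3d`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Atom coordinates as an N x 3 matrix
#' @param structure a `structure3d`.
#' @return numeric matrix, Angstrom.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param structure a `structure3d`.
#' @param xyz N x 3 matrix, Angstrom.
#' @return a `structure3d` with updated coordinates.
#' @export
set_coords <- function(structure, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atoms(structure) || ncol(xyz) != 3L)
    stop(sprintf("coordinate matrix must be %d x 3, got %d x %d",
                 n_atoms(structure), nrow(xyz), ncol(xyz)))
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}

#' Coordinate trajectory over a fixed topology
#'
#' Frames are stored as an F x 3N matrix (the layout used throughout the
#' trajectory-analysis R ecosystem): row t is `c(x1,y1,z1, x2,y2,z2, ...)`
#' for frame t.
#'
#' @param topology a `structure3d`.
#' @param xyz F x 3N numeric matrix, Angstrom.
#' @param frame_spacing optional time between stored frames, ps.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, xyz, frame_spacing = NULL) {
  if (!inherits(topology, "structure3d")) stop("topology must be a structure3d")
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) stop("a trajectory needs at least one frame")
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop(sprintf("frame width mismatch: expected %d coordinates (%d atoms), got %d",
                 3L * n_atoms(topology), n_atoms(topology), ncol(xyz)))
  out <- list(topology = topology, xyz = xyz, frame_spacing = frame_spacing)
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms\n", n_frames(x), n_atoms(x$topology)))
  invisible(x)
}

#' Number of frames of a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame as an N x 3 matrix
#' @param traj a `trajectory`.
#' @param frame frame index (1-based).
#' @return N x 3 numeric matrix, Angstrom.
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(frame >= 1L, frame <= n_frames(traj))
  matrix(traj$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

#' The structure of a single trajectory frame
#' @param traj a `trajectory`.
#' @param frame frame index (1-based).
#' @return a `structure3d` with the topology's atom table and that frame's
#'   coordinates.
#' @export
frame_structure <- function(traj, frame) {
  set_coords(traj$topology, frame_coords(traj, frame))
}

# ---- PDB I/O -----------------------------------------------------------

validate_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1L, 6L)
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_idx) == 0L)
    stop("no ATOM/HETATM records in ", path)
  for (i in atom_idx) {
    ln <- lines[[i]]
    if (nchar(ln) < 54L)
      stop(sprintf("malformed PDB record at line %d of %s: shorter than 54 columns", i, path))
    fields <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stop(sprintf("malformed PDB record at line %d of %s: non-numeric coordinate field", i, path))
  }
  invisible(atom_idx)
}

resolve_altloc <- function(atom) {
  if (!"alt" %in% names(atom)) return(atom)
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atom)
  occ <- if ("o" %in% names(atom)) ifelse(is.na(atom$o), 1, atom$o) else rep(1, nrow(atom))
  key <- paste(atom$chain, atom$resno, atom$resid, atom$elety)
  # highest occupancy wins; ties broken in favour of altloc 'A', then file order
  pref <- order(key, -occ, alt != "A", seq_len(nrow(atom)))
  atom_sorted <- atom[pref, ]
  keep <- !duplicated(paste(atom_sorted$chain, atom_sorted$resno,
                            atom_sorted$resid, atom_sorted$elety))
  kept <- atom_sorted[keep, ]
  kept[order(as.integer(rownames(kept))), ]
}

guess_element <- function(elety) {
  first <- substr(gsub("[0-9']", "", elety), 1L, 1L)
  ifelse(first == "", "C", first)
}

bio3d_atoms_to_table <- function(atom) {
  atom <- resolve_altloc(atom)
  chain <- atom$chain
  chain[is.na(chain)] <- " "
  elesy <- if ("elesy" %in% names(atom)) atom$elesy else NA_character_
  elesy <- ifelse(is.na(elesy) | elesy == "", guess_element(atom$elety), trimws(elesy))
  data.frame(eleno = atom$eleno, elety = atom$elety, resid = atom$resid,
             chain = chain, resno = atom$resno,
             x = atom$x, y = atom$y, z = atom$z,
             elesy = elesy, stringsAsFactors = FALSE)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records of the first MODEL. Alternate locations are
#' resolved by highest occupancy, ties broken in favour of altloc `A`.
#' Chain identifiers and author residue numbers are preserved verbatim.
#'
#' @param path path to a PDB (v3.3) file.
#' @return a `structure3d`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path)
  validate_pdb_lines(lines, path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  structure3d(bio3d_atoms_to_table(pdb$atom), source = path)
}

fmt_pdb_atom_name <- function(elety, elesy) {
  # names of 1-3 chars start in column 14 when the element symbol is 1 char
  ifelse(nchar(elety) >= 4L | nchar(elesy) == 2L,
         sprintf("%-4s", elety), sprintf(" %-3s", elety))
}

#' Write a structure to a PDB file
#'
#' @param structure a `structure3d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  lines <- sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$eleno %% 100000L, fmt_pdb_atom_name(a$elety, a$elesy),
                   a$resid, a$chain, a$resno, a$x, a$y, a$z, 1, 0, a$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a coordinate trajectory
#'
#' Supports multi-model PDB files (each MODEL is a frame) and CHARMM/NAMD
#' binary DCD files. Frames are returned in storage order.
#'
#' @param path trajectory file.
#' @param topology `structure3d` whose atom count every frame must match.
#' @param format `"pdb"` or `"dcd"`; default guesses from the file extension.
#' @param frame_spacing optional frame spacing, ps.
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path, topology, format = c("auto", "pdb", "dcd"),
                            frame_spacing = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  xyz <- if (format == "dcd") {
    as.matrix(bio3d::read.dcd(path, verbose = FALSE))
  } else {
    as.matrix(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)$xyz)
  }
  got <- ncol(xyz) / 3L
  if (got != n_atoms(topology))
    stop(sprintf("atom-count mismatch: topology has %d atoms, trajectory frames have %d",
                 n_atoms(topology), got))
  trajectory(topology, xyz, frame_spacing = frame_spacing)
}

#' Write a trajectory as a CHARMM-dialect DCD file
#'
#' Minimal single-precision CHARMM/NAMD DCD writer (native endianness,
#' no unit cell). Round-trips with standard DCD readers.
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj); na <- n_atoms(traj$topology)
  icntrl <- integer(20L)
  icntrl[1L] <- nf          # number of frames
  icntrl[2L] <- 1L          # first step
  icntrl[3L] <- 1L          # save interval
  icntrl[4L] <- nf          # last step
  icntrl[20L] <- 24L        # CHARMM version stamp
  writeBin(84L, con, size = 4L)
  writeChar("CORD", con, nchars = 4L, eos = NULL)
  writeBin(icntrl[1:9], con, size = 4L)
  writeBin(numeric(1L), con, size = 4L)   # delta, float32
  writeBin(icntrl[11:20], con, size = 4L)
  writeBin(84L, con, size = 4L)
  title <- sprintf("%-80s", "written by allodyn")
  writeBin(84L + 4L, con, size = 4L)
  writeBin(1L, con, size = 4L)
  writeChar(title, con, nchars = 80L, eos = NULL)
  writeBin(84L + 4L, con, size = 4L)
  writeBin(4L, con, size = 4L)
  writeBin(na, con, size = 4L)
  writeBin(4L, con, size = 4L)
  blk <- 4L * na
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    for (d in 1:3) {
      writeBin(blk, con, size = 4L)
      writeBin(as.numeric(m[, d]), con, size = 4L)
      writeBin(blk, con, size = 4L)
    }
  }
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$topology$atoms
  out <- character(0L)
  for (f in seq_len(n_frames(traj))) {
    m <- frame_coords(traj, f)
    lines <- sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     a$eleno %% 100000L, fmt_pdb_atom_name(a$elety, a$elesy),
                     a$resid, a$chain, a$resno, m[, 1], m[, 2], m[, 3], 1, 0, a$elesy)
    out <- c(out, sprintf("MODEL     %4d", f), lines, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Restrict a trajectory to a subset of atoms
#' @param traj a `trajectory`.
#' @param indices atom indices into the topology, strictly increasing.
#' @return a `trajectory` over the selected atoms.
#' @export
subset_trajectory <- function(traj, indices) {
  indices <- as.integer(indices)
  stopifnot(all(diff(indices) > 0L), all(indices >= 1L),
            all(indices <= n_atoms(traj$topology)))
  cols <- as.integer(t(outer(3L * (indices - 1L), 1:3, `+`)))
  top <- structure3d(traj$topology$atoms[indices, , drop = FALSE],
                     source = traj$topology$source)
  trajectory(top, traj$xyz[, cols, drop = FALSE],
             frame_spacing = traj$frame_spacing)
}

# ---- selection ---------------------------------------------------------

#' Select atoms by chain, residue range and atom name
#'
#' Returns the indices (into the structure's atom table, in storage order)
#' of atoms matching every criterion supplied. Omitted criteria do not
#' filter; an empty result is valid.
#'
#' @param structure a `structure3d`.
#' @param chain chain identifier, or `NULL`.
#' @param residue_range `c(lo, hi)` inclusive author-numbering range, or `NULL`.
#' @param atom_names character vector of atom names (e.g. `"CA"`), or `NULL`.
#' @return strictly increasing integer vector of atom indices.
#' @export
select_atoms <- function(structure, chain = NULL, residue_range = NULL,
                         atom_names = NULL) {
  if (n_atoms(structure) == 0L) stop("empty structure")
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    keep <- keep & a$resno >= residue_range[1L] & a$resno <= residue_range[2L]
  }
  if (!is.null(atom_names)) keep <- keep & a$elety %in% atom_names
  which(keep)
}

# residue classification used by selection helpers and the interaction census
PROTEIN_RESNAMES <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS",
                      "ILE","LEU","LYS","MET","PHE","PRO","SER","THR","TRP",
                      "TYR","VAL","HID","HIE","HIP","CYX")
NUCLEIC_RESNAMES <- c("DA","DT","DG","DC","DU","A","T","G","C","U",
                      "DA3","DA5","DT3","DT5","DG3","DG5","DC3","DC5")

#' Is a residue name a standard amino acid?
#' @param resid character vector of residue names.
#' @return logical vector.
#' @export
is_protein_resname <- function(resid) resid %in% PROTEIN_RESNAMES

#' Is a residue name a nucleic-acid residue?
#' @param resid character vector of residue names.
#' @return logical vector.
#' @export
is_nucleic_resname <- function(resid) resid %in% NUCLEIC_RESNAMES
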