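# Census of protein-DNA interface interactions: hydrogen bonds, ionic
# interactions and hydrophobic contacts, per structure and per frame.
# The geometric criteria are package defaults, configurable, and always
# embedded in the returned objects.

#' Geometric criteria for the interaction census
#'
#' @param hbond_distance donor-acceptor heavy-atom cutoff, Angstrom
#'   (default 3.5).
#' @param hbond_angle_min minimum donor-H...acceptor angle in degrees
#'   (default 120); applied only when hydrogens are present, otherwise
#'   detection degrades to the distance-only criterion.
#' @param ionic_distance cationic-N to phosphate-O cutoff, Angstrom
#'   (default 4.0).
#' @param hydrophobic_distance apolar carbon-carbon cutoff, Angstrom
#'   (default 4.5).
#' @return object of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hbond_distance = 3.5, hbond_angle_min = 120,
                                 ionic_distance = 4.0,
                                 hydrophobic_distance = 4.5) {
  vals <- c(hbond_distance, hbond_angle_min, ionic_distance, hydrophobic_distance)
  if (any(vals <= 0)) stop("all criteria must be positive")
  out <- list(hbond_distance = hbond_distance, hbond_angle_min = hbond_angle_min,
              ionic_distance = ionic_distance,
              hydrophobic_distance = hydrophobic_distance)
  class(out) <- "interaction_criteria"
  out
}

# --- donor/acceptor/apolar atom tables ---------------------------------

PROTEIN_DONORS <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  HID = "ND1", HIE = "NE2", HIP = c("ND1", "NE2"),
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  TRP = "NE1", CYS = "SG")

PROTEIN_ACCEPTORS <- list(
  backbone = "O",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"),
  HID = "NE2", HIE = "ND1", MET = "SD")

DNA_ACCEPTORS <- c("OP1", "OP2", "O3'", "O5'", "O4'",   # backbone/sugar
                   "O2", "O4", "O6", "N1", "N3", "N7")  # base acceptors
DNA_DONORS <- c("N4", "N6", "N2", "N3", "N1")           # amino/imino nitrogens

CATIONIC_N <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                   HIS = c("ND1", "NE2"), HIP = c("ND1", "NE2"))
PHOSPHATE_O <- c("OP1", "OP2", "O3'", "O5'")

APOLAR_SIDECHAINS <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "PRO", "TRP")
DNA_APOLAR_C <- c("C1'", "C2'", "C3'", "C4'", "C5'",    # deoxyribose ring
                  "C2", "C4", "C5", "C6", "C7", "C8", "C5M")

split_interface <- function(structure) {
  a <- structure$atoms
  prot <- is_protein_resname(a$resid)
  nuc <- is_nucleic_resname(a$resid)
  if (!any(prot)) stop("no protein chain found")
  if (!any(nuc)) stop("no nucleic chain found")
  list(atoms = a, prot = which(prot), nuc = which(nuc),
       has_h = any(a$elesy == "H"))
}

protein_donor_idx <- function(a, rows) {
  rows[a$elety[rows] %in% PROTEIN_DONORS$backbone |
         mapply(function(rn, an) an %in% (PROTEIN_DONORS[[rn]] %||% character(0L)),
                a$resid[rows], a$elety[rows])]
}
protein_acceptor_idx <- function(a, rows) {
  rows[a$elety[rows] %in% PROTEIN_ACCEPTORS$backbone |
         mapply(function(rn, an) an %in% (PROTEIN_ACCEPTORS[[rn]] %||% character(0L)),
                a$resid[rows], a$elety[rows])]
}
`%||%` <- function(x, y) if (is.null(x)) y else x

pair_distances <- function(a, idx1, idx2) {
  m1 <- as.matrix(a[idx1, c("x", "y", "z")])
  m2 <- as.matrix(a[idx2, c("x", "y", "z")])
  d2 <- outer(rowSums(m1^2), rowSums(m2^2), `+`) - 2 * tcrossprod(m1, m2)
  sqrt(pmax(d2, 0))
}

build_records <- function(a, prot_idx, dna_idx, dist, kind, angle = NA_real_) {
  data.frame(kind = kind,
             protein_chain = a$chain[prot_idx], protein_resno = a$resno[prot_idx],
             protein_resid = a$resid[prot_idx], protein_atom = a$elety[prot_idx],
             dna_chain = a$chain[dna_idx], dna_resno = a$resno[dna_idx],
             dna_resid = a$resid[dna_idx], dna_atom = a$elety[dna_idx],
             distance = dist, angle = angle, stringsAsFactors = FALSE)
}

hbond_geometry_ok <- function(a, donor_idx, acceptor_idx, angle_min) {
  # find hydrogens covalently attached to the donor (within 1.25 A)
  hs <- which(a$elesy == "H")
  if (length(hs) == 0L) return(list(ok = TRUE, angle = NA_real_))
  dpos <- as.numeric(a[donor_idx, c("x", "y", "z")])
  apos <- as.numeric(a[acceptor_idx, c("x", "y", "z")])
  hpos <- as.matrix(a[hs, c("x", "y", "z")])
  dh <- sqrt(rowSums(sweep(hpos, 2L, dpos)^2))
  attached <- hs[dh <= 1.25]
  if (length(attached) == 0L) return(list(ok = TRUE, angle = NA_real_))
  best <- -Inf
  for (h in attached) {
    hp <- as.numeric(a[h, c("x", "y", "z")])
    v1 <- dpos - hp; v2 <- apos - hp
    ang <- acos(pmin(pmax(sum(v1 * v2) /
                            (sqrt(sum(v1^2)) * sqrt(sum(v2^2))), -1), 1)) * 180 / pi
    best <- max(best, ang)
  }
  list(ok = best >= angle_min, angle = best)
}

#' Protein-DNA hydrogen bonds
#'
#' Donor-acceptor pairs across the protein/DNA interface with heavy-atom
#' distance at most the cutoff. Donor and acceptor atom classes come from a
#' built-in table covering the 20 amino acids (backbone N/O plus side-chain
#' donors/acceptors) and DNA (backbone OP1/OP2/O3'/O5'/O4' and base N/O).
#' When the structure contains hydrogens, the donor-H...acceptor angle must
#' also reach `hbond_angle_min`; hydrogen-free structures use the distance
#' criterion alone.
#'
#' @param structure a `structure3d` containing at least one protein and one
#'   nucleic chain.
#' @param criteria an [interaction_criteria()].
#' @return data.frame of interaction records (one row per donor/acceptor
#'   atom pair).
#' @export
hydrogen_bonds <- function(structure, criteria = interaction_criteria()) {
  iface <- split_interface(structure)
  a <- iface$atoms
  p_don <- protein_donor_idx(a, iface$prot)
  p_acc <- protein_acceptor_idx(a, iface$prot)
  n_don <- iface$nuc[a$elety[iface$nuc] %in% DNA_DONORS & a$elesy[iface$nuc] == "N"]
  n_acc <- iface$nuc[a$elety[iface$nuc] %in% DNA_ACCEPTORS]
  out <- list()
  add_pairs <- function(don, acc, prot_is_donor) {
    if (length(don) == 0L || length(acc) == 0L) return()
    dm <- pair_distances(a, don, acc)
    hits <- which(dm <= criteria$hbond_distance, arr.ind = TRUE)
    for (r in seq_len(nrow(hits))) {
      di <- don[hits[r, 1L]]; ai <- acc[hits[r, 2L]]
      geom <- hbond_geometry_ok(a, di, ai, criteria$hbond_angle_min)
      if (!geom$ok) next
      rec <- if (prot_is_donor)
        build_records(a, di, ai, dm[hits[r, 1L], hits[r, 2L]], "hbond", geom$angle)
      else
        build_records(a, ai, di, dm[hits[r, 1L], hits[r, 2L]], "hbond", geom$angle)
      out[[length(out) + 1L]] <<- rec
    }
  }
  add_pairs(p_don, n_acc, prot_is_donor = TRUE)
  add_pairs(n_don, p_acc, prot_is_donor = FALSE)
  collect_records(out)
}

#' Protein-DNA ionic interactions
#'
#' Side-chain cationic nitrogens of Lys/Arg/His (NZ; NE/NH1/NH2; ND1/NE2)
#' within the cutoff of DNA phosphate-backbone oxygens (OP1/OP2/O3'/O5').
#'
#' @inheritParams hydrogen_bonds
#' @return data.frame of interaction records.
#' @export
ionic_interactions <- function(structure, criteria = interaction_criteria()) {
  iface <- split_interface(structure)
  a <- iface$atoms
  cat_n <- iface$prot[mapply(function(rn, an)
    an %in% (CATIONIC_N[[rn]] %||% character(0L)),
    a$resid[iface$prot], a$elety[iface$prot])]
  phos_o <- iface$nuc[a$elety[iface$nuc] %in% PHOSPHATE_O]
  if (length(cat_n) == 0L || length(phos_o) == 0L) return(collect_records(list()))
  dm <- pair_distances(a, cat_n, phos_o)
  hits <- which(dm <= criteria$ionic_distance, arr.ind = TRUE)
  out <- lapply(seq_len(nrow(hits)), function(r)
    build_records(a, cat_n[hits[r, 1L]], phos_o[hits[r, 2L]],
                  dm[hits[r, 1L], hits[r, 2L]], "ionic"))
  collect_records(out)
}

#' Protein-DNA hydrophobic contacts
#'
#' Apolar side-chain carbons of Ala/Val/Leu/Ile/Met/Phe/Pro/Trp (plus Thr
#' CG2) within the cutoff of DNA deoxyribose-ring or base carbons,
#' aggregated to one record per (protein residue, nucleotide) pair keeping
#' the minimum distance.
#'
#' @inheritParams hydrogen_bonds
#' @return data.frame of interaction records.
#' @export
hydrophobic_contacts <- function(structure, criteria = interaction_criteria()) {
  iface <- split_interface(structure)
  a <- iface$atoms
  apolar_p <- iface$prot[
    a$elesy[iface$prot] == "C" &
      !(a$elety[iface$prot] %in% c("C", "CA")) &   # exclude backbone C/CA
      (a$resid[iface$prot] %in% APOLAR_SIDECHAINS |
         (a$resid[iface$prot] == "THR" & a$elety[iface$prot] == "CG2"))]
  apolar_n <- iface$nuc[a$elety[iface$nuc] %in% DNA_APOLAR_C]
  if (length(apolar_p) == 0L || length(apolar_n) == 0L)
    return(collect_records(list()))
  dm <- pair_distances(a, apolar_p, apolar_n)
  hits <- which(dm <= criteria$hydrophobic_distance, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(collect_records(list()))
  recs <- build_records(a, apolar_p[hits[, 1L]], apolar_n[hits[, 2L]],
                        dm[hits], "hydrophobic")
  # aggregate to one record per residue pair, keeping the closest approach
  key <- paste(recs$protein_chain, recs$protein_resno,
               recs$dna_chain, recs$dna_resno)
  recs <- recs[order(key, recs$distance), , drop = FALSE]
  recs <- recs[!duplicated(paste(recs$protein_chain, recs$protein_resno,
                                 recs$dna_chain, recs$dna_resno)), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

collect_records <- function(lst) {
  if (length(lst) == 0L)
    return(data.frame(kind = character(), protein_chain = character(),
                      protein_resno = integer(), protein_resid = character(),
                      protein_atom = character(), dna_chain = character(),
                      dna_resno = integer(), dna_resid = character(),
                      dna_atom = character(), distance = numeric(),
                      angle = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lst)
  out <- out[!duplicated(paste(out$protein_chain, out$protein_resno,
                               out$protein_atom, out$dna_chain,
                               out$dna_resno, out$dna_atom)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interface interaction counts by kind
#'
#' @inheritParams hydrogen_bonds
#' @return named list `hbond`, `ionic`, `hydrophobic` with integer counts;
#'   attribute `"criteria"` records the thresholds used.
#' @export
interaction_summary <- function(structure, criteria = interaction_criteria()) {
  out <- list(hbond = nrow(hydrogen_bonds(structure, criteria)),
              ionic = nrow(ionic_interactions(structure, criteria)),
              hydrophobic = nrow(hydrophobic_contacts(structure, criteria)))
  attr(out, "criteria") <- criteria
  out
}

#' Per-frame interaction counts over a trajectory
#'
#' @param traj a `trajectory` over a protein-DNA complex.
#' @param criteria an [interaction_criteria()].
#' @return data.frame with columns `frame`, `hbond`, `ionic`, `hydrophobic`;
#'   attribute `"criteria"` records the thresholds used.
#' @export
interaction_timeseries <- function(traj, criteria = interaction_criteria()) {
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    s <- interaction_summary(frame_structure(traj, f), criteria)
    data.frame(frame = f, hbond = s$hbond, ionic = s$ionic,
               hydrophobic = s$hydrophobic)
  })
  out <- do.call(rbind, rows)
  attr(out, "criteria") <- criteria
  out
}
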