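# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# minimal structure from a coordinate matrix (one CA bead per residue,
# chains split evenly when two_chains = TRUE)
bead_structure <- function(xyz, two_chains = TRUE) {
  n <- nrow(xyz)
  half <- if (two_chains) n %/% 2L else n
  structure3d(data.frame(
    eleno = seq_len(n), elety = "CA", resid = "GLY",
    chain = rep(c("A", "B"), c(half, n - half))[seq_len(n)],
    resno = c(seq_len(half), seq_len(n - half))[seq_len(n)],
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], elesy = "C",
    stringsAsFactors = FALSE), source = "test fixture")
}

# trajectory from a list of N x 3 coordinate matrices
traj_from_frames <- function(topology, frames) {
  trajectory(topology, do.call(rbind, lapply(frames, function(m)
    as.numeric(t(m)))))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# independent numeric superposition oracle: minimise RMSD over Euler angles
# and translation (translation handled by centering)
brute_force_rmsd <- function(mobile, reference) {
  a <- sweep(mobile, 2L, colMeans(mobile))
  b <- sweep(reference, 2L, colMeans(reference))
  rot_euler <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    rx %*% ry %*% rz
  }
  obj <- function(p) sqrt(mean(rowSums((a %*% rot_euler(p) - b)^2)))
  best <- Inf
  for (start in list(c(0, 0, 0), c(1, 1, 1), c(-1, 2, 0.5), c(2, -1, -2))) {
    r <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, r$value)
  }
  best
}

# protein-DNA complex with planted interface interactions:
#   5 hydrogen bonds (SER OG / backbone N donors at 3.0 A from OP1/O4 etc.)
#   2 ionic contacts (LYS NZ, ARG NH1 at 3.2 A from OP2/OP1)
#   3 hydrophobic contacts (VAL CG1, LEU CD1, ALA CB near sugar/base C)
# Atoms are spread far apart (>20 A) between planted pairs so no
# accidental extra contacts arise.
planted_complex <- function() {
  rows <- list()
  add <- function(elety, resid, chain, resno, x, y, z, elesy) {
    rows[[length(rows) + 1L]] <<- data.frame(
      eleno = length(rows) + 1L, elety = elety, resid = resid, chain = chain,
      resno = resno, x = x, y = y, z = z, elesy = elesy,
      stringsAsFactors = FALSE)
  }
  # --- hydrogen bonds: donor heavy atom exactly 3.0 A from acceptor
  add("OG", "SER", "A", 1, 0, 0, 0, "O");   add("OP1", "DT", "C", 1, 3, 0, 0, "O")
  add("OG1", "THR", "A", 2, 0, 30, 0, "O"); add("OP2", "DA", "C", 2, 3, 30, 0, "O")
  add("NE2", "GLN", "A", 3, 0, 60, 0, "N"); add("O4'", "DG", "C", 3, 3, 60, 0, "O")
  add("OH", "TYR", "A", 4, 0, 90, 0, "O");  add("O3'", "DC", "C", 4, 3, 90, 0, "O")
  add("N4", "DC", "C", 5, 0, 120, 0, "N");  add("O", "GLY", "A", 5, 3, 120, 0, "O")
  # --- ionic: cationic N exactly 3.7 A from phosphate O (beyond the
  # hydrogen-bond cutoff so the categories stay disjoint here)
  add("NZ", "LYS", "A", 6, 50, 0, 0, "N");  add("OP2", "DT", "C", 6, 53.7, 0, 0, "O")
  add("NH1", "ARG", "A", 7, 50, 30, 0, "N"); add("OP1", "DA", "C", 7, 53.7, 30, 0, "O")
  # --- hydrophobic: apolar carbons exactly 4.0 A apart
  add("CG1", "VAL", "A", 8, 100, 0, 0, "C"); add("C7", "DT", "C", 8, 104, 0, 0, "C")
  add("CD1", "LEU", "A", 9, 100, 30, 0, "C"); add("C1'", "DA", "C", 9, 104, 30, 0, "C")
  add("CB", "ALA", "A", 10, 100, 60, 0, "C"); add("C5", "DC", "C", 10, 104, 60, 0, "C")
  structure3d(do.call(rbind, rows), source = "planted interface fixture")
}

PLANTED_COUNTS <- list(hbond = 5L, ionic = 2L, hydrophobic = 3L)

# enumerate all set partitions of n items (restricted growth strings);
# Bell(8) = 4140, used for exhaustive modularity optimisation
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxl) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return(invisible()) }
    for (v in seq_len(maxl + 1L)) grow(c(prefix, v), max(maxl, v))
  }
  grow(1L, 1L)
  out
}

# small, fast dimer models used across test files
small_dimer <- function(...) {
  build_dimer_model(n_beads_per_chain = 8, community_layout = c(4, 4), ...)
}
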