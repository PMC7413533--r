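# Reaction coordinates, 2D potential-of-mean-force surfaces, basin
# detection and representative-structure extraction.

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation (det = +1) and translation minimising the RMSD
#' between two paired point sets, via SVD of the cross-covariance of the
#' centred coordinates.
#'
#' @param mobile n x 3 matrix to be superposed.
#' @param reference n x 3 matrix held fixed.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fitted
#'   mobile is `mobile %*% rotation + translation`), `rmsd` (Angstrom) and
#'   `fitted` (the transformed mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("point sets must be equal-sized n x 3 matrices")
  if (nrow(mobile) < 3L) stop("at least 3 points required")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  a <- sweep(mobile, 2L, mc); b <- sweep(reference, 2L, rc)
  if (sum(a^2) < 1e-12 || min(svd(a)$d) + svd(a)$d[2L] < 1e-10)
    stop("degenerate (collinear or coincident) point set")
  s <- svd(crossprod(a, b))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- a %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  list(rotation = rot, translation = rc - mc %*% rot, rmsd = rmsd,
       fitted = sweep(fitted, 2L, rc, `+`))
}

domain_ca_indices <- function(structure, region) {
  idx <- select_atoms(structure, chain = region$chains,
                      residue_range = region$dna_binding_domain,
                      atom_names = "CA")
  if (length(idx) == 0L)
    stop("no C-alpha atoms in the DNA-binding-domain range ",
         paste(region$dna_binding_domain, collapse = "-"))
  idx
}

#' Per-frame RMSD of the DNA-binding domain
#'
#' For every frame, the domain C-alpha atoms of both chains (pooled) are
#' superposed onto the same atoms of the reference structure and the
#' post-fit RMSD over that atom set is reported. The fit set and the report
#' set are identical by default.
#'
#' @param traj a `trajectory`.
#' @param reference a `structure3d` (the starting structure of the system
#'   without DNA, in the intended use).
#' @param region a `region_config` supplying the domain residue range.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
domain_rmsd <- function(traj, reference, region) {
  idx_t <- domain_ca_indices(traj$topology, region)
  idx_r <- domain_ca_indices(reference, region)
  if (length(idx_t) != length(idx_r)) {
    at <- traj$topology$atoms[idx_t, ]; ar <- reference$atoms[idx_r, ]
    miss <- setdiff(paste(ar$chain, ar$resno), paste(at$chain, at$resno))
    stop("domain selection mismatch (", length(idx_t), " vs ", length(idx_r),
         " atoms); missing in trajectory: ",
         paste(head(miss, 5L), collapse = ", "))
  }
  ref <- coords(reference)[idx_r, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(f) {
    kabsch_superpose(frame_coords(traj, f)[idx_t, , drop = FALSE], ref)$rmsd
  }, numeric(1L))
}

#' Per-frame distance between the two recognition-helix probe C-alphas
#'
#' The Euclidean distance between the probe residue's C-alpha on the first
#' protein chain and the same residue's C-alpha on the second chain.
#'
#' @param traj a `trajectory`.
#' @param region a `region_config` supplying `probe_residue` and the chains.
#' @return numeric vector, one distance (Angstrom) per frame.
#' @export
interhelix_distance <- function(traj, region) {
  structure <- traj$topology
  pr <- region$probe_residue
  idx <- lapply(region$chains, function(ch)
    select_atoms(structure, chain = ch, residue_range = c(pr, pr),
                 atom_names = "CA"))
  bad <- lengths(idx) != 1L
  if (any(bad))
    stop("probe residue ", pr, " C-alpha absent or ambiguous on chain ",
         paste(region$chains[bad], collapse = ","))
  i <- idx[[1L]]; j <- idx[[2L]]
  vapply(seq_len(n_frames(traj)), function(f) {
    m <- frame_coords(traj, f)
    sqrt(sum((m[i, ] - m[j, ])^2))
  }, numeric(1L))
}

#' Probe distance of a single structure
#' @param structure a `structure3d`.
#' @param region a `region_config`.
#' @return distance, Angstrom.
#' @export
structure_interhelix_distance <- function(structure, region) {
  interhelix_distance(trajectory(structure, matrix(as.numeric(t(coords(structure))),
                                                   nrow = 1L)), region)
}

#' Two-dimensional potential of mean force
#'
#' Histograms the two reaction coordinates on an `n_bins x n_bins` grid of
#' equal-width bins, normalises to a joint probability `g(x, y)`, and
#' converts to free energy `deltaG = -kB T log g`, shifted so the minimum
#' over occupied bins is zero. Empty bins are undefined (`NA`). Bin ranges
#' default to the observed `[min, max]` per axis; explicit ranges allow
#' surfaces of different systems to share axes.
#'
#' @param x,y reaction-coordinate series (e.g. domain RMSD and inter-helix
#'   distance), equal length, Angstrom.
#' @param n_bins bins per axis (default 30).
#' @param temperature K.
#' @param weights optional per-frame weights (e.g. [reweight_frames()]);
#'   default unweighted.
#' @param x_range,y_range optional explicit `c(lo, hi)` bin ranges.
#' @return object of class `free_energy_surface`: `x_edges`, `y_edges`
#'   (length `n_bins + 1`), `counts`, `weight_sum`, `delta_g` (kcal/mol,
#'   `NA` where empty) and `temperature`.
#' @export
pmf_2d <- function(x, y, n_bins = 30L, temperature = 300, weights = NULL,
                   x_range = range(x), y_range = range(y)) {
  stopifnot(length(x) == length(y), length(x) >= 1L, n_bins >= 2L)
  if (diff(range(x_range)) == 0 || diff(range(y_range)) == 0)
    stop("zero-variance reaction coordinate: degenerate landscape")
  if (is.null(weights)) weights <- rep(1 / length(x), length(x))
  weights <- weights / sum(weights)
  x_edges <- seq(x_range[1L], x_range[2L], length.out = n_bins + 1L)
  y_edges <- seq(y_range[1L], y_range[2L], length.out = n_bins + 1L)
  bx <- pmin(pmax(findInterval(x, x_edges, rightmost.closed = TRUE), 1L), n_bins)
  by <- pmin(pmax(findInterval(y, y_edges, rightmost.closed = TRUE), 1L), n_bins)
  inside <- x >= x_range[1L] & x <= x_range[2L] & y >= y_range[1L] & y <= y_range[2L]
  counts <- matrix(0L, n_bins, n_bins)
  wsum <- matrix(0, n_bins, n_bins)
  for (r in which(inside)) {
    counts[bx[r], by[r]] <- counts[bx[r], by[r]] + 1L
    wsum[bx[r], by[r]] <- wsum[bx[r], by[r]] + weights[r]
  }
  g <- wsum / sum(wsum)
  kt <- KB_KCAL * temperature
  dg <- -kt * log(g)
  dg[g == 0] <- NA_real_
  dg <- dg - min(dg, na.rm = TRUE)
  out <- list(x_edges = x_edges, y_edges = y_edges, counts = counts,
              weight_sum = wsum, delta_g = dg, temperature = temperature,
              bin_x = bx, bin_y = by)
  class(out) <- "free_energy_surface"
  out
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("free_energy_surface: %d x %d bins, %d frames, T = %g K, max deltaG %.2f kcal/mol\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts), x$temperature,
              max(x$delta_g, na.rm = TRUE)))
  invisible(x)
}

#' Detect free-energy basins on a 2D surface
#'
#' A basin is an occupied bin whose free energy is strictly lower than that
#' of every occupied bin among its 8 neighbours (undefined neighbours count
#' as infinitely high; ties disqualify). Basins are returned sorted by
#' increasing free energy, with bin centers and, when the surface retains
#' frame assignments, the member frame indices.
#'
#' @param surface a `free_energy_surface`.
#' @return data.frame with columns `i`, `j` (bin indices), `x_center`,
#'   `y_center`, `delta_g`, and a list-column `members` of frame indices.
#' @export
find_basins <- function(surface) {
  dg <- surface$delta_g
  n1 <- nrow(dg); n2 <- ncol(dg)
  hits <- list()
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    v <- dg[i, j]
    if (is.na(v)) next
    lower <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- i + di; jj <- j + dj
      if (ii < 1L || ii > n1 || jj < 1L || jj > n2) next
      nb <- dg[ii, jj]
      if (!is.na(nb) && nb <= v) lower <- FALSE
    }
    if (lower) hits[[length(hits) + 1L]] <- c(i, j, v)
  }
  if (length(hits) == 0L)
    return(data.frame(i = integer(), j = integer(), x_center = numeric(),
                      y_center = numeric(), delta_g = numeric()))
  m <- do.call(rbind, hits)
  xc <- (surface$x_edges[-1L] + surface$x_edges[-length(surface$x_edges)]) / 2
  yc <- (surface$y_edges[-1L] + surface$y_edges[-length(surface$y_edges)]) / 2
  out <- data.frame(i = as.integer(m[, 1L]), j = as.integer(m[, 2L]),
                    x_center = xc[m[, 1L]], y_center = yc[m[, 2L]],
                    delta_g = m[, 3L])
  out <- out[order(out$delta_g), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(surface$bin_x))
    out$members <- lapply(seq_len(nrow(out)), function(r)
      which(surface$bin_x == out$i[r] & surface$bin_y == out$j[r]))
  out
}

pairwise_domain_rmsd <- function(traj, frames, region) {
  idx <- domain_ca_indices(traj$topology, region)
  sets <- lapply(frames, function(f) frame_coords(traj, f)[idx, , drop = FALSE])
  n <- length(sets)
  d <- matrix(0, n, n)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
    d[a, b] <- d[b, a] <- kabsch_superpose(sets[[a]], sets[[b]])$rmsd
  d
}

#' Representative frame of a basin
#'
#' Member frames of the basin are clustered by average-linkage hierarchical
#' clustering on pairwise DNA-binding-domain C-alpha RMSD; the dendrogram is
#' cut at half its maximum merge height, the largest cluster is taken, and
#' the frame minimising the summed RMSD to the other members of that cluster
#' (the medoid) is returned. A single-member basin returns its frame.
#'
#' Populous basins are thinned deterministically (every k-th member) to at
#' most `max_members` frames before the quadratic-cost clustering.
#'
#' @param traj a `trajectory`.
#' @param basin one row of [find_basins()] output (with `members`).
#' @param region a `region_config`.
#' @param max_members ceiling on frames entering the pairwise-RMSD
#'   clustering (default 120).
#' @return frame index into `traj`.
#' @export
representative_frame <- function(traj, basin, region, max_members = 120L) {
  members <- if (is.list(basin$members)) basin$members[[1L]] else basin$members
  if (length(members) == 0L) stop("basin has no member frames")
  if (length(members) == 1L) return(members)
  if (length(members) > max_members) {
    step <- ceiling(length(members) / max_members)
    members <- members[seq(1L, length(members), by = step)]
  }
  d <- pairwise_domain_rmsd(traj, members, region)
  if (max(d) < 1e-12) return(members[1L])
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, h = max(hc$height) / 2)
  biggest <- as.integer(names(which.max(table(cl))))
  in_big <- which(cl == biggest)
  sums <- rowSums(d[in_big, in_big, drop = FALSE])
  members[in_big[which.min(sums)]]
}

#' Block-bootstrap standard error of the basin free-energy gap
#'
#' Resamples contiguous frame blocks, rebuilds the surface on the original
#' bin edges, re-detects the two lowest basins and records their
#' free-energy gap. Reports the bootstrap standard error. The default block
#' length is five times the integrated autocorrelation time of the slower
#' reaction coordinate (blocks must exceed the correlation time of the
#' well-exchange dynamics, or the error is understated), capped at a tenth
#' of the series.
#'
#' @param x,y reaction-coordinate series.
#' @param surface the original `free_energy_surface` (its edges are reused).
#' @param n_boot bootstrap replicates (default 200).
#' @param block_len block length in frames; default as described above.
#' @param seed RNG seed for resampling.
#' @return list with `se`, `block_len` and the vector of replicate `gaps`
#'   (NA where a replicate had fewer than two basins).
#' @export
bootstrap_basin_gap <- function(x, y, surface, n_boot = 200L,
                                block_len = NULL, seed = 1L) {
  if (is.null(block_len)) {
    tau <- max(integrated_act(x), integrated_act(y))
    block_len <- max(1L, min(ceiling(5 * tau), length(x) %/% 10L))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  nf <- length(x)
  n_blocks <- ceiling(nf / block_len)
  starts_all <- seq_len(max(nf - block_len + 1L, 1L))
  gaps <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    starts <- sample(starts_all, n_blocks, replace = TRUE)
    idx <- unlist(lapply(starts, function(s) s:min(s + block_len - 1L, nf)))[seq_len(nf)]
    surf <- pmf_2d(x[idx], y[idx], n_bins = length(surface$x_edges) - 1L,
                   temperature = surface$temperature,
                   x_range = range(surface$x_edges),
                   y_range = range(surface$y_edges))
    bas <- find_basins(surf)
    if (nrow(bas) >= 2L) gaps[b] <- bas$delta_g[2L] - bas$delta_g[1L]
  }
  list(se = stats::sd(gaps, na.rm = TRUE), block_len = block_len, gaps = gaps)
}

# integrated autocorrelation time (frames) by initial-positive-sequence sum
integrated_act <- function(x, max_lag = min(length(x) %/% 3L, 5000L)) {
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1L]
  pos <- which(rho <= 0)
  if (length(pos) > 0L) rho <- rho[seq_len(pos[1L] - 1L)]
  1 + 2 * sum(rho)
}
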