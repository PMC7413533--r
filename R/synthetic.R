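# Coarse-grained two-chain dimer with planted ground truth:
#  - an elastic network holding each chain together,
#  - a double-well (or harmonic) potential on the distance between the two
#    "recognition helix" group centroids, giving a two-state ensemble,
#  - a block layout of beads giving a known contact-graph community
#    structure and known correlated/anticorrelated bead pairs.

BLOCK_SPACING <- 3.0   # bead grid spacing within a block, Angstrom
BLOCK_GAP <- 8         # gap between consecutive blocks, Angstrom
SPRING_CUT <- 4.5      # rest-distance cutoff for intra-block springs
K_INTRA <- 10          # intra-block spring constant, kcal/mol/A^2
K_BACKBONE <- 10       # block-connector spring constant
K_TETHER <- 0.5        # bead positional tether, kcal/mol/A^2
K_MIDPOINT <- 20       # restraint on the symmetric helix-pair x-translation

# snake-ordered 3D grid positions for n beads (near-cubic footprint)
block_grid <- function(n, a = BLOCK_SPACING) {
  nz <- max(1L, floor(n^(1 / 3)))
  nx <- ceiling(sqrt(n / nz))
  ny <- ceiling(n / (nx * nz))
  pos <- matrix(0, n, 3L)
  i <- 1L
  for (k in seq_len(nz)) {
    for (j in seq_len(ny)) {
      cols <- seq_len(nx)
      if (j %% 2L == 0L) cols <- rev(cols)   # snake within layer
      for (c in cols) {
        if (i > n) break
        pos[i, ] <- c((c - 1L) * a, (j - 1L) * a, (k - 1L) * a)
        i <- i + 1L
      }
    }
  }
  pos
}

#' Build a coarse-grained two-chain dimer model with planted ground truth
#'
#' Each chain is a stack of compact bead blocks (one planted community per
#' block) connected by weak backbone springs; beads within a block are
#' cross-linked by stiff springs so blocks move quasi-rigidly. The final
#' block of each chain plays the role of the recognition helix: the distance
#' between the two final-block centroids is governed by a double-well
#' potential, so the dimer samples an open and a closed state. The model
#' records the planted community partition and a set of bead pairs with
#' known fluctuation-correlation signs (same-block pairs move together;
#' recognition-helix pairs across chains move in antiphase).
#'
#' The chains are not free-floating: beads outside the recognition-helix
#' blocks carry weak three-dimensional positional tethers, and helix beads
#' carry tethers in the two directions transverse to the separation axis,
#' mimicking the orientational confinement a folded dimer has. The
#' symmetric x-translation of the two helix groups (their midpoint) is also
#' restrained. Together these suppress whole-chain tumbling and slow
#' pendulum modes (which would otherwise drown the planted correlation
#' structure in unbounded diffusion) while leaving the antisymmetric
#' inter-helix separation coordinate fully unrestrained, so the double well
#' alone governs its equilibrium distribution.
#'
#' @param n_beads_per_chain beads per chain; must equal `sum(community_layout)`.
#' @param community_layout integer vector of block sizes per chain; every
#'   block must have at least 3 beads so no planted community falls under the
#'   small-community discard rule.
#' @param doublewell_spec either `list(d1=, d2=, barrier=, delta_g=)` for a
#'   quartic double well on the inter-group centroid distance (well centers
#'   `d1 < d2` in Angstrom, `barrier` in kcal/mol above the well floor,
#'   `delta_g` the free-energy tilt of well 1 relative to well 2, default 0),
#'   or `list(type="harmonic", k=, d0=)` for a harmonic tether (used for
#'   closed-form variance checks).
#' @param anticorrelated_pairs optional list of global bead index pairs whose
#'   planted correlation sign is negative; defaults to three pairs spanning
#'   the two recognition-helix blocks.
#' @param seed integer seed recorded in the model (placement is
#'   deterministic; the seed namespaces downstream simulations).
#' @return object of class `dimer_model`.
#' @export
build_dimer_model <- function(n_beads_per_chain = 40,
                              community_layout = c(14, 13, 13),
                              doublewell_spec = list(d1 = 24, d2 = 32,
                                                     barrier = 4, delta_g = 0),
                              anticorrelated_pairs = NULL,
                              seed = 1L) {
  if (sum(community_layout) != n_beads_per_chain)
    stop("community_layout must sum to n_beads_per_chain")
  if (any(community_layout < 3L))
    stop("every planted community needs at least 3 beads")
  dw <- normalize_doublewell(doublewell_spec)

  n_blocks <- length(community_layout)
  # chain A geometry: blocks stacked along y
  pos <- matrix(0, 0, 3L)
  block_id <- integer(0L)
  y0 <- 0
  for (b in seq_len(n_blocks)) {
    g <- block_grid(community_layout[b])
    g[, 2L] <- g[, 2L] + y0
    y0 <- max(g[, 2L]) + BLOCK_GAP
    pos <- rbind(pos, g)
    block_id <- c(block_id, rep(b, community_layout[b]))
  }
  helix_a <- which(block_id == n_blocks)

  # chain B: translate along x so the two recognition-helix centroids start
  # at the model's resting separation (outer well for a double well)
  d_start <- if (dw$type == "harmonic") dw$d0 else dw$d2
  ca <- colMeans(pos[helix_a, , drop = FALSE])
  pos_b <- pos
  pos_b[, 1L] <- pos_b[, 1L] + d_start
  n <- n_beads_per_chain
  beads <- data.frame(
    chain = rep(c("A", "B"), each = n),
    resno = rep(seq_len(n), 2L),
    block = rep(block_id, 2L),
    stringsAsFactors = FALSE)
  xyz <- rbind(pos, pos_b)

  # springs: stiff within blocks, one weak connector between consecutive blocks
  edges <- list()
  for (ch in 0:1) {
    off <- ch * n
    d <- as.matrix(stats::dist(xyz[off + seq_len(n), , drop = FALSE]))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (block_id[i] == block_id[j] && d[i, j] <= SPRING_CUT)
        edges[[length(edges) + 1L]] <- c(off + i, off + j, K_INTRA, d[i, j])
    }
    for (b in seq_len(n_blocks - 1L)) {
      ii <- which(block_id == b); jj <- which(block_id == b + 1L)
      sub <- d[ii, jj, drop = FALSE]
      w <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
      edges[[length(edges) + 1L]] <- c(off + ii[w[1L]], off + jj[w[2L]],
                                       K_BACKBONE, sub[w[1L], w[2L]])
    }
  }
  edges <- do.call(rbind, edges)
  colnames(edges) <- c("i", "j", "k", "r0")

  group_a <- helix_a
  group_b <- helix_a + n
  partition <- paste0(beads$chain, beads$block)

  if (is.null(anticorrelated_pairs)) {
    k <- min(3L, length(group_a))
    anticorrelated_pairs <- lapply(seq_len(k),
                                   function(t) c(group_a[t], group_b[t]))
  }
  sign_pairs <- do.call(rbind, lapply(anticorrelated_pairs, function(p)
    data.frame(i = p[1L], j = p[2L], sign = -1L)))
  # planted positive pairs: bead pairs inside the chain-A recognition helix
  kpos <- min(3L, length(group_a) - 1L)
  pos_pairs <- data.frame(i = group_a[seq_len(kpos)],
                          j = group_a[seq_len(kpos) + 1L], sign = 1L)
  sign_pairs <- rbind(sign_pairs, pos_pairs)

  model <- list(beads = beads, xyz = xyz, edges = as.data.frame(edges),
                doublewell = c(dw, list(group_a = group_a, group_b = group_b)),
                planted_partition = partition,
                planted_sign_pairs = sign_pairs,
                community_layout = community_layout,
                probe_residue = beads$resno[helix_a[ceiling(length(helix_a) / 2)]],
                domain_range = range(beads$resno[helix_a]),
                k_tether = K_TETHER, k_midpoint = K_MIDPOINT,
                seed = as.integer(seed))
  class(model) <- "dimer_model"
  model
}

normalize_doublewell <- function(spec) {
  if (!is.null(spec$type) && spec$type == "harmonic") {
    stopifnot(spec$k > 0, spec$d0 > 0)
    return(list(type = "harmonic", k = spec$k, d0 = spec$d0))
  }
  stopifnot(spec$d1 != spec$d2, spec$barrier > 0)
  d1 <- min(spec$d1, spec$d2); d2 <- max(spec$d1, spec$d2)
  delta_g <- if (is.null(spec$delta_g)) 0 else spec$delta_g
  c0 <- (d1 + d2) / 2; w <- (d2 - d1) / 2
  list(type = "quartic", d1 = d1, d2 = d2, barrier = spec$barrier,
       delta_g = delta_g, center = c0, halfwidth = w,
       tilt = -delta_g / (2 * w))
}

#' Double-well energy as a function of the inter-group centroid distance
#' @param dw the `doublewell` element of a `dimer_model` (or the output of
#'   the internal normaliser).
#' @param d centroid distance(s), Angstrom.
#' @return energy, kcal/mol.
#' @export
doublewell_energy <- function(dw, d) {
  if (dw$type == "harmonic") return(0.5 * dw$k * (d - dw$d0)^2)
  x <- d - dw$center
  dw$barrier * (x^2 - dw$halfwidth^2)^2 / dw$halfwidth^4 + dw$tilt * x
}

doublewell_dudd <- function(dw, d) {
  if (dw$type == "harmonic") return(dw$k * (d - dw$d0))
  x <- d - dw$center
  dw$barrier * 4 * x * (x^2 - dw$halfwidth^2) / dw$halfwidth^4 + dw$tilt
}

#' Analytic equilibrium properties of the planted double well
#'
#' Because the transverse components of the inter-group vector are tethered,
#' the centroid distance behaves as a one-dimensional coordinate with
#' equilibrium density `p(d) proportional to exp(-U(d)/kBT)`. This helper
#' locates the two potential minima and the barrier top (roots of the cubic
#' derivative), integrates the density over each well, and reports the well
#' populations and the implied free-energy gap. It is the closed-form
#' reference that simulated populations and recovered landscapes are
#' checked against.
#'
#' @param dw the `doublewell` element of a `dimer_model`.
#' @param temperature K.
#' @return list with `minima` (Angstrom), `split` (barrier-top distance),
#'   `p1`, `p2` (well populations) and `delta_g` (= -kBT log(p1/p2),
#'   kcal/mol).
#' @export
doublewell_reference <- function(dw, temperature = 300) {
  stopifnot(dw$type == "quartic")
  kt <- KB_KCAL * temperature
  # U'(x) = (4h/w^4) x^3 - (4h/w^2) x + tilt
  h <- dw$barrier; w <- dw$halfwidth
  roots <- polyroot(c(dw$tilt, -4 * h / w^2, 0, 4 * h / w^4))
  re <- sort(Re(roots[abs(Im(roots)) < 1e-8]))
  if (length(re) != 3L) stop("double well has no barrier at this tilt")
  minima <- dw$center + re[c(1L, 3L)]
  split <- dw$center + re[2L]
  dens <- function(d) exp(-(doublewell_energy(dw, d) -
                              doublewell_energy(dw, minima[1L])) / kt)
  lo <- max(0, minima[1L] - 6 * w); hi <- minima[2L] + 6 * w
  z1 <- stats::integrate(dens, lo, split)$value
  z2 <- stats::integrate(dens, split, hi)$value
  p1 <- z1 / (z1 + z2); p2 <- z2 / (z1 + z2)
  list(minima = minima, split = split, p1 = p1, p2 = p2,
       delta_g = -kt * log(p1 / p2))
}

#' Simulate overdamped Langevin dynamics of a dimer model
#'
#' Euler-Maruyama integration of position Langevin dynamics on the elastic +
#' double-well potential: `dx = F/gamma dt + sqrt(2 kBT dt / gamma) N(0,1)`.
#' The friction `gamma` is expressed so that the diffusion constant is
#' `kBT/gamma` in A^2/ps; the stationary distribution is Boltzmann at the
#' requested temperature regardless of `gamma`. When `boost` is supplied the
#' double-well term is propagated on the accelerated-MD modified potential:
#' its force is scaled by [boost_force_scale()] whenever the double-well
#' energy falls below the threshold, which flattens the barrier and speeds
#' well-to-well exchange.
#'
#' @param model a `dimer_model`.
#' @param n_steps number of integration steps (>= 1).
#' @param dt time step, ps.
#' @param temperature K.
#' @param friction friction, ps^-1 (default 0.2, chosen so the inter-group
#'   distance decorrelates within short desk-scale runs; the stationary
#'   distribution does not depend on it).
#' @param seed mandatory integer seed; identical seeds give bitwise-identical
#'   trajectories. The global RNG state is restored on exit.
#' @param stride store every `stride`-th step (the initial configuration is
#'   not stored).
#' @param boost optional `list(e_thresh=, alpha=)` in kcal/mol applied to the
#'   double-well energy term.
#' @return a `trajectory` whose topology is [model_structure()]; the extra
#'   element `$observables` holds per-stored-frame step number, inter-group
#'   centroid distance, double-well energy and boost energy.
#' @export
simulate_dimer <- function(model, n_steps, dt = 0.002, temperature = 300,
                           friction = 0.2, seed, stride = 10L, boost = NULL) {
  stopifnot(inherits(model, "dimer_model"), n_steps >= 1, dt > 0)
  if (missing(seed)) stop("seed is mandatory")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  x <- model$xyz
  x_rest <- model$xyz
  k_teth <- if (is.null(model$k_tether)) 0 else model$k_tether
  k_mid <- if (is.null(model$k_midpoint)) 0 else model$k_midpoint
  nb <- nrow(x)
  ei <- model$edges$i; ej <- model$edges$j
  ek <- model$edges$k; er0 <- model$edges$r0
  # signed incidence matrix: force on beads = inc %*% per-edge force vectors
  ne <- length(ei)
  inc <- matrix(0, nb, ne)
  inc[cbind(ei, seq_len(ne))] <- 1
  inc[cbind(ej, seq_len(ne))] <- -1
  dw <- model$doublewell
  ga <- dw$group_a; gb <- dw$group_b
  na_g <- length(ga); nb_g <- length(gb)
  kt <- KB_KCAL * temperature
  noise_sd <- sqrt(2 * kt * dt / friction)
  mob <- dt / friction
  helix <- c(ga, gb)
  nonhelix <- setdiff(seq_len(nb), helix)
  mid_rest <- (mean(x_rest[ga, 1L]) + mean(x_rest[gb, 1L])) / 2

  n_store <- n_steps %/% stride
  xyz_out <- matrix(NA_real_, max(n_store, 1L), 3L * nb)
  obs <- matrix(NA_real_, max(n_store, 1L), 4L)
  row <- 0L

  for (s in seq_len(n_steps)) {
    # elastic forces
    dvec <- x[ei, , drop = FALSE] - x[ej, , drop = FALSE]
    dlen <- sqrt(.rowSums(dvec^2, ne, 3L))
    fmag <- -ek * (dlen - er0) / pmax(dlen, 1e-12)
    f <- inc %*% (dvec * fmag)
    # tethers: transverse everywhere, x only outside the helix groups;
    # the symmetric helix-pair x-translation is restrained via its midpoint
    f[, 2L] <- f[, 2L] - k_teth * (x[, 2L] - x_rest[, 2L])
    f[, 3L] <- f[, 3L] - k_teth * (x[, 3L] - x_rest[, 3L])
    f[nonhelix, 1L] <- f[nonhelix, 1L] -
      k_teth * (x[nonhelix, 1L] - x_rest[nonhelix, 1L])
    mid <- (mean(x[ga, 1L]) + mean(x[gb, 1L])) / 2
    f[ga, 1L] <- f[ga, 1L] - k_mid * (mid - mid_rest) / (2 * na_g)
    f[gb, 1L] <- f[gb, 1L] - k_mid * (mid - mid_rest) / (2 * nb_g)
    # double-well force on group centroids
    ca <- colMeans(x[ga, , drop = FALSE])
    cb <- colMeans(x[gb, , drop = FALSE])
    dab <- ca - cb
    dcen <- sqrt(sum(dab^2))
    u_dw <- doublewell_energy(dw, dcen)
    scale <- if (!is.null(boost)) boost_force_scale(u_dw, boost$e_thresh, boost$alpha) else 1
    fd <- -doublewell_dudd(dw, dcen) * scale * dab / max(dcen, 1e-12)
    f[ga, ] <- f[ga, ] + matrix(fd / na_g, na_g, 3L, byrow = TRUE)
    f[gb, ] <- f[gb, ] - matrix(fd / nb_g, nb_g, 3L, byrow = TRUE)

    x <- x + f * mob + matrix(stats::rnorm(nb * 3L, sd = noise_sd), nb, 3L)
    if (max(abs(x)) > 1e6)
      stop("simulation blew up (coordinate beyond 1e6 A); use a smaller dt")
    if (s %% stride == 0L) {
      row <- row + 1L
      xyz_out[row, ] <- as.numeric(t(x))
      dv <- if (!is.null(boost)) boost_potential(u_dw, boost$e_thresh, boost$alpha) else 0
      obs[row, ] <- c(s, dcen, u_dw, dv)
    }
  }
  if (row == 0L) {  # fewer steps than stride: store the final state
    row <- 1L
    xyz_out[1L, ] <- as.numeric(t(x))
    ca <- colMeans(x[ga, , drop = FALSE]); cb <- colMeans(x[gb, , drop = FALSE])
    dcen <- sqrt(sum((ca - cb)^2))
    obs[1L, ] <- c(n_steps, dcen, doublewell_energy(dw, dcen), 0)
  }
  traj <- trajectory(model_structure(model), xyz_out[seq_len(row), , drop = FALSE],
                     frame_spacing = dt * stride)
  obs <- as.data.frame(obs[seq_len(row), , drop = FALSE])
  names(obs) <- c("step", "centroid_distance", "u_doublewell", "delta_v")
  traj$observables <- obs
  traj
}

#' Structure view of a dimer model
#'
#' Beads are rendered as glycine C-alpha pseudo-atoms (one per residue) on
#' two chains with 1-based residue numbering.
#'
#' @param model a `dimer_model`.
#' @param xyz optional replacement coordinates (defaults to rest coordinates).
#' @return a `structure3d`.
#' @export
model_structure <- function(model, xyz = model$xyz) {
  b <- model$beads
  structure3d(data.frame(eleno = seq_len(nrow(b)), elety = "CA", resid = "GLY",
                         chain = b$chain, resno = b$resno,
                         x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                         elesy = "C", stringsAsFactors = FALSE),
              source = "synthetic dimer model")
}

#' Region configuration matching a dimer model
#'
#' The DNA-binding-domain range is the recognition-helix block and the probe
#' residue is its central bead.
#'
#' @param model a `dimer_model`.
#' @param temperature K.
#' @return a `region_config`.
#' @export
model_region_config <- function(model, temperature = 300) {
  region_config(chains = c("A", "B"),
                elements = list(),
                dna_binding_domain = model$domain_range,
                probe_residue = model$probe_residue,
                temperature = temperature)
}

#' Count well-to-well crossings of a distance series
#'
#' Hysteretic two-state assignment: the series is in state 1 below
#' `d1 + margin` and in state 2 above `d2 - margin`; a crossing is a change
#' of assigned state. Frames in the barrier region keep the last assigned
#' state, so barrier-top jitter is not counted.
#'
#' @param distance numeric series of the reaction coordinate, Angstrom.
#' @param d1,d2 well centers, Angstrom (`d1 < d2`).
#' @param margin hysteresis margin, Angstrom; default a quarter of the well
#'   separation.
#' @return integer number of crossings.
#' @export
count_well_crossings <- function(distance, d1, d2, margin = (d2 - d1) / 4) {
  state <- ifelse(distance < d1 + margin, 1L,
                  ifelse(distance > d2 - margin, 2L, NA_integer_))
  state <- filled_state(state)
  sum(diff(state[!is.na(state)]) != 0L)
}

filled_state <- function(state) {
  last <- NA_integer_
  for (t in seq_along(state)) {
    if (is.na(state[t])) state[t] <- last else last <- state[t]
  }
  state
}

#' Write a reusable fixture bundle for a simulated dimer
#'
#' Emits the four files every downstream stage needs: `topology.pdb` (rest
#' structure), `trajectory.dcd`, `regions.yaml` and `ground_truth.json`
#' (schema version 1: planted partition, planted sign pairs, well centers,
#' analytic well populations, probe residue and domain range).
#'
#' @param model a `dimer_model`.
#' @param traj a `trajectory` from [simulate_dimer()].
#' @param out_dir output directory (created if absent).
#' @param temperature K, used for the analytic population entry.
#' @return named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(model, traj, out_dir, temperature = 300) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(topology = file.path(out_dir, "topology.pdb"),
             trajectory = file.path(out_dir, "trajectory.dcd"),
             regions = file.path(out_dir, "regions.yaml"),
             ground_truth = file.path(out_dir, "ground_truth.json"))
  write_structure(model_structure(model), paths[["topology"]])
  write_dcd(traj, paths[["trajectory"]])
  write_region_config(model_region_config(model, temperature), paths[["regions"]])
  gt <- list(schema_version = 1L,
             planted_partition = model$planted_partition,
             planted_sign_pairs = model$planted_sign_pairs,
             doublewell = model$doublewell[setdiff(names(model$doublewell),
                                                   c("group_a", "group_b"))],
             probe_residue = model$probe_residue,
             domain_range = model$domain_range,
             seed = model$seed)
  if (model$doublewell$type == "quartic") {
    ref <- doublewell_reference(model$doublewell, temperature)
    gt$well_centers <- ref$minima
    gt$expected_populations <- c(ref$p1, ref$p2)
    gt$expected_delta_g <- ref$delta_g
  }
  jsonlite::write_json(gt, paths[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
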