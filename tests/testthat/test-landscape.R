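test_that("Kabsch superposition recovers exact rigid transformations", {
  set.seed(7)
  ref <- matrix(rnorm(30, sd = 5), 10L, 3L)
  fit <- kabsch_superpose(ref, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  for (rep in 1:5) {
    rot <- random_rotation()
    moved <- ref %*% rot + matrix(rnorm(3, sd = 20), 10L, 3L, byrow = TRUE)
    fit <- kabsch_superpose(moved, ref)
    expect_equal(fit$rmsd, 0, tolerance = 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  }
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "3 points")
  collinear <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(collinear, collinear), "degenerate")
})

test_that("Kabsch RMSD matches a brute-force rotational optimiser", {
  square <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0))
  bumped <- square
  bumped[2L, ] <- bumped[2L, ] + c(0, 0, 1)
  expect_equal(kabsch_superpose(bumped, square)$rmsd,
               brute_force_rmsd(bumped, square), tolerance = 1e-5)
  set.seed(21)
  for (rep in 1:5) {
    a <- matrix(rnorm(18, sd = 4), 6L, 3L)
    b <- a + matrix(rnorm(18, sd = 0.7), 6L, 3L)
    expect_equal(kabsch_superpose(a, b)$rmsd, brute_force_rmsd(a, b),
                 tolerance = 1e-4)
  }
  # cross-check against an established fitter
  a <- matrix(rnorm(24, sd = 4), 8L, 3L)
  b <- a + matrix(rnorm(24, sd = 0.5), 8L, 3L)
  ours <- kabsch_superpose(a, b)$rmsd
  theirs <- bio3d::rmsd(as.numeric(t(b)), as.numeric(t(a)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("domain RMSD is zero for the reference and rigid copies of it", {
  m <- small_dimer()
  s <- model_structure(m)
  region <- model_region_config(m)
  ref_xyz <- coords(s)
  rot <- ref_xyz %*% random_rotation() + 5
  tr <- traj_from_frames(s, list(ref_xyz, rot))
  r <- domain_rmsd(tr, s, region)
  expect_equal(r, c(0, 0), tolerance = 1e-8)
})

test_that("domain RMSD of a perturbed frame matches the brute-force oracle", {
  set.seed(31)
  m <- small_dimer()
  s <- model_structure(m)
  region <- model_region_config(m)
  idx <- select_atoms(s, chain = c("A", "B"),
                      residue_range = region$dna_binding_domain,
                      atom_names = "CA")
  moved <- coords(s)
  moved[idx, ] <- moved[idx, ] + matrix(rnorm(length(idx) * 3, sd = 1),
                                        length(idx), 3L)
  tr <- traj_from_frames(s, list(moved))
  expect_equal(domain_rmsd(tr, s, region),
               brute_force_rmsd(moved[idx, ], coords(s)[idx, ]),
               tolerance = 1e-4)
})

test_that("the inter-helix probe distance is the plain Euclidean distance", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
               c(0, 0, 30), c(1, 0, 30), c(2, 0, 30))
  s <- bead_structure(xyz)
  region <- region_config(dna_binding_domain = c(1, 3), probe_residue = 2)
  tr <- traj_from_frames(s, list(xyz, xyz + 7))  # translation invariance
  expect_equal(interhelix_distance(tr, region), c(30, 30))
  expect_equal(structure_interhelix_distance(s, region), 30)
  bad <- region_config(dna_binding_domain = c(1, 3), probe_residue = 9)
  expect_error(interhelix_distance(tr, bad), "probe")
})

test_that("two-bin free-energy gaps follow the closed form", {
  x <- c(rep(0.25, 100), rep(0.75, 10))
  y <- rep(c(0.25, 0.75), 55)
  surf <- pmf_2d(x, y, n_bins = 2L, temperature = 300,
                 x_range = c(0, 1), y_range = c(0, 1))
  expect_equal(sum(surf$counts), 110L)
  kt <- KB_KCAL * 300
  gaps <- surf$delta_g
  defined <- sort(gaps[!is.na(gaps)])
  expect_equal(min(defined), 0)
  # counts per x-level are 100 vs 10 spread evenly over y -> gap kT ln 10
  x2 <- c(rep(0.25, 100), rep(0.75, 10))
  y2 <- rep(0.5, 110)
  surf2 <- pmf_2d(x2, y2, n_bins = 2L, x_range = c(0, 1), y_range = c(0, 1))
  g2 <- surf2$delta_g[!is.na(surf2$delta_g)]
  expect_equal(max(g2) - min(g2), kt * log(10), tolerance = 1e-10)
  expect_equal(kt * log(10), 1.37268, tolerance = 1e-4)
})

test_that("degenerate and trivial landscapes behave as documented", {
  one <- pmf_2d(rep(1, 5), rep(2, 5), n_bins = 5L,
                x_range = c(0, 4), y_range = c(0, 4))
  expect_equal(sum(!is.na(one$delta_g)), 1L)
  expect_equal(min(one$delta_g, na.rm = TRUE), 0)
  expect_error(pmf_2d(rep(1, 5), 1:5, n_bins = 3L), "zero-variance")
  # uniform occupancy -> all-zero surface
  g <- expand.grid(x = (1:4 - 0.5) / 4, y = (1:4 - 0.5) / 4)
  u <- pmf_2d(g$x, g$y, n_bins = 4L, x_range = c(0, 1), y_range = c(0, 1))
  expect_true(all(abs(u$delta_g) < 1e-12))
})

test_that("free-energy differences between bins are histogram-exact", {
  set.seed(5)
  x <- rnorm(2000); y <- rnorm(2000)
  surf <- pmf_2d(x, y, n_bins = 10L, temperature = 300)
  kt <- KB_KCAL * 300
  filled <- which(surf$counts > 0, arr.ind = TRUE)
  pick <- filled[sample(nrow(filled), 10L), , drop = FALSE]
  for (r in 2:nrow(pick)) {
    n1 <- surf$counts[pick[1L, 1L], pick[1L, 2L]]
    n2 <- surf$counts[pick[r, 1L], pick[r, 2L]]
    dg <- surf$delta_g[pick[r, 1L], pick[r, 2L]] -
      surf$delta_g[pick[1L, 1L], pick[1L, 2L]]
    expect_equal(dg, -kt * log(n2 / n1), tolerance = 1e-10)
  }
})

test_that("reweighted landscapes use the supplied frame weights", {
  x <- c(0.25, 0.75); y <- c(0.5, 0.5)
  surf <- pmf_2d(x, y, n_bins = 2L, weights = c(2 / 3, 1 / 3),
                 x_range = c(0, 1), y_range = c(0, 1))
  g <- surf$delta_g[!is.na(surf$delta_g)]
  expect_equal(max(g), KB_KCAL * 300 * log(2), tolerance = 1e-10)
})

# independent basin oracle: exhaustive neighbour comparison written from
# scratch (treating NA as +Inf, strict inequality)
oracle_basins <- function(dg) {
  out <- NULL
  for (i in seq_len(nrow(dg))) for (j in seq_len(ncol(dg))) {
    if (is.na(dg[i, j])) next
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di || dj) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nrow(dg) && jj >= 1 && jj <= ncol(dg))
          nb <- c(nb, dg[ii, jj])
      }
    }
    nb <- nb[!is.na(nb)]
    if (length(nb) == 0L || all(dg[i, j] < nb)) out <- rbind(out, c(i, j))
  }
  out
}

fes_from_grid <- function(dg) {
  structure(list(x_edges = 0:nrow(dg), y_edges = 0:ncol(dg),
                 counts = ifelse(is.na(dg), 0L, 1L), delta_g = dg,
                 temperature = 300),
            class = "free_energy_surface")
}

test_that("basin detection agrees with the exhaustive neighbour oracle", {
  # paraboloid: single minimum
  g <- outer((1:9 - 5)^2, (1:9 - 5)^2, `+`) / 10
  b <- find_basins(fes_from_grid(g))
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$i, b$j), c(5L, 5L))
  # two wells separated by a ridge
  xs <- seq(-1, 1, length.out = 15)
  g2 <- outer(xs, xs, function(x, y) (x^2 - 0.4^2)^2 * 8 + y^2)
  b2 <- find_basins(fes_from_grid(g2))
  expect_equal(nrow(b2), 2L)
  expect_equal(oracle_basins(g2)[order(oracle_basins(g2)[, 1L]), ],
               as.matrix(b2[order(b2$i), c("i", "j")]), ignore_attr = TRUE)
  # monotone ramp: one basin at the low corner
  g3 <- outer(1:6, 1:6, `+`) / 3
  b3 <- find_basins(fes_from_grid(g3))
  expect_equal(nrow(b3), 1L)
  expect_equal(c(b3$i, b3$j), c(1L, 1L))
  # random surfaces with missing bins
  set.seed(11)
  for (rep in 1:10) {
    g4 <- matrix(runif(64), 8L, 8L)
    g4[sample(64, 15)] <- NA
    b4 <- find_basins(fes_from_grid(g4))
    o4 <- oracle_basins(g4)
    expect_equal(nrow(b4), if (is.null(o4)) 0L else nrow(o4))
    if (nrow(b4) > 0L)
      expect_setequal(paste(b4$i, b4$j), paste(o4[, 1L], o4[, 2L]))
  }
})

test_that("basins are invariant to constant surface shifts and ties disqualify", {
  g <- outer((1:7 - 4)^2, (1:7 - 4)^2, `+`) / 5
  b1 <- find_basins(fes_from_grid(g))
  b2 <- find_basins(fes_from_grid(g + 3.7))
  expect_equal(b1[, c("i", "j")], b2[, c("i", "j")])
  flat <- matrix(1, 4L, 4L)  # all tied: no strict minima anywhere
  expect_equal(nrow(find_basins(fes_from_grid(flat))), 0L)
})

test_that("representative frames are medoids of the dominant cluster", {
  m <- small_dimer()
  s <- model_structure(m)
  region <- model_region_config(m)
  base <- coords(s)
  # 10 near-copies of conformation X plus one far outlier
  set.seed(9)
  outlier <- base
  outlier[5:8, 1L] <- outlier[5:8, 1L] + 8   # move chain A's domain block only
  frames <- c(lapply(1:10, function(i) base + rnorm(length(base), sd = 0.01)),
              list(outlier))
  tr <- traj_from_frames(s, frames)
  basin <- data.frame(i = 1L, j = 1L, delta_g = 0)
  basin$members <- list(1:11)
  rep_f <- representative_frame(tr, basin, region)
  expect_lte(rep_f, 10L)       # the outlier is never representative
  # singleton basin
  basin1 <- data.frame(i = 1L, j = 1L, delta_g = 0)
  basin1$members <- list(4L)
  expect_equal(representative_frame(tr, basin1, region), 4L)
  # two planted clusters (distinct shapes): the larger one wins
  deformed <- base
  deformed[5:8, 1L] <- deformed[5:8, 1L] + 6   # non-rigid domain shape change
  frames2 <- c(lapply(1:14, function(i) base + rnorm(length(base), sd = 0.01)),
               lapply(1:6, function(i) deformed + rnorm(length(base), sd = 0.01)))
  tr2 <- traj_from_frames(s, frames2)
  basin2 <- data.frame(i = 1L, j = 1L, delta_g = 0)
  basin2$members <- list(1:20)
  expect_lte(representative_frame(tr2, basin2, region), 14L)
})
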