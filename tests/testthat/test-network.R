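# brute-force DCCM oracle: literal loop over frames and atom pairs on
# already-superposed coordinates
oracle_dccm <- function(fitted) {
  nf <- dim(fitted)[1L]; n <- dim(fitted)[2L]
  mean_pos <- apply(fitted, c(2L, 3L), mean)
  C <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- 0; mi <- 0; mj <- 0
    for (f in seq_len(nf)) {
      di <- fitted[f, i, ] - mean_pos[i, ]
      dj <- fitted[f, j, ] - mean_pos[j, ]
      num <- num + sum(di * dj)
      mi <- mi + sum(di^2); mj <- mj + sum(dj^2)
    }
    C[i, j] <- (num / nf) / sqrt((mi / nf) * (mj / nf))
  }
  C
}

test_that("hand-built motions give the expected correlation signs", {
  # atoms 1/2 mirror each other along x; atoms 3/4 move along y with
  # amplitudes orthogonal (over frames) to the x pattern
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 0))
  ax <- c(1, 1, -1, -1)   # x pattern over 4 frames
  ay <- c(1, -1, 1, -1)   # y pattern, orthogonal to ax
  frames <- lapply(1:4, function(f)
    base + rbind(c(ax[f], 0, 0), c(-ax[f], 0, 0),
                 c(0, ay[f], 0), c(0, -ay[f], 0)))
  s <- bead_structure(base, two_chains = FALSE)
  tr <- traj_from_frames(s, frames)
  cm <- dccm(tr, 1:4, superpose = FALSE)  # frames already aligned
  expect_equal(diag(cm$C), rep(1, 4))                    # self-correlation
  expect_equal(cm$C[1L, 2L], -1, tolerance = 1e-12)      # exact antiphase
  expect_equal(cm$C[3L, 4L], -1, tolerance = 1e-12)
  expect_equal(cm$C[1L, 3L], 0, tolerance = 1e-12)       # orthogonal motions
  expect_true(all(cm$C >= -1 & cm$C <= 1))
  expect_equal(cm$C, t(cm$C))
})

test_that("dccm equals the literal frame-loop evaluation on random instances", {
  set.seed(17)
  for (rep in 1:12) {
    n <- sample(3:5, 1L); nf <- sample(4:10, 1L)
    base <- matrix(rnorm(n * 3, sd = 6), n, 3L)
    frames <- lapply(seq_len(nf), function(f) base + matrix(rnorm(n * 3), n, 3L))
    s <- bead_structure(base, two_chains = FALSE)
    tr <- traj_from_frames(s, frames)
    fit <- superpose_to_mean(tr, seq_len(n))
    expect_equal(dccm(tr, seq_len(n))$C, oracle_dccm(fit$coords),
                 tolerance = 1e-9)
  }
})

test_that("dccm matches the established field implementation", {
  set.seed(23)
  n <- 6L
  base <- matrix(rnorm(n * 3, sd = 6), n, 3L)
  frames <- lapply(1:20, function(f) base + matrix(rnorm(n * 3, sd = 0.5), n, 3L))
  tr <- traj_from_frames(bead_structure(base, two_chains = FALSE), frames)
  fit <- superpose_to_mean(tr, seq_len(n))
  xyz <- t(apply(fit$coords, 1L, function(m) as.numeric(t(m))))
  theirs <- bio3d::dccm(xyz)
  expect_equal(unclass(dccm(tr, seq_len(n))$C), unclass(theirs),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("zero-fluctuation atoms are reported by name", {
  base <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(5, 5, 0))
  moving <- base + rbind(c(1, 0, 0), 0, c(0, 1, 0), c(0, 0, 1))
  tr <- traj_from_frames(bead_structure(base, two_chains = FALSE),
                         list(base, moving, base, moving))
  expect_error(dccm(tr, 1:4, superpose = FALSE), "zero fluctuation")
  # a fully static trajectory fails whichever alignment is used
  tr2 <- traj_from_frames(bead_structure(base, two_chains = FALSE),
                          list(base, base, base))
  expect_error(dccm(tr2, 1:4), "zero fluctuation")
})

test_that("display thresholding masks weak entries but keeps the diagonal", {
  C <- matrix(c(1, 0.29, -0.31, 0.29, 1, 0.05, -0.31, 0.05, 1), 3L, 3L)
  cm <- structure(list(C = C, labels = data.frame(chain = "A", resno = 1:3)),
                  class = "correlation_matrix")
  masked <- threshold_for_display(cm, cutoff = 0.3)
  expect_equal(masked$C[1L, 2L], 0)          # |0.29| < 0.3 is neglected
  expect_equal(masked$C[1L, 3L], -0.31)      # |-0.31| is retained
  expect_equal(diag(masked$C), rep(1, 3))
  ident <- structure(list(C = diag(3), labels = cm$labels),
                     class = "correlation_matrix")
  expect_equal(threshold_for_display(ident)$C, diag(3))
})

test_that("contact edges respect cutoff, occupancy and neighbour exclusion", {
  # residues A1, A2, A5 and B1: A1-B1 always 4.0 apart; A1-A5 within cutoff
  # in half the frames only; A1-A2 are sequence neighbours
  f1 <- rbind(c(0, 0, 0), c(0, 4, 0), c(0, 30, 0), c(4, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(0, 4, 0), c(0, 4.2, 1), c(4, 0, 0))
  s <- structure3d(data.frame(eleno = 1:4, elety = "CA", resid = "GLY",
                              chain = c("A", "A", "A", "B"),
                              resno = c(1L, 2L, 5L, 1L),
                              x = f1[, 1], y = f1[, 2], z = f1[, 3],
                              elesy = "C"), source = "test")
  tr <- traj_from_frames(s, list(f1, f2))
  e <- contact_edges(tr, cutoff = 4.5, occupancy = 0.75)
  nodes <- attr(e, "nodes")
  lab <- function(k) paste0(nodes$chain[k], nodes$resno[k])
  got <- paste(lab(e$i), lab(e$j))
  expect_true("A1 B1" %in% got)          # persistent cross-chain contact
  expect_false(any(grepl("A1 A2", got))) # sequence neighbours excluded
  expect_false(any(grepl("A5", got)))    # 50% occupancy < 75%
  e2 <- contact_edges(tr, cutoff = 4.5, occupancy = 0.5)
  expect_true(any(grepl("A5", paste(lab(e2$i), lab(e2$j)))))
  e3 <- contact_edges(tr, cutoff = 4.5, occupancy = 0.75,
                      exclude_neighbors = FALSE)
  expect_true("A1 A2" %in% paste(lab(e3$i), lab(e3$j)))
  expect_equal(e$occupancy[got == "A1 B1"], 1.0)
})

test_that("contact edges on the dimer fixture match rest-geometry ground truth", {
  m <- build_dimer_model()
  tr <- simulate_dimer(m, n_steps = 2000L, seed = 12L)
  e <- contact_edges(tr)
  nodes <- attr(e, "nodes")
  # expectation from the planted rest geometry: pairs within 4.5 A at rest,
  # same block, not sequence-adjacent
  d <- as.matrix(stats::dist(m$xyz))
  blk <- paste0(m$beads$chain, m$beads$block)
  expected <- c()
  for (i in 1:(nrow(m$xyz) - 1L)) for (j in (i + 1L):nrow(m$xyz)) {
    if (d[i, j] <= 4.5 && blk[i] == blk[j] &&
        abs(m$beads$resno[i] - m$beads$resno[j]) > 1L)
      expected <- c(expected, paste(i, j))
  }
  got <- paste(e$i, e$j)
  expect_gt(length(intersect(got, expected)) / length(expected), 0.95)
  # and nothing crosses blocks
  expect_true(all(blk[e$i] == blk[e$j]))
})

test_that("Floyd-Warshall distances equal Dijkstra on random graphs", {
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(4:30, 1L)
    p <- runif(1, 0.1, 0.5)
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- runif(1, 0.1, 3)
    }
    w <- ifelse(adj > 0, adj, Inf); diag(w) <- 0
    fw <- floyd_warshall(w)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    ref <- igraph::distances(g, algorithm = "dijkstra")
    expect_equal(fw$dist, ref, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("canonical paths are valid shortest paths with deterministic ties", {
  w <- matrix(Inf, 4L, 4L); diag(w) <- 0
  # two equal-cost routes 1-2-4 and 1-3-4; lower intermediate index wins
  w[1, 2] <- w[2, 1] <- 1; w[2, 4] <- w[4, 2] <- 1
  w[1, 3] <- w[3, 1] <- 1; w[3, 4] <- w[4, 3] <- 1
  fw <- floyd_warshall(w)
  expect_equal(allodyn:::reconstruct_path(fw$nxt, 1L, 4L), c(1L, 2L, 4L))
  expect_equal(fw$dist[1L, 4L], 2)
})

mk_cm <- function(C, chains = "A") {
  n <- nrow(C)
  structure(list(C = C, labels = data.frame(chain = rep(chains, length.out = n),
                                            resno = seq_len(n))),
            class = "correlation_matrix")
}

mk_edges <- function(pairs, n) {
  e <- data.frame(i = vapply(pairs, `[`, numeric(1L), 1L),
                  j = vapply(pairs, `[`, numeric(1L), 2L),
                  occupancy = 1)
  attr(e, "nodes") <- data.frame(chain = "A", resno = seq_len(n))
  e
}

test_that("path-graph betweenness counts pairwise optimal paths", {
  C <- matrix(0.5, 3L, 3L); diag(C) <- 1
  net <- build_network(mk_edges(list(c(1, 2), c(2, 3)), 3L), mk_cm(C))
  expect_equal(net$edges$weight, rep(-log(0.5), 2L))
  # pairs: (1,2) uses edge a-b; (1,3) uses both; (2,3) uses b-c
  expect_equal(net$edges$betweenness, c(2L, 2L))
  single <- build_network(mk_edges(list(c(1, 2)), 2L), mk_cm(diag(2) * 0.5 + 0.5))
  expect_equal(single$edges$betweenness, 1L)
})

test_that("a weak triangle edge carries only its endpoint pair, or none", {
  # moderately weak direct edge: still cheaper than the two-hop detour
  # (-log 0.4 < 2 * -log 0.6), so it carries exactly its endpoint pair
  C <- matrix(0.6, 3L, 3L); diag(C) <- 1
  C[1L, 3L] <- C[3L, 1L] <- 0.4
  net <- build_network(mk_edges(list(c(1, 2), c(1, 3), c(2, 3)), 3L), mk_cm(C))
  weak <- which(net$edges$i == 1L & net$edges$j == 3L)
  expect_equal(net$edges$betweenness[weak], 1L)
  # an extremely weak edge is bypassed even by its own endpoints
  C2 <- C; C2[1L, 3L] <- C2[3L, 1L] <- 0.01
  net2 <- build_network(mk_edges(list(c(1, 2), c(1, 3), c(2, 3)), 3L), mk_cm(C2))
  expect_equal(net2$edges$betweenness[weak], 0L)
  # total betweenness equals the summed path lengths over connected pairs
  fw_len <- sapply(list(c(1, 2), c(1, 3), c(2, 3)), function(p)
    length(allodyn:::reconstruct_path(net$nxt, p[1L], p[2L])) - 1L)
  expect_equal(sum(net$edges$betweenness), sum(fw_len))
})

test_that("betweenness sums to total path length on random networks", {
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(5:15, 1L)
    pairs <- list()
    for (i in 1:(n - 1L)) for (j in (i + 1L):n)
      if (runif(1) < 0.4) pairs[[length(pairs) + 1L]] <- c(i, j)
    if (length(pairs) == 0L) next
    C <- matrix(runif(n * n, 0.2, 0.95), n, n)
    C <- (C + t(C)) / 2; diag(C) <- 1
    net <- build_network(mk_edges(pairs, n), mk_cm(C))
    total_len <- 0L
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (is.finite(net$dist[i, j])) {
        p <- allodyn:::reconstruct_path(net$nxt, i, j)
        if (length(p) >= 2L) total_len <- total_len + length(p) - 1L
      }
    }
    expect_equal(sum(net$edges$betweenness), total_len)
  }
})

test_that("Girvan-Newman on a two-clique barbell equals the exhaustive optimum", {
  # two 4-cliques joined by one edge
  pairs <- list()
  for (i in 1:3) for (j in (i + 1L):4) pairs[[length(pairs) + 1L]] <- c(i, j)
  for (i in 5:7) for (j in (i + 1L):8) pairs[[length(pairs) + 1L]] <- c(i, j)
  pairs[[length(pairs) + 1L]] <- c(4L, 5L)
  C <- matrix(0.5, 8L, 8L); diag(C) <- 1
  net <- build_network(mk_edges(pairs, 8L), mk_cm(C))
  part <- girvan_newman_communities(net)
  expect_length(unique(part$membership), 2L)
  expect_length(unique(part$membership[1:4]), 1L)
  expect_length(unique(part$membership[5:8]), 1L)
  expect_false(any(part$discarded))
  # exhaustive modularity over all 4140 partitions of 8 nodes, scored with
  # an independent implementation
  g <- igraph::graph_from_data_frame(
    data.frame(from = sapply(pairs, `[`, 1L), to = sapply(pairs, `[`, 2L)),
    directed = FALSE, vertices = data.frame(name = 1:8))
  best_q <- max(vapply(all_partitions(8L), function(mem)
    igraph::modularity(g, mem), numeric(1L)))
  expect_equal(part$modularity, best_q, tolerance = 1e-10)
})

test_that("complete graphs stay one community; small ones are discarded", {
  pairs <- list()
  for (i in 1:4) for (j in (i + 1L):5) pairs[[length(pairs) + 1L]] <- c(i, j)
  C <- matrix(0.6, 5L, 5L); diag(C) <- 1
  net <- build_network(mk_edges(pairs, 5L), mk_cm(C))
  part <- girvan_newman_communities(net)
  expect_length(unique(part$membership), 1L)
  # K4 plus a connected pair: the pair's community is discarded
  pairs2 <- list()
  for (i in 1:3) for (j in (i + 1L):4) pairs2[[length(pairs2) + 1L]] <- c(i, j)
  pairs2[[length(pairs2) + 1L]] <- c(5L, 6L)
  C2 <- matrix(0.6, 6L, 6L); diag(C2) <- 1
  net2 <- build_network(mk_edges(pairs2, 6L), mk_cm(C2))
  part2 <- girvan_newman_communities(net2)
  expect_true(all(part2$discarded[5:6]))
  expect_false(any(part2$discarded[1:4]))
})

test_that("community connectivity takes the maximum bridging betweenness", {
  # two triangles joined by two bridges of different betweenness
  pairs <- list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                c(3, 4), c(1, 6))
  C <- matrix(0.5, 6L, 6L); diag(C) <- 1
  C[3L, 4L] <- C[4L, 3L] <- 0.9    # cheap bridge: carries most paths
  C[1L, 6L] <- C[6L, 1L] <- 0.05   # expensive bridge
  net <- build_network(mk_edges(pairs, 6L), mk_cm(C))
  part <- girvan_newman_communities(net)
  conn <- community_connectivity(net, part)
  expect_equal(nrow(conn), 1L)
  bridges <- net$edges$betweenness[(net$edges$i == 3 & net$edges$j == 4) |
                                     (net$edges$i == 1 & net$edges$j == 6)]
  expect_equal(conn$score, max(bridges))
  # no connecting edge -> pair absent
  pairs3 <- list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  net3 <- build_network(mk_edges(pairs3, 6L), mk_cm(matrix(0.5, 6, 6) + diag(6) * 0.5))
  part3 <- girvan_newman_communities(net3)
  expect_equal(nrow(community_connectivity(net3, part3)), 0L)
})

test_that("planted communities are recovered exactly from simulated dynamics", {
  m <- build_dimer_model(n_beads_per_chain = 8, community_layout = c(4, 4))
  tr <- simulate_dimer(m, n_steps = 4000L, seed = 19L)
  e <- contact_edges(tr)
  cm <- dccm(tr, select_atoms(model_structure(m), atom_names = "CA"))
  part <- girvan_newman_communities(build_network(e, cm))
  expect_equal(adjusted_rand_index(part$membership, m$planted_partition), 1)
  expect_equal(adjusted_rand_index(part$membership, part$membership), 1)
  # agreement with the reference ARI implementation
  expect_equal(adjusted_rand_index(part$membership, m$planted_partition),
               mclust::adjustedRandIndex(part$membership, m$planted_partition))
})

test_that("planted correlation signs are recovered from a crossing trajectory", {
  m <- build_dimer_model(doublewell_spec = list(d1 = 24, d2 = 32,
                                                barrier = 1.2, delta_g = 0))
  tr <- simulate_dimer(m, n_steps = 30000L, seed = 9L, dt = 0.004)
  cm <- dccm(tr, select_atoms(model_structure(m), atom_names = "CA"))
  sp <- m$planted_sign_pairs
  got <- cm$C[cbind(sp$i, sp$j)]
  expect_equal(sign(got), as.numeric(sp$sign))
})
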