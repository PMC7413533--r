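# Dynamic cross-correlation matrices and dynamical community networks:
# occupancy-filtered contact graphs with correlation-derived edge weights,
# Floyd-Warshall optimal paths, canonical-path edge betweenness,
# Girvan-Newman communities and inter-community connectivity.

#' Iteratively superpose trajectory frames onto their mean structure
#'
#' Frames are rigid-body fitted (Kabsch) on the given atom subset to the
#' running mean structure, which is recomputed after each pass, until the
#' mean moves by less than `tol` RMSD or `max_iter` passes.
#'
#' @param traj a `trajectory`.
#' @param selection atom indices used both for fitting and in the output.
#' @param max_iter maximum refinement passes.
#' @param tol convergence threshold on the mean structure, Angstrom.
#' @return list with `coords` (F x n x 3 array of fitted selection
#'   coordinates) and `mean` (n x 3).
#' @export
superpose_to_mean <- function(traj, selection, max_iter = 10L, tol = 1e-6) {
  nf <- n_frames(traj)
  n <- length(selection)
  raw <- lapply(seq_len(nf), function(f)
    frame_coords(traj, f)[selection, , drop = FALSE])
  ref <- raw[[1L]]
  fitted <- raw
  for (it in seq_len(max_iter)) {
    fitted <- lapply(raw, function(m) kabsch_superpose(m, ref)$fitted)
    new_mean <- Reduce(`+`, fitted) / nf
    shift <- sqrt(mean(rowSums((new_mean - ref)^2)))
    ref <- new_mean
    if (shift < tol) break
  }
  arr <- array(NA_real_, c(nf, n, 3L))
  for (f in seq_len(nf)) arr[f, , ] <- fitted[[f]]
  list(coords = arr, mean = ref)
}

#' Dynamic cross-correlation matrix of C-alpha fluctuations
#'
#' After iterative superposition onto the mean structure, the displacement
#' of atom i in frame t is `dr_i(t) = r_i(t) - <r_i>`, and
#' \deqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#'   (\langle |\Delta r_i|^2 \rangle \langle |\Delta r_j|^2 \rangle)^{1/2}.}
#' Entries lie in [-1, 1]: +1 for fully correlated motion, -1 for motion in
#' exact antiphase.
#'
#' @param traj a `trajectory` with at least 2 frames.
#' @param ca_selection atom indices (typically one C-alpha per residue) with
#'   at least 2 atoms.
#' @param superpose superpose frames onto the iteratively-computed mean
#'   structure first (default). Set `FALSE` for coordinates that are already
#'   aligned.
#' @return object of class `correlation_matrix`: `C` (n x n) plus a `labels`
#'   data.frame (chain, resno) aligned with the rows.
#' @export
dccm <- function(traj, ca_selection, superpose = TRUE) {
  if (n_frames(traj) < 2L) stop("at least 2 frames required")
  if (length(ca_selection) < 2L) stop("at least 2 atoms required")
  fit <- if (superpose) superpose_to_mean(traj, ca_selection)
  else {
    arr <- array(NA_real_, c(n_frames(traj), length(ca_selection), 3L))
    for (f in seq_len(n_frames(traj)))
      arr[f, , ] <- frame_coords(traj, f)[ca_selection, , drop = FALSE]
    list(coords = arr)
  }
  nf <- dim(fit$coords)[1L]; n <- dim(fit$coords)[2L]
  # deviations as three n x F matrices
  devs <- lapply(1:3, function(d) {
    m <- t(fit$coords[, , d])            # n x F
    m - rowMeans(m)
  })
  num <- Reduce(`+`, lapply(devs, tcrossprod)) / nf
  msf <- diag(num)
  zero <- which(msf < 1e-14)
  if (length(zero) > 0L) {
    at <- traj$topology$atoms[ca_selection[zero[1L]], ]
    stop(sprintf("atom %s%d %s has zero fluctuation; correlation undefined",
                 at$chain, at$resno, at$elety))
  }
  C <- num / sqrt(outer(msf, msf))
  C <- pmin(pmax(C, -1), 1)
  diag(C) <- 1
  at <- traj$topology$atoms[ca_selection, ]
  out <- list(C = C, labels = data.frame(chain = at$chain, resno = at$resno,
                                         stringsAsFactors = FALSE))
  class(out) <- "correlation_matrix"
  out
}

#' Mask weak correlations for display
#'
#' Entries with absolute correlation below the cutoff are neglected (set to
#' zero); the diagonal is retained. This is presentation-only and does not
#' feed the network construction.
#'
#' @param cm a `correlation_matrix`.
#' @param cutoff absolute-correlation display threshold (default 0.3).
#' @return a `correlation_matrix` with masked entries.
#' @export
threshold_for_display <- function(cm, cutoff = 0.3) {
  C <- cm$C
  C[abs(C) < cutoff] <- 0
  diag(C) <- diag(cm$C)
  cm$C <- C
  cm
}

residue_index_table <- function(structure, heavy_only = TRUE) {
  a <- structure$atoms
  keep <- if (heavy_only) a$elesy != "H" else rep(TRUE, nrow(a))
  key <- paste(a$chain, a$resno)
  res_keys <- unique(key[keep])
  list(keys = res_keys,
       chain = vapply(strsplit(res_keys, " "), `[`, character(1L), 1L),
       resno = as.integer(vapply(strsplit(res_keys, " "), `[`, character(1L), 2L)),
       atom_idx = lapply(res_keys, function(k) which(key == k & keep)))
}

#' Occupancy-filtered residue contact edges
#'
#' Two residues are in contact in a frame when their minimum inter-residue
#' distance (over heavy atoms by default, or C-alpha only) is at most
#' `cutoff`. An edge is emitted for every residue pair in contact in at
#' least the `occupancy` fraction of frames. Sequence-adjacent residues of
#' the same chain (|resno difference| = 1) are excluded by default so
#' trivially persistent backbone contacts do not dominate the graph.
#'
#' @param traj a `trajectory`.
#' @param cutoff contact distance, Angstrom (default 4.5).
#' @param occupancy minimum fraction of frames (default 0.75).
#' @param mode `"heavy"` (minimum heavy-atom distance) or `"ca"`.
#' @param exclude_neighbors drop same-chain sequence neighbours (default TRUE).
#' @return data.frame with columns `i`, `j` (residue indices into the node
#'   table), `occupancy`; attribute `"nodes"` carries the residue table.
#' @export
contact_edges <- function(traj, cutoff = 4.5, occupancy = 0.75,
                          mode = c("heavy", "ca"), exclude_neighbors = TRUE) {
  mode <- match.arg(mode)
  top <- traj$topology
  rt <- if (mode == "ca") {
    idx <- select_atoms(top, atom_names = "CA")
    a <- top$atoms[idx, ]
    list(keys = paste(a$chain, a$resno), chain = a$chain, resno = a$resno,
         atom_idx = as.list(idx))
  } else residue_index_table(top)
  nr <- length(rt$keys)
  nf <- n_frames(traj)
  hit <- matrix(0L, nr, nr)
  single <- all(lengths(rt$atom_idx) == 1L)
  flat <- unlist(rt$atom_idx)
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)
    if (single) {
      dm <- as.matrix(stats::dist(m[flat, , drop = FALSE]))
    } else {
      dm <- matrix(Inf, nr, nr)
      for (a in seq_len(nr - 1L)) for (b in (a + 1L):nr) {
        da <- m[rt$atom_idx[[a]], , drop = FALSE]
        db <- m[rt$atom_idx[[b]], , drop = FALSE]
        d2 <- outer(rowSums(da^2), rowSums(db^2), `+`) - 2 * tcrossprod(da, db)
        dm[a, b] <- dm[b, a] <- sqrt(max(min(d2), 0))
      }
    }
    hit <- hit + (dm <= cutoff)
  }
  occ <- hit / nf
  pairs <- which(upper.tri(occ) & occ >= occupancy, arr.ind = TRUE)
  if (exclude_neighbors && nrow(pairs) > 0L) {
    same_chain <- rt$chain[pairs[, 1L]] == rt$chain[pairs[, 2L]]
    adjacent <- abs(rt$resno[pairs[, 1L]] - rt$resno[pairs[, 2L]]) == 1L
    pairs <- pairs[!(same_chain & adjacent), , drop = FALSE]
  }
  out <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                    occupancy = occ[pairs])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nodes") <- data.frame(chain = rt$chain, resno = rt$resno,
                                   stringsAsFactors = FALSE)
  out
}

#' Floyd-Warshall all-pairs optimal paths with canonical path reconstruction
#'
#' Computes all-pairs shortest path costs on a weighted undirected graph and
#' a next-hop table from which one canonical optimal path per ordered pair
#' can be reconstructed. Updates are applied only on strict improvement with
#' intermediate nodes scanned in ascending index order, so tie-breaking is
#' deterministic and favours paths found through lower-indexed intermediates.
#'
#' @param w n x n symmetric weight matrix with `Inf` for non-edges and 0 on
#'   the diagonal.
#' @return list with `dist` (n x n costs) and `nxt` (n x n next-hop indices,
#'   `NA` where unreachable).
#' @export
floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- w
  nxt <- matrix(NA_integer_, n, n)
  has_edge <- is.finite(w) & w > 0
  nxt[has_edge] <- col(w)[has_edge]
  diag(nxt) <- seq_len(n)
  for (k in seq_len(n)) {
    via <- outer(d[, k], d[k, ], `+`)
    better <- via < d
    if (any(better)) {
      d[better] <- via[better]
      nxt[better] <- nxt[cbind(row(nxt)[better], k)]
    }
  }
  list(dist = d, nxt = nxt)
}

reconstruct_path <- function(nxt, i, j) {
  if (is.na(nxt[i, j])) return(NULL)
  path <- i
  while (i != j) {
    i <- nxt[i, j]
    path <- c(path, i)
  }
  path
}

#' Build the dynamical network from contact edges and a correlation matrix
#'
#' Residue nodes are connected by the occupancy-filtered contact edges,
#' weighted by `w_ij = -log |C_ij|` (high correlation = short edge; the
#' absolute correlation is clamped to [1e-6, 1 - 1e-12] so weights stay
#' finite and positive). All-pairs optimal paths are computed with the
#' Floyd-Warshall algorithm, one canonical path per unordered pair, and each
#' edge's betweenness is the number of those optimal paths traversing it.
#' Pairs in different components contribute no paths.
#'
#' @param edges output of [contact_edges()] (`i`, `j`, `occupancy`).
#' @param cm a `correlation_matrix` whose rows match the edge node table.
#' @param weight_floor lower clamp on `|C_ij|` (default 1e-6).
#' @return object of class `dynamical_network`: `nodes`, `edges` (with
#'   `weight` and `betweenness`), `dist`, `nxt`.
#' @export
build_network <- function(edges, cm, weight_floor = 1e-6) {
  nodes <- attr(edges, "nodes")
  if (is.null(nodes)) nodes <- cm$labels
  n <- nrow(nodes)
  if (nrow(cm$C) != n)
    stop("correlation matrix (", nrow(cm$C), " rows) does not match node table (",
         n, " nodes)")
  w <- matrix(Inf, n, n)
  diag(w) <- 0
  if (nrow(edges) > 0L) {
    cvals <- cm$C[cbind(edges$i, edges$j)]
    wts <- -log(pmin(pmax(abs(cvals), weight_floor), 1 - 1e-12))
    w[cbind(edges$i, edges$j)] <- wts
    w[cbind(edges$j, edges$i)] <- wts
    edges$weight <- wts
  } else {
    edges$weight <- numeric(0L)
  }
  fw <- floyd_warshall(w)
  bet <- matrix(0L, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (!is.finite(fw$dist[i, j])) next
      p <- reconstruct_path(fw$nxt, i, j)
      if (length(p) >= 2L) {
        a <- p[-length(p)]; b <- p[-1L]
        bet[cbind(pmin(a, b), pmax(a, b))] <- bet[cbind(pmin(a, b), pmax(a, b))] + 1L
      }
    }
  }
  edges$betweenness <- bet[cbind(pmin(edges$i, edges$j), pmax(edges$i, edges$j))]
  out <- list(nodes = nodes, edges = edges, dist = fw$dist, nxt = fw$nxt)
  class(out) <- "dynamical_network"
  out
}

#' @export
print.dynamical_network <- function(x, ...) {
  cat(sprintf("dynamical_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Newman-Girvan modularity of a partition on an unweighted undirected graph
# given as an edge list (i, j) over n nodes.
modularity_q <- function(edge_i, edge_j, membership) {
  m <- length(edge_i)
  if (m == 0L) return(0)
  deg <- tabulate(c(edge_i, edge_j), nbins = length(membership))
  q <- 0
  for (com in unique(membership)) {
    in_com <- membership == com
    e_c <- sum(in_com[edge_i] & in_com[edge_j])
    d_c <- sum(deg[in_com])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# connected-component labels (1-based, in order of first appearance)
component_membership <- function(n, edge_i, edge_j) {
  edge_i <- as.integer(edge_i); edge_j <- as.integer(edge_j)
  parent <- seq_len(n)
  find <- function(x) { r <- x; while (parent[r] != r) r <- parent[r]
                        while (parent[x] != r) { nx <- parent[x]; parent[x] <<- r; x <- nx }; r }
  for (e in seq_along(edge_i)) {
    a <- find(edge_i[e]); b <- find(edge_j[e])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  match(roots, unique(roots))
}

#' Girvan-Newman community detection maximising modularity
#'
#' Iteratively removes the edge with the highest betweenness (recomputed
#' after every removal from the canonical Floyd-Warshall optimal paths on
#' the remaining graph, with ties broken by lexicographic edge order),
#' evaluates the Newman-Girvan modularity of each intermediate component
#' partition on the ORIGINAL unweighted contact graph, and returns the
#' partition with maximal modularity. Communities with fewer than 3
#' residues are then marked discarded: they keep their labels but are
#' excluded from connectivity reporting.
#'
#' @param net a `dynamical_network`.
#' @return object of class `community_partition`: `membership` (integer per
#'   node), `discarded` (logical per node), `modularity`, `sizes`.
#' @export
girvan_newman_communities <- function(net) {
  n <- nrow(net$nodes)
  if (n < 2L) stop("at least 2 nodes required")
  orig_i <- net$edges$i; orig_j <- net$edges$j
  cur <- net$edges[order(net$edges$i, net$edges$j), , drop = FALSE]
  best_mem <- component_membership(n, orig_i, orig_j)
  best_q <- modularity_q(orig_i, orig_j, best_mem)
  work <- cur
  while (nrow(work) > 0L) {
    bet <- edge_betweenness_of(n, work)
    # highest betweenness; ties -> lexicographically first edge
    top <- which(bet == max(bet))[1L]
    work <- work[-top, , drop = FALSE]
    mem <- component_membership(n, work$i, work$j)
    q <- modularity_q(orig_i, orig_j, mem)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_mem <- mem
    }
  }
  sizes <- as.integer(table(factor(best_mem, levels = sort(unique(best_mem)))))
  discarded <- sizes[best_mem] < 3L
  out <- list(membership = best_mem, discarded = discarded,
              modularity = best_q,
              sizes = sizes)
  class(out) <- "community_partition"
  out
}

edge_betweenness_of <- function(n, edges) {
  w <- matrix(Inf, n, n); diag(w) <- 0
  w[cbind(edges$i, edges$j)] <- edges$weight
  w[cbind(edges$j, edges$i)] <- edges$weight
  fw <- floyd_warshall(w)
  bet <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!is.finite(fw$dist[i, j])) next
    p <- reconstruct_path(fw$nxt, i, j)
    if (length(p) >= 2L) {
      a <- p[-length(p)]; b <- p[-1L]
      bet[cbind(pmin(a, b), pmax(a, b))] <- bet[cbind(pmin(a, b), pmax(a, b))] + 1L
    }
  }
  bet[cbind(pmin(edges$i, edges$j), pmax(edges$i, edges$j))]
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities (%d discarded), Q = %.4f\n",
              length(x$sizes), sum(x$sizes < 3L), x$modularity))
  invisible(x)
}

#' Inter-community connectivity scores
#'
#' For every pair of non-discarded communities joined by at least one edge,
#' the connectivity score is the maximum edge betweenness over the
#' connecting edges (the quantity drawn as bond width in community
#' diagrams). Pairs with no connecting edge are absent.
#'
#' @param net a `dynamical_network`.
#' @param partition a `community_partition` from [girvan_newman_communities()].
#' @return data.frame with `community_a`, `community_b`, `score`.
#' @export
community_connectivity <- function(net, partition) {
  mem <- partition$membership
  keep_com <- which(partition$sizes >= 3L)
  e <- net$edges
  ca <- mem[e$i]; cb <- mem[e$j]
  cross <- ca != cb & ca %in% keep_com & cb %in% keep_com
  if (!any(cross))
    return(data.frame(community_a = integer(), community_b = integer(),
                      score = numeric()))
  a <- pmin(ca[cross], cb[cross]); b <- pmax(ca[cross], cb[cross])
  bt <- e$betweenness[cross]
  key <- paste(a, b)
  agg <- tapply(bt, key, max)
  parts <- strsplit(names(agg), " ")
  out <- data.frame(community_a = as.integer(vapply(parts, `[`, character(1L), 1L)),
                    community_b = as.integer(vapply(parts, `[`, character(1L), 2L)),
                    score = as.numeric(agg))
  out[order(out$community_a, out$community_b), , drop = FALSE]
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items; 1
#' means identical up to label permutation.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
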