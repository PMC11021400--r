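# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (brute force, enumeration, closed form)
# kept separate from the package's own code paths.

# Horn's quaternion method for optimal rigid-body superposition: returns the
# rotated-and-recentred moving frame. Independent of the SVD route used by
# superpose().
quaternion_align <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  S <- crossprod(Pc, Qc)        # S[a,b] = sum_i P_a Q_b
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  q0 <- q[1]; qx <- q[2]; qy <- q[3]; qz <- q[4]
  R <- matrix(c(
    q0^2+qx^2-qy^2-qz^2, 2*(qx*qy - q0*qz),   2*(qx*qz + q0*qy),
    2*(qy*qx + q0*qz),   q0^2-qx^2+qy^2-qz^2, 2*(qy*qz - q0*qx),
    2*(qz*qx - q0*qy),   2*(qz*qy + q0*qx),   q0^2-qx^2-qy^2+qz^2),
    3, 3, byrow = TRUE)
  sweep(Pc %*% t(R), 2, qc, "+")
}

rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

# All-pairs, all-frames, all-atoms contact occupancy loop.
brute_occupancy <- function(traj, nodemap, cutoff = 4) {
  n <- length(nodemap$nodes)
  Fn <- dim(traj$coords)[1]
  O <- matrix(NA_real_, n, n,
              dimnames = list(nodemap$node_ids, nodemap$node_ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    hits <- 0L
    for (f in seq_len(Fn)) {
      found <- FALSE
      for (a in nodemap$nodes[[i]]$members) {
        for (b in nodemap$nodes[[j]]$members) {
          d <- sqrt(sum((traj$coords[f, a, ] - traj$coords[f, b, ])^2))
          if (d < cutoff) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found) hits <- hits + 1L
    }
    O[i, j] <- hits / Fn
  }
  O
}

# All set partitions of n elements as restricted-growth label vectors.
all_partitions <- function(n) {
  res <- list()
  rec <- function(labels, maxl) {
    if (length(labels) == n) {
      res[[length(res) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(maxl + 1L)) rec(c(labels, l), max(maxl, l))
  }
  rec(integer(0), 0L)
  res
}

# Exhaustive maximum modularity over every partition of the graph's nodes.
brute_max_modularity <- function(g, strengths) {
  parts <- all_partitions(igraph::vcount(g))
  best <- -Inf
  for (p in parts) {
    q <- igraph::modularity(g, p, weights = strengths)
    if (q > best) best <- q
  }
  best
}

# A dyn_network from an explicit edge list with |C| strengths.
toy_network <- function(n, from, to, strength) {
  ids <- paste0("N", seq_len(n))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::add_edges(g, as.vector(rbind(ids[from], ids[to])))
  g <- igraph::set_edge_attr(g, "strength", value = strength)
  g <- igraph::set_edge_attr(g, "weight", value = -log(strength))
  g <- igraph::set_edge_attr(g, "occupancy", value = rep(1, length(from)))
  g <- igraph::set_edge_attr(g, "correlation", value = strength)
  structure(list(graph = g, config = network_config()),
            class = "dyn_network")
}

# Planted two-block weighted graph: complete within blocks, one weak
# cross edge; weights drawn per seed.
planted_block_network <- function(n1, n2, seed) {
  set.seed(seed)
  n <- n1 + n2
  from <- integer(0); to <- integer(0); s <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- (i <= n1) == (j <= n1)
    if (same) {
      from <- c(from, i); to <- c(to, j)
      s <- c(s, runif(1, 0.7, 0.95))
    }
  }
  from <- c(from, n1); to <- c(to, n1 + 1)
  s <- c(s, runif(1, 0.05, 0.2))
  toy_network(n, from, to, s)
}

# Direct grid search over (A, k, c) for the mono-exponential model.
grid_monoexp <- function(t, I, A_grid, k_grid, c_grid) {
  best <- list(sse = Inf)
  for (A in A_grid) for (k in k_grid) for (c in c_grid) {
    sse <- sum((I - (A * exp(-k * t) + c))^2)
    if (sse < best$sse) best <- list(A = A, k = k, c = c, sse = sse)
  }
  best
}

# Direct grid search over (a_max, pKa) for the Henderson-Hasselbalch model.
grid_pka <- function(ph, a, amax_grid, pka_grid) {
  best <- list(sse = Inf)
  for (am in amax_grid) for (pk in pka_grid) {
    sse <- sum((a - am / (1 + 10^(pk - ph)))^2)
    if (sse < best$sse) best <- list(a_max = am, pKa = pk, sse = sse)
  }
  best
}

# Exact-recovery check: detected labels are a relabelling of the planted ones.
labels_match <- function(detected, planted) {
  length(unique(paste(detected, planted))) == length(unique(planted)) &&
    length(unique(detected)) == length(unique(planted))
}

# Shared protocol for the planted-community replicate studies.
run_recovery_replicate <- function(seed, n_groups, flag,
                                   noise_sigma = 0.2, n_frames = 300) {
  spec <- trajectory_spec(n_residues = n_groups * 9, n_groups = n_groups,
                          noise_sigma = noise_sigma, n_frames = n_frames,
                          chromophore = flag, seed = seed)
  gen <- gen_trajectory(spec)
  traj <- superpose(gen$trajectory)
  nm <- build_node_map(traj, gen$fragment_table)
  part <- detect_communities(build_graph(
    contact_occupancy(traj, nm), correlation_matrix(traj, nm), nm))
  res_ids <- paste0("R", seq_len(spec$n_residues))
  planted <- gen$truth$community[match(res_ids, gen$truth$node_id)]
  list(exact = labels_match(part$membership[res_ids], planted),
       verdict = if (!is.null(flag)) co_membership(part, nm) else NA)
}
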