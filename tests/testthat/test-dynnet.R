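static_pair_traj <- function(d) {
  co <- array(0, dim = c(3, 2, 3))
  co[, 2, 1] <- d
  meta <- data.frame(name = c("CA", "CA"), residue_index = c(1, 3),
                    residue_name = "ALA", chain = "A")
  new_trajectory(co, meta)
}

test_that("contact occupancy is 1 inside and 0 outside the cutoff", {
  nm3 <- build_node_map(static_pair_traj(3))
  expect_equal(contact_occupancy(static_pair_traj(3), nm3)["R1", "R3"], 1)
  expect_equal(contact_occupancy(static_pair_traj(5), nm3)["R1", "R3"], 0)
})

test_that("contact occupancy equals the brute-force all-pairs loop", {
  gen <- gen_trajectory(trajectory_spec(n_residues = 6, n_groups = 2,
                                        atoms_per_residue = 2, n_frames = 50,
                                        noise_sigma = 0.3, seed = 8))
  nm <- build_node_map(gen$trajectory)
  fast <- contact_occupancy(gen$trajectory, nm)
  slow <- brute_occupancy(gen$trajectory, nm)
  expect_equal(fast, slow, tolerance = 1e-12)
  expect_equal(fast, t(fast), tolerance = 1e-12)
})

test_that("correlations hit +1 and -1 for copied and mirrored motion", {
  set.seed(3)
  base <- cbind(rnorm(20), rnorm(20), rnorm(20))
  co <- array(0, dim = c(20, 3, 3))
  co[, 1, ] <- base
  co[, 2, ] <- base + 5          # identical displacements
  co[, 3, ] <- -base             # anti-correlated displacements
  meta <- data.frame(name = rep("CA", 3), residue_index = c(1, 3, 5),
                     residue_name = "ALA", chain = "A")
  traj <- new_trajectory(co, meta)
  C <- correlation_matrix(traj, build_node_map(traj))
  expect_equal(C["R1", "R3"], 1, tolerance = 1e-12)
  expect_equal(C["R1", "R5"], -1, tolerance = 1e-12)
  expect_equal(C, t(C), tolerance = 1e-12)
  expect_equal(diag(C), rep(1, 3), ignore_attr = TRUE)
})

test_that("correlation matches a direct evaluation of the DCCM formula", {
  set.seed(9)
  co <- array(rnorm(5 * 4 * 3), dim = c(5, 4, 3))
  meta <- data.frame(name = rep("CA", 4), residue_index = c(1, 3, 5, 7),
                     residue_name = "ALA", chain = "A")
  traj <- new_trajectory(co, meta)
  nm <- build_node_map(traj)
  C <- correlation_matrix(traj, nm)
  for (i in 1:3) for (j in (i + 1):4) {
    di <- sweep(co[, i, ], 2, colMeans(co[, i, ]))
    dj <- sweep(co[, j, ], 2, colMeans(co[, j, ]))
    num <- mean(rowSums(di * dj))
    den <- sqrt(mean(rowSums(di^2)) * mean(rowSums(dj^2)))
    expect_equal(C[i, j], num / den, tolerance = 1e-12)
  }
})

test_that("zero-variance nodes give zero correlation with a warning", {
  co <- array(0, dim = c(4, 2, 3))
  co[, 1, 1] <- 1:4
  meta <- data.frame(name = c("CA", "CA"), residue_index = c(1, 3),
                     residue_name = "ALA", chain = "A")
  traj <- new_trajectory(co, meta)
  expect_warning(C <- correlation_matrix(traj, build_node_map(traj)),
                 "zero-variance")
  expect_equal(C["R1", "R3"], 0)
  expect_equal(diag(C), rep(1, 2), ignore_attr = TRUE)
})

test_that("edges require strictly more than the occupancy threshold", {
  gen <- gen_trajectory(trajectory_spec(n_residues = 4, n_groups = 1,
                                        n_frames = 8, seed = 2))
  nm <- build_node_map(gen$trajectory)
  n <- length(nm$nodes)
  O <- matrix(1, n, n, dimnames = list(nm$node_ids, nm$node_ids))
  C <- matrix(0.5, n, n, dimnames = dimnames(O))
  diag(C) <- 1
  O["R1", "R3"] <- O["R3", "R1"] <- 0.75   # exactly the threshold: no edge
  net <- build_graph(O, C, nm)
  g <- net$graph
  pairs <- apply(igraph::ends(g, igraph::E(g)), 1,
                 function(p) paste(sort(p), collapse = "|"))
  expect_false("R1|R3" %in% pairs)
  # neighbours R1-R2 are excluded despite O = 1
  expect_false("R1|R2" %in% pairs)
  # surviving edges carry w = -log|C|
  expect_equal(unique(igraph::E(g)$weight), -log(0.5), tolerance = 1e-12)
  expect_true("R1|R4" %in% pairs)
})

test_that("raising the occupancy threshold never adds edges", {
  gen <- gen_trajectory(trajectory_spec(n_residues = 9, n_groups = 2,
                                        n_frames = 60, noise_sigma = 0.4,
                                        seed = 13))
  nm <- build_node_map(gen$trajectory)
  O <- contact_occupancy(gen$trajectory, nm)
  C <- correlation_matrix(gen$trajectory, nm)
  prev <- Inf
  for (th in c(0.3, 0.5, 0.75, 0.9)) {
    net <- build_graph(O, C, nm, network_config(occupancy_threshold = th))
    expect_lte(igraph::ecount(net$graph), prev)
    prev <- igraph::ecount(net$graph)
  }
})

test_that("two cliques joined by one weak edge split into the cliques", {
  net <- toy_network(8,
                     from = c(1,1,1,2,2,3, 5,5,5,6,6,7, 4),
                     to   = c(2,3,4,3,4,4, 6,7,8,7,8,8, 5),
                     strength = c(rep(0.9, 12), 0.1))
  part <- detect_communities(net)
  expect_equal(part$n_communities, 2)
  expect_equal(unname(part$membership[paste0("N", 1:4)]), rep(1L, 4))
  expect_equal(unname(part$membership[paste0("N", 5:8)]), rep(2L, 4))
  # deterministic
  part2 <- detect_communities(net)
  expect_identical(part$membership, part2$membership)
  expect_identical(part$modularity, part2$modularity)
})

test_that("an edgeless graph yields singleton communities with Q = 0", {
  g <- igraph::make_empty_graph(n = 4, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("N", 1:4))
  part <- detect_communities(g)
  expect_equal(part$n_communities, 4)
  expect_equal(part$modularity, 0)
})

test_that("disconnected components are never merged", {
  net <- toy_network(6, from = c(1, 2, 4, 5), to = c(2, 3, 5, 6),
                     strength = rep(0.8, 4))
  part <- detect_communities(net)
  expect_true(all(part$membership[paste0("N", 1:3)] !=
                    part$membership[paste0("N", 4:6)]))
})

test_that("detected modularity equals the exhaustive-search optimum", {
  cases <- list(c(3, 3, 101), c(3, 4, 202), c(4, 4, 303), c(4, 5, 404),
                c(3, 5, 505))
  for (cs in cases) {
    net <- planted_block_network(cs[1], cs[2], cs[3])
    part <- detect_communities(net)
    qmax <- brute_max_modularity(net$graph, igraph::E(net$graph)$strength)
    expect_equal(part$modularity, qmax, tolerance = 1e-10)
  }
})

test_that("co-membership verdict reads the phenyl and his66 labels", {
  memb <- c(R1 = 1L, phenyl = 1L, his66 = 1L, imidazolinone = 1L)
  part <- structure(list(membership = memb, modularity = 0.1,
                         n_communities = 1L),
                    class = "community_partition")
  nm <- list(chromophore_nodes = c("imidazolinone", "phenyl", "his66"))
  class(nm) <- "node_map"
  expect_true(co_membership(part, nm))
  part$membership["his66"] <- 2L
  expect_false(co_membership(part, nm))
  nm$chromophore_nodes <- NULL
  expect_error(co_membership(part, nm), "chromophore")
})

test_that("community report lists the phenyl community and flags residues", {
  memb <- c(R1 = 1L, R2 = 1L, R163 = 1L, R177 = 2L, phenyl = 1L,
            his66 = 2L, imidazolinone = 1L)
  part <- structure(list(membership = memb, modularity = 0.2,
                         n_communities = 2L),
                    class = "community_partition")
  nm <- structure(list(chromophore_nodes = c("imidazolinone", "phenyl",
                                             "his66")),
                  class = "node_map")
  rep1 <- community_report(part, nm, residues_of_interest = c(163, 177))
  expect_setequal(rep1$members, c("R1", "R2", "R163", "phenyl",
                                  "imidazolinone"))
  expect_false(rep1$his66_in)
  expect_equal(rep1$residues_of_interest$in_phenyl_community, c(TRUE, FALSE))
  rep2 <- community_report(part, nm)
  expect_equal(nrow(rep2$residues_of_interest), 0)
})

test_that("network files are written as GraphML and TSV", {
  net <- toy_network(4, from = c(1, 2, 3), to = c(2, 3, 4),
                     strength = c(0.9, 0.8, 0.7))
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, gml, tsv)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), 3)
  df <- read.delim(tsv)
  expect_equal(nrow(df), 3)
  expect_equal(df$weight, -log(c(0.9, 0.8, 0.7)), tolerance = 1e-6)
})
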