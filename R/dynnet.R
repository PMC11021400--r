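#' Dynamic-network construction parameters
#'
#' Two nodes are connected when the minimum distance between any pair of
#' their atoms stays below `contact_cutoff` in more than
#' `occupancy_threshold` of the frames (strict inequality), excluding
#' sequence-neighbour pairs.
#'
#' @param contact_cutoff contact distance cutoff (Angstrom).
#' @param occupancy_threshold occupancy fraction an edge must exceed.
#' @param exclude_neighbors drop sequence-adjacent pairs from the edge set.
#' @return an object of class `network_config`.
#' @export
network_config <- function(contact_cutoff = 4.0, occupancy_threshold = 0.75,
                           exclude_neighbors = TRUE) {
  if (contact_cutoff <= 0) stop("contact_cutoff must be > 0")
  if (occupancy_threshold <= 0 || occupancy_threshold >= 1) {
    stop("occupancy_threshold must be in (0, 1)")
  }
  structure(list(contact_cutoff = contact_cutoff,
                 occupancy_threshold = occupancy_threshold,
                 exclude_neighbors = isTRUE(exclude_neighbors)),
            class = "network_config")
}

#' Contact occupancy between network nodes
#'
#' `O[i, j]` is the fraction of frames in which the minimum inter-atomic
#' distance between the member atoms of nodes i and j is strictly below the
#' cutoff. The diagonal is `NA`.
#'
#' @param traj a `trajectory`.
#' @param nodemap a `node_map`.
#' @param cutoff contact distance cutoff (Angstrom).
#' @return symmetric `nodes x nodes` matrix of occupancies.
#' @export
contact_occupancy <- function(traj, nodemap, cutoff = 4.0) {
  stopifnot(inherits(traj, "trajectory"), inherits(nodemap, "node_map"))
  n <- length(nodemap$nodes)
  Fn <- n_frames(traj)
  members <- lapply(nodemap$nodes, `[[`, "members")
  if (any(lengths(members) == 0)) stop("empty node member set")
  O <- matrix(NA_real_, n, n,
              dimnames = list(nodemap$node_ids, nodemap$node_ids))
  cut2 <- cutoff^2
  co <- traj$coords
  for (i in seq_len(n - 1L)) {
    mi <- members[[i]]
    for (j in (i + 1L):n) {
      mj <- members[[j]]
      min_d2 <- rep(Inf, Fn)
      for (a in mi) {
        da <- co[, a, , drop = FALSE]
        for (b in mj) {
          d2 <- (co[, a, 1] - co[, b, 1])^2 +
                (co[, a, 2] - co[, b, 2])^2 +
                (co[, a, 3] - co[, b, 3])^2
          min_d2 <- pmin(min_d2, d2)
        }
      }
      O[i, j] <- O[j, i] <- mean(min_d2 < cut2)
    }
  }
  O
}

#' Dynamical cross-correlation matrix of node motions
#'
#' Normalised covariance of the 3-D displacement vectors of the node
#' representatives (scalar dot-product form):
#' `C[i, j] = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)`, with `dr` the
#' displacement of each node representative from its trajectory mean.
#' Zero-variance nodes yield undefined correlations, which are set to 0
#' with a warning.
#'
#' @param traj a `trajectory`, already superposed if rigid-body motion is to
#'   be excluded.
#' @param nodemap a `node_map`.
#' @return symmetric `nodes x nodes` correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(traj, nodemap) {
  stopifnot(inherits(traj, "trajectory"), inherits(nodemap, "node_map"))
  if (n_frames(traj) < 3) stop("correlation needs at least 3 frames")
  rc <- .node_coords(traj, nodemap)
  Dx <- scale(rc[, , 1], scale = FALSE)
  Dy <- scale(rc[, , 2], scale = FALSE)
  Dz <- scale(rc[, , 3], scale = FALSE)
  N <- crossprod(Dx) + crossprod(Dy) + crossprod(Dz)
  v <- diag(N)
  zero <- v <= 0
  if (any(zero)) {
    warning("zero-variance node(s): ",
            paste(nodemap$node_ids[zero], collapse = ", "),
            "; correlations set to 0")
    v[zero] <- 1
  }
  C <- N / sqrt(outer(v, v))
  if (any(zero)) {
    C[zero, ] <- 0
    C[, zero] <- 0
  }
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 1
  dimnames(C) <- list(nodemap$node_ids, nodemap$node_ids)
  C
}

#' Build the occupancy-filtered, correlation-weighted network
#'
#' Nodes i and j are connected iff `O[i, j]` strictly exceeds the occupancy
#' threshold and the pair is not a sequence-neighbour pair (when exclusion
#' is on). Each edge carries the occupancy, the correlation `C[i, j]`, the
#' distance-like weight `w = -log |C|` (with `|C|` floored at 1e-6 to cap
#' the weight) and the strength `|C|` used for modularity.
#'
#' @param occupancy matrix from [contact_occupancy()].
#' @param correlation matrix from [correlation_matrix()].
#' @param nodemap a `node_map`.
#' @param config a [network_config()].
#' @return an object of class `dyn_network` wrapping an igraph graph.
#' @export
build_graph <- function(occupancy, correlation, nodemap,
                        config = network_config()) {
  stopifnot(inherits(nodemap, "node_map"))
  ids <- nodemap$node_ids
  n <- length(ids)
  if (!all(dim(occupancy) == n) || !all(dim(correlation) == n)) {
    stop("matrix dimensions do not match the node map")
  }
  nb <- .neighbor_matrix(nodemap)
  from <- character(0); to <- character(0)
  occ <- corr <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (is.na(occupancy[i, j])) next
      if (occupancy[i, j] <= config$occupancy_threshold) next
      if (config$exclude_neighbors && nb[i, j]) next
      from <- c(from, ids[i]); to <- c(to, ids[j])
      occ <- c(occ, occupancy[i, j]); corr <- c(corr, correlation[i, j])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (length(from)) {
    ev <- rbind(from, to)
    g <- igraph::add_edges(g, as.vector(ev))
    strength <- pmax(abs(corr), 1e-6)
    g <- igraph::set_edge_attr(g, "occupancy", value = occ)
    g <- igraph::set_edge_attr(g, "correlation", value = corr)
    g <- igraph::set_edge_attr(g, "strength", value = strength)
    g <- igraph::set_edge_attr(g, "weight", value = -log(strength))
  }
  structure(list(graph = g, config = config), class = "dyn_network")
}

#' @export
print.dyn_network <- function(x, ...) {
  cat(sprintf(
    "dyn_network: %d nodes, %d edges (cutoff %.2f A, occupancy > %.2f%s)\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    x$config$contact_cutoff, x$config$occupancy_threshold,
    if (x$config$exclude_neighbors) ", neighbours excluded" else ""))
  invisible(x)
}

.as_igraph <- function(graph) {
  if (inherits(graph, "dyn_network")) graph$graph else graph
}

#' Detect communities of correlated motion (Girvan-Newman)
#'
#' Iteratively removes the edge with the highest betweenness, computing
#' betweenness on the `-log |C|` edge weights interpreted as distances, and
#' returns the partition along the removal dendrogram that maximises
#' Newman-Girvan modularity Q, computed with `|C|` as edge strengths. Ties
#' in betweenness are broken by removing the lexicographically smallest
#' edge (by sorted endpoint names), making the procedure deterministic.
#' A graph with no edges yields singleton communities with Q = 0.
#'
#' @param graph a `dyn_network` or an igraph graph with `weight` (distance)
#'   and `strength` edge attributes; if `strength` is missing, `exp(-weight)`
#'   is used.
#' @return an object of class `community_partition` with `membership`
#'   (named integer vector), `modularity` and `n_communities`.
#' @export
detect_communities <- function(graph) {
  g <- .as_igraph(graph)
  if (igraph::vcount(g) == 0) stop("graph is empty")
  ids <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  if (igraph::ecount(g) == 0) {
    memb <- seq_along(ids)
    names(memb) <- ids
    return(structure(list(membership = memb, modularity = 0,
                          n_communities = length(ids)),
                     class = "community_partition"))
  }
  strength <- igraph::E(g)$strength
  if (is.null(strength)) strength <- exp(-igraph::E(g)$weight)

  full <- g
  work <- g
  best_Q <- -Inf
  best_memb <- NULL
  last_ncomp <- -1L

  score <- function(membership) {
    igraph::modularity(full, membership, weights = strength)
  }

  repeat {
    comp <- igraph::components(work)$membership
    if (max(comp) != last_ncomp) {
      last_ncomp <- max(comp)
      Q <- score(comp)
      if (Q > best_Q + 1e-12) {
        best_Q <- Q
        best_memb <- comp
      }
    }
    if (igraph::ecount(work) == 0) break
    w <- pmax(igraph::E(work)$weight, 1e-12)
    eb <- igraph::edge_betweenness(work, weights = w)
    cand <- which(eb >= max(eb) - 1e-9)
    if (length(cand) > 1L) {
      en <- igraph::ends(work, igraph::E(work)[cand], names = TRUE)
      keys <- apply(en, 1, function(p) paste(sort(p), collapse = "|"))
      cand <- cand[order(keys)][1L]
    }
    work <- igraph::delete_edges(work, igraph::E(work)[cand[1L]])
  }

  memb <- as.integer(best_memb)
  names(memb) <- ids
  structure(list(membership = memb, modularity = best_Q,
                 n_communities = max(memb)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities, Q = %.4f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

#' @export
summary.community_partition <- function(object, ...) {
  sizes <- table(object$membership)
  cat(sprintf("%d communities (Q = %.4f)\n", object$n_communities,
              object$modularity))
  for (k in names(sizes)) {
    cat(sprintf("  community %s (%d): %s\n", k, sizes[[k]],
                paste(names(object$membership)[object$membership ==
                                                 as.integer(k)],
                      collapse = ", ")))
  }
  invisible(object)
}

#' Isomerizability verdict: do phenyl and his66 share a community?
#'
#' A variant is classified isomerization-competent when the chromophore
#' phenyl fragment and the His66-derived node carry the same community
#' label.
#'
#' @param partition a `community_partition`.
#' @param nodemap a `node_map` with chromophore nodes.
#' @return logical verdict.
#' @export
co_membership <- function(partition, nodemap) {
  stopifnot(inherits(partition, "community_partition"),
            inherits(nodemap, "node_map"))
  if (is.null(nodemap$chromophore_nodes)) {
    stop("node map has no chromophore nodes")
  }
  need <- c("phenyl", "his66")
  if (!all(need %in% names(partition$membership))) {
    stop("partition does not cover the chromophore nodes")
  }
  unname(partition$membership["phenyl"] == partition$membership["his66"])
}

#' Summarise the community containing the chromophore phenyl fragment
#'
#' Lists the members of the phenyl fragment's community and flags whether
#' nominated residues of interest (e.g. the 161/163/177 positions known to
#' gate photoswitching) belong to it.
#'
#' @param partition a `community_partition`.
#' @param nodemap a `node_map` with chromophore nodes.
#' @param residues_of_interest integer residue indices to flag.
#' @return an object of class `community_report`.
#' @export
community_report <- function(partition, nodemap,
                             residues_of_interest = integer()) {
  stopifnot(inherits(partition, "community_partition"),
            inherits(nodemap, "node_map"))
  if (is.null(nodemap$chromophore_nodes)) {
    stop("node map has no chromophore nodes")
  }
  lab <- partition$membership["phenyl"]
  members <- names(partition$membership)[partition$membership == lab]
  roi <- data.frame(residue = integer(0), node_id = character(0),
                    in_phenyl_community = logical(0))
  if (length(residues_of_interest)) {
    nid <- paste0("R", residues_of_interest)
    roi <- data.frame(residue = residues_of_interest, node_id = nid,
                      in_phenyl_community = nid %in% members,
                      stringsAsFactors = FALSE)
  }
  structure(list(phenyl_community = unname(lab), members = members,
                 his66_in = "his66" %in% members,
                 residues_of_interest = roi),
            class = "community_report")
}

#' @export
print.community_report <- function(x, ...) {
  cat(sprintf("phenyl fragment community (%d members): %s\n",
              length(x$members), paste(x$members, collapse = ", ")))
  cat(sprintf("his66 in the same community: %s\n", x$his66_in))
  if (nrow(x$residues_of_interest)) {
    print(x$residues_of_interest, row.names = FALSE)
  }
  invisible(x)
}

#' Write the network as GraphML and a TSV edge list
#'
#' @param net a `dyn_network`.
#' @param graphml_path GraphML output (NULL to skip).
#' @param edges_tsv_path TSV edge-list output `(i, j, occupancy, correlation,
#'   weight)` (NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, graphml_path = NULL, edges_tsv_path = NULL) {
  g <- .as_igraph(net)
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_tsv_path)) {
    en <- igraph::ends(g, igraph::E(g), names = TRUE)
    df <- data.frame(i = en[, 1], j = en[, 2],
                     occupancy = igraph::E(g)$occupancy,
                     correlation = igraph::E(g)$correlation,
                     weight = igraph::E(g)$weight,
                     stringsAsFactors = FALSE)
    utils::write.table(df, edges_tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(graphml = graphml_path, edges = edges_tsv_path))
}
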