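#' Construct a trajectory object
#'
#' A `trajectory` holds coordinates as a `frames x atoms x 3` array (Angstrom)
#' plus per-atom metadata (`name`, `residue_index`, `residue_name`, `chain`).
#'
#' @param coords numeric array, `frames x atoms x 3`.
#' @param atom_meta data frame with one row per atom.
#' @return an object of class `trajectory`.
#' @export
new_trajectory <- function(coords, atom_meta) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be a frames x atoms x 3 array")
  }
  if (dim(coords)[1] < 1) stop("trajectory needs at least one frame")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (nrow(atom_meta) != dim(coords)[2]) {
    stop("atom_meta must have one row per atom")
  }
  structure(list(coords = coords, atom_meta = atom_meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("trajectory: %d frame(s), %d atoms, %d residues\n",
              d[1], d[2], length(unique(x$atom_meta$residue_index))))
  invisible(x)
}

#' @export
dim.trajectory <- function(x) dim(x$coords)

n_frames <- function(traj) dim(traj$coords)[1]

#' Read a single-model PDB file as a one-frame trajectory
#'
#' Parsing is delegated to [bio3d::read.pdb()].
#'
#' @param path PDB file.
#' @return a `trajectory` with one frame.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("cannot parse PDB '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no ATOM records in ", path)
  coords <- array(0, dim = c(1, nrow(at), 3))
  coords[1, , 1] <- at$x; coords[1, , 2] <- at$y; coords[1, , 3] <- at$z
  meta <- data.frame(name = trimws(at$elety),
                     residue_index = at$resno,
                     residue_name = trimws(at$resid),
                     chain = ifelse(is.na(at$chain) | at$chain == "",
                                    "A", at$chain),
                     stringsAsFactors = FALSE)
  new_trajectory(coords, meta)
}

#' Read a coordinate trajectory (multi-frame XYZ or DCD)
#'
#' The structure supplies atom metadata; every frame must have the same atom
#' count as the structure. XYZ frames are standard blocks (atom count,
#' comment, `name x y z` records); DCD files are read with
#' [bio3d::read.dcd()].
#'
#' @param structure a `trajectory` (typically from [read_structure()]).
#' @param path trajectory file (`.xyz` or `.dcd`).
#' @return a `trajectory` with all frames in file order.
#' @export
read_trajectory <- function(structure, path) {
  stopifnot(inherits(structure, "trajectory"))
  if (!file.exists(path)) stop("file not found: ", path)
  n_atoms <- dim(structure$coords)[2]
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (ncol(xyz) != 3 * n_atoms) {
      stop(sprintf("DCD atom count (%d) does not match structure (%d)",
                   ncol(xyz) / 3, n_atoms))
    }
    coords <- array(0, dim = c(nrow(xyz), n_atoms, 3))
    for (ax in 1:3) coords[, , ax] <- xyz[, seq(ax, ncol(xyz), by = 3)]
    return(new_trajectory(coords, structure$atom_meta))
  }
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ at line ", i, ": expected atom count")
    f <- f + 1L
    if (n != n_atoms) {
      stop(sprintf("frame %d has %d atoms; structure has %d", f, n, n_atoms))
    }
    if (i + 1L + n > length(lines)) {
      stop("truncated XYZ frame ", f)
    }
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad)) {
      stop("malformed XYZ at line ", i + 1L + bad[1], ": expected 'name x y z'")
    }
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(m))) stop("non-numeric coordinates in XYZ frame ", f)
    frames[[f]] <- m
    i <- i + 2L + n
  }
  if (f == 0L) stop("no frames found in ", path)
  coords <- array(0, dim = c(f, n_atoms, 3))
  for (k in seq_len(f)) coords[k, , ] <- frames[[k]]
  new_trajectory(coords, structure$atom_meta)
}

# Kabsch rigid-body superposition of one frame onto centred reference
# coordinates; returns the aligned (already re-centred) frame.
.kabsch_align <- function(X, Qc, q_center) {
  p_center <- colMeans(X)
  Pc <- sweep(X, 2, p_center)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(Pc %*% t(R), 2, q_center, "+")
}

#' Remove global rotation and translation from a trajectory
#'
#' Each frame is rigid-body aligned to the chosen reference frame by the
#' Kabsch (SVD) procedure over all atoms, unweighted. A degenerate
#' (collinear) reference cannot define a rotation; the trajectory is then
#' returned unchanged with a warning.
#'
#' @param traj a `trajectory`.
#' @param reference reference frame index.
#' @return the superposed `trajectory`.
#' @export
superpose <- function(traj, reference = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  Fn <- n_frames(traj)
  if (reference < 1 || reference > Fn) stop("reference frame out of range")
  Q <- traj$coords[reference, , ]
  q_center <- colMeans(Q)
  Qc <- sweep(Q, 2, q_center)
  sv <- svd(Qc)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    warning("reference frame is (nearly) collinear; superposition skipped")
    return(traj)
  }
  out <- traj$coords
  for (f in seq_len(Fn)) {
    out[f, , ] <- .kabsch_align(traj$coords[f, , ], Qc, q_center)
  }
  new_trajectory(out, traj$atom_meta)
}

#' Map trajectory atoms to network nodes
#'
#' Every amino acid becomes a single node; the chromophore residue, when a
#' fragment table is supplied, is divided into three nodes (imidazolinone,
#' phenyl, his66). Sequence-adjacent node pairs within a chain are recorded
#' as neighbours (to be excluded from network edges); the three chromophore
#' nodes are mutual neighbours and each is a neighbour of the residues
#' flanking the chromophore in sequence.
#'
#' @param traj a `trajectory`.
#' @param chromophore_table NULL, a list
#'   `list(residue = <index>, fragments = list(imidazolinone =, phenyl =,
#'   his66 = <atom names>))`, or the path of a JSON file with those fields.
#' @param representative `"cog"` (centre of geometry of member atoms, the
#'   default: uniform across residues and chromophore fragments) or
#'   `"calpha"` (CA atom for residues that have one, centre of geometry
#'   otherwise).
#' @return an object of class `node_map` with elements `nodes` (list of
#'   `node_id`, `members`, `residue_index`, `chain`), `neighbor_pairs`
#'   (two-column character matrix), and `chromophore_nodes`.
#' @export
build_node_map <- function(traj, chromophore_table = NULL,
                           representative = c("cog", "calpha")) {
  stopifnot(inherits(traj, "trajectory"))
  representative <- match.arg(representative)
  m <- traj$atom_meta
  if (is.character(chromophore_table) && length(chromophore_table) == 1) {
    chromophore_table <- read_fragment_table(chromophore_table)
  }
  cro_res <- chromophore_table$residue %||% NA_integer_

  key <- paste(m$chain, m$residue_index)
  res_tab <- unique(data.frame(chain = m$chain,
                               residue_index = m$residue_index,
                               stringsAsFactors = FALSE))
  res_tab <- res_tab[order(res_tab$chain, res_tab$residue_index), ]

  nodes <- list()
  chromo_ids <- NULL
  for (r in seq_len(nrow(res_tab))) {
    ch <- res_tab$chain[r]; resno <- res_tab$residue_index[r]
    idx <- which(m$chain == ch & m$residue_index == resno)
    if (!is.na(cro_res) && resno == cro_res) {
      frs <- chromophore_table$fragments
      need <- c("imidazolinone", "phenyl", "his66")
      if (!all(need %in% names(frs))) {
        stop("fragment table must name imidazolinone, phenyl and his66")
      }
      all_members <- integer(0)
      for (fn in need) {
        fidx <- idx[m$name[idx] %in% frs[[fn]]]
        if (length(fidx) != length(frs[[fn]])) {
          stop("chromophore atoms not found for fragment '", fn, "'")
        }
        if (length(intersect(fidx, all_members))) {
          stop("chromophore fragments must use disjoint atom sets")
        }
        all_members <- c(all_members, fidx)
        nodes[[length(nodes) + 1L]] <- list(
          node_id = fn, members = fidx, residue_index = resno, chain = ch)
      }
      chromo_ids <- need
    } else {
      if (length(idx) == 0) stop("empty node member set for residue ", resno)
      nodes[[length(nodes) + 1L]] <- list(
        node_id = paste0("R", resno), members = idx,
        residue_index = resno, chain = ch)
    }
  }

  ids <- vapply(nodes, `[[`, "", "node_id")
  resno_of <- vapply(nodes, `[[`, 0, "residue_index")
  chain_of <- vapply(nodes, `[[`, "", "chain")

  pairs <- NULL
  for (a in seq_along(nodes)) {
    for (b in seq_along(nodes)) {
      if (b <= a) next
      if (chain_of[a] != chain_of[b]) next
      dr <- abs(resno_of[a] - resno_of[b])
      same_cro <- !is.na(cro_res) &&
        resno_of[a] == cro_res && resno_of[b] == cro_res
      if (dr == 1 || same_cro) {
        pairs <- rbind(pairs, c(ids[a], ids[b]))
      }
    }
  }

  structure(list(nodes = nodes, node_ids = ids,
                 neighbor_pairs = pairs, chromophore_nodes = chromo_ids,
                 representative = representative),
            class = "node_map")
}

#' @export
print.node_map <- function(x, ...) {
  cat(sprintf("node_map: %d nodes (%s), %d neighbour pairs\n",
              length(x$nodes),
              if (is.null(x$chromophore_nodes)) "no chromophore"
              else "3 chromophore fragments",
              NROW(x$neighbor_pairs)))
  invisible(x)
}

# representative (per-node) coordinates: frames x nodes x 3
.node_coords <- function(traj, nodemap) {
  Fn <- n_frames(traj)
  n <- length(nodemap$nodes)
  out <- array(0, dim = c(Fn, n, 3))
  for (i in seq_len(n)) {
    members <- nodemap$nodes[[i]]$members
    if (nodemap$representative == "calpha") {
      ca <- members[traj$atom_meta$name[members] == "CA"]
      if (length(ca) == 1) members <- ca
    }
    if (length(members) == 1) {
      out[, i, ] <- traj$coords[, members, ]
    } else {
      out[, i, ] <- apply(traj$coords[, members, , drop = FALSE], c(1, 3),
                          mean)
    }
  }
  dimnames(out) <- list(NULL, nodemap$node_ids, c("x", "y", "z"))
  out
}

.neighbor_matrix <- function(nodemap) {
  n <- length(nodemap$node_ids)
  nb <- matrix(FALSE, n, n, dimnames = list(nodemap$node_ids,
                                            nodemap$node_ids))
  if (!is.null(nodemap$neighbor_pairs)) {
    for (r in seq_len(nrow(nodemap$neighbor_pairs))) {
      a <- nodemap$neighbor_pairs[r, 1]; b <- nodemap$neighbor_pairs[r, 2]
      nb[a, b] <- TRUE; nb[b, a] <- TRUE
    }
  }
  nb
}

#' Read a chromophore fragment table from JSON
#'
#' @param path JSON file with fields `residue` and `fragments`
#'   (`{fragment_name: [atom names]}`).
#' @return list suitable for [build_node_map()].
#' @export
read_fragment_table <- function(path) {
  ft <- jsonlite::read_json(path, simplifyVector = TRUE)
  ft$fragments <- as.list(ft$fragments)
  ft
}

#' Write a chromophore fragment table as JSON
#' @param table fragment table list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(table, path) {
  jsonlite::write_json(table, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
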