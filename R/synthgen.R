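#' Specification for a synthetic multi-residue trajectory
#'
#' Describes a toy protein whose residues move as rigid groups driven by a
#' shared latent random walk, on top of a fixed reference geometry with
#' controllable contact structure. The generated trajectory is the test
#' substrate for the dynamic-network stages: groups of residues with common
#' latent motion are the planted communities that community detection is
#' expected to recover.
#'
#' The reference geometry lays each group's residues on a three-row
#' boustrophedon lattice (spacing `lattice_spacing`), so that many
#' non-sequence-adjacent residue pairs are within contact range and each
#' group's contact graph is connected. Consecutive groups are separated by
#' `group_gap` (out of contact range) except for one bridging contact between
#' the last residue of a group and the second residue of the next, which
#' keeps the overall contact graph connected while leaving the communities
#' separable.
#'
#' An optional chromophore is appended as a single extra residue carrying
#' three named atom subsets (fragments `imidazolinone`, `phenyl`, `his66`),
#' mirroring the convention of splitting a fluorescent-protein chromophore
#' into three network nodes. With `chromophore = "same"` all three fragments
#' sit next to, and move with, the first group; with `"different"` the
#' `his66` fragment is placed next to, and moves with, the second group, so
#' the phenyl and his66 nodes end up in different communities.
#'
#' @param n_residues number of ordinary residues (excluding the chromophore).
#' @param atoms_per_residue atoms per ordinary residue (>= 1).
#' @param group_labels integer community label per residue; must form
#'   contiguous blocks `1, 2, ...` along the sequence. Defaults to
#'   `n_groups` equal blocks.
#' @param n_groups number of planted groups used when `group_labels` is NULL.
#' @param shared_motion_amplitude RMS 3-D displacement (Angstrom) of each
#'   group's latent walk about its trajectory mean; recycled per group.
#' @param noise_sigma per-atom, per-axis i.i.d. Gaussian noise sd (Angstrom).
#' @param n_frames number of frames (>= 2).
#' @param lattice_spacing in-group lattice spacing (Angstrom).
#' @param group_gap gap between consecutive group lattices (Angstrom).
#' @param chromophore NULL, `"same"` or `"different"` (see Details).
#' @param seed integer seed; all randomness of [gen_trajectory()] flows from it.
#' @return an object of class `trajectory_spec`.
#' @seealso [gen_trajectory()]
#' @export
trajectory_spec <- function(n_residues = 24,
                            atoms_per_residue = 3,
                            group_labels = NULL,
                            n_groups = 2,
                            shared_motion_amplitude = 0.5,
                            noise_sigma = 0.1,
                            n_frames = 500,
                            lattice_spacing = 2.7,
                            group_gap = 9.0,
                            chromophore = NULL,
                            seed = 1) {
  if (is.null(group_labels)) {
    group_labels <- sort(rep_len(seq_len(n_groups), n_residues))
  }
  if (length(group_labels) != n_residues) {
    stop("group_labels must assign exactly one label to every residue")
  }
  labs <- unique(group_labels)
  if (!identical(as.integer(labs), seq_along(labs)) ||
      is.unsorted(group_labels)) {
    stop("group_labels must form contiguous blocks 1, 2, ... along the sequence")
  }
  if (!is.numeric(n_frames) || n_frames < 2) {
    stop("n_frames must be at least 2")
  }
  if (atoms_per_residue < 1) stop("atoms_per_residue must be >= 1")
  amp <- rep_len(shared_motion_amplitude, length(labs))
  if (any(amp < 0)) stop("shared_motion_amplitude must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (!is.null(chromophore)) {
    chromophore <- match.arg(chromophore, c("same", "different"))
    if (chromophore == "different" && length(labs) < 2) {
      stop("chromophore = 'different' needs at least two groups")
    }
  }
  structure(list(
    n_residues = as.integer(n_residues),
    atoms_per_residue = as.integer(atoms_per_residue),
    group_labels = as.integer(group_labels),
    shared_motion_amplitude = amp,
    noise_sigma = noise_sigma,
    n_frames = as.integer(n_frames),
    lattice_spacing = lattice_spacing,
    group_gap = group_gap,
    chromophore = chromophore,
    seed = seed
  ), class = "trajectory_spec")
}

# Residue centres for one group: boustrophedon walk through a 3-row lattice,
# so residues i and i+3 (same row, adjacent columns) and the diagonals
# (spacing * sqrt(2) apart) are in contact while never being sequence
# neighbours.
.snake_positions <- function(m, spacing, x0 = 0) {
  k <- seq_len(m) - 1L
  col <- k %/% 3L
  r0 <- k %% 3L
  row <- ifelse(col %% 2L == 1L, 2L - r0, r0)
  cbind(x0 + col * spacing, row * spacing, rep(0, m))
}

#' Generate a synthetic trajectory with planted correlated-motion groups
#'
#' Coordinates follow `x_i(t) = ref_i + W_g(i)(t) + eta_i(t)`: a fixed
#' reference position, a latent cumulative-sum Gaussian random walk shared by
#' all residues of group `g` (normalised so its mean-centred 3-D RMS
#' displacement equals the group amplitude), and i.i.d. Gaussian per-atom
#' noise. The latent walk gives smooth, strongly autocorrelated motion
#' resembling collective modes.
#'
#' @param spec a [trajectory_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{trajectory}{a `trajectory` object (see [read_structure()]).}
#'     \item{truth}{data frame `(node_id, community)` — the planted partition,
#'       using the node ids that [build_node_map()] assigns.}
#'     \item{fragment_table}{chromophore fragment table (or NULL), in the form
#'       [build_node_map()] consumes.}
#'   }
#' @export
gen_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  s <- spec$lattice_spacing
  labs <- unique(spec$group_labels)
  n_groups <- length(labs)
  sizes <- tabulate(spec$group_labels, nbins = n_groups)

  ## --- reference geometry -------------------------------------------------
  centers <- matrix(0, spec$n_residues, 3)
  x0 <- 0
  group_x_range <- matrix(0, n_groups, 2)
  for (g in seq_len(n_groups)) {
    idx <- which(spec$group_labels == g)
    pos <- .snake_positions(length(idx), s, x0)
    centers[idx, ] <- pos
    group_x_range[g, ] <- range(pos[, 1])
    x0 <- max(pos[, 1]) + spec$group_gap
  }

  A <- spec$atoms_per_residue
  zoff <- (seq_len(A) - (A + 1) / 2) * 0.3
  atom_names <- if (A == 1) "CA" else c("CA", paste0("B", seq_len(A)[-1]))

  name <- character(0); resno <- integer(0); resid <- character(0)
  xyz <- NULL
  motion_group <- integer(0)  # latent-walk index per atom

  for (i in seq_len(spec$n_residues)) {
    at <- matrix(rep(centers[i, ], each = A), A, 3)
    at[, 3] <- at[, 3] + zoff
    xyz <- rbind(xyz, at)
    name <- c(name, atom_names)
    resno <- c(resno, rep(i, A))
    resid <- c(resid, rep("ALA", A))
    motion_group <- c(motion_group, rep(spec$group_labels[i], A))
  }

  ## Bridging atom: a central residue of group g gets an extra atom in
  ## contact with a central residue of group g+1 (central residues sit deep
  ## in their lattice, with many in-group contacts, so the single bridging
  ## edge concentrates all inter-group shortest-path traffic). The pair is
  ## never sequence-adjacent, and the atom approaches from +z so it touches
  ## only its target residue.
  for (g in seq_len(n_groups - 1L)) {
    own <- which(spec$group_labels == g)
    nxt <- which(spec$group_labels == g + 1L)
    if (length(own) < 3L || length(nxt) < 3L) next
    owner <- own[ceiling(length(own) / 2)]
    target_res <- nxt[ceiling(length(nxt) / 2)]
    bpos <- centers[target_res, ] + c(0, 0, 3.4)
    xyz <- rbind(xyz, bpos)
    name <- c(name, "XB")
    resno <- c(resno, owner)
    resid <- c(resid, "ALA")
    motion_group <- c(motion_group, g)
  }

  fragment_table <- NULL
  if (!is.null(spec$chromophore)) {
    cro_res <- spec$n_residues + 1L
    site_a <- c(group_x_range[1, 2] + s, s, 2.3)
    frag_names <- c("imidazolinone", "phenyl", "his66")
    frag_prefix <- c(imidazolinone = "I", phenyl = "P", his66 = "H")
    if (spec$chromophore == "same") {
      frag_sites <- rbind(site_a + c(0, -0.9, 0), site_a, site_a + c(0, 0.9, 0))
      frag_motion <- c(1L, 1L, 1L)
    } else {
      site_b <- c(group_x_range[2, 1] - s, s, 2.3)
      frag_sites <- rbind(site_a + c(0, -0.45, 0), site_a + c(0, 0.45, 0),
                          site_b)
      frag_motion <- c(1L, 1L, 2L)
    }
    fragments <- list()
    for (f in 1:3) {
      fz <- c(-0.2, 0, 0.2)
      at <- matrix(rep(frag_sites[f, ], each = 3), 3, 3)
      at[, 3] <- at[, 3] + fz
      anames <- paste0(frag_prefix[f], 1:3)
      xyz <- rbind(xyz, at)
      name <- c(name, anames)
      resno <- c(resno, rep(cro_res, 3))
      resid <- c(resid, rep("CRO", 3))
      motion_group <- c(motion_group, rep(frag_motion[f], 3))
      fragments[[frag_names[f]]] <- anames
    }
    fragment_table <- list(residue = cro_res, fragments = fragments)
  }

  n_atoms <- nrow(xyz)
  Fn <- spec$n_frames

  ## --- motion -------------------------------------------------------------
  coords <- with_seed(spec$seed, {
    walks <- lapply(seq_len(n_groups), function(g) {
      a <- spec$shared_motion_amplitude[g]
      if (a == 0) return(matrix(0, Fn, 3))
      w <- apply(matrix(stats::rnorm(Fn * 3), Fn, 3), 2, cumsum)
      w <- scale(w, scale = FALSE)
      # normalise the realised walk so its mean-centred 3-D RMS displacement
      # equals the requested amplitude exactly, seed by seed
      rms <- sqrt(mean(rowSums(w^2)))
      if (rms > 0) w * (a / rms) else w
    })
    co <- array(0, dim = c(Fn, n_atoms, 3))
    for (ax in 1:3) {
      disp <- vapply(motion_group, function(g) walks[[g]][, ax],
                     numeric(Fn))                       # frames x atoms
      base <- matrix(xyz[, ax], Fn, n_atoms, byrow = TRUE)
      co[, , ax] <- base + disp
    }
    if (spec$noise_sigma > 0) {
      co <- co + array(stats::rnorm(Fn * n_atoms * 3, 0, spec$noise_sigma),
                       dim = c(Fn, n_atoms, 3))
    }
    co
  })

  atom_meta <- data.frame(name = name, residue_index = resno,
                          residue_name = resid, chain = "A",
                          stringsAsFactors = FALSE)
  # fragments own disjoint atom sets by construction; guard regressions
  if (!is.null(fragment_table)) {
    fa <- unlist(fragment_table$fragments)
    if (anyDuplicated(fa)) stop("overlapping chromophore atom assignments")
  }
  traj <- new_trajectory(coords, atom_meta)

  truth <- data.frame(node_id = paste0("R", seq_len(spec$n_residues)),
                      community = spec$group_labels,
                      stringsAsFactors = FALSE)
  if (!is.null(spec$chromophore)) {
    his_grp <- if (spec$chromophore == "same") 1L else 2L
    truth <- rbind(truth, data.frame(
      node_id = c("imidazolinone", "phenyl", "his66"),
      community = c(1L, 1L, his_grp), stringsAsFactors = FALSE))
  }
  list(trajectory = traj, truth = truth, fragment_table = fragment_table)
}

#' Specification for synthetic photoswitching decay traces
#'
#' Parameters of the mono-exponential on-to-off decay model
#' `I(t) = A * exp(-k * t) + c` plus sampling and noise settings, and the
#' multi-cycle bleaching model (cycle m starts at amplitude
#' `A * bleach_factor^(m-1)`).
#'
#' @param A decay amplitude (a.u., >= 0).
#' @param k off-switching rate constant (1/s, > 0).
#' @param c residual plateau intensity (a.u., >= 0).
#' @param dt sampling interval (s).
#' @param n_points samples per trace.
#' @param noise_sigma additive Gaussian noise sd (a.u., >= 0).
#' @param n_cycles number of on-off cycles for [gen_switch_cycles()].
#' @param bleach_factor per-cycle amplitude multiplier in (0, 1].
#' @param seed integer seed.
#' @return an object of class `kinetic_spec`.
#' @export
kinetic_spec <- function(A = 1, k = 1, c = 0, dt = 0.05, n_points = 200,
                         noise_sigma = 0, n_cycles = 1, bleach_factor = 1,
                         seed = 1) {
  if (A < 0 || c < 0) stop("A and c must be >= 0")
  if (k <= 0) stop("k must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (bleach_factor <= 0 || bleach_factor > 1) {
    stop("bleach_factor must be in (0, 1]")
  }
  structure(list(A = A, k = k, c = c, dt = dt,
                 n_points = as.integer(n_points),
                 noise_sigma = noise_sigma, n_cycles = as.integer(n_cycles),
                 bleach_factor = bleach_factor, seed = seed),
            class = "kinetic_spec")
}

#' Generate a noisy mono-exponential decay trace
#'
#' @param spec a [kinetic_spec()].
#' @return a `decay_trace`: data frame with columns `time_s`, `intensity`.
#' @export
gen_decay_trace <- function(spec) {
  stopifnot(inherits(spec, "kinetic_spec"))
  t <- (seq_len(spec$n_points) - 1L) * spec$dt
  I <- spec$A * exp(-spec$k * t) + spec$c
  if (spec$noise_sigma > 0) {
    I <- I + with_seed(spec$seed, stats::rnorm(length(t), 0, spec$noise_sigma))
  }
  decay_trace(t, I)
}

#' Generate repeated on-off switching cycles with photobleaching
#'
#' Cycle m has initial amplitude `A * bleach_factor^(m-1)`; rate and plateau
#' are shared across cycles. Each cycle draws fresh noise from the one
#' seeded stream.
#'
#' @param spec a [kinetic_spec()] with `n_cycles >= 1`.
#' @return list of `decay_trace` objects, each carrying a `cycle` attribute.
#' @export
gen_switch_cycles <- function(spec) {
  stopifnot(inherits(spec, "kinetic_spec"))
  t <- (seq_len(spec$n_points) - 1L) * spec$dt
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_cycles), function(m) {
      I <- spec$A * spec$bleach_factor^(m - 1L) * exp(-spec$k * t) + spec$c
      if (spec$noise_sigma > 0) {
        I <- I + stats::rnorm(length(t), 0, spec$noise_sigma)
      }
      tr <- decay_trace(t, I)
      attr(tr, "cycle") <- m
      tr
    })
  })
}

#' Generate a synthetic pH titration of the anionic chromophore band
#'
#' Single-site Henderson-Hasselbalch form:
#' `A(pH) = a_max / (1 + 10^(pKa - pH)) + noise`.
#'
#' @param pka planted pKa (pH units).
#' @param a_max plateau absorbance of the fully anionic form.
#' @param ph_grid strictly increasing pH values.
#' @param sigma additive Gaussian noise sd.
#' @param seed integer seed (NULL for no seeding).
#' @return a `titration_curve`: data frame with columns `pH`, `absorbance`.
#' @export
gen_titration <- function(pka, a_max = 1, ph_grid = seq(4, 10, by = 0.5),
                          sigma = 0, seed = NULL) {
  if (length(ph_grid) == 0 || is.unsorted(ph_grid, strictly = TRUE)) {
    stop("ph_grid must be non-empty and strictly increasing")
  }
  if (sigma < 0) stop("sigma must be >= 0")
  a <- a_max / (1 + 10^(pka - ph_grid))
  if (sigma > 0) a <- a + with_seed(seed, stats::rnorm(length(a), 0, sigma))
  structure(data.frame(pH = ph_grid, absorbance = a),
            class = c("titration_curve", "data.frame"))
}

#' Draw samples from a three-component Gaussian mixture
#'
#' Emulates the per-frame bond-length-alternation values whose distribution
#' the mixture decomposition stage analyses.
#'
#' @param weights component weights, summing to 1.
#' @param means component means (Angstrom).
#' @param sds component standard deviations (> 0).
#' @param n number of draws.
#' @param seed integer seed (NULL for no seeding).
#' @return numeric vector of samples with a `components` attribute giving the
#'   drawn component index per sample.
#' @export
gen_bla_samples <- function(weights, means, sds, n, seed = NULL) {
  if (length(weights) != length(means) || length(means) != length(sds)) {
    stop("weights, means and sds must have the same length")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(sds <= 0)) stop("sds must be > 0")
  with_seed(seed, {
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    x <- stats::rnorm(n, means[comp], sds[comp])
    attr(x, "components") <- comp
    x
  })
}

#' Record a paired before/after-illumination absorbance change
#'
#' Photoconversion moves absorbance from the green band (which must
#' decrease) to the red band; the pair of band-maximum changes is the input
#' to the red-form extinction-coefficient estimator [epsilon_red()].
#'
#' @param delta_green change in green-band absorbance (must be < 0).
#' @param delta_red change in red-band absorbance (>= 0).
#' @return an object of class `spectrum_pair`.
#' @export
gen_spectra_pair <- function(delta_green, delta_red) {
  if (!is.numeric(delta_green) || delta_green >= 0) {
    stop("delta_green must be negative (green band is consumed)")
  }
  if (delta_red < 0) stop("delta_red must be >= 0")
  structure(list(delta_green = delta_green, delta_red = delta_red),
            class = "spectrum_pair")
}

## ---- plain-text writers ----------------------------------------------------

#' Write one trajectory frame as a single-model PDB file
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @param frame frame index to write.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(traj, path, frame = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  co <- traj$coords[frame, , , drop = FALSE]
  m <- traj$atom_meta
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(nrow(m)),
    substr(m$name, 1, 4), substr(m$residue_name, 1, 3),
    substr(m$chain, 1, 1), m$residue_index,
    co[1, , 1], co[1, , 2], co[1, , 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Standard XYZ blocks: atom count, a comment line carrying the frame index,
#' then `name x y z` per atom.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  n <- dim(traj$coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(traj$coords)[1])) {
    writeLines(c(as.character(n), paste("frame", f)), con)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", traj$atom_meta$name,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  invisible(path)
}

#' Write a node partition (planted or detected) as TSV
#'
#' @param partition a data frame `(node_id, community)` or a
#'   `community_partition`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  if (inherits(partition, "community_partition")) {
    partition <- data.frame(node_id = names(partition$membership),
                            community = unname(partition$membership),
                            stringsAsFactors = FALSE)
  }
  utils::write.table(partition, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a decay trace as CSV
#' @param trace a `decay_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  cyc <- attr(trace, "cycle")
  if (!is.null(cyc)) df$cycle <- cyc
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a titration curve as CSV
#' @param curve a `titration_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
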