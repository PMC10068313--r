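#' One-bead-per-residue structure
#'
#' Container for a coarse-grained protein complex: one bead per residue at
#' the alpha-carbon, with the residue's heavy-atom coordinates retained for
#' contact detection.
#'
#' @param xyz n x 3 matrix of bead (CA) coordinates, Angstrom.
#' @param chain character chain id per bead.
#' @param resno residue number per bead.
#' @param heavy optional list (one element per bead) of matrices of
#'   heavy-atom coordinates with a `element` attribute; defaults to the CA
#'   position with element "C".
#' @param chain_map optional named character vector mapping chain ids to
#'   molecular roles (e.g. `c(A = "MHC", C = "peptide", E = "TCRb")`).
#' @return Object of class `cg_structure`.
#' @export
cg_structure <- function(xyz, chain, resno, heavy = NULL, chain_map = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(chain),
            length(resno) == length(chain), all(is.finite(xyz)))
  if (is.null(heavy)) {
    heavy <- lapply(seq_len(nrow(xyz)), function(i) {
      m <- xyz[i, , drop = FALSE]
      attr(m, "element") <- "C"
      m
    })
  }
  structure(list(xyz = xyz, chain = chain, resno = resno, heavy = heavy,
                 chain_map = chain_map),
            class = "cg_structure")
}

#' @export
print.cg_structure <- function(x, ...) {
  cat(sprintf("Coarse-grained structure: %d beads, chains %s\n",
              nrow(x$xyz), paste(unique(x$chain), collapse = ", ")))
  if (!is.null(x$chain_map))
    cat("  roles:", paste(names(x$chain_map), x$chain_map, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Bead index of a chain's C-terminus
#'
#' @param structure a `cg_structure`.
#' @param chain chain id (or mapped role name when a chain_map is present).
#' @return integer bead index.
#' @export
chain_cterm <- function(structure, chain) {
  ch <- chain
  if (!is.null(structure$chain_map) && chain %in% structure$chain_map)
    ch <- names(structure$chain_map)[match(chain, structure$chain_map)]
  idx <- which(structure$chain == ch)
  if (length(idx) == 0L) stop("chain not found: ", chain)
  idx[which.max(structure$resno[idx])]
}

#' Load a PDB structure as a coarse-grained bead model
#'
#' One bead per residue placed at the alpha-carbon; all heavy (non-hydrogen)
#' atoms of each residue are cached for the contact-overlap criterion. For
#' altloc duplicates the highest-occupancy conformer is kept. Residues
#' without a CA atom and requested chains that are absent raise structured
#' errors.
#'
#' @param pdb_path path to a PDB file.
#' @param chain_map optional named character vector `c(pdb_chain = role)`;
#'   all named chains must be present.
#' @return a [cg_structure()].
#' @export
load_structure <- function(pdb_path, chain_map = NULL) {
  if (!file.exists(pdb_path)) stop("PDB file not found: ", pdb_path)
  pdb <- bio3d::read.pdb(pdb_path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$elesy %in% "H") &
             !grepl("^H", trimws(at$elety)), , drop = FALSE]
  # resolve altlocs: keep the highest-occupancy copy of each atom,
  # preserving file order otherwise
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  occ <- replace(at$o, is.na(at$o), 1)
  best <- unlist(lapply(split(seq_len(nrow(at)), key),
                        function(i) i[which.max(occ[i])]), use.names = FALSE)
  at <- at[sort(best), , drop = FALSE]

  if (!is.null(chain_map)) {
    missing <- setdiff(names(chain_map), unique(at$chain))
    if (length(missing))
      stop("chains absent from PDB: ", paste(missing, collapse = ", "))
    at <- at[at$chain %in% names(chain_map), , drop = FALSE]
  }
  rkey <- paste(at$chain, at$resno, at$insert)
  residues <- unique(rkey)
  ca <- at[trimws(at$elety) == "CA", , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, ca$insert)
  no_ca <- setdiff(residues, ca_key)
  if (length(no_ca))
    stop("residues without a CA atom: ", paste(utils::head(no_ca, 5), collapse = "; "))
  ca <- ca[match(residues, ca_key), , drop = FALSE]

  heavy <- lapply(residues, function(r) {
    rows <- at[rkey == r, , drop = FALSE]
    m <- as.matrix(rows[, c("x", "y", "z")])
    el <- toupper(substr(trimws(ifelse(rows$elesy == "" | is.na(rows$elesy),
                                       substr(trimws(rows$elety), 1, 1),
                                       rows$elesy)), 1, 1))
    attr(m, "element") <- el
    m
  })
  cg_structure(as.matrix(ca[, c("x", "y", "z")]), chain = ca$chain,
               resno = ca$resno, heavy = heavy, chain_map = chain_map)
}

#' Write a CA-only PDB file
#'
#' Minimal PDB writer for coarse-grained structures (used for toy
#' fixtures round-tripping through [load_structure()]).
#'
#' @param structure a `cg_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "cg_structure"))
  n <- nrow(structure$xyz)
  lines <- sprintf(
    "ATOM  %5d  CA  GLY %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), structure$chain, structure$resno,
    structure$xyz[, 1], structure$xyz[, 2], structure$xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# van der Waals radii (A) by element for the overlap criterion
.vdw_radius <- function(el) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  out <- r[el]
  out[is.na(out)] <- 1.70
  unname(out)
}

#' Native contact map
#'
#' Two residues are in native contact when any heavy-atom pair overlaps:
#' distance below `scale * (r_vdw_i + r_vdw_j)` (overlap criterion, default
#' scale 1.24), or below a plain distance `cutoff` (fallback criterion,
#' useful for CA-only toy structures). Sequentially adjacent intra-chain
#' pairs (i, i+1) and (i, i+2) are excluded. The native distance `r0`
#' attached to each contact is the bead (CA-CA) distance.
#'
#' @param structure a `cg_structure`.
#' @param method `"overlap"` or `"cutoff"`.
#' @param scale overlap scale factor.
#' @param cutoff plain distance cutoff, A.
#' @return Object of class `contact_map`: data.frame with `i`, `j`
#'   (bead indices, i < j), `r0`, `class` ("intra" or "inter"), `chain_i`,
#'   `chain_j`, `resno_i`, `resno_j`.
#' @export
native_contacts <- function(structure, method = c("overlap", "cutoff"),
                            scale = 1.24, cutoff = 4.5) {
  method <- match.arg(method)
  stopifnot(inherits(structure, "cg_structure"))
  n <- nrow(structure$xyz)
  res <- list()
  for (i in seq_len(n - 1L)) {
    hi <- structure$heavy[[i]]
    for (j in (i + 1L):n) {
      same <- structure$chain[i] == structure$chain[j]
      if (same && abs(structure$resno[i] - structure$resno[j]) <= 2L) next
      hj <- structure$heavy[[j]]
      # fast reject on bead distance (max heavy-atom reach ~ 10 A per residue)
      d_bead <- sqrt(sum((structure$xyz[i, ] - structure$xyz[j, ])^2))
      if (d_bead > 25) next
      dmat <- sqrt(outer(rowSums(hi^2), rowSums(hj^2), "+") - 2 * hi %*% t(hj))
      hit <- if (method == "cutoff") {
        any(dmat < cutoff)
      } else {
        thr <- outer(.vdw_radius(attr(hi, "element")),
                     .vdw_radius(attr(hj, "element")), "+") * scale
        any(dmat < thr)
      }
      if (hit) {
        res[[length(res) + 1L]] <- data.frame(
          i = i, j = j, r0 = d_bead,
          class = if (same) "intra" else "inter",
          chain_i = structure$chain[i], chain_j = structure$chain[j],
          resno_i = structure$resno[i], resno_j = structure$resno[j])
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
               class = character(0), chain_i = character(0),
               chain_j = character(0), resno_i = integer(0),
               resno_j = integer(0))
  base::structure(out, class = c("contact_map", "data.frame"))
}

#' Delete inter-molecular contacts between chain selections
#'
#' Removes from a contact map every inter-molecular contact linking
#' `chain_a` (optionally restricted to `resno_a`) with any chain in
#' `chain_b`. Intra-molecular contacts are never touched. Used to define
#' affinity-lowering constructs (e.g. removing peptide-TCR contacts).
#'
#' @param contacts a `contact_map`.
#' @param chain_a,chain_b chain ids on either side of the interface.
#' @param resno_a optional residue numbers restricting the `chain_a` side.
#' @return the reduced `contact_map`.
#' @export
delete_contacts <- function(contacts, chain_a, chain_b, resno_a = NULL) {
  stopifnot(inherits(contacts, "contact_map"))
  side_a_i <- contacts$chain_i %in% chain_a &
    (is.null(resno_a) | contacts$resno_i %in% resno_a)
  side_a_j <- contacts$chain_j %in% chain_a &
    (is.null(resno_a) | contacts$resno_j %in% resno_a)
  drop <- contacts$class == "inter" &
    ((side_a_i & contacts$chain_j %in% chain_b) |
       (side_a_j & contacts$chain_i %in% chain_b))
  contacts[!drop, , drop = FALSE]
}

#' Build the coarse-grained topology
#'
#' Assembles the structure-based potential: stiff harmonic backbone springs
#' between consecutive residues of each chain, harmonic springs for
#' intra-molecular native contacts (preventing unfolding of the individual
#' chains), 12-6 Lennard-Jones wells of depth `epsilon` with minimum at the
#' native distance for inter-molecular contacts, harmonic disulphide
#' springs between specified bead pairs, and a short-range repulsion for
#' all remaining pairs. Energies in kBT, lengths in Angstrom.
#'
#' @param structure a `cg_structure`.
#' @param contacts a `contact_map` (possibly after [delete_contacts()]).
#' @param epsilon inter-molecular contact depth, kBT.
#' @param k_backbone backbone spring constant, kBT/A^2.
#' @param k_contact intra-molecular contact spring constant, kBT/A^2.
#' @param disulphides optional 2-column matrix of bead index pairs.
#' @param k_ss disulphide spring constant, kBT/A^2.
#' @param rep_sigma repulsion range, A.
#' @param rep_epsilon repulsion strength, kBT.
#' @return Object of class `cg_topology`.
#' @export
build_model <- function(structure, contacts, epsilon = 1,
                        k_backbone = 20, k_contact = 2,
                        disulphides = NULL, k_ss = 20,
                        rep_sigma = 4, rep_epsilon = 1) {
  stopifnot(inherits(structure, "cg_structure"), inherits(contacts, "contact_map"))
  xyz <- structure$xyz
  n <- nrow(xyz)
  d0 <- function(i, j) sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))

  bb_i <- integer(0); bb_j <- integer(0)
  for (ch in unique(structure$chain)) {
    idx <- which(structure$chain == ch)
    idx <- idx[order(structure$resno[idx])]
    if (length(idx) > 1L) {
      bb_i <- c(bb_i, idx[-length(idx)])
      bb_j <- c(bb_j, idx[-1L])
    }
  }
  bonds <- data.frame(i = bb_i, j = bb_j,
                      k = rep(k_backbone, length(bb_i)),
                      r0 = if (length(bb_i)) d0(bb_i, bb_j) else numeric(0))

  intra <- contacts[contacts$class == "intra", , drop = FALSE]
  if (nrow(intra))
    bonds <- rbind(bonds, data.frame(i = intra$i, j = intra$j,
                                     k = k_contact, r0 = intra$r0))
  if (!is.null(disulphides)) {
    disulphides <- as.matrix(disulphides)
    bonds <- rbind(bonds, data.frame(i = disulphides[, 1], j = disulphides[, 2],
                                     k = k_ss,
                                     r0 = d0(disulphides[, 1], disulphides[, 2])))
  }
  inter <- contacts[contacts$class == "inter", , drop = FALSE]
  lj <- data.frame(i = inter$i, j = inter$j,
                   eps = rep(epsilon, nrow(inter)), r0 = inter$r0)

  base::structure(list(xyz0 = xyz, n = n, chain = structure$chain,
                 bonds = bonds, lj = lj,
                 rep_sigma = rep_sigma, rep_epsilon = rep_epsilon,
                 k_max = max(bonds$k, 72 * epsilon / min(c(lj$r0, Inf))^2)),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("CG topology: %d beads, %d harmonic springs, %d inter-molecular LJ contacts\n",
              x$n, nrow(x$bonds), nrow(x$lj)))
  invisible(x)
}

#' Potential energy and gradient of a topology (R reference implementation)
#'
#' Used for stationarity checks of the native configuration; the production
#' integrator lives in compiled code.
#'
#' @param topology a `cg_topology`.
#' @param xyz coordinates (defaults to native).
#' @return list with `energy` (kBT) and `gradient` (n x 3, kBT/A).
#' @export
cg_energy <- function(topology, xyz = topology$xyz0) {
  n <- topology$n
  grad <- matrix(0, n, 3)
  e <- 0
  pair_acc <- function(i, j, f_over_r, de) {
    dx <- xyz[i, ] - xyz[j, ]
    grad[i, ] <<- grad[i, ] + f_over_r * dx
    grad[j, ] <<- grad[j, ] - f_over_r * dx
    e <<- e + de
  }
  b <- topology$bonds
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    pair_acc(i, j, b$k[r] * (d - b$r0[r]) / d, 0.5 * b$k[r] * (d - b$r0[r])^2)
  }
  l <- topology$lj
  for (r in seq_len(nrow(l))) {
    i <- l$i[r]; j <- l$j[r]
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    s6 <- (l$r0[r] / d)^6
    pair_acc(i, j, -12 * l$eps[r] * (s6^2 - s6) / d^2,
             l$eps[r] * (s6^2 - 2 * s6))
  }
  excl <- .pair_keys(topology)
  sig <- topology$rep_sigma; repe <- topology$rep_epsilon
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (paste(i, j) %in% excl) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < 2 * sig) {
      s12 <- (sig / d)^12
      pair_acc(i, j, -12 * repe * s12 / d^2, repe * s12)
    }
  }
  list(energy = e, gradient = grad)
}

.pair_keys <- function(topology) {
  ex <- rbind(topology$bonds[, c("i", "j")], topology$lj[, c("i", "j")])
  # also exclude sequential neighbours (i, i+1), (i, i+2) within chains
  for (ch in unique(topology$chain)) {
    idx <- which(topology$chain == ch)
    if (length(idx) > 2L) {
      ex <- rbind(ex,
                  data.frame(i = idx[seq_len(length(idx) - 2L)],
                             j = idx[seq_len(length(idx) - 2L) + 2L]))
    }
  }
  paste(pmin(ex$i, ex$j), pmax(ex$i, ex$j))
}

#' Constant-speed pulling simulation
#'
#' Langevin dynamics of the coarse-grained complex with two harmonic
#' springs of stiffness `kappa`: one tethers the `fixed_bead` to its native
#' position, the other connects the `moving_bead` to an anchor retracted at
#' constant speed `v` along the initial fixed-to-moving axis. The recorded
#' response force is the extension of the pulling spring projected on the
#' pulling direction times `kappa`. Dynamics are overdamped Brownian by
#' default (`mode = "brownian"`); `mode = "langevin"` runs underdamped
#' BAOAB (velocity Verlet in the zero-friction, zero-noise limit).
#'
#' @param topology a `cg_topology`.
#' @param v pulling speed, A per time unit.
#' @param fixed_bead,moving_bead bead indices (e.g. from [chain_cterm()]).
#' @param kappa pulling-spring stiffness, kBT/A^2.
#' @param pull_distance total anchor travel, A.
#' @param seed integer seed.
#' @param kBT thermal energy (simulation units).
#' @param gamma friction coefficient.
#' @param mass bead mass (langevin mode).
#' @param dt time step; auto-derived from the stiffest interaction when NULL.
#' @param stride record every `stride` steps.
#' @param mode `"brownian"` or `"langevin"`.
#' @return Object of class `pull_trace`: data.frame columns `t`, `F`
#'   (kBT/A), `n_intact` (surviving inter-molecular contacts), plus the
#'   protocol parameters as attributes.
#' @export
run_pulling <- function(topology, v, fixed_bead, moving_bead,
                        kappa = 0.12, pull_distance = 40, seed = 1,
                        kBT = 1, gamma = 1, mass = 1, dt = NULL,
                        stride = NULL, mode = c("brownian", "langevin")) {
  mode <- match.arg(mode)
  stopifnot(inherits(topology, "cg_topology"), v >= 0, kappa > 0)
  k_stiff <- max(topology$k_max, kappa)
  if (is.null(dt)) {
    dt <- if (mode == "brownian") 0.05 * gamma / k_stiff
          else 0.05 * sqrt(mass / k_stiff)
  }
  n_steps <- if (v > 0) ceiling(pull_distance / v / dt) else
    ceiling(pull_distance / dt)  # v = 0: interpret pull_distance as total time
  if (is.null(stride)) stride <- max(1L, floor(n_steps / 2000))
  dir <- topology$xyz0[moving_bead, ] - topology$xyz0[fixed_bead, ]
  dir <- dir / sqrt(sum(dir^2))

  set.seed(seed)
  res <- cg_pull_cpp(topology$xyz0,
                     as.integer(topology$bonds$i - 1L),
                     as.integer(topology$bonds$j - 1L),
                     topology$bonds$k, topology$bonds$r0,
                     as.integer(topology$lj$i - 1L),
                     as.integer(topology$lj$j - 1L),
                     topology$lj$eps, topology$lj$r0,
                     .exclusion_matrix(topology),
                     topology$rep_sigma, topology$rep_epsilon,
                     as.integer(fixed_bead - 1L), as.integer(moving_bead - 1L),
                     dir, kappa, v, dt, gamma, kBT, mass,
                     as.integer(n_steps), as.integer(stride),
                     as.integer(seed), mode == "langevin")
  out <- data.frame(t = res$t, F = res$F, n_intact = res$n_intact)
  attr(out, "params") <- list(v = v, kappa = kappa, dt = dt, mode = mode,
                              kBT = kBT, gamma = gamma, seed = seed,
                              fixed_bead = fixed_bead, moving_bead = moving_bead)
  attr(out, "xyz_final") <- res$xyz_final
  attr(out, "energy") <- res$energy
  class(out) <- c("pull_trace", "data.frame")
  out
}

.exclusion_matrix <- function(topology) {
  n <- topology$n
  m <- matrix(0L, n, n)
  mark <- function(i, j) {
    m[cbind(i, j)] <<- 1L
    m[cbind(j, i)] <<- 1L
  }
  mark(topology$bonds$i, topology$bonds$j)
  if (nrow(topology$lj)) mark(topology$lj$i, topology$lj$j)
  for (ch in unique(topology$chain)) {
    idx <- which(topology$chain == ch)
    if (length(idx) > 2L)
      mark(idx[seq_len(length(idx) - 2L)], idx[seq_len(length(idx) - 2L) + 2L])
  }
  m
}

#' Rupture force of a pulling trace
#'
#' The rupture force is the maximum of the lightly smoothed force trace,
#' validated by requiring that all inter-molecular contacts are broken and
#' the force stays below `frac` of the peak after it. Traces that never
#' rupture are flagged so the caller can extend the simulation.
#'
#' @param trace a `pull_trace`.
#' @param frac post-rupture force ceiling as a fraction of the peak.
#' @param smooth_window running-mean window (samples).
#' @return list with `f_max`, `t_max`, `ruptured` and `multi_peak`.
#' @export
detect_rupture <- function(trace, frac = 0.1, smooth_window = 5) {
  stopifnot(inherits(trace, "pull_trace") || is.data.frame(trace))
  f <- trace$F
  if (smooth_window > 1 && length(f) > smooth_window)
    f <- stats::filter(f, rep(1 / smooth_window, smooth_window), sides = 2)
  f[is.na(f)] <- trace$F[is.na(f)]
  imax <- which.max(f)
  f_max <- f[imax]
  tail_ok <- length(f) > imax &&
    all(f[seq(imax + max(3L, length(f) %/% 20), length(f))] < frac * f_max)
  contacts_gone <- if ("n_intact" %in% names(trace))
    trace$n_intact[length(f)] == 0 else TRUE
  ruptured <- isTRUE(tail_ok) && contacts_gone
  above <- f > 0.6 * f_max
  runs <- rle(as.vector(above))
  multi_peak <- sum(runs$values) >= 2
  list(f_max = as.numeric(f_max), t_max = trace$t[imax],
       ruptured = ruptured, multi_peak = multi_peak)
}

#' Dynamic force spectroscopy of contact-deletion constructs
#'
#' Orchestrates the full simulation protocol: for each construct (a contact
#' map, typically nested deletions of the wild-type interface) and each
#' pulling speed, runs `n` replicate pulling simulations, averages the
#' per-trajectory rupture forces, fits the Bell-Evans model per construct,
#' and regresses the fitted x_beta on log10(k_off tau) across constructs.
#'
#' @param structure a `cg_structure`.
#' @param constructs named list of `contact_map`s.
#' @param speeds pulling speeds, A per time unit (>= 3).
#' @param n replicates per (construct, speed).
#' @param fixed_bead,moving_bead pulled bead indices.
#' @param kappa pulling-spring stiffness, kBT/A^2.
#' @param pull_distance anchor travel per run, A.
#' @param seed integer seed; replicate seeds are derived from it.
#' @param build_args list of arguments forwarded to [build_model()]
#'   (e.g. `epsilon`).
#' @param ... further arguments passed to [run_pulling()].
#' @return Object of class `cg_force_spectrum`: `table` (per construct x
#'   speed: mean and SEM of F_max, rupture fraction), `fits` (per-construct
#'   `bell_evans_fit`), and `relation` (the x_beta vs log10 k_off
#'   `xbeta_relation_fit`, NULL with < 2 identifiable constructs).
#' @export
cg_force_spectrum <- function(structure, constructs, speeds, n = 20,
                              fixed_bead, moving_bead, kappa = 0.12,
                              pull_distance = 40, seed = 1,
                              build_args = list(), ...) {
  stopifnot(length(speeds) >= 3, length(constructs) >= 1, n >= 2)
  if (is.null(names(constructs)))
    names(constructs) <- paste0("construct", seq_along(constructs))
  rows <- list(); fits <- list()
  rep_seed <- seed
  for (cn in names(constructs)) {
    topo <- do.call(build_model,
                    c(list(structure, constructs[[cn]]), build_args))
    means <- sems <- rupt <- numeric(length(speeds))
    for (si in seq_along(speeds)) {
      fm <- numeric(n); ok <- logical(n)
      for (r in seq_len(n)) {
        rep_seed <- rep_seed + 1L
        tr <- run_pulling(topo, v = speeds[si], fixed_bead = fixed_bead,
                          moving_bead = moving_bead, kappa = kappa,
                          pull_distance = pull_distance, seed = rep_seed, ...)
        det <- detect_rupture(tr)
        fm[r] <- det$f_max; ok[r] <- det$ruptured
      }
      means[si] <- mean(fm); sems[si] <- stats::sd(fm) / sqrt(n)
      rupt[si] <- mean(ok)
    }
    rows[[cn]] <- data.frame(construct = cn, v = speeds, f_max_mean = means,
                             f_max_sem = sems, rupture_fraction = rupt, n = n)
    fits[[cn]] <- fit_bell_evans(speeds, means, sems, kappa = kappa)
  }
  tab <- do.call(rbind, rows)
  idf <- Filter(function(f) isTRUE(f$identifiable) && is.finite(f$k_off_tau) &&
                  f$k_off_tau > 0, fits)
  relation <- NULL
  if (length(idf) >= 2) {
    relation <- fit_xbeta_relation(vapply(idf, `[[`, 0, "k_off_tau"),
                                   vapply(idf, `[[`, 0, "x_beta"),
                                   argument = "k_off")
  }
  base::structure(list(table = tab, fits = fits, relation = relation),
            class = "cg_force_spectrum")
}

#' @export
print.cg_force_spectrum <- function(x, ...) {
  cat("Coarse-grained dynamic force spectroscopy\n")
  print(x$table, row.names = FALSE, digits = 4)
  for (cn in names(x$fits)) {
    f <- x$fits[[cn]]
    if (isTRUE(f$identifiable))
      cat(sprintf("  %s: k_off = %.3g /tau, x_beta = %.3g A\n",
                  cn, f$k_off_tau, f$x_beta))
  }
  if (!is.null(x$relation))
    cat(sprintf("  x_beta vs log10(k_off tau): slope = %+.4g (SE %.3g)\n",
                x$relation$slope, x$relation$se_slope))
  invisible(x)
}
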