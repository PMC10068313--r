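#' Configuration for the synthetic flow-chamber assay
#'
#' Parameters of the generative model that emulates a laminar-flow-chamber
#' bead-arrest experiment with known ground truth: specific arrests draw
#' their lifetime from a mixture of a Bell-model exponential (rate set by
#' the bond parameters and the bin force) and a slowly-decaying plateau
#' subpopulation; non-specific arrests are short exponential events present
#' on sample and control surfaces alike; counts scale with ligand density
#' and travelled distance; durations are frame-quantized and censored at
#' the movie end.
#'
#' @param k0_off,x_beta_nm true zero-force off-rate (1/s) and force
#'   sensitivity (nm) of the specific bond.
#' @param plateau_fraction fraction of specific arrests in the long-lived
#'   plateau subpopulation.
#' @param plateau_rate off-rate of the plateau subpopulation, 1/s (slow but
#'   finite so censoring behaves realistically).
#' @param nonspecific_rate off-rate of non-specific arrests, 1/s.
#' @param specific_bld specific arrests per mm travelled at unit density.
#' @param nonspecific_bld non-specific arrests per mm travelled.
#' @param binding_midpoint,binding_scale logistic decrease of binding
#'   probability with velocity (um/s): fast beads have too short an
#'   encounter time to bind. Affects arrest counts only, never lifetimes.
#' @param densities relative pMHC surface densities to simulate.
#' @param velocities nominal bead velocity per bin, um/s.
#' @param n_beads beads tracked per velocity condition (scalar, or one
#'   value per velocity: slow conditions are often recorded with more
#'   beads to balance event counts across bins).
#' @param movie_length_s,fps movie duration and frame rate.
#' @param bead a [bead_model()] used to map velocity to force.
#' @param temp a [temp_context()].
#' @param ligand label written to the output table.
#' @return list of class `lfc_sim_config`.
#' @export
lfc_sim_config <- function(k0_off = 0.29, x_beta_nm = 0.3,
                           plateau_fraction = 0.1, plateau_rate = 0.02,
                           nonspecific_rate = 2,
                           specific_bld = 0.55, nonspecific_bld = 0.1,
                           binding_midpoint = 150, binding_scale = 30,
                           densities = 1,
                           velocities = c(6, 15, 30, 50, 70, 100),
                           n_beads = 200, movie_length_s = 90, fps = 50,
                           bead = bead_model(), temp = temp_context(),
                           ligand = "synthetic") {
  stopifnot(k0_off > 0, plateau_rate > 0, nonspecific_rate > 0,
            plateau_fraction >= 0, plateau_fraction <= 1,
            all(densities > 0), all(velocities > 0), n_beads > 0,
            movie_length_s > 0, fps > 0)
  structure(as.list(environment()), class = "lfc_sim_config")
}

# frame-quantize durations (nearest frame); sub-half-frame arrests are
# unresolvable and dropped by the caller
.quantize <- function(d, fps) round(d * fps) / fps

#' Simulate a flow-chamber arrest table
#'
#' Draws a full synthetic assay under an [lfc_sim_config()]: for every
#' (density, velocity) condition the bond force follows from the chamber
#' hydrodynamics, specific lifetimes are exponential at the Bell rate with a
#' plateau admixture, non-specific lifetimes are fast-exponential, counts
#' are Poisson with means proportional to density, travelled distance and
#' the velocity-dependent binding probability. A paired no-pMHC control
#' table is generated from the non-specific process alone. Output is
#' reproducible: a given (config, seed) always yields the same tables.
#'
#' @param config an [lfc_sim_config()].
#' @param seed integer seed.
#' @return list with `events` (specific-surface arrests: `duration_s`,
#'   `velocity_um_s`, `condition`, `ligand`, `density_label`,
#'   `experiment_id`, `censored`), `controls` (no-pMHC surface),
#'   `summaries` (per condition: `n_arrests`, `total_distance_mm`) and
#'   `truth` (per-bin force and Bell rate plus all generator parameters).
#' @export
simulate_arrest_table <- function(config = lfc_sim_config(), seed = 1) {
  stopifnot(inherits(config, "lfc_sim_config"))
  set.seed(seed)
  cfg <- config
  ev <- list(); ct <- list(); sm <- list()
  truth_bins <- list()
  n_beads <- rep_len(cfg$n_beads, length(cfg$velocities))
  exp_id <- 0L
  for (dens in cfg$densities) {
    exp_id <- exp_id + 1L
    for (vi in seq_along(cfg$velocities)) {
      v <- cfg$velocities[vi]
      force <- force_for_velocity_bin(v, cfg$bead)
      k_bell <- membrane_off_rate(cfg$k0_off, cfg$x_beta_nm, force, cfg$temp)
      dist_mm <- n_beads[vi] * v * cfg$movie_length_s / 1000
      p_bind <- 1 / (1 + exp((v - cfg$binding_midpoint) / cfg$binding_scale))
      n_spec <- stats::rpois(1, cfg$specific_bld * dens * p_bind * dist_mm)
      n_ns_sample <- stats::rpois(1, cfg$nonspecific_bld * dist_mm)
      n_ns_ctrl <- stats::rpois(1, cfg$nonspecific_bld * dist_mm)

      draw <- function(n, rates, weights = 1) {
        if (n == 0L) return(numeric(0))
        comp <- sample.int(length(rates), n, replace = TRUE, prob = weights)
        stats::rexp(n, rates[comp])
      }
      d_spec <- draw(n_spec, c(k_bell, cfg$plateau_rate),
                     c(1 - cfg$plateau_fraction, cfg$plateau_fraction))
      d_ns_s <- draw(n_ns_sample, cfg$nonspecific_rate)
      d_ns_c <- draw(n_ns_ctrl, cfg$nonspecific_rate)

      finish <- function(d, cond) {
        cens <- d > cfg$movie_length_s
        d <- .quantize(pmin(d, cfg$movie_length_s), cfg$fps)
        keep <- d > 0
        n <- sum(keep)
        if (n == 0L) return(NULL)
        vel <- stats::rnorm(n, v, 0.05 * v)
        data.frame(duration_s = d[keep],
                   velocity_um_s = pmin(pmax(vel, 0.8 * v), 1.2 * v),
                   condition = cond, ligand = cfg$ligand,
                   density_label = as.character(dens),
                   experiment_id = exp_id, censored = cens[keep])
      }
      ev[[length(ev) + 1L]] <- rbind(finish(d_spec, "specific"),
                                     finish(d_ns_s, "specific"))
      ct[[length(ct) + 1L]] <- finish(d_ns_c, "no_pMHC")
      sm[[length(sm) + 1L]] <- data.frame(
        experiment_id = exp_id, density_label = as.character(dens),
        velocity_um_s = v, n_arrests = n_spec + n_ns_sample,
        n_arrests_control = n_ns_ctrl, total_distance_mm = dist_mm)
      if (dens == cfg$densities[1L]) {
        truth_bins[[length(truth_bins) + 1L]] <-
          data.frame(velocity_um_s = v, force_pN = force, k_bell = k_bell)
      }
    }
  }
  list(events = do.call(rbind, ev),
       controls = do.call(rbind, ct),
       summaries = do.call(rbind, sm),
       truth = list(k0_off = cfg$k0_off, x_beta_nm = cfg$x_beta_nm,
                    plateau_fraction = cfg$plateau_fraction,
                    plateau_rate = cfg$plateau_rate,
                    nonspecific_rate = cfg$nonspecific_rate,
                    bins = do.call(rbind, truth_bins), seed = seed))
}

#' Simulate a Langmuir binding isotherm
#'
#' `B = Bmax * C / (KD + C)` plus i.i.d. Gaussian noise.
#'
#' @param KD_uM dissociation constant, uM.
#' @param Bmax maximal response, RU.
#' @param concentrations_uM analyte concentrations, uM.
#' @param noise_sd response noise SD, RU.
#' @param seed integer seed.
#' @return data.frame with `conc_uM`, `response_RU`.
#' @export
simulate_isotherm <- function(KD_uM, Bmax, concentrations_uM,
                              noise_sd = 0, seed = 1) {
  stopifnot(KD_uM > 0, Bmax > 0, all(concentrations_uM >= 0))
  set.seed(seed)
  b <- Bmax * concentrations_uM / (KD_uM + concentrations_uM)
  data.frame(conc_uM = concentrations_uM,
             response_RU = b + stats::rnorm(length(b), 0, noise_sd))
}

#' Simulate a mono-exponential dissociation trace
#'
#' `R(t) = R0 * exp(-k_off t)` plus Gaussian noise, sampled at `fps` Hz.
#'
#' @param koff off-rate, 1/s (0 allowed: flat trace).
#' @param R0 initial response, RU.
#' @param fps sampling rate, Hz.
#' @param duration_s trace length, s.
#' @param noise_sd noise SD, RU.
#' @param seed integer seed.
#' @return data.frame with `t_s`, `response_RU`.
#' @export
simulate_dissociation_trace <- function(koff, R0, fps = 100, duration_s = 5,
                                        noise_sd = 0, seed = 1) {
  stopifnot(koff >= 0, R0 > 0, fps > 0, duration_s > 0)
  set.seed(seed)
  t <- seq(0, duration_s, by = 1 / fps)
  data.frame(t_s = t,
             response_RU = R0 * exp(-koff * t) + stats::rnorm(length(t), 0, noise_sd))
}

#' Simulate a potency-vs-affinity dataset from the proofreading model
#'
#' Forward model: log-potency `P = lambda + N log10(1 + k_off_m(F)/k_p)`
#' per condition, with Gaussian noise on the log scale. Ground truth for
#' [fit_potency()] recovery tests.
#'
#' @param conditions data.frame with columns `condition`, `F_pN`, `lambda`.
#' @param KD_uM antigen dissociation constants, uM.
#' @param params a [kp_params()] (N, k_p, k_on, x_beta relation, kBT).
#' @param noise_sd SD of the noise on log10 potency.
#' @param seed integer seed.
#' @return data.frame with `condition`, `ligand`, `KD_uM`, `logP_obs`,
#'   `sem`.
#' @export
simulate_potency_dataset <- function(conditions, KD_uM, params = kp_params(),
                                     noise_sd = 0.1, seed = 1) {
  stopifnot(all(c("condition", "F_pN", "lambda") %in% names(conditions)),
            all(KD_uM > 0))
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(conditions))) {
    lp <- potency_linearized(KD_uM, params, force = conditions$F_pN[i],
                             lambda = conditions$lambda[i])
    out[[i]] <- data.frame(
      condition = conditions$condition[i],
      ligand = paste0("L", seq_along(KD_uM)),
      KD_uM = KD_uM,
      logP_obs = lp + stats::rnorm(length(lp), 0, noise_sd),
      sem = noise_sd)
  }
  do.call(rbind, out)
}

#' Build a toy two-chain complex with a planted interface
#'
#' Two antiparallel chains of residue beads, 3.8 A backbone spacing, running
#' side by side along z. Residues listed in `interface` sit 5 A apart across
#' the interface (in contact); all other residue pairs are bulged out to
#' > 8 A so a distance criterion recovers exactly the planted pairs. The
#' antiparallel arrangement puts the two C-termini at opposite ends of the
#' complex, giving a shear-loading pulling geometry. Coordinates receive a
#' small seeded jitter to avoid exact symmetries.
#'
#' @param n_res_per_chain residues per chain.
#' @param interface indices (along chain A) of residues in contact with the
#'   spatially facing residue of chain B.
#' @param jitter_sd coordinate jitter, A.
#' @param seed integer seed.
#' @param pdb_file optional path; when given the complex is also written as
#'   a minimal PDB file (CA atoms only).
#' @return list with `structure` (a `cg_structure`), `contacts`
#'   (data.frame `i`, `j` of planted bead pairs, global bead indexing) and
#'   `pdb_file`.
#' @export
make_toy_complex <- function(n_res_per_chain = 15,
                             interface = 4:11,
                             jitter_sd = 0.1, seed = 1,
                             pdb_file = NULL) {
  stopifnot(n_res_per_chain >= 4, all(interface >= 1),
            all(interface <= n_res_per_chain))
  set.seed(seed)
  n <- n_res_per_chain
  spacing <- 3.8; gap <- 5; bulge <- 9
  z <- (seq_len(n) - 1) * spacing
  # chain A along +z at x = 0; chain B antiparallel (resno 1 at top)
  xa <- rep(0, n)
  # chain B residue j faces chain A residue (n + 1 - j)
  xb <- ifelse((n + 1 - seq_len(n)) %in% interface, gap, bulge)
  xyz <- rbind(cbind(xa, 0, z),
               cbind(xb, 0, rev(z)))
  xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter_sd), ncol = 3)
  chain <- rep(c("A", "B"), each = n)
  resno <- c(seq_len(n), seq_len(n))
  structure_obj <- cg_structure(xyz, chain = chain, resno = resno)
  contacts <- data.frame(i = interface, j = n + (n + 1 - interface))
  if (!is.null(pdb_file)) write_ca_pdb(structure_obj, pdb_file)
  list(structure = structure_obj, contacts = contacts[order(contacts$i), ],
       pdb_file = pdb_file)
}
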