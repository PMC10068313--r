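toy <- make_toy_complex(seed = 1)
toy_cm <- native_contacts(toy$structure, method = "cutoff", cutoff = 6)

test_that("toy complex round-trips through PDB", {
  path <- tempfile(fileext = ".pdb")
  write_ca_pdb(toy$structure, path)
  st <- load_structure(path)
  expect_identical(nrow(st$xyz), nrow(toy$structure$xyz))
  expect_equal(unname(st$xyz), unname(toy$structure$xyz), tolerance = 1e-3)
  expect_identical(sort(unique(st$chain)), c("A", "B"))
  # contact map identical after the round trip
  cm2 <- native_contacts(st, method = "cutoff", cutoff = 6)
  expect_identical(cm2$i, toy_cm$i)
  expect_identical(cm2$j, toy_cm$j)
  expect_error(load_structure(path, chain_map = c(Z = "MHC")), "absent")
  expect_error(load_structure(tempfile()), "not found")
})

test_that("altloc duplicates resolve to the highest occupancy", {
  pdb <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BGLY A   1       5.000   0.000   0.000  0.70  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   1.000  1.00  0.00           C",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  st <- load_structure(path)
  expect_identical(nrow(st$xyz), 2L)
  expect_equal(st$xyz[1, 1], 5.0)  # occupancy 0.70 conformer kept
})

test_that("native-contact detection excludes sequential neighbours", {
  # a hairpin: residues 1 and 3 close in space but (i, i+2); 1 and 4 kept
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 2), c(2.0, 0, 3), c(1.0, 0, 3.9),
               c(20, 0, 0))
  st <- cg_structure(xyz, chain = rep("A", 5), resno = 1:5)
  cm <- native_contacts(st, method = "cutoff", cutoff = 5)
  expect_false(any(cm$resno_i == 1 & cm$resno_j == 3))
  expect_true(any(cm$resno_i == 1 & cm$resno_j == 4))
  # residues 20 A apart are never in contact
  expect_false(any(cm$resno_j == 5))
  # overlap criterion on CA-only data: threshold 1.24 * (1.7 + 1.7) = 4.216 A
  cm_ov <- native_contacts(st, method = "overlap")
  expect_true(all(cm_ov$r0 < 1.24 * 3.4))
  expect_true(any(cm_ov$resno_i == 1 & cm_ov$resno_j == 4))
})

test_that("construct deletions remove exactly the requested contacts", {
  full <- toy_cm
  n_inter <- sum(full$class == "inter")
  # deleting nothing
  same <- delete_contacts(full, "A", "B", resno_a = integer(0))
  expect_identical(nrow(same), nrow(full))
  # full interface removal: no A-B pairs left, intra untouched
  none <- delete_contacts(full, "A", "B")
  expect_identical(sum(none$class == "inter"), 0L)
  expect_identical(sum(none$class == "intra"), sum(full$class == "intra"))
  # targeted range: exactly the A-residues 4-8 contacts disappear
  part <- delete_contacts(full, "A", "B", resno_a = 4:8)
  gone <- setdiff(paste(full$i, full$j), paste(part$i, part$j))
  expected_gone <- with(full[full$class == "inter" & full$resno_i %in% 4:8, ],
                        paste(i, j))
  expect_setequal(gone, expected_gone)
})

test_that("the native configuration is stationary", {
  topo <- build_model(toy$structure, toy_cm)
  g <- cg_energy(topo)
  expect_lt(max(abs(g$gradient)), 0.1)   # kBT/A: small vs thermal forces
  # backbone springs and LJ wells are exactly at their minima
  b <- topo$bonds
  d <- sqrt(rowSums((topo$xyz0[b$i, ] - topo$xyz0[b$j, ])^2))
  expect_equal(d, b$r0, tolerance = 1e-12)
})

test_that("pulling simulations are deterministic and well-behaved at v = 0", {
  topo <- build_model(toy$structure, toy_cm, epsilon = 6)
  fx <- chain_cterm(toy$structure, "A"); mv <- chain_cterm(toy$structure, "B")
  t1 <- run_pulling(topo, v = 0.05, fixed_bead = fx, moving_bead = mv,
                    pull_distance = 10, seed = 9)
  t2 <- run_pulling(topo, v = 0.05, fixed_bead = fx, moving_bead = mv,
                    pull_distance = 10, seed = 9)
  expect_identical(t1$F, t2$F)
  t3 <- run_pulling(topo, v = 0.05, fixed_bead = fx, moving_bead = mv,
                    pull_distance = 10, seed = 10)
  expect_false(identical(t1$F, t3$F))
  # no ramp without pulling: |mean F| below 3 thermal SD
  t0 <- run_pulling(topo, v = 0, fixed_bead = fx, moving_bead = mv,
                    pull_distance = 1500, seed = 11)
  expect_lt(abs(mean(t0$F)), 3 * sd(t0$F))
})

test_that("energy is conserved in the zero-friction zero-noise limit", {
  topo <- build_model(toy$structure, toy_cm)
  # perturb the native state to inject potential energy, then integrate
  # the deterministic (velocity Verlet) limit of the Langevin scheme
  set.seed(18)
  topo$xyz0 <- topo$xyz0 + matrix(rnorm(length(topo$xyz0), 0, 0.1),
                                  ncol = 3)
  fx <- chain_cterm(toy$structure, "A"); mv <- chain_cterm(toy$structure, "B")
  dt <- 0.05 * sqrt(1 / topo$k_max)
  tr <- run_pulling(topo, v = 0, fixed_bead = fx, moving_bead = mv,
                    pull_distance = 1e5 * dt, seed = 1, mode = "langevin",
                    gamma = 0, kBT = 0, dt = dt, stride = 100)
  e <- attr(tr, "energy")
  e0 <- e[1]
  # the perturbation stored meaningful energy above the native minimum
  e_native <- cg_energy(build_model(toy$structure, toy_cm))$energy
  scale <- e0 - e_native
  expect_gt(scale, 0.5)
  # no secular drift over 1e5 velocity-Verlet steps
  drift <- abs(mean(utils::tail(e, 50)) - mean(utils::head(e, 50)))
  expect_lt(drift / scale, 1e-3)
  # bounded fluctuation around the conserved value
  expect_lt(max(abs(e - e0)) / scale, 0.02)
})

test_that("rupture detection reads synthetic traces correctly", {
  mk <- function(F, n_intact) {
    out <- data.frame(t = seq_along(F), F = F, n_intact = n_intact)
    class(out) <- c("pull_trace", "data.frame")
    out
  }
  ramp <- mk(c(seq(0, 12, length.out = 60), rep(0, 60)),
             c(rep(1L, 60), rep(0L, 60)))
  det <- detect_rupture(ramp, smooth_window = 1)
  expect_equal(det$f_max, 12)
  expect_true(det$ruptured)
  expect_false(det$multi_peak)
  # two-peak trace: global maximum returned, flagged
  two <- mk(c(seq(0, 8, length.out = 40), seq(8, 2, length.out = 20),
              seq(2, 12, length.out = 40), rep(0, 60)),
            c(rep(1L, 100), rep(0L, 60)))
  det2 <- detect_rupture(two, smooth_window = 1)
  expect_equal(det2$f_max, 12)
  expect_true(det2$multi_peak)
  # no rupture: flagged for extension
  unr <- mk(seq(0, 12, length.out = 100), rep(1L, 100))
  expect_false(detect_rupture(unr, smooth_window = 1)$ruptured)
})

test_that("single-bond rupture force matches a Kramers escape-rate oracle", {
  eps <- 8; r0 <- 5; kap <- 0.12; kBT <- 1
  beta <- 1; D <- 2        # relative-coordinate diffusion, both beads mobile
  kser <- kap / 2          # the two pulling springs load the bond in series
  st <- cg_structure(rbind(c(0, 0, 0), c(r0, 0, 0)),
                     chain = c("A", "B"), resno = c(1, 1))
  topo <- build_model(st, native_contacts(st, method = "cutoff", cutoff = 6),
                      epsilon = eps)
  rupture_force <- function(tr, w = 25) {
    f <- stats::filter(tr$F, rep(1 / w, w), sides = 2)
    i <- which(tr$n_intact == 0)[1]
    if (is.na(i) || i < w) return(NA_real_)
    max(f[seq_len(i)], na.rm = TRUE)
  }
  sim_mean <- function(v, n = 25, seed0 = 100) {
    fr <- vapply(seq_len(n), function(r)
      rupture_force(run_pulling(topo, v = v, fixed_bead = 1L, moving_bead = 2L,
                                kappa = kap, pull_distance = 30,
                                seed = seed0 + r)), 0)
    mean(fr, na.rm = TRUE)
  }
  U <- function(x, d) eps * ((r0 / x)^12 - 2 * (r0 / x)^6) +
    0.5 * kser * (x - d)^2
  rate_and_force <- function(d) {
    grw <- seq(3.8, 8, length.out = 400)
    uw <- U(grw, d); iw <- which.min(uw); xw <- grw[iw]; uwv <- uw[iw]
    f <- kser * (d - xw)
    grb <- seq(xw + 0.05, xw + 25, length.out = 2000)
    ub <- U(grb, d)
    loc <- which(diff(sign(diff(ub))) == -2) + 1L
    if (!length(loc)) {
      if (ub[length(ub)] > uwv) return(c(k = 0, f = f))  # confined
      return(c(k = 50, f = f))                           # barrier gone
    }
    xb <- grb[loc[1L]]
    if (ub[loc[1L]] - uwv < 0.3) return(c(k = 50, f = f))
    inner <- function(y) sapply(y, function(yy)
      integrate(function(x) exp(-beta * (U(x, d) - uwv)), 3.8, yy,
                rel.tol = 1e-7)$value)
    mfpt <- integrate(function(y) exp(beta * (U(y, d) - uwv)) * inner(y),
                      xw, xb + 1, subdivisions = 600, rel.tol = 1e-6)$value / D
    c(k = 1 / mfpt, f = f)
  }
  oracle_mean <- function(v) {
    t <- seq(0, 30 / v, length.out = 600); dt <- t[2] - t[1]
    kf <- t(vapply(r0 + v * t, rate_and_force, c(k = 0, f = 0)))
    S <- exp(-cumsum(kf[, "k"] * dt))
    pd <- -diff(c(1, S))
    sum(kf[, "f"] * pd) + kf[length(t), "f"] * S[length(t)]
  }
  for (v in c(0.02, 0.05)) {
    expect_lt(abs(sim_mean(v) / oracle_mean(v) - 1), 0.15)
  }
})
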