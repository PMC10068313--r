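#' Standard velocity bins for flow-chamber arrest analysis
#'
#' Half-open bins `[lo, hi)` in um/s used to pool experiments with small
#' velocity variations; events outside `[2, 120)` um/s are discarded.
#'
#' @return data.frame with columns `lo`, `hi`.
#' @export
velocity_bins <- function() {
  data.frame(lo = c(2, 10, 20, 40, 60, 80),
             hi = c(10, 20, 40, 60, 80, 120))
}

# bin index for each velocity (NA outside range); half-open [lo, hi)
.assign_bin <- function(v, bins = velocity_bins()) {
  idx <- rep(NA_integer_, length(v))
  for (i in seq_len(nrow(bins))) {
    idx[v >= bins$lo[i] & v < bins$hi[i]] <- i
  }
  idx
}

#' Detect bead arrests in a position trace
#'
#' An arrest is a maximal run of frames whose instantaneous speed falls below
#' a velocity threshold; its duration is the run length times the frame
#' interval. The bead transport velocity is the median speed outside arrests.
#'
#' @param positions bead x-positions in um, uniformly sampled.
#' @param velocity_threshold speed below which a frame counts as arrested,
#'   um/s.
#' @param fps frame rate, frames/s.
#' @return data.frame with columns `start_s`, `duration_s`, `bead_velocity`
#'   (one row per arrest; zero rows if fewer than 2 frames or no arrest).
#' @export
detect_arrests <- function(positions, velocity_threshold, fps = 50) {
  empty <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                      bead_velocity = numeric(0))
  if (length(positions) < 2L) return(empty)
  speed <- abs(diff(positions)) * fps
  below <- speed < velocity_threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty)
  v_out <- if (all(below)) NA_real_ else stats::median(speed[!below])
  data.frame(start_s = (starts[keep] - 1L) / fps,
             duration_s = r$lengths[keep] / fps,
             bead_velocity = v_out)
}

#' Binding linear density with geometric summary statistics
#'
#' Per-experiment BLD is the number of arrests divided by the total distance
#' travelled by sedimented beads; across experiments the aggregate is the
#' geometric mean with a multiplicative geometric SEM factor
#' `exp(sd(log BLD)/sqrt(n))`.
#'
#' @param n_arrests arrest counts per experiment.
#' @param distance_mm distance travelled per experiment, mm (> 0).
#' @return list with `bld` (per experiment, arrests/mm), `geo_mean`,
#'   `geo_sem_factor` (NA for a single experiment) and `n`.
#' @export
binding_linear_density <- function(n_arrests, distance_mm) {
  if (length(n_arrests) != length(distance_mm)) stop("length mismatch")
  if (length(n_arrests) < 1L) stop("need at least one experiment")
  if (any(distance_mm <= 0)) stop("distance must be positive")
  if (any(n_arrests < 0)) stop("arrest counts must be non-negative")
  bld <- n_arrests / distance_mm
  lb <- log(bld[bld > 0])
  n <- length(lb)
  geo_mean <- if (n > 0) exp(mean(lb)) else 0
  geo_sem <- if (n > 1) exp(stats::sd(lb) / sqrt(n)) else NA_real_
  list(bld = bld, geo_mean = geo_mean, geo_sem_factor = geo_sem, n = length(bld))
}

#' Specificity filter on per-bin BLD fold-changes
#'
#' For each velocity bin, computes the fold-change of sample over control
#' BLD across paired experiments and drops bins whose lower error bound
#' (geometric mean divided by the geometric SEM factor; `mode =
#' "subtract"` uses geo mean minus additive geo SEM instead) is below 1 --
#' arrests in such bins are mostly non-specific.
#'
#' @param sample_bld,control_bld numeric vectors of per-experiment BLD.
#' @param bin integer bin index parallel to the BLD vectors.
#' @param mode how "geo mean - geo SEM" is interpreted: `"divide"` (default,
#'   multiplicative error bars) or `"subtract"`.
#' @return data.frame with one row per bin: `bin`, `n`, `fold_geo_mean`,
#'   `lower`, `retained`. Bins lacking control data are dropped with a
#'   warning.
#' @export
specificity_filter <- function(sample_bld, control_bld, bin,
                               mode = c("divide", "subtract")) {
  mode <- match.arg(mode)
  stopifnot(length(sample_bld) == length(bin))
  if (length(control_bld) != length(sample_bld))
    stop("sample and control BLD must be paired per experiment")
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- which(bin == b)
    ctl <- control_bld[i]
    if (all(is.na(ctl)) || all(ctl <= 0, na.rm = TRUE)) {
      warning(sprintf("bin %s dropped: no usable control BLD", b))
      return(NULL)
    }
    ok <- !is.na(ctl) & ctl > 0 & sample_bld[i] > 0
    folds <- sample_bld[i][ok] / ctl[ok]
    if (length(folds) == 0L) {
      warning(sprintf("bin %s dropped: no usable fold-changes", b))
      return(NULL)
    }
    lf <- log(folds)
    gm <- exp(mean(lf))
    sem <- if (length(lf) > 1) exp(stats::sd(lf) / sqrt(length(lf))) else 1
    lower <- if (mode == "divide") gm / sem else gm - (gm * sem - gm)
    data.frame(bin = b, n = length(folds), fold_geo_mean = gm,
               lower = lower, retained = lower >= 1)
  }))
  out
}

#' Empirical survival curve of arrest durations
#'
#' For each time point with at least one recorded event, the survival
#' fraction `s(t) = P(duration >= t)` is computed on the sorted set of
#' observed durations; `s(0) = 1` by construction and the curve is a
#' non-increasing step function in `[0, 1]`.
#'
#' @param durations arrest durations, s (>= 1 event).
#' @return Object of class `survival_curve` with `times`, `survival`,
#'   `n_events` and the raw `durations`.
#' @export
empirical_survival <- function(durations) {
  if (length(durations) < 1L) stop("need at least one duration")
  if (any(durations < 0)) stop("durations must be non-negative")
  tab <- table(durations)
  times <- as.numeric(names(tab))
  n <- length(durations)
  at_least <- rev(cumsum(rev(as.integer(tab))))  # count of durations >= t
  structure(list(times = times, survival = at_least / n, n_events = n,
                 durations = durations, corrected = FALSE),
            class = "survival_curve")
}

#' Evaluate a survival curve at arbitrary times
#'
#' `s(t) = P(duration >= t)`, left-continuous between event times.
#'
#' @param curve a `survival_curve`.
#' @param t times at which to evaluate.
#' @return survival fractions.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  # s(t) equals the survival value at the first event time >= t
  # (1 before the first event, 0 past the last)
  vapply(t, function(ti) {
    j <- which(curve$times >= ti)
    if (length(j) == 0L) 0 else curve$survival[j[1L]]
  }, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: %d events, %d time points, s in [%.3f, 1]%s\n",
              x$n_events, length(x$times), min(x$survival),
              if (isTRUE(x$corrected)) ", corrected for non-specific binding" else ""))
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, ..., xlab = "time (s)", ylab = "survival fraction") {
  graphics::plot(stats::stepfun(x$times, c(1, x$survival)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, main = "", ...)
  invisible(x)
}

#' Correct a survival curve for non-specific arrests
#'
#' Treats the sample as a mixture of specific and non-specific arrests with
#' mixture weights proportional to arrest counts per unit distance (BLD):
#' `s_corr(t) = (w_s s_s(t) - w_c s_c(t)) / (w_s - w_c)`, clipped to
#' `[0, 1]`. The unweighted mode subtracts the control survival pointwise.
#' Refused when the control weight reaches the sample weight (the bin is
#' fully non-specific).
#'
#' @param sample,control `survival_curve` objects from the same velocity bin.
#' @param w_sample,w_control arrest counts per unit distance for sample and
#'   control. Defaults to raw event counts (equal distances).
#' @param mode `"weighted"` (default) or `"unweighted"`.
#' @return a corrected `survival_curve` on the sample's time grid (raw sample
#'   durations retained for QC).
#' @export
correct_nonspecific <- function(sample, control,
                                w_sample = sample$n_events,
                                w_control = control$n_events,
                                mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "survival_curve"), inherits(control, "survival_curve"))
  s_c <- vapply(sample$times, function(t) mean(control$durations >= t), 0)
  if (mode == "weighted") {
    if (w_control >= w_sample)
      stop("control weight >= sample weight: bin is fully non-specific, correction refused")
    s <- (w_sample * sample$survival - w_control * s_c) / (w_sample - w_control)
  } else {
    s <- sample$survival - s_c
  }
  s <- pmin(pmax(s, 0), 1)
  structure(list(times = sample$times, survival = s, n_events = sample$n_events,
                 durations = sample$durations, corrected = TRUE),
            class = "survival_curve")
}

#' Minimum-events quality filter
#'
#' A survival curve passes only if at least `min_events` arrest durations
#' fall in the half-open interval `(1 s, 2 s]` -- shorter-lived samples do
#' not constrain the 1-2 s survival fractions the off-rate estimators use.
#'
#' @param curve a `survival_curve` with raw durations attached.
#' @param min_events threshold count (default 15).
#' @return logical pass/fail.
#' @export
qc_min_events <- function(curve, min_events = 15) {
  stopifnot(inherits(curve, "survival_curve"))
  d <- curve$durations
  sum(d > 1 & d <= 2) >= min_events
}

#' Off-rate from the survival fraction at a fixed time
#'
#' `k_off = -ln(s(t)) / t` evaluated at the first event time at or after `t`
#' (the nominal `t`, 1 s or 2 s, stays in the denominator when the survival
#' value comes from a slightly later event). The SE is propagated from the
#' binomial error of the survival fraction.
#'
#' @param curve a `survival_curve`.
#' @param t evaluation time, s (1 or 2 in the standard analysis).
#' @return Object of class `off_rate_estimate` with `method`, `value`, `se`,
#'   `s_at_t`, `t_used`.
#' @export
off_rate_at_time <- function(curve, t = 1) {
  stopifnot(inherits(curve, "survival_curve"), length(t) == 1L, t > 0)
  idx <- which(curve$times >= t)
  if (length(idx) == 0L) stop("no event at or after t = ", t)
  i <- idx[1L]
  s <- curve$survival[i]
  if (s <= 0) stop("survival fraction is zero at t = ", t, ": off-rate undefined")
  value <- -log(s) / t
  se_s <- sqrt(s * (1 - s) / curve$n_events)
  structure(list(method = if (isTRUE(all.equal(t, 2))) "at_2s" else "at_1s",
                 value = value, se = se_s / (s * t),
                 s_at_t = s, t_used = curve$times[i]),
            class = "off_rate_estimate")
}

#' @export
print.off_rate_estimate <- function(x, ...) {
  cat(sprintf("Off-rate estimate (%s): %.4g 1/s (SE %.3g)\n", x$method, x$value,
              if (is.null(x$se) || is.na(x$se)) NA else x$se))
  if (!is.null(x$plateau)) cat(sprintf("  amplitude A = %.3f, plateau B = %.3f%s\n",
                                       x$amplitude, x$plateau,
                                       if (isTRUE(x$flagged)) " [flagged]" else ""))
  invisible(x)
}

#' One-phase exponential fit with baseline plateau
#'
#' Fits `s(t) = (A - B) exp(-k_off t) + B` to the survival points within the
#' first `window` seconds by nonlinear least squares with bounds
#' `0 <= B, A <= 1.05`, `k_off > 0`. The plateau B captures the long-lived
#' arrest subpopulation so that k_off reflects the dominant exponential
#' phase.
#'
#' @param curve a `survival_curve` (typically after non-specific correction).
#' @param window fit window, s (default 5: bead collisions corrupt longer
#'   timescales).
#' @param origin time origin of the exponential. `"zero"` fits the model
#'   exactly as written; `"first_event"` shifts the clock to the first
#'   observed event time, appropriate for frame-quantized data where the
#'   survival fraction is 1 by construction at the first resolvable frame
#'   (without the shift the amplitude absorbs a factor exp(k/fps), which
#'   collides with the A <= 1.05 bound at fast off-rates).
#' @return Object of class `off_rate_estimate` with `method = "exp_fit"`,
#'   `value` (k_off), `se`, `amplitude` (A), `plateau` (B), and a `flagged`
#'   field set when the fit did not converge or k_off sits on its boundary.
#' @export
fit_exponential_plateau <- function(curve, window = 5,
                                    origin = c("zero", "first_event")) {
  origin <- match.arg(origin)
  stopifnot(inherits(curve, "survival_curve"))
  keep <- curve$times <= window
  t <- curve$times[keep]; s <- curve$survival[keep]
  if (length(unique(t)) < 5L) stop("need >= 5 distinct time points within the window")
  if (origin == "first_event") t <- t - min(t)
  b0 <- max(min(s), 1e-3)
  k0 <- {
    half <- t[which(s <= (1 + b0) / 2)[1L]]
    if (is.na(half) || half <= 0) 1 else log(2) / half
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ (A - B) * exp(-k * t) + B,
                      start = list(A = 1, B = b0, k = k0),
                      lower = c(A = 0, B = 0, k = 1e-8),
                      upper = c(A = 1.05, B = 1.05, k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(method = "exp_fit", value = NA_real_, se = NA_real_,
                          amplitude = NA_real_, plateau = NA_real_,
                          flagged = TRUE, message = conditionMessage(fit)),
                     class = "off_rate_estimate"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["k"]], error = function(e) NA_real_)
  flagged <- cf[["k"]] <= 1e-6 || cf[["B"]] > cf[["A"]] ||
    (cf[["A"]] - cf[["B"]]) < 1e-3 ||  # no decaying phase: k non-identifiable
    !isTRUE(fit$convInfo$isConv %||% TRUE)
  structure(list(method = "exp_fit", value = cf[["k"]], se = se,
                 amplitude = cf[["A"]], plateau = cf[["B"]],
                 flagged = flagged, fit = fit),
            class = "off_rate_estimate")
}

#' Per-ligand force spectrum: from arrest events to a Bell fit
#'
#' The full analysis pipeline for one ligand: assign events to velocity
#' bins, convert bin-mean velocity to bond force, build the empirical
#' survival curve per bin, correct it with the paired no-pMHC control,
#' apply the minimum-events filter, estimate the off-rate with all three
#' estimators (survival at 1 s, at 2 s, exponential-plateau fit), and fit
#' Bell's model across the surviving bins for each estimator.
#'
#' @param events data.frame of specific arrests with columns `duration_s`
#'   and `velocity_um_s`.
#' @param controls optional data.frame of control (no-pMHC) arrests, same
#'   columns.
#' @param bead a [bead_model()] mapping velocity to force.
#' @param bins velocity bins, see [velocity_bins()].
#' @param sample_distance_mm,control_distance_mm total distances travelled
#'   (scalar or per bin) used to express correction weights as arrests per
#'   mm; equal distances by default.
#' @param min_events per-bin events required in (1 s, 2 s], see
#'   [qc_min_events()].
#' @param temp a [temp_context()].
#' @return Object of class `force_spectrum`: `table` (one row per bin with
#'   force, event counts, QC flag and the three estimates) and `bell`, a
#'   list of `bell_fit` objects per estimator (NULL when fewer than 3 bins
#'   survive).
#' @export
ligand_force_spectrum <- function(events, controls = NULL, bead = bead_model(),
                                  bins = velocity_bins(),
                                  sample_distance_mm = 1,
                                  control_distance_mm = 1,
                                  min_events = 15,
                                  temp = temp_context()) {
  stopifnot(all(c("duration_s", "velocity_um_s") %in% names(events)))
  ev_bin <- .assign_bin(events$velocity_um_s, bins)
  ct_bin <- if (is.null(controls)) integer(0) else .assign_bin(controls$velocity_um_s, bins)

  rows <- vector("list", nrow(bins))
  for (b in seq_len(nrow(bins))) {
    d <- events$duration_s[which(ev_bin == b)]
    if (length(d) == 0L) next
    v_mean <- mean(events$velocity_um_s[which(ev_bin == b)])
    force <- force_for_velocity_bin(v_mean, bead)
    curve <- empirical_survival(d)
    n_ctl <- 0L
    if (!is.null(controls)) {
      dc <- controls$duration_s[which(ct_bin == b)]
      n_ctl <- length(dc)
      if (n_ctl > 0L) {
        w_s <- length(d) / (if (length(sample_distance_mm) > 1) sample_distance_mm[b] else sample_distance_mm)
        w_c <- n_ctl / (if (length(control_distance_mm) > 1) control_distance_mm[b] else control_distance_mm)
        curve <- tryCatch(
          correct_nonspecific(curve, empirical_survival(dc), w_s, w_c),
          error = function(e) NULL)
        if (is.null(curve)) next  # fully non-specific bin
      }
    }
    qc <- qc_min_events(curve, min_events)
    est1 <- tryCatch(off_rate_at_time(curve, 1), error = function(e) NULL)
    est2 <- tryCatch(off_rate_at_time(curve, 2), error = function(e) NULL)
    este <- tryCatch(fit_exponential_plateau(curve, origin = "first_event"),
                     error = function(e) NULL)
    g <- function(e, fld = "value") if (is.null(e)) NA_real_ else e[[fld]]
    rows[[b]] <- data.frame(
      bin = b, lo = bins$lo[b], hi = bins$hi[b],
      mean_velocity = v_mean, force_pN = force,
      n_events = length(d), n_control = n_ctl, qc_pass = qc,
      koff_at_1s = g(est1), se_at_1s = g(est1, "se"),
      koff_at_2s = g(est2), se_at_2s = g(est2, "se"),
      koff_exp_fit = if (!is.null(este) && !isTRUE(este$flagged)) este$value else NA_real_,
      se_exp_fit = g(este, "se"),
      plateau_B = g(este, "plateau"))
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no velocity bin contained events")

  fit_one <- function(col, secol) {
    ok <- tab$qc_pass & is.finite(tab[[col]]) & tab[[col]] > 0
    if (sum(ok) < 3L) return(NULL)
    fit_bell(tab$force_pN[ok], tab[[col]][ok],
             rate_se = NULL, temp = temp)
  }
  bell <- list(at_1s = fit_one("koff_at_1s"),
               at_2s = fit_one("koff_at_2s"),
               exp_fit = fit_one("koff_exp_fit"))
  structure(list(table = tab, bell = bell), class = "force_spectrum")
}

#' @export
print.force_spectrum <- function(x, ...) {
  cat(sprintf("Force spectrum: %d velocity bins (%d passing QC)\n",
              nrow(x$table), sum(x$table$qc_pass)))
  print(x$table[, c("bin", "mean_velocity", "force_pN", "n_events", "qc_pass",
                    "koff_at_1s", "koff_at_2s", "koff_exp_fit")],
        row.names = FALSE, digits = 4)
  for (m in names(x$bell)) {
    if (!is.null(x$bell[[m]])) {
      cat(sprintf("Bell fit [%s]: k0_off = %.3g 1/s, x_beta = %+.3g nm\n",
                  m, x$bell[[m]]$k0_off, x$bell[[m]]$x_beta))
    }
  }
  invisible(x)
}

#' Correlate fitted force sensitivities with solution affinity
#'
#' Regresses the Bell-model x_beta of a ligand panel on log10(K_D),
#' delegating to [fit_xbeta_relation()]. The slope summarises whether force
#' preferentially destabilises high-affinity (negative slope) or
#' low-affinity (positive slope) ligands.
#'
#' @param bell_fits list of `bell_fit` objects (one per ligand).
#' @param KD_uM dissociation constants, uM, parallel to `bell_fits`.
#' @param weighted use the x_beta standard errors as inverse-variance
#'   weights.
#' @return an `xbeta_relation_fit`.
#' @export
xbeta_affinity_correlation <- function(bell_fits, KD_uM, weighted = FALSE) {
  if (length(bell_fits) != length(KD_uM)) stop("one K_D per Bell fit required")
  if (length(bell_fits) < 2L) stop("need at least 2 ligands")
  xb <- vapply(bell_fits, function(f) f$x_beta, 0)
  se <- vapply(bell_fits, function(f) f$se_x_beta, 0)
  fit_xbeta_relation(KD_uM, xb, xbeta_se = if (weighted) se else NULL,
                     argument = "K_D")
}
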