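#' Fit a 1:1 Langmuir binding isotherm
#'
#' Nonlinear least squares of `B = Bmax * C / (KD + C)` to equilibrium
#' responses, with `Bmax` either free or fixed to an externally derived
#' value (standard-curve constraint). Warns when the highest analyte
#' concentration is below 2.5 x the fitted K_D: the isotherm does not
#' saturate and Bmax (hence K_D) is poorly constrained.
#'
#' @param conc_uM analyte concentrations, uM.
#' @param response_RU double-referenced equilibrium responses, RU.
#' @param bmax `"free"` or a fixed numeric Bmax (RU).
#' @return Object of class `langmuir_fit`: `KD`, `Bmax`, `se_KD`,
#'   `se_Bmax`, `saturation_ratio`, `bmax_mode`.
#' @export
fit_langmuir <- function(conc_uM, response_RU, bmax = "free") {
  stopifnot(length(conc_uM) == length(response_RU), all(conc_uM >= 0))
  free <- identical(bmax, "free")
  if (length(unique(conc_uM)) < (if (free) 3L else 2L))
    stop("need at least ", if (free) 3 else 2, " distinct concentrations")
  kd0 <- max(stats::median(conc_uM), 1e-6)
  fit <- if (free) {
    .nlsLM_safe(response_RU ~ Bmax * conc_uM / (KD + conc_uM),
                start = list(Bmax = max(response_RU) * 1.5, KD = kd0),
                lower = c(Bmax = 0, KD = 1e-12))
  } else {
    stopifnot(is.numeric(bmax), bmax > 0)
    Bfix <- bmax
    .nlsLM_safe(response_RU ~ Bfix * conc_uM / (KD + conc_uM),
                start = list(KD = kd0), lower = c(KD = 1e-12))
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  KD <- cf[["KD"]]
  Bmax_hat <- if (free) cf[["Bmax"]] else bmax
  sat <- max(conc_uM) / KD
  if (sat < 2.5)
    warning(sprintf("unsaturated design: max conc / KD = %.2f < 2.5", sat))
  structure(list(KD = KD, Bmax = Bmax_hat,
                 se_KD = se[["KD"]],
                 se_Bmax = if (free) se[["Bmax"]] else NA_real_,
                 saturation_ratio = sat,
                 bmax_mode = if (free) "free" else "fixed", fit = fit),
            class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("Langmuir fit (Bmax %s): KD = %.4g uM (SE %.3g), Bmax = %.4g RU\n",
              x$bmax_mode, x$KD, x$se_KD, x$Bmax))
  cat(sprintf("  saturation ratio max[C]/KD = %.2f%s\n", x$saturation_ratio,
              if (x$saturation_ratio < 2.5) " (unsaturated)" else ""))
  invisible(x)
}

#' @export
coef.langmuir_fit <- function(object, ...) c(KD = object$KD, Bmax = object$Bmax)

#' Maximal antibody binding from a saturation time course
#'
#' Fits the empirical hyperbolic model `R = Rmax * t / (K_t + t)` to a
#' conformation-specific antibody (W6/32) binding trace; `Rmax` quantifies
#' active immobilized pMHC and `K_t` is a nuisance timescale. Flat traces
#' are flagged non-identifiable.
#'
#' @param t_s time since injection start, s (> 0).
#' @param response_RU single-referenced responses, RU.
#' @return list with `Rmax`, `K_t`, SEs and a `flagged` field.
#' @export
fit_w6_32_rmax <- function(t_s, response_RU) {
  stopifnot(length(t_s) == length(response_RU), all(t_s > 0))
  if (stats::sd(response_RU) < 1e-12 * max(abs(response_RU), 1)) {
    return(list(Rmax = NA_real_, K_t = NA_real_, se_Rmax = NA_real_,
                se_K_t = NA_real_, flagged = TRUE))
  }
  fit <- .nlsLM_safe(response_RU ~ Rmax * t_s / (K_t + t_s),
                     start = list(Rmax = max(response_RU),
                                  K_t = stats::median(t_s)),
                     lower = c(Rmax = 0, K_t = 1e-9))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  list(Rmax = cf[["Rmax"]], K_t = cf[["K_t"]],
       se_Rmax = se[["Rmax"]], se_K_t = se[["K_t"]], flagged = FALSE, fit = fit)
}

#' Constrain Bmax through the antibody standard curve
#'
#' Regresses TCR Bmax on W6/32 Rmax across reference surfaces (through the
#' origin by default: immobilized-site counts are proportional) and
#' predicts the Bmax of a new surface from its measured Rmax. Only
#' reference points whose isotherm saturated (`saturation_ratio >= 2.5`)
#' enter the curve; with none the function returns NA with a warning so
#' the caller can fall back to the free-Bmax fit.
#'
#' @param rmax_std W6/32 Rmax of the reference surfaces, RU.
#' @param bmax_std fitted TCR Bmax of the reference surfaces, RU.
#' @param saturation_ratio max conc / fitted K_D per reference point.
#' @param new_rmax Rmax of the surface whose Bmax is wanted.
#' @param through_origin drop the intercept (default).
#' @return predicted Bmax (RU), with attribute `n_points`.
#' @export
constrained_bmax <- function(rmax_std, bmax_std, saturation_ratio, new_rmax,
                             through_origin = TRUE) {
  stopifnot(length(rmax_std) == length(bmax_std),
            length(saturation_ratio) == length(rmax_std))
  keep <- saturation_ratio >= 2.5
  if (!any(keep)) {
    warning("no reference point saturated (ratio >= 2.5): cannot constrain Bmax")
    return(structure(NA_real_, n_points = 0L))
  }
  r <- rmax_std[keep]; b <- bmax_std[keep]
  pred <- if (sum(keep) == 1L) {
    new_rmax * b / r                       # single point: proportionality
  } else if (through_origin) {
    unname(stats::coef(stats::lm(b ~ 0 + r))[1L]) * new_rmax
  } else {
    f <- stats::lm(b ~ r)
    unname(stats::predict(f, data.frame(r = new_rmax)))
  }
  structure(pred, n_points = sum(keep))
}

#' Reported K_D decision rule
#'
#' The constrained-Bmax K_D is reported when it exceeds 20 uM (weak
#' binders, where the free-Bmax fit is unreliable); otherwise the
#' free-Bmax K_D is reported. With only one estimate available the rule
#' degenerates to that estimate.
#'
#' @param free_KD K_D from the free-Bmax fit, uM (NA allowed).
#' @param constrained_KD K_D from the constrained-Bmax fit, uM (NA
#'   allowed).
#' @return the reported K_D, uM.
#' @export
report_kd <- function(free_KD, constrained_KD) {
  if (is.na(constrained_KD)) return(free_KD)
  if (is.na(free_KD)) return(constrained_KD)
  if (constrained_KD > 20) constrained_KD else free_KD
}

#' Fit a mono-exponential dissociation curve
#'
#' `R(t) = R0 exp(-k_off t)` (plus an optional baseline offset) fitted to
#' a double-referenced dissociation trace. The fit window starts
#' `skip_points` samples after the first point to avoid injection-stop
#' transition artefacts. Rising traces are rejected; flat traces give a
#' flagged near-zero rate.
#'
#' @param t_s time since dissociation start, s.
#' @param response_RU responses, RU.
#' @param offset fit an additive baseline.
#' @param skip_points samples dropped at the start of the window.
#' @return list with `k_off`, `R0`, `se_k_off`, `offset`, `flagged`.
#' @export
fit_dissociation <- function(t_s, response_RU, offset = FALSE, skip_points = 1L) {
  stopifnot(length(t_s) == length(response_RU), length(t_s) >= 5L)
  keep <- seq_along(t_s) > skip_points
  t <- t_s[keep]; r <- response_RU[keep]
  sl <- stats::coef(stats::lm(r ~ t))[[2L]]
  if (sl > 1e-8 * max(abs(r)))
    stop("rising trace: not a dissociation curve")
  k0 <- {
    below <- which(r <= r[1L] / 2)
    if (length(below)) log(2) / max(t[below[1L]] - t[1L], diff(range(t)) / 100)
    else 0.1 / diff(range(t))
  }
  fit <- if (offset) {
    .nlsLM_safe(r ~ R0 * exp(-k * (t - t[1])) + C,
                start = list(R0 = r[1L], k = k0, C = min(r)),
                lower = c(R0 = 0, k = 0, C = -Inf))
  } else {
    .nlsLM_safe(r ~ R0 * exp(-k * (t - t[1])),
                start = list(R0 = r[1L], k = k0),
                lower = c(R0 = 0, k = 0))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  flagged <- cf[["k"]] < 1e-6
  list(k_off = cf[["k"]], R0 = cf[["R0"]], se_k_off = se[["k"]],
       offset = if (offset) cf[["C"]] else 0, flagged = flagged, fit = fit)
}

#' On-rate from off-rate and affinity
#'
#' `k_on = k_off / K_D`.
#'
#' @param k_off off-rate, 1/s.
#' @param KD_uM dissociation constant, uM.
#' @return on-rate, 1/(uM s).
#' @examples
#' on_rate(4.3, 34)  # 0.126 -> reported as 0.13
#' @export
on_rate <- function(k_off, KD_uM) {
  stopifnot(k_off > 0, KD_uM > 0)
  k_off / KD_uM
}
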