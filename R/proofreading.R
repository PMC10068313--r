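#' Parameters of the force-modified kinetic proofreading model
#'
#' A ligand-bound TCR must traverse `N` sequential modification steps, each
#' at rate `k_p`, before it signals; dissociation at the membrane off-rate
#' `k^m_off(F)` resets the chain. Force enters through an empirical relation
#' tying the Bell force sensitivity to the ligand's affinity,
#' `x_beta = slope * log10(K_D) + intercept` (defaults: the relation
#' measured for the 1G4 TCR, with kBT fixed to the constant 4.2797 pN nm
#' used throughout the model's calculations).
#'
#' @param N number of proofreading steps (non-integer allowed).
#' @param k_p step rate, 1/s.
#' @param k_on on-rate, 1/(uM s).
#' @param relation an [xbeta_relation()] with `argument = "K_D"` (nm vs
#'   log10 uM).
#' @param kBT thermal energy, pN nm.
#' @param R_0 total TCR concentration, uM-equivalent.
#' @param threshold activation threshold on the signalling occupancy C_N.
#' @return list of class `kp_params`.
#' @export
kp_params <- function(N = 2.46, k_p = 2.15, k_on = 0.0447,
                      relation = xbeta_relation(-0.029, -0.11, "K_D"),
                      kBT = 4.2797, R_0 = 1, threshold = 1e-4) {
  stopifnot(N >= 0, k_p > 0, k_on > 0, kBT > 0, R_0 > 0, threshold > 0,
            inherits(relation, "xbeta_relation"))
  structure(list(N = N, k_p = k_p, k_on = k_on, relation = relation,
                 kBT = kBT, R_0 = R_0, threshold = threshold),
            class = "kp_params")
}

#' Membrane off-rate from affinity under force
#'
#' \eqn{k^m_{off}(F) = k_{on} K_D \exp(x_\beta(K_D) F / k_B T)} with the
#' empirical force-sensitivity relation evaluated at the ligand's own K_D.
#' At zero force this reduces to the solution off-rate `k_on * K_D`.
#'
#' @param KD_uM dissociation constant, uM (vectorized).
#' @param force applied force, pN.
#' @param params a [kp_params()].
#' @return off-rate, 1/s.
#' @examples
#' membrane_off_rate_from_KD(1, 10)  # 0.0447 * exp(-1.1 / 4.2797)
#' @export
membrane_off_rate_from_KD <- function(KD_uM, force, params = kp_params()) {
  stopifnot(all(KD_uM > 0), all(force >= 0))
  xb <- xbeta(params$relation, KD_uM)
  params$k_on * KD_uM * exp(xb * force / params$kBT)
}

#' Equilibrium bound-complex concentration
#'
#' Closed-form two-species binding equilibrium:
#' \deqn{C_T = \tfrac12\left(L_0 + R_0 + K - \sqrt{(L_0 + R_0 + K)^2 - 4 L_0 R_0}\right)}
#' with \eqn{K = k^m_{off}/k_{on}}. Bounded by `min(L_0, R_0)`.
#'
#' @param L_0 total ligand concentration, uM.
#' @param R_0 total receptor concentration, uM.
#' @param koffm membrane off-rate, 1/s.
#' @param k_on on-rate, 1/(uM s).
#' @return C_T, uM.
#' @export
bound_complex <- function(L_0, R_0, koffm, k_on) {
  stopifnot(all(L_0 >= 0), all(R_0 >= 0), all(koffm >= 0), k_on > 0)
  K <- koffm / k_on
  s <- L_0 + R_0 + K
  disc <- s^2 - 4 * L_0 * R_0
  if (any(disc < 0)) {
    warning("negative discriminant clamped to 0")
    disc <- pmax(disc, 0)
  }
  0.5 * (s - sqrt(disc))
}

#' Occupancy of the signalling-competent state
#'
#' \eqn{C_N = (1 + k^m_{off}/k_p)^{-N} C_T}: the fraction of bound
#' complexes that completes all N proofreading steps before dissociating.
#'
#' @param C_T bound-complex concentration, uM.
#' @param koffm membrane off-rate, 1/s.
#' @param N number of proofreading steps.
#' @param k_p step rate, 1/s.
#' @return C_N, uM.
#' @export
signalling_occupancy <- function(C_T, koffm, N, k_p) {
  stopifnot(all(C_T >= 0), all(koffm >= 0), N >= 0, k_p > 0)
  (1 + koffm / k_p)^(-N) * C_T
}

#' Potency: ligand concentration needed to reach the activation threshold
#'
#' Solves `C_N(L_0) = threshold` for the pMHC concentration `L_0` by
#' monotone bisection on `log10 L_0` over `[1e-8, 1e6]` uM. When even a
#' saturating ligand concentration cannot reach the threshold the potency
#' is infinite and flagged.
#'
#' @param KD_uM ligand dissociation constant, uM (vectorized).
#' @param force applied force, pN.
#' @param params a [kp_params()].
#' @param tol relative tolerance of the bisection.
#' @return data.frame with `KD_uM`, `P_uM`, `logP` (log10 uM) and
#'   `reachable`.
#' @export
potency <- function(KD_uM, force, params = kp_params(), tol = 1e-6) {
  stopifnot(all(KD_uM > 0), force >= 0)
  out <- lapply(KD_uM, function(kd) {
    koffm <- membrane_off_rate_from_KD(kd, force, params)
    cn <- function(l10) {
      ct <- bound_complex(10^l10, params$R_0, koffm, params$k_on)
      signalling_occupancy(ct, koffm, params$N, params$k_p)
    }
    lo <- -8; hi <- 6
    if (cn(hi) < params$threshold)
      return(data.frame(KD_uM = kd, P_uM = Inf, logP = Inf, reachable = FALSE))
    if (cn(lo) > params$threshold)
      return(data.frame(KD_uM = kd, P_uM = 10^lo, logP = lo, reachable = TRUE))
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (cn(mid) < params$threshold) lo <- mid else hi <- mid
    }
    data.frame(KD_uM = kd, P_uM = 10^((lo + hi) / 2), logP = (lo + hi) / 2,
               reachable = TRUE)
  })
  do.call(rbind, out)
}

#' Linearized log-potency
#'
#' In the regime where receptors are in excess and far from saturation the
#' potency has the closed form
#' \eqn{P = \lambda + N \log_{10}(1 + k^m_{off}(F)/k_p)} (log10 uM), with
#' \eqn{\lambda} proportional to the log of the activation threshold. This
#' is the expression fitted to experimental potency data.
#'
#' @param KD_uM dissociation constants, uM (vectorized).
#' @param params a [kp_params()].
#' @param force applied force, pN.
#' @param lambda threshold offset, log10 uM.
#' @return log10 potency.
#' @export
potency_linearized <- function(KD_uM, params = kp_params(), force, lambda) {
  koffm <- membrane_off_rate_from_KD(KD_uM, force, params)
  lambda + params$N * log10(1 + koffm / params$k_p)
}

#' Discrimination power
#'
#' The ratio of the log fold-change in potency to the log fold-change in
#' off-rate between a lower-affinity reference ligand (`koff_lo`) and a
#' higher-affinity one (`koff_hi`):
#' \eqn{\alpha = (\log_{10} P_{lo} - \log_{10} P_{hi}) /
#' (\log_{10} k_{lo} - \log_{10} k_{hi})}. Computed from the linearized
#' potency (the threshold offset cancels). Larger alpha means sharper
#' antigen discrimination; force reduces alpha when the force-sensitivity
#' relation has a negative slope.
#'
#' @param force applied force, pN.
#' @param params a [kp_params()].
#' @param koff_hi,koff_lo zero-force off-rates of the two reference
#'   ligands, 1/s.
#' @return alpha, dimensionless.
#' @examples
#' discrimination_power(0)  # ~ 1.51 with default N, k_p
#' @export
discrimination_power <- function(force, params = kp_params(),
                                 koff_hi = 0.5, koff_lo = 10^1.5) {
  stopifnot(koff_hi > 0, koff_lo > 0, koff_hi != koff_lo)
  kd <- c(hi = koff_hi, lo = koff_lo) / params$k_on
  lp <- potency_linearized(kd, params, force = force, lambda = 0)
  (lp[["lo"]] - lp[["hi"]]) / (log10(koff_lo) - log10(koff_hi))
}

#' Fit the force-modified proofreading model to potency data
#'
#' Least squares of observed log-potency on
#' `lambda_c + N log10(1 + k^m_off(K_D, F_c)/k_p)` with N and k_p fixed.
#' The applied force F is always fitted per condition ("local force");
#' the threshold offset lambda is a single shared value
#' (`mode = "global_lambda"`) or one per condition (`"local_lambda"`).
#' Standard errors come from the least-squares covariance; non-convergence
#' triggers multi-start retries before the fit is flagged.
#'
#' @param data data.frame with columns `condition`, `KD_uM`, `logP_obs`
#'   and optionally `sem` (used as inverse-variance weights when
#'   `weighted = TRUE`).
#' @param params a [kp_params()] fixing N, k_p, k_on and the x_beta
#'   relation.
#' @param mode `"global_lambda"` or `"local_lambda"`.
#' @param weighted weight residuals by 1/sem.
#' @return Object of class `kp_fit`: data.frame `coefficients` (per-
#'   condition F and lambda with SEs), `sse`, `df`, `mode`, `converged`,
#'   `fitted` values and the input data.
#' @export
fit_potency <- function(data, params = kp_params(),
                        mode = c("global_lambda", "local_lambda"),
                        weighted = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(c("condition", "KD_uM", "logP_obs") %in% names(data)))
  conds <- unique(as.character(data$condition))
  n_c <- length(conds)
  for (cc in conds) {
    if (sum(data$condition == cc) < 2L)
      stop("need >= 2 antigens per condition (", cc, ")")
  }
  ci <- match(as.character(data$condition), conds)
  wts <- if (weighted && "sem" %in% names(data)) 1 / data$sem else
    rep(1, nrow(data))

  n_lambda <- if (mode == "global_lambda") 1L else n_c
  pred <- function(par) {
    Fs <- par[seq_len(n_c)]
    lam <- par[n_c + seq_len(n_lambda)]
    lam_i <- if (n_lambda == 1L) rep(lam, nrow(data)) else lam[ci]
    lam_i + params$N *
      log10(1 + membrane_off_rate_from_KD(data$KD_uM, 0, params) *
              exp(xbeta(params$relation, data$KD_uM) * Fs[ci] / params$kBT) /
              params$k_p)
  }
  resid_fun <- function(par) wts * (data$logP_obs - pred(par))

  starts <- list(c(rep(20, n_c), rep(stats::median(data$logP_obs), n_lambda)),
                 c(rep(50, n_c), rep(min(data$logP_obs), n_lambda)),
                 c(rep(5, n_c), rep(max(data$logP_obs) - 1, n_lambda)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         lower = c(rep(0, n_c), rep(-Inf, n_lambda)),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("potency fit failed from all starts")
  converged <- best$info %in% 1:4
  sse <- best$deviance
  p <- n_c + n_lambda
  df <- nrow(data) - p
  covm <- tryCatch({
    sm <- summary(best)
    sm$coefficients[, "Std. Error"]
  }, error = function(e) rep(NA_real_, p))

  par <- best$par
  co <- data.frame(
    condition = c(conds, if (n_lambda == 1L) "(global)" else conds),
    parameter = c(rep("F_pN", n_c), rep("lambda", n_lambda)),
    estimate = par, se = covm)
  structure(list(coefficients = co, sse = sse, df = df, mode = mode,
                 converged = converged, params = params,
                 fitted = pred(par), data = data),
            class = "kp_fit")
}

#' @export
print.kp_fit <- function(x, ...) {
  cat(sprintf("Force-modified proofreading fit (%s%s)\n", x$mode,
              if (!x$converged) ", NOT converged" else ""))
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("  SSE = %.4g on %d df\n", x$sse, x$df))
  invisible(x)
}

#' @export
coef.kp_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  paste(object$coefficients$parameter,
                        object$coefficients$condition, sep = "."))
}

#' F-test between nested proofreading fits
#'
#' Compares the global-threshold fit (fewer parameters) with the
#' local-threshold fit: \eqn{F = ((SSE_g - SSE_l)/(df_g - df_l)) /
#' (SSE_l/df_l)}, with the p-value from the F distribution. Accepts
#' `kp_fit` objects or raw `(sse, df)` lists.
#'
#' @param global the restricted (nested) fit.
#' @param local the fuller fit.
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @examples
#' f_test_nested(list(sse = 10, df = 9), list(sse = 5, df = 7))
#' @export
f_test_nested <- function(global, local) {
  g <- if (inherits(global, "kp_fit")) list(sse = global$sse, df = global$df) else global
  l <- if (inherits(local, "kp_fit")) list(sse = local$sse, df = local$df) else local
  if (l$df >= g$df) stop("local model must have fewer residual df than global")
  if (l$sse > g$sse * (1 + 1e-10)) stop("invalid nesting: SSE_local > SSE_global")
  df1 <- g$df - l$df
  df2 <- l$df
  Fstat <- ((g$sse - l$sse) / df1) / (l$sse / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}
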