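#' Thermal energy context
#'
#' Bundles the Boltzmann constant and absolute temperature used to convert
#' between force and rate scales. The default corresponds to physiological
#' temperature (310.15 K) with \eqn{k_B} in pN nm/K, giving
#' \eqn{k_B T \approx 4.28} pN nm.
#'
#' @param k_B Boltzmann constant in pN nm/K.
#' @param T absolute temperature in K.
#' @return An object of class `temp_context` with fields `k_B`, `T` and
#'   their product `k_B_T` (pN nm).
#' @examples
#' temp_context()$k_B_T
#' @export
temp_context <- function(k_B = 0.0138, T = 310.15) {
  if (!is.finite(k_B) || k_B <= 0) stop("k_B must be a positive finite number")
  if (!is.finite(T) || T <= 0) stop("T must be a positive finite number")
  structure(list(k_B = k_B, T = T, k_B_T = k_B * T), class = "temp_context")
}

#' @export
print.temp_context <- function(x, ...) {
  cat(sprintf("Thermal context: k_B = %.4g pN nm/K, T = %.2f K, k_B T = %.4f pN nm\n",
              x$k_B, x$T, x$k_B_T))
  invisible(x)
}

# resolve a temp argument that may be a context or a bare k_B_T value
.kbt <- function(temp) {
  if (inherits(temp, "temp_context")) return(temp$k_B_T)
  if (is.numeric(temp) && length(temp) == 1L && is.finite(temp) && temp > 0) return(temp)
  stop("temp must be a temp_context or a positive k_B*T value")
}

#' Force-sensitivity relation x_beta(log10 argument)
#'
#' Linear relation between the Bell force-sensitivity length and the log10 of
#' a rate or affinity: `x_beta = slope * log10(argument) + intercept`. Positive
#' slopes make fast-dissociating ligands more force sensitive (discrimination
#' enhanced by force); negative slopes make them less sensitive
#' (discrimination impaired by force).
#'
#' @param slope nm per log10 unit of the argument.
#' @param intercept nm.
#' @param argument what the relation is evaluated at: solution off-rate
#'   (`"k_off"`, 1/s) or dissociation constant (`"K_D"`, uM).
#' @return Object of class `xbeta_relation`.
#' @examples
#' rel <- xbeta_relation(slope = -0.029, intercept = -0.11, argument = "K_D")
#' xbeta(rel, 1)    # -0.11 nm at K_D = 1 uM
#' @export
xbeta_relation <- function(slope, intercept = 0, argument = c("k_off", "K_D")) {
  argument <- match.arg(argument)
  stopifnot(is.finite(slope), is.finite(intercept))
  structure(list(slope = slope, intercept = intercept, argument = argument),
            class = "xbeta_relation")
}

#' Evaluate a force-sensitivity relation
#'
#' @param relation an [xbeta_relation()].
#' @param value positive rate (1/s) or K_D (uM), per `relation$argument`.
#' @return x_beta in nm (vectorized over `value`).
#' @export
xbeta <- function(relation, value) {
  stopifnot(inherits(relation, "xbeta_relation"))
  if (any(!is.finite(value) | value <= 0)) stop("relation argument must be positive and finite")
  relation$slope * log10(value) + relation$intercept
}

#' @export
print.xbeta_relation <- function(x, ...) {
  cat(sprintf("x_beta = %+.4g log10(%s) %+.4g nm\n", x$slope, x$argument, x$intercept))
  invisible(x)
}

#' Bell's model: membrane off-rate under force
#'
#' Evaluates \eqn{k_{off}(F) = k^0_{off} \exp(F x_\beta / k_B T)}. A positive
#' `x_beta` gives a slip bond (force accelerates dissociation), a negative one
#' a catch bond.
#'
#' @param k0_off zero-force off-rate, 1/s.
#' @param x_beta force-sensitivity length, nm (signed).
#' @param force pulling force in pN (vectorized, must be >= 0).
#' @param temp a [temp_context()] or a bare k_B*T value in pN nm.
#' @return off-rate(s) in 1/s.
#' @examples
#' membrane_off_rate(1, 0.4, 15, temp = 4.2797)
#' @export
membrane_off_rate <- function(k0_off, x_beta, force, temp = temp_context()) {
  if (!is.finite(k0_off) || k0_off <= 0) stop("k0_off must be positive and finite")
  if (!is.finite(x_beta)) stop("x_beta must be finite")
  if (any(!is.finite(force)) || any(force < 0)) stop("force must be finite and non-negative")
  k0_off * exp(force * x_beta / .kbt(temp))
}

#' Fold-change in membrane off-rate between two ligands under force
#'
#' Given two ligands with zero-force off-rates `k_off_A` and `k_off_B` and a
#' relation tying each ligand's force sensitivity to its own off-rate,
#' computes the ratio of their membrane off-rates under an applied force.
#' With no force the ratio is simply `k_off_B / k_off_A`; under force it is
#' amplified when the relation slope is positive and dampened when negative.
#'
#' @param k_off_A,k_off_B zero-force off-rates, 1/s (typically B the faster).
#' @param relation an [xbeta_relation()] with `argument = "k_off"`.
#' @param force applied force, pN.
#' @param temp a [temp_context()] or k_B*T value.
#' @return dimensionless fold-change k_m(B)/k_m(A).
#' @examples
#' rel <- xbeta_relation(slope = 0.3, argument = "k_off")
#' fold_change_under_force(0.1, 10, rel, force = 15, temp = 4.2797)  # ~ 820
#' @export
fold_change_under_force <- function(k_off_A, k_off_B, relation, force,
                                    temp = temp_context()) {
  if (k_off_A <= 0 || k_off_B <= 0) stop("off-rates must be positive")
  km_A <- membrane_off_rate(k_off_A, xbeta(relation, k_off_A), force, temp)
  km_B <- membrane_off_rate(k_off_B, xbeta(relation, k_off_B), force, temp)
  km_B / km_A
}

#' Fit Bell's model to off-rates measured under force
#'
#' Fits \eqn{k_{off}(F) = k^0_{off} \exp(F x_\beta / k_B T)}. The default
#' fit is linear regression of `log(rate)` on force, which matches the
#' multiplicative error structure of rate estimates and yields closed-form
#' standard errors; `method = "nls"` refits by nonlinear least squares in
#' rate space. When `rate_se` is supplied the log-space fit is weighted by
#' inverse variance of `log(rate)` (delta method: `se/rate`).
#'
#' @param force forces in pN (>= 3 distinct values required).
#' @param rate off-rates in 1/s (all > 0).
#' @param rate_se optional standard errors of the rates.
#' @param temp a [temp_context()] or k_B*T in pN nm.
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return Object of class `bell_fit` with elements `k0_off`, `x_beta`,
#'   `se_k0_off`, `se_x_beta`, `temp`, `method`, `data` and the underlying
#'   model object `fit`.
#' @examples
#' f <- c(0, 10, 20, 30)
#' k <- membrane_off_rate(1, 0.4, f)
#' fit_bell(f, k)
#' @export
fit_bell <- function(force, rate, rate_se = NULL, temp = temp_context(),
                     method = c("loglinear", "nls")) {
  method <- match.arg(method)
  if (length(force) != length(rate)) stop("force and rate lengths differ")
  if (length(unique(force)) < 3L) stop("need at least 3 distinct force points")
  if (any(!is.finite(rate)) || any(rate <= 0)) stop("all rates must be positive and finite")
  if (any(!is.finite(force)) || any(force < 0)) stop("forces must be finite and non-negative")
  kbt <- .kbt(temp)

  w <- NULL
  if (!is.null(rate_se)) {
    if (length(rate_se) != length(rate) || any(rate_se <= 0))
      stop("rate_se must be positive and match rate")
    w <- (rate / rate_se)^2  # inverse variance of log(rate)
  }
  lfit <- stats::lm(log(rate) ~ force, weights = w)
  cf <- stats::coef(lfit)
  vc <- stats::vcov(lfit)
  k0 <- exp(cf[[1L]])
  xb <- cf[[2L]] * kbt
  se_k0 <- k0 * sqrt(vc[1L, 1L])
  se_xb <- kbt * sqrt(vc[2L, 2L])
  fit <- lfit

  if (method == "nls") {
    start <- list(lk0 = log(k0), xb = xb)
    nfit <- tryCatch(
      .nlsLM_safe(rate ~ exp(lk0) * exp(force * xb / kbt),
                  start = start,
                  weights = if (is.null(rate_se)) NULL else 1 / rate_se^2),
      error = function(e) e)
    if (inherits(nfit, "error")) {
      # zero-residual (noiseless) data defeats the nonlinear machinery;
      # the log-linear solution is the exact optimum there
      warning("nonlinear refit degenerate (", conditionMessage(nfit),
              "); returning the log-linear estimates")
      method <- "loglinear"
    } else {
      cf <- stats::coef(nfit)
      vc <- stats::vcov(nfit)
      k0 <- exp(cf[["lk0"]]); xb <- cf[["xb"]]
      se_k0 <- k0 * sqrt(vc["lk0", "lk0"]); se_xb <- sqrt(vc["xb", "xb"])
      fit <- nfit
    }
  }

  structure(list(k0_off = k0, x_beta = xb, se_k0_off = se_k0, se_x_beta = se_xb,
                 k_B_T = kbt, method = method, fit = fit,
                 data = data.frame(force = force, rate = rate)),
            class = "bell_fit")
}

#' @export
print.bell_fit <- function(x, ...) {
  cat("Bell model fit: k_off(F) = k0_off * exp(F * x_beta / kBT)\n")
  cat(sprintf("  k0_off  = %.4g 1/s (SE %.3g)\n", x$k0_off, x$se_k0_off))
  cat(sprintf("  x_beta  = %+.4g nm  (SE %.3g)  [%s]\n", x$x_beta, x$se_x_beta,
              if (x$x_beta >= 0) "slip bond" else "catch bond"))
  cat(sprintf("  n = %d force points, method = %s, kBT = %.4f pN nm\n",
              nrow(x$data), x$method, x$k_B_T))
  invisible(x)
}

#' @export
coef.bell_fit <- function(object, ...) {
  c(k0_off = object$k0_off, x_beta = object$x_beta)
}

#' @export
predict.bell_fit <- function(object, force = object$data$force, ...) {
  membrane_off_rate(object$k0_off, object$x_beta, force, object$k_B_T)
}

#' @export
summary.bell_fit <- function(object, ...) {
  out <- data.frame(
    estimate = c(object$k0_off, object$x_beta),
    se = c(object$se_k0_off, object$se_x_beta),
    row.names = c("k0_off (1/s)", "x_beta (nm)"))
  out
}

#' Bell-Evans most-probable rupture force
#'
#' \eqn{F = (k_B T / x_\beta) \ln(x_\beta \kappa v / (k_B T k_{off}))}: the
#' characteristic rupture force in constant-speed pulling with a spring of
#' stiffness `kappa` retracted at speed `v` (loading rate `kappa * v`).
#' When the log argument is at or below 1 the most probable rupture force is
#' reported as 0 (dissociation is thermally dominated; rupture force is
#' non-negative by construction) with a warning.
#'
#' @param v pulling speed, length/time in simulation units (vectorized).
#' @param k_off_tau intrinsic dissociation rate, 1/time-unit.
#' @param x_beta force-sensitivity length (same length unit as v).
#' @param kappa spring stiffness, k_B_T/length^2.
#' @param k_B_T thermal energy (default 1: simulation units).
#' @return force in k_B_T/length units.
#' @examples
#' bell_evans_force(0.005, k_off_tau = 1e-5, x_beta = 5, kappa = 0.12)
#' @export
bell_evans_force <- function(v, k_off_tau, x_beta, kappa, k_B_T = 1) {
  stopifnot(k_off_tau > 0, kappa > 0, x_beta > 0, k_B_T > 0)
  if (any(v <= 0)) stop("pulling speed must be positive")
  arg <- x_beta * kappa * v / (k_B_T * k_off_tau)
  f <- ifelse(arg > 1, (k_B_T / x_beta) * log(pmax(arg, 1)), 0)
  if (any(arg < 1))
    warning("log argument < 1 for some speeds; rupture force clamped to 0")
  f
}

#' Fit the Bell-Evans model to rupture-force vs pulling-speed data
#'
#' Weighted least squares of mean rupture force on `log(v)`:
#' slope `= k_B_T / x_beta`, intercept fixes `k_off_tau` through
#' `F = (kBT/x_beta) ln(x_beta kappa v / (kBT k_off))`. Weights are inverse
#' variance when `f_sem` is given.
#'
#' @param speed pulling speeds (>= 3, not all equal).
#' @param f_max mean rupture force at each speed.
#' @param f_sem optional SEM of each mean force.
#' @param kappa pulling-spring stiffness, k_B_T/length^2.
#' @param k_B_T thermal energy (default 1).
#' @return Object of class `bell_evans_fit` with `k_off_tau`, `x_beta`,
#'   standard errors, an `identifiable` flag and the underlying `lm` fit.
#' @export
fit_bell_evans <- function(speed, f_max, f_sem = NULL, kappa, k_B_T = 1) {
  if (length(speed) != length(f_max)) stop("speed and f_max lengths differ")
  if (length(unique(speed)) < 3L) stop("need at least 3 distinct pulling speeds")
  stopifnot(all(speed > 0), kappa > 0)
  if (any(diff(f_max[order(speed)]) < 0))
    warning("mean forces are not monotone increasing in speed")

  w <- NULL
  if (!is.null(f_sem)) {
    if (length(f_sem) != length(f_max) || any(f_sem <= 0))
      stop("f_sem must be positive and match f_max")
    w <- 1 / f_sem^2
  }
  lv <- log(speed)
  lfit <- stats::lm(f_max ~ lv, weights = w)
  cf <- stats::coef(lfit)
  vc <- stats::vcov(lfit)
  if (!is.null(w)) {
    # SEMs are measured variances (replicate means), not relative weights:
    # use the absolute-variance covariance (X' W X)^-1 instead of rescaling
    # by the residual variance of a 2-parameter fit
    X <- cbind(1, lv)
    vc <- solve(t(X) %*% (w * X))
  }
  a <- cf[[1L]]; b <- cf[[2L]]

  if (!is.finite(b) || b <= .Machine$double.eps^0.5 * max(abs(f_max), 1)) {
    return(structure(list(k_off_tau = NA_real_, x_beta = Inf,
                          se_k_off_tau = NA_real_, se_x_beta = NA_real_,
                          kappa = kappa, k_B_T = k_B_T, identifiable = FALSE,
                          fit = lfit),
                     class = "bell_evans_fit"))
  }
  x_beta <- k_B_T / b
  k_off <- (kappa / b) * exp(-a / b)
  # delta method on (a, b)
  dk_da <- -k_off / b
  dk_db <- (k_off / b) * (a / b - 1)
  g <- c(dk_da, dk_db)
  se_k <- sqrt(drop(t(g) %*% vc %*% g))
  se_xb <- k_B_T / b^2 * sqrt(vc[2L, 2L])
  structure(list(k_off_tau = k_off, x_beta = x_beta,
                 se_k_off_tau = se_k, se_x_beta = se_xb,
                 kappa = kappa, k_B_T = k_B_T, identifiable = TRUE, fit = lfit),
            class = "bell_evans_fit")
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("Bell-Evans fit: non-identifiable (zero slope of F vs ln v)\n")
    return(invisible(x))
  }
  cat("Bell-Evans fit: F = (kBT/x_beta) ln(x_beta kappa v / (kBT k_off))\n")
  cat(sprintf("  k_off  = %.4g per time unit (SE %.3g)\n", x$k_off_tau, x$se_k_off_tau))
  cat(sprintf("  x_beta = %.4g length units (SE %.3g)\n", x$x_beta, x$se_x_beta))
  invisible(x)
}

#' @export
coef.bell_evans_fit <- function(object, ...) {
  c(k_off_tau = object$k_off_tau, x_beta = object$x_beta)
}

#' @export
predict.bell_evans_fit <- function(object, speed, ...) {
  bell_evans_force(speed, object$k_off_tau, object$x_beta, object$kappa, object$k_B_T)
}

#' Fit x_beta against the log10 of off-rate or affinity
#'
#' Ordinary (or inverse-variance weighted) least squares of the
#' force-sensitivity length on `log10(x)`, the summary regression of a force
#' spectroscopy panel. The fitted slope is the quantity of interest: negative
#' means higher-affinity (slower, tighter) ligands are more force sensitive.
#'
#' @param x positive abscissae: off-rates (1/s) or K_D values (uM).
#' @param x_beta fitted force sensitivities, nm (or A for simulations).
#' @param xbeta_se optional standard errors for weighting.
#' @param argument `"k_off"` or `"K_D"` (bookkeeping for the returned relation).
#' @return Object of class `xbeta_relation_fit`: the fitted [xbeta_relation()]
#'   plus `se_slope`, `se_intercept` and the `lm` fit.
#' @export
fit_xbeta_relation <- function(x, x_beta, xbeta_se = NULL,
                               argument = c("k_off", "K_D")) {
  argument <- match.arg(argument)
  if (length(x) != length(x_beta)) stop("x and x_beta lengths differ")
  if (any(x <= 0)) stop("abscissae must be positive")
  if (length(unique(x)) < 2L) stop("need at least 2 distinct abscissae")
  w <- if (is.null(xbeta_se)) NULL else 1 / xbeta_se^2
  lx <- log10(x)
  lfit <- stats::lm(x_beta ~ lx, weights = w)
  cf <- stats::coef(lfit)
  se <- sqrt(diag(stats::vcov(lfit)))
  structure(list(relation = xbeta_relation(cf[[2L]], cf[[1L]], argument),
                 slope = cf[[2L]], intercept = cf[[1L]],
                 se_slope = se[[2L]], se_intercept = se[[1L]], fit = lfit),
            class = "xbeta_relation_fit")
}

#' @export
print.xbeta_relation_fit <- function(x, ...) {
  cat(sprintf("x_beta vs log10(%s): slope = %+.4g (SE %.3g), intercept = %+.4g (SE %.3g)\n",
              x$relation$argument, x$slope, x$se_slope, x$intercept, x$se_intercept))
  invisible(x)
}

#' @export
coef.xbeta_relation_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}
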