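# Robust nlsLM wrapper: the bounded Levenberg-Marquardt path can fail with
# a singular-gradient error on (near-)zero-residual data; retry without
# bounds, then from a perturbed start, before giving up.
.nlsLM_safe <- function(formula, start, lower = NULL, upper = NULL,
                        weights = NULL, env = parent.frame()) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500)
  try_one <- function(st, bounded) {
    args <- list(formula, start = st, control = ctrl)
    if (bounded) {
      if (!is.null(lower)) args$lower <- lower
      if (!is.null(upper)) args$upper <- upper
    }
    if (!is.null(weights)) args$weights <- weights
    # keep the call head symbolic: nlsLM's match.call() handling chokes on
    # an inlined closure (as do.call(minpack.lm::nlsLM, ...) would produce)
    cl <- as.call(c(quote(minpack.lm::nlsLM), args))
    tryCatch(eval(cl, envir = env), error = function(e) e)
  }
  fit <- try_one(start, bounded = TRUE)
  if (inherits(fit, "error")) fit <- try_one(start, bounded = FALSE)
  if (inherits(fit, "error")) {
    jig <- lapply(start, function(v) v * 1.07 + 0.01)
    fit <- try_one(jig, bounded = TRUE)
    if (inherits(fit, "error")) fit <- try_one(jig, bounded = FALSE)
  }
  if (inherits(fit, "error")) stop(conditionMessage(fit))
  fit
}
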