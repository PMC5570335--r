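# Subject-specific parameter estimation.
#
# Bounded trust-region nonlinear least squares (minpack.lm) on the residuals
# between simulated and measured perfusion, with a Latin-hypercube
# multi-start (5 LHS points plus the bound-box center) to guard against the
# non-convex objective surface.  Two schedules: the two-step healthy
# schedule (adenosine/arterial parameters from the long-cuff responses, ATP
# parameters from the short-cuff responses) and the one-step patient
# schedule (five free parameters on a single 2-min response, adenosine
# fixed at the healthy-group means).

#' Reduced chi-square of a fit
#'
#' `chi2_red = sum((model - data)^2) / (sigma2 * (N - n - 1))` with `sigma2`
#' the variance of the pre-cuff baseline perfusion samples, `N` the data
#' length and `n` the number of free parameters.
#'
#' @param model_f,data_f Perfusion series, mL/100mL/min.
#' @param sigma2 Baseline perfusion variance.
#' @param n_free Number of free parameters.
#' @return The reduced chi-square (non-negative scalar).
#' @export
rh_reduced_chisq <- function(model_f, data_f, sigma2, n_free) {
  N <- length(data_f)
  if (length(model_f) != N) stop("model and data series differ in length")
  if (N <= n_free + 1) stop("too few samples (N must exceed n_free + 1)")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  sum((model_f - data_f)^2) / sigma2 / (N - n_free - 1)
}

.trace_protocol <- function(trace) {
  prot <- attr(trace, "protocol")
  if (is.null(prot)) stop("trace lacks a protocol attribute")
  prot
}

# Pooled variance of the pre-cuff samples over one or more traces.
.baseline_sigma2 <- function(traces) {
  b <- unlist(lapply(traces, function(tr) tr$perfusion[tr$phase == "baseline"]))
  if (length(b) < 3) stop("too few baseline samples to estimate sigma2")
  stats::var(b)
}

# Model perfusion at the data's sample times for one trace.
.rh_model_f <- function(subject, trace, constants, rtol = 1e-7, atol = 1e-7) {
  prot <- .trace_protocol(trace)
  sim <- rh_simulate(subject, prot, constants, times = trace$time_s,
                     rtol = rtol, atol = atol)
  sim$perfusion[match(round(trace$time_s, 6), round(sim$time_s, 6))]
}

# Residual vector over all traces, given values for the free parameters.
.rh_residuals <- function(par, free, base, traces, constants) {
  sub <- base
  sub[free] <- as.list(par)
  sub <- do.call(rh_subject, sub)
  unlist(lapply(traces, function(tr) {
    mf <- tryCatch(.rh_model_f(sub, tr, constants),
                   error = function(e) rep(NA_real_, nrow(tr)))
    if (anyNA(mf)) rep(1e3, nrow(tr)) else mf - tr$perfusion
  }), use.names = FALSE)
}

# Multi-start bounded least squares over the named free parameters.
.rh_fit_ls <- function(traces, free, lower, upper, base, constants,
                       n_starts = 6, seed = 1, maxiter = 50) {
  k <- length(free)
  set.seed(seed)
  centers <- (lower + upper) / 2
  starts <- rbind(centers,
                  if (n_starts > 1)
                    sweep(sweep(lhs::randomLHS(n_starts - 1, k), 2,
                                upper - lower, "*"), 2, lower, "+"))
  colnames(starts) <- free

  best <- NULL
  n_used <- 0
  for (i in seq_len(nrow(starts))) {
    n_used <- n_used + 1
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = .rh_residuals, free = free, base = base,
                         traces = traces, constants = constants,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-10, ptol = 1e-8,
                           epsfcn = 1e-6)),   # FD step must exceed ODE-solver noise
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  list(par = best$par, deviance = best$deviance,
       converged = best$info %in% 1:4, n_restarts_used = n_used)
}

.rh_finalize_fit <- function(params, traces, constants, n_free, mode,
                             converged, n_restarts_used, extra = list()) {
  sub <- do.call(rh_subject, params)
  sigma2 <- .baseline_sigma2(traces)
  res <- lapply(traces, function(tr) {
    tibble::tibble(time_s = tr$time_s, data = tr$perfusion,
                   model = .rh_model_f(sub, tr, constants, 1e-8, 1e-8),
                   t_cuff = .trace_protocol(tr)$t_cuff)
  })
  res <- dplyr::bind_rows(res)
  chi2 <- rh_reduced_chisq(res$model, res$data, sigma2, n_free)
  structure(c(list(params = sub, chi2_red = chi2, sigma2 = sigma2,
                   residuals = res, n_free = n_free, n_obs = nrow(res),
                   converged = converged, n_restarts_used = n_restarts_used,
                   mode = mode, traces = traces, constants = constants),
              extra),
            class = "rh_fit")
}

#' Fit the cuffing-duration-varying responses of a healthy subject
#'
#' Two-step schedule.  Step 1 frees `f_r`, `g_ado`, `tau_ado`, `tau_p` (with
#' the ATP parameters fixed at the healthy-group means) against the 3- and
#' 5-min traces jointly; step 2 frees `f_r`, `g_atp`, `tau_atp` (with the
#' step-1 adenosine/arterial estimates fixed) against the 1- and/or 2-min
#' traces.  The objective is the unweighted concatenation of residuals over
#' the fitted traces; the healthy bounds of [rh_bounds()] apply.
#'
#' @param traces A list of perfusion traces (tibbles with `time_s`,
#'   `perfusion`, `phase` and a protocol attribute), one per cuff duration;
#'   must include the 3- and 5-min durations and at least one of 1-/2-min.
#' @param constants An [rh_constants()] list.
#' @param g_atp_fixed,tau_atp_fixed Values held fixed during step 1
#'   (healthy-group means by default).
#' @param n_starts Optimizer starts per step (Latin hypercube + box center).
#' @param seed Seed for the multi-start draw.
#' @return An object of class `"rh_fit"`; see [tidy.rh_fit()] and
#'   [glance.rh_fit()].
#' @export
rh_fit_healthy <- function(traces, constants = rh_constants(),
                           g_atp_fixed = 15.66, tau_atp_fixed = 15.86,
                           n_starts = 6, seed = 1) {
  durs <- vapply(traces, function(tr) .trace_protocol(tr)$t_cuff, numeric(1))
  long <- traces[durs %in% c(180, 300)]
  short <- traces[durs %in% c(60, 120)]
  if (length(long) < 2)
    stop("healthy fitting requires both the 3- and 5-min traces")
  if (length(short) < 1)
    stop("healthy fitting requires at least one 1- or 2-min trace")

  bounds <- rh_bounds("healthy")
  bnd <- function(pars) {
    i <- match(pars, bounds$param)
    list(lower = bounds$lower[i], upper = bounds$upper[i])
  }

  ## step 1: adenosine + arterial time constant from the long responses
  free1 <- c("f_r", "g_ado", "tau_ado", "tau_p")
  base1 <- unclass(rh_subject(g_atp = g_atp_fixed, tau_atp = tau_atp_fixed))
  b1 <- bnd(free1)
  s1 <- .rh_fit_ls(long, free1, b1$lower, b1$upper, base1, constants,
                   n_starts = n_starts, seed = seed)

  ## step 2: ATP parameters from the short responses
  free2 <- c("f_r", "g_atp", "tau_atp")
  base2 <- base1
  base2[free1] <- as.list(s1$par)
  b2 <- bnd(free2)
  s2 <- .rh_fit_ls(short, free2, b2$lower, b2$upper, base2, constants,
                   n_starts = n_starts, seed = seed + 1)

  params <- base2
  params[free2] <- as.list(s2$par)
  .rh_finalize_fit(params, c(long, short), constants, n_free = 6,
                   mode = "healthy",
                   converged = s1$converged && s2$converged,
                   n_restarts_used = s1$n_restarts_used + s2$n_restarts_used,
                   extra = list(step1 = s1, step2 = s2,
                                bounds = bounds))
}

#' Fit a patient's 2-min-cuff response
#'
#' One-step schedule: frees `f_r`, `g_atp`, `tau_atp`, `r_p_scale`, `tau_p`
#' under the patient bounds of [rh_bounds()], with the adenosine parameters
#' fixed at the healthy-group means.  A response with fewer than 4 samples
#' two baseline standard deviations above the baseline mean is flagged
#' `insufficient_response` (the five parameters are then poorly determined).
#'
#' @param trace A single 2-min-cuff perfusion trace.
#' @param constants An [rh_constants()] list.
#' @param g_ado_fixed,tau_ado_fixed Fixed adenosine parameters
#'   (healthy-group means by default).
#' @inheritParams rh_fit_healthy
#' @return An object of class `"rh_fit"` with an `insufficient_response`
#'   flag.
#' @export
rh_fit_patient <- function(trace, constants = rh_constants(),
                           g_ado_fixed = 4.18, tau_ado_fixed = 43.20,
                           n_starts = 6, seed = 1) {
  bounds <- rh_bounds("patient")
  free <- bounds$param
  base <- unclass(rh_subject(g_ado = g_ado_fixed, tau_ado = tau_ado_fixed))

  b <- trace$perfusion[trace$phase == "baseline"]
  post <- trace$perfusion[trace$phase == "recovery"]
  n_above <- sum(post > mean(b) + 2 * stats::sd(b))
  insufficient <- n_above < 4

  s <- .rh_fit_ls(list(trace), free, bounds$lower, bounds$upper, base,
                  constants, n_starts = n_starts, seed = seed)
  params <- base
  params[free] <- as.list(s$par)
  .rh_finalize_fit(params, list(trace), constants, n_free = 5,
                   mode = "patient", converged = s$converged,
                   n_restarts_used = s$n_restarts_used,
                   extra = list(insufficient_response = insufficient,
                                n_above_baseline = n_above, bounds = bounds))
}

#' @export
print.rh_fit <- function(x, ...) {
  cat("<rh_fit> mode=", x$mode, ", chi2_red=", format(x$chi2_red, digits = 4),
      ", N=", x$n_obs, ", n_free=", x$n_free,
      if (!x$converged) " (NOT converged)" else "", "\n", sep = "")
  if (isTRUE(x$insufficient_response))
    cat("  flagged: insufficient response (", x$n_above_baseline,
        " samples > 2 SD above baseline)\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Tidy a fitted reactive-hyperemia model
#'
#' @param x An `rh_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per subject parameter: `term`, `estimate`,
#'   `fixed` (logical), and the bounds applied to the free parameters.
#' @export
tidy.rh_fit <- function(x, ...) {
  est <- unlist(unclass(x$params))
  out <- tibble::tibble(term = names(est), estimate = unname(est))
  out$fixed <- !(out$term %in% x$bounds$param)
  out <- dplyr::left_join(out, x$bounds, by = c(term = "param"))
  out$at_bound <- !out$fixed &
    (abs(out$estimate - out$lower) < 1e-8 | abs(out$estimate - out$upper) < 1e-8)
  out
}

#' One-line fit summary
#'
#' @param x An `rh_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `chi2_red`, `sigma2`, `n_obs`, `n_free`,
#'   `converged`, `n_restarts_used` and (patients) the insufficient-response
#'   flag.
#' @export
glance.rh_fit <- function(x, ...) {
  tibble::tibble(chi2_red = x$chi2_red, sigma2 = x$sigma2, n_obs = x$n_obs,
                 n_free = x$n_free, converged = x$converged,
                 n_restarts_used = x$n_restarts_used,
                 insufficient_response = isTRUE(x$insufficient_response))
}
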