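## Simultaneous (global) nonlinear regression of a progress-curve family
## under a chosen binding scheme.  Rate constants are shared across all
## curves of the family; optimisation is Levenberg-Marquardt on
## log-transformed rates (tight-binding objectives are ill-conditioned
## and log-parameterisation both conditions the problem and prevents
## negative excursions).

free_param_names <- function(scheme, fixed) {
  nms <- c("k_on",
           if (scheme != "irreversible") "k_off",
           if (scheme == "two_step") c("k_isom_f", "k_isom_r"),
           "k_cat")
  setdiff(nms, names(fixed))
}

default_inits <- function(family, fixed) {
  # crude turnover estimate from the initial slope of the control curve
  ctrl <- family$curves[[which(family$design$inhibitor_concs == 0)[1]]]
  n0 <- max(3, ceiling(nrow(ctrl) * 0.1))
  v0 <- coef(stats::lm(signal ~ time_s, data = ctrl[seq_len(n0), ]))[2] /
    family$design$signal_coeff
  K_m <- if (!is.null(fixed$K_m)) fixed$K_m else 200e-6
  S_0 <- family$design$S_0
  k_cat0 <- as.numeric(v0) * (K_m + S_0) / (family$design$E_total * S_0)
  if (!is.finite(k_cat0) || k_cat0 <= 0) k_cat0 <- 10
  list(k_on = 1e5, k_off = 1e-3, k_isom_f = 1e-3, k_isom_r = 1e-3,
       k_cat = k_cat0)
}

build_params <- function(theta, scheme, fixed, K_m) {
  est <- as.list(exp(theta))
  full <- list(k_on = 0, k_off = 0, k_isom_f = 0, k_isom_r = 0,
               k_cat = 10, K_m = K_m)
  full[names(fixed)] <- fixed
  full[names(est)] <- est
  do.call(rate_parameters, full)
}

family_residuals <- function(theta, scheme, fixed, family, K_m,
                             rtol, atol) {
  n_tot <- sum(vapply(family$curves, nrow, 1L))
  # box on the log scale: rates outside [1e-10, 1e10] are unphysical and
  # only serve to blow up the integrator during line-search excursions
  excess <- sum(pmax(theta - log(1e10), 0) + pmax(log(1e-10) - theta, 0))
  if (excess > 0) return(rep(1e3 * (1 + excess), n_tot))
  params <- try(build_params(theta, scheme, fixed, K_m), silent = TRUE)
  if (inherits(params, "try-error"))
    return(rep(1e3, n_tot))
  des <- family$design
  parms <- scheme_parms(scheme, params)
  unlist(lapply(seq_along(family$curves), function(i) {
    cur <- family$curves[[i]]
    cond <- assay_conditions(des$E_total, des$inhibitor_concs[i], des$S_0,
                             times = cur$time_s, signal_coeff =
                               des$signal_coeff, baseline = des$baseline)
    out <- try(suppressWarnings(
      integrate_scheme(parms, cond, rtol, atol)), silent = TRUE)
    if (inherits(out, "try-error") || nrow(out) < length(cur$time_s))
      return(rep(1e3, nrow(cur)))
    pred <- des$baseline + des$signal_coeff * pmax(out[, "P"], 0)
    cur$signal - pred
  }), use.names = FALSE)
}

num_jacobian <- function(fn, theta, h = 1e-5) {
  r0 <- fn(theta)
  J <- matrix(NA_real_, length(r0), length(theta))
  for (j in seq_along(theta)) {
    tp <- tm <- theta
    tp[j] <- tp[j] + h
    tm[j] <- tm[j] - h
    J[, j] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  J
}

#' Global fit of a progress-curve family under one binding scheme
#'
#' Fits all curves of the family simultaneously: `k_on`, `k_off` (and
#' isomerisation rates for the two-step scheme) are shared across
#' curves, and the uninhibited velocity enters through the turnover
#' number `k_cat` fitted as one shared scale unless fixed.  Optimisation
#' is multi-start Levenberg-Marquardt ([minpack.lm::nls.lm]) on
#' log-transformed parameters, started from decade-spaced initial rate
#' guesses; standard errors come from the Gauss-Newton covariance
#' `(J'J)^-1 * rss/(n_obs - n_params)` mapped back to the natural scale.
#'
#' @param family a `curve_family` (at least two curves including an
#'   uninhibited control).
#' @param scheme one of [scheme_ids()].
#' @param fixed named list of parameters to hold fixed (any of `k_on`,
#'   `k_off`, `k_isom_f`, `k_isom_r`, `k_cat`, `K_m`).
#' @param init named list of starting values for the free parameters
#'   (defaults are heuristic: see Details).
#' @param n_starts number of decade-spaced starts (default 3).
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param rtol,atol integrator tolerances used inside the objective.
#' @return An object of class `fit_result`: list with `scheme`,
#'   `estimates`, `se` (natural scale), `rss`, `n_obs`, `n_params`,
#'   `covariance` (natural scale), `converged`, `identifiable`,
#'   `r_per_curve`, `fitted` (list of fitted signal vectors) and
#'   `log_estimates`.
#' @export
fit_family <- function(family, scheme, fixed = list(), init = NULL,
                       n_starts = 3, maxiter = 100,
                       rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(family, "curve_family"))
  scheme <- match_scheme(scheme)
  if (length(family$curves) < 2)
    stop("fit_family: need at least two curves")
  if (!any(family$design$inhibitor_concs == 0))
    stop("fit_family: family must include an uninhibited (I = 0) control")
  if (scheme == "irreversible" && "k_off" %in% names(fixed) &&
      fixed$k_off != 0)
    stop("irreversible scheme fixes k_off = 0")
  if (scheme == "irreversible") fixed$k_off <- 0

  K_m <- if (!is.null(fixed$K_m)) fixed$K_m else 200e-6
  fixed_rates <- fixed[setdiff(names(fixed), "K_m")]
  free <- free_param_names(scheme, fixed_rates)
  base_init <- default_inits(family, fixed)
  if (!is.null(init)) base_init[names(init)] <- init
  for (nm in free) if (!is.finite(base_init[[nm]]) || base_init[[nm]] <= 0)
    stop("fit_family: initial value for ", nm, " must be finite and positive")

  fn <- function(theta) family_residuals(theta, scheme, fixed_rates,
                                         family, K_m, rtol, atol)
  n_obs <- sum(vapply(family$curves, nrow, 1L))
  if (n_obs <= length(free))
    stop("fit_family: more parameters than observations")

  mults <- 10^seq(-1, 1, length.out = n_starts)
  best <- NULL
  for (m in mults) {
    th0 <- log(unlist(base_init[free]))
    rate_free <- intersect(free, c("k_on", "k_off"))
    th0[rate_free] <- th0[rate_free] + log(m)
    fit <- try(minpack.lm::nls.lm(
      par = th0, fn = fn,
      control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss_raw) {
      best <- fit
      best$rss_raw <- rss
    }
  }
  if (is.null(best)) stop("fit_family: all starts failed")

  theta <- best$par
  resid <- best$fvec
  rss <- sum(resid^2)
  p <- length(theta)
  converged <- best$info %in% 1:4 && best$niter < maxiter

  # Gauss-Newton covariance on the log scale, then delta method
  J <- num_jacobian(fn, theta)
  sigma2 <- rss / (n_obs - p)
  cov_log <- try(solve(crossprod(J)) * sigma2, silent = TRUE)
  identifiable <- !inherits(cov_log, "try-error") &&
    all(is.finite(cov_log))
  est <- exp(theta)
  if (identifiable) {
    cov_log <- (cov_log + t(cov_log)) / 2
    D <- diag(est, nrow = p)
    covariance <- D %*% cov_log %*% D
    dimnames(covariance) <- list(free, free)
    se <- sqrt(pmax(diag(covariance), 0))
  } else {
    warning("fit_family: singular covariance; fit flagged non-identifiable")
    covariance <- matrix(NA_real_, p, p, dimnames = list(free, free))
    se <- rep(NA_real_, p)
  }
  names(est) <- names(se) <- free

  # fitted signals and per-curve correlation coefficients
  params_hat <- build_params(theta, scheme, fixed_rates, K_m)
  des <- family$design
  parms_hat <- scheme_parms(scheme, params_hat)
  fitted <- lapply(seq_along(family$curves), function(i) {
    cond <- assay_conditions(des$E_total, des$inhibitor_concs[i], des$S_0,
                             times = family$curves[[i]]$time_s,
                             signal_coeff = des$signal_coeff,
                             baseline = des$baseline)
    out <- integrate_scheme(parms_hat, cond, rtol, atol)
    des$baseline + des$signal_coeff * pmax(out[, "P"], 0)
  })
  r_per_curve <- vapply(seq_along(fitted), function(i) {
    obs <- family$curves[[i]]$signal
    if (sd(obs) == 0 || sd(fitted[[i]]) == 0) return(NA_real_)
    cor(obs, fitted[[i]])
  }, 1)

  structure(list(scheme = scheme, estimates = est, se = se,
                 log_estimates = theta, rss = rss, n_obs = n_obs,
                 n_params = p, covariance = covariance,
                 converged = converged, identifiable = identifiable,
                 r_per_curve = r_per_curve, fitted = fitted,
                 fixed = fixed, K_m = K_m,
                 params = params_hat, niter = best$niter,
                 info = best$info),
            class = "fit_result")
}

#' Per-curve correlation between observed and fitted signals
#'
#' @param fit a [fit_family()] result.
#' @param family the fitted `curve_family`.
#' @return Numeric vector in `[-1, 1]`, one value per curve; `NA` for a
#'   constant observed curve (undefined correlation).
#' @export
curve_r <- function(fit, family) {
  stopifnot(inherits(fit, "fit_result"), inherits(family, "curve_family"))
  if (!fit$converged)
    warning("curve_r: fit did not converge; correlations may be meaningless")
  vapply(seq_along(family$curves), function(i) {
    obs <- family$curves[[i]]$signal
    pred <- fit$fitted[[i]]
    if (sd(obs) == 0 || sd(pred) == 0) return(NA_real_)
    cor(obs, pred)
  }, 1)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Global progress-curve fit (", x$scheme, " scheme)\n", sep = "")
  cat("  n_obs = ", x$n_obs, ", n_params = ", x$n_params,
      ", rss = ", format(x$rss, digits = 4),
      ", converged = ", x$converged, "\n", sep = "")
  tab <- data.frame(estimate = x$estimates, se = x$se)
  print(tab, digits = 4)
  invisible(x)
}
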