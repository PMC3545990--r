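## Binding schemes, their deterministic dynamics, and closed-form limit
## oracles for slow tight-binding inhibition with competitive substrate
## turnover.

#' Binding scheme identifiers
#'
#' The three candidate mechanisms for slow, tight-binding inhibition:
#' \describe{
#'   \item{`one_step`}{`E + I <-> EI` with rate constants `k_on`, `k_off`.}
#'   \item{`two_step`}{`E + I <-> EI <-> EI*`: initial encounter complex
#'     followed by first-order isomerisation (`k_isom_f`, `k_isom_r`) to a
#'     tightened complex.}
#'   \item{`irreversible`}{the one-step scheme with `k_off` fixed to 0.}
#' }
#'
#' @return Character vector of the three valid scheme identifiers.
#' @export
scheme_ids <- function() c("one_step", "two_step", "irreversible")

match_scheme <- function(scheme) {
  match.arg(scheme, scheme_ids())
}

#' Rate constants of a binding scheme plus substrate turnover constants
#'
#' @param k_on second-order association rate constant (M^-1 s^-1).
#' @param k_off first-order dissociation rate constant (s^-1).
#' @param k_isom_f,k_isom_r forward / reverse isomerisation rates (s^-1);
#'   used only by the `two_step` scheme.
#' @param k_cat substrate turnover number (s^-1).
#' @param K_m Michaelis constant of the chromogenic substrate (M).
#'
#' The substrate constants parameterise the competitive reporter
#' reaction; the default `K_m` = 200 uM and `k_cat` = 10 s^-1 are
#' representative of p-nitroanilide substrates.
#'
#' @return An object of class `rate_parameters`.
#' @export
rate_parameters <- function(k_on, k_off = 0, k_isom_f = 0, k_isom_r = 0,
                            k_cat = 10, K_m = 200e-6) {
  p <- list(k_on = k_on, k_off = k_off, k_isom_f = k_isom_f,
            k_isom_r = k_isom_r, k_cat = k_cat, K_m = K_m)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]))
      stop("rate_parameters: '", nm, "' must be a finite numeric scalar")
    if (p[[nm]] < 0)
      stop("rate_parameters: '", nm, "' must be non-negative")
  }
  if (p$K_m <= 0) stop("rate_parameters: K_m must be > 0")
  structure(p, class = "rate_parameters")
}

check_scheme_params <- function(scheme, params) {
  scheme <- match_scheme(scheme)
  stopifnot(inherits(params, "rate_parameters"))
  if (scheme == "irreversible" && params$k_off != 0)
    stop("irreversible scheme requires k_off = 0 (got ", params$k_off, ")")
  invisible(scheme)
}

#' Assay conditions for one progress curve
#'
#' @param E_total total enzyme concentration (M).
#' @param I_total total inhibitor concentration (M).
#' @param S_0 initial substrate concentration (M).
#' @param times strictly increasing sampling grid in seconds, starting at 0.
#' @param signal_coeff signal units per molar product (default 1: report
#'   product concentration directly).
#' @param baseline signal offset.
#'
#' @return An object of class `assay_conditions`.
#' @export
assay_conditions <- function(E_total, I_total, S_0 = 500e-6, times,
                             signal_coeff = 1, baseline = 0) {
  if (any(c(E_total, I_total, S_0) < 0))
    stop("assay_conditions: concentrations must be non-negative")
  times <- as.numeric(times)
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0))
    stop("assay_conditions: times must be strictly increasing and start at 0")
  structure(list(E_total = E_total, I_total = I_total, S_0 = S_0,
                 times = times, signal_coeff = signal_coeff,
                 baseline = baseline),
            class = "assay_conditions")
}

#' Species concentrations at one instant
#'
#' `E_free` is the enzyme bound to neither inhibitor nor (on the
#' rapid-equilibrium view of the reporter reaction) committed substrate;
#' the totals `E_free + EI + EI_star`, `I_free + EI + EI_star` and
#' `S + P` are conserved by the dynamics.
#'
#' @param E_free,I_free,EI,EI_star,S,P concentrations (M).
#' @return An object of class `assay_state` (named numeric vector).
#' @export
assay_state <- function(E_free, I_free, EI = 0, EI_star = 0, S, P = 0) {
  st <- c(E_free = E_free, I_free = I_free, EI = EI, EI_star = EI_star,
          S = S, P = P)
  if (any(!is.finite(st))) stop("assay_state: non-finite concentration")
  if (any(st < 0)) stop("invalid state: negative concentration")
  structure(st, class = c("assay_state", "numeric"))
}

## Parameter vector for the compiled ODE kernel; one-step and
## irreversible schemes have no isomerisation step.
scheme_parms <- function(scheme, params) {
  c(k_on = params$k_on, k_off = params$k_off,
    k_isom_f = if (scheme == "two_step") params$k_isom_f else 0,
    k_isom_r = if (scheme == "two_step") params$k_isom_r else 0,
    k_cat = params$k_cat, K_m = params$K_m)
}

## Low-level integration of the scheme dynamics (compiled RHS).
integrate_scheme <- function(parms, cond, rtol = 1e-8, atol = 1e-12) {
  y0 <- c(E_free = cond$E_total, I_free = cond$I_total, EI = 0,
          EI_star = 0, S = cond$S_0, P = 0)
  out <- deSolve::lsoda(y = y0, times = cond$times, func = "st_derivs",
                        parms = parms, dllname = "slowtight",
                        initfunc = "st_initparms",
                        rtol = rtol, atol = atol)
  colnames(out) <- c("time", names(y0))
  out
}

## Raw derivative kernel shared by scheme_rhs() and the integrator oracle.
scheme_deriv <- function(scheme, params, y) {
  with(as.list(c(y, unclass(params))), {
    protect <- K_m / (K_m + S)       # competitive substrate protection
    bind  <- k_on * E_free * I_free * protect
    unbind <- k_off * EI
    isom_f <- if (scheme == "two_step") k_isom_f * EI      else 0
    isom_r <- if (scheme == "two_step") k_isom_r * EI_star else 0
    v <- k_cat * E_free * S / (K_m + S)
    c(E_free  = -bind + unbind,
      I_free  = -bind + unbind,
      EI      =  bind - unbind - isom_f + isom_r,
      EI_star =  isom_f - isom_r,
      S       = -v,
      P       =  v)
  })
}

#' Time derivatives of the assay state under a binding scheme
#'
#' The dynamics treat the chromogenic reporter reaction as a
#' quasi-steady-state Michaelis-Menten flux, `dP/dt =
#' k_cat * E_free * S/(K_m + S)`, competing with inhibitor binding: the
#' association term carries the protection factor `K_m/(K_m + S)` so that
#' the apparent approach rate in the excess-inhibitor limit is
#' `k_off + k_on * I/(1 + S/K_m)` (see [kobs_one_step()]).
#'
#' @param scheme one of [scheme_ids()].
#' @param params a [rate_parameters()] object.
#' @param state an [assay_state()] (or named numeric with the same fields).
#' @return Named numeric vector of derivatives (M/s) over the state fields.
#' @export
scheme_rhs <- function(scheme, params, state) {
  scheme <- check_scheme_params(scheme, params)
  if (any(state < 0)) stop("invalid state: negative concentration")
  need <- c("E_free", "I_free", "EI", "EI_star", "S", "P")
  if (!all(need %in% names(state)))
    stop("state must carry fields: ", paste(need, collapse = ", "))
  scheme_deriv(scheme, params, unclass(state)[need])
}

#' Simulate a progress curve by numerical integration
#'
#' Integrates the scheme dynamics with a stiff-capable solver
#' (`deSolve::lsoda`, rtol 1e-8, atol 1e-12 M -- nanomolar species with
#' second-order terms make the system stiff) and returns product
#' concentration and signal on the requested time grid.
#'
#' @param scheme one of [scheme_ids()].
#' @param params a [rate_parameters()] object.
#' @param cond an [assay_conditions()] object.
#' @param rtol,atol integrator tolerances.
#' @return A data frame of class `progress_curve` with columns `time_s`,
#'   `product_M` and `signal`; the full species trajectory is attached as
#'   attribute `states`.
#' @export
simulate_progress <- function(scheme, params, cond, rtol = 1e-8, atol = 1e-12) {
  scheme <- check_scheme_params(scheme, params)
  stopifnot(inherits(cond, "assay_conditions"))
  out <- integrate_scheme(scheme_parms(scheme, params), cond, rtol, atol)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("integrator failed to converge (istate = ", diagn[1], ")")
  out <- as.data.frame(out)
  if (nrow(out) < length(cond$times))
    stop("integrator failed to reach the end of the time grid (",
         nrow(out), "/", length(cond$times), " points)")
  # guard against tolerance-level negative excursions
  P <- pmax(out$P, 0)
  curve <- data.frame(time_s = out$time, product_M = P,
                      signal = cond$baseline + cond$signal_coeff * P)
  attr(curve, "states") <- out
  attr(curve, "scheme") <- scheme
  attr(curve, "conditions") <- cond
  class(curve) <- c("progress_curve", "data.frame")
  curve
}

#' Apparent first-order approach rate in the excess-inhibitor limit
#'
#' Standard competitive slow-binding result used as the closed-form
#' oracle for the one-step scheme when inhibitor depletion is negligible:
#' `k_obs = k_off + k_on * I / (1 + S/K_m)`.
#'
#' @param params a [rate_parameters()] object.
#' @param I free inhibitor concentration (M).
#' @param S substrate concentration (M).
#' @return Apparent rate (s^-1), always `>= k_off`.
#' @export
kobs_one_step <- function(params, I, S = 0) {
  stopifnot(inherits(params, "rate_parameters"), I >= 0, S >= 0)
  params$k_off + params$k_on * I / (1 + S / params$K_m)
}

#' Closed-form slow-binding progress curve
#'
#' The classical biphasic form `P(t) = vs*t + (v0 - vs) * (1 -
#' exp(-k_obs*t)) / k_obs`: initial velocity `v0` relaxing to steady-state
#' velocity `vs` with apparent rate `k_obs`.  For `k_obs = 0` the limit
#' form `v0 * t` is returned.
#'
#' @param v0,vs initial and steady-state velocities (M/s).
#' @param k_obs apparent first-order rate (s^-1).
#' @param times sampling times (s).
#' @return Product concentrations (M) at `times`.
#' @export
morrison_walsh_curve <- function(v0, vs, k_obs, times) {
  stopifnot(k_obs >= 0, v0 >= 0, vs >= 0)
  if (k_obs == 0) return(v0 * times)
  vs * times + (v0 - vs) * (1 - exp(-k_obs * times)) / k_obs
}

#' Check mass-conservation of a simulated progress curve
#'
#' @param curve a [simulate_progress()] result.
#' @return Maximum relative conservation error over enzyme, inhibitor and
#'   substrate totals at all output times.
#' @export
conservation_error <- function(curve) {
  st <- attr(curve, "states")
  cond <- attr(curve, "conditions")
  stopifnot(!is.null(st), !is.null(cond))
  rel <- function(x, tot) if (tot > 0) max(abs(x - tot)) / tot else max(abs(x))
  max(rel(st$E_free + st$EI + st$EI_star, cond$E_total),
      rel(st$I_free + st$EI + st$EI_star, cond$I_total),
      rel(st$S + st$P, cond$S_0))
}
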