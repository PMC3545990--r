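## Model discrimination (small-sample Akaike weights + variance-ratio F
## test), derived inhibition constants with propagated uncertainty, and
## the summary report.

#' Compare scheme fits on the same family by small-sample AICc
#'
#' `AICc = n*ln(rss/n) + 2p + 2p(p+1)/(n-p-1)` per fit; Akaike weights
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)`.  When exactly two
#' nested fits are supplied the variance-ratio test
#' ([variance_ratio_test()]) is run on the pair, and a scheme is
#' selected: the simpler model is preferred unless the complex model
#' both carries Akaike weight > 0.5 and rejects the simple one at
#' `p < alpha`.
#'
#' @param fits named (by scheme) or unnamed list of [fit_family()]
#'   results on the same data (identical `n_obs`).
#' @param alpha significance level for the F test (default 0.05).
#' @return An object of class `model_comparison`: data frame `table`
#'   (scheme, n_params, rss, AICc, delta, weight), the F test (for a
#'   nested pair), and `selected`.
#' @export
akaike_compare <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, TRUE, "fit_result")))
  n <- vapply(fits, function(f) f$n_obs, 1)
  if (length(unique(n)) != 1)
    stop("akaike_compare: fits must be on the same data (equal n_obs)")
  n <- n[1]
  schemes <- vapply(fits, function(f) f$scheme, "")
  p <- vapply(fits, function(f) f$n_params, 1)
  rss <- vapply(fits, function(f) f$rss, 1)
  aicc <- n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tab <- data.frame(scheme = schemes, n_params = p, rss = rss,
                    AICc = aicc, delta = delta, weight = w,
                    row.names = NULL, stringsAsFactors = FALSE)

  ftest <- NULL
  selected <- schemes[which.min(p)]
  if (length(fits) == 2) {
    o <- order(p)
    simple <- fits[[o[1]]]
    complex <- fits[[o[2]]]
    if (complex$n_params > simple$n_params) {
      ftest <- variance_ratio_test(simple, complex)
      w_complex <- tab$weight[tab$scheme == complex$scheme]
      selected <- if (w_complex > 0.5 && ftest$p_value < alpha)
        complex$scheme else simple$scheme
    }
  }
  structure(list(table = tab, f_test = ftest, selected = selected,
                 alpha = alpha),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, digits = 4)
  if (!is.null(x$f_test))
    cat(sprintf("F(%d, %d) = %.4g, p = %.4g\n", x$f_test$df1, x$f_test$df2,
                x$f_test$F, x$f_test$p_value))
  cat("selected scheme:", x$selected, "\n")
  invisible(x)
}

#' Variance-ratio (F) test between nested scheme fits
#'
#' `F = ((rss1 - rss2)/(p2 - p1)) / (rss2/(n - p2))` with `(p2 - p1,
#' n - p2)` degrees of freedom; `rss2 > rss1` (complex fit worse) clamps
#' F at 0 with a warning.
#'
#' @param fit_simple,fit_complex nested [fit_family()] results on the
#'   same data; `fit_complex` must have more free parameters.
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
variance_ratio_test <- function(fit_simple, fit_complex) {
  stopifnot(inherits(fit_simple, "fit_result"),
            inherits(fit_complex, "fit_result"))
  if (fit_simple$n_obs != fit_complex$n_obs)
    stop("variance_ratio_test: fits must share the same data")
  p1 <- fit_simple$n_params
  p2 <- fit_complex$n_params
  if (p2 <= p1)
    stop("variance_ratio_test: the complex fit must have more parameters")
  n <- fit_simple$n_obs
  num <- (fit_simple$rss - fit_complex$rss) / (p2 - p1)
  den <- fit_complex$rss / (n - p2)
  Fstat <- num / den
  if (Fstat < 0) {
    warning("complex fit has larger rss; F clamped at 0")
    Fstat <- 0
  }
  list(F = Fstat, df1 = p2 - p1, df2 = n - p2,
       p_value = pf(Fstat, p2 - p1, n - p2, lower.tail = FALSE))
}

#' Inhibition constant with propagated uncertainty
#'
#' `Ki = k_off/k_on`; its coefficient of variation is the square root of
#' the sum of squares of the CVs of the two rate constants, and
#' `se = Ki * cv`.  A zero `k_off` flags apparently irreversible
#' inhibition (`Ki = 0`, `se = 0`).
#'
#' @param k_on,k_off rate constants (M^-1 s^-1, s^-1).
#' @param k_on_se,k_off_se their standard errors.
#' @return List with `K_i` (M), `K_i_se`, `cv` and `irreversible`.
#' @export
ki_with_error <- function(k_on, k_on_se, k_off, k_off_se) {
  if (k_on <= 0) stop("ki_with_error: k_on must be positive")
  if (k_off == 0)
    return(list(K_i = 0, K_i_se = 0, cv = 0, irreversible = TRUE))
  cv <- sqrt((k_on_se / k_on)^2 + (k_off_se / k_off)^2)
  K_i <- k_off / k_on
  list(K_i = K_i, K_i_se = K_i * cv, cv = cv, irreversible = FALSE)
}

#' Association and dissociation half-lives
#'
#' `t_half_on = ln(2)/(k_on * I_ref)` in seconds at a reference inhibitor
#' concentration (default 1 uM); `t_half_off = ln(2)/k_off` reported in
#' minutes.  For irreversible inhibition (`k_off = 0`) the dissociation
#' half-life is undefined and returned as `NA`.
#'
#' @param k_on,k_off rate constants.
#' @param reference_I reference inhibitor concentration (M).
#' @return List with `t_half_on_s`, `t_half_off_min`, `reference_I`.
#' @export
half_lives <- function(k_on, k_off, reference_I = 1e-6) {
  if (reference_I <= 0) stop("half_lives: reference_I must be positive")
  if (k_on <= 0) stop("half_lives: k_on must be positive")
  list(t_half_on_s = log(2) / (k_on * reference_I),
       t_half_off_min = if (k_off > 0) log(2) / k_off / 60 else NA_real_,
       reference_I = reference_I)
}

#' Full inhibition summary for one enzyme/inhibitor pair
#'
#' @param k_on,k_on_se,k_off,k_off_se rate constants and SEs.
#' @param reference_I reference inhibitor concentration for the
#'   association half-life (M).
#' @param enzyme,inhibitor optional labels.
#' @return Object of class `inhibition_summary` combining
#'   [ki_with_error()] and [half_lives()] with the input rates.
#' @export
inhibition_summary <- function(k_on, k_on_se, k_off, k_off_se,
                               reference_I = 1e-6,
                               enzyme = NA_character_,
                               inhibitor = NA_character_) {
  ki <- ki_with_error(k_on, k_on_se, k_off, k_off_se)
  th <- half_lives(k_on, k_off, reference_I)
  structure(c(list(enzyme = enzyme, inhibitor = inhibitor,
                   k_on = k_on, k_on_se = k_on_se,
                   k_off = k_off, k_off_se = k_off_se),
              ki, th),
            class = "inhibition_summary")
}

#' @param fit a converged [fit_family()] result.
#' @rdname inhibition_summary
#' @export
summary_from_fit <- function(fit, reference_I = 1e-6,
                             enzyme = NA_character_,
                             inhibitor = NA_character_) {
  stopifnot(inherits(fit, "fit_result"))
  k_off <- if ("k_off" %in% names(fit$estimates))
    fit$estimates[["k_off"]] else 0
  k_off_se <- if ("k_off" %in% names(fit$se)) fit$se[["k_off"]] else 0
  inhibition_summary(fit$estimates[["k_on"]], fit$se[["k_on"]],
                     k_off, k_off_se, reference_I, enzyme, inhibitor)
}

#' Selectivity (fold) ratios between inhibition summaries
#'
#' Pairwise ratios of `Ki` (or dissociation half-life) between the
#' supplied summaries: entry `[i, j]` is `value_i / value_j`.  Division
#' by a zero `Ki` (irreversible comparator) yields `Inf` and is flagged
#' with a warning.
#'
#' @param summaries named list of [inhibition_summary()] objects.
#' @param what `"K_i"` (default) or `"t_half_off_min"`.
#' @return Square matrix of fold ratios.
#' @export
selectivity_ratios <- function(summaries, what = c("K_i", "t_half_off_min")) {
  what <- match.arg(what)
  stopifnot(length(summaries) >= 2,
            all(vapply(summaries, inherits, TRUE, "inhibition_summary")))
  v <- vapply(summaries, function(s) as.numeric(s[[what]]), 1)
  if (any(v == 0, na.rm = TRUE))
    warning("selectivity_ratios: zero ", what,
            " (irreversible comparator); ratios against it are Inf")
  m <- outer(v, v, "/")
  dimnames(m) <- list(names(summaries), names(summaries))
  m
}

#' Scheme discrimination with the irreversible-refit rule
#'
#' Fits the one-step and two-step schemes to a family, compares them by
#' Akaike weight and F test, and -- when the selected reversible fit has
#' `cv(k_off)` above `cv_threshold` (poorly determined dissociation, the
#' hallmark of apparently irreversible inhibition) -- refits with
#' `k_off` fixed at 0 and re-compares one-step versus irreversible.
#'
#' @param family a `curve_family`.
#' @param fixed,init,n_starts passed to [fit_family()].
#' @param cv_threshold relative-error trigger for the irreversible refit
#'   (default 1, i.e. cv(k_off) > 100%).
#' @param alpha F-test significance level.
#' @return List with `fits` (by scheme), `comparison` (one vs two step),
#'   optional `comparison_irreversible`, and `selected`.
#' @export
discriminate_schemes <- function(family, fixed = list(), init = NULL,
                                 n_starts = 3, cv_threshold = 1,
                                 alpha = 0.05) {
  f1 <- fit_family(family, "one_step", fixed = fixed, init = init,
                   n_starts = n_starts)
  f2 <- fit_family(family, "two_step", fixed = fixed, init = init,
                   n_starts = n_starts)
  cmp <- akaike_compare(list(f1, f2), alpha = alpha)
  fits <- list(one_step = f1, two_step = f2)
  selected <- cmp$selected
  cmp_irr <- NULL
  sel_fit <- fits[[selected]]
  koff_cv <- if ("k_off" %in% names(sel_fit$estimates))
    sel_fit$se[["k_off"]] / sel_fit$estimates[["k_off"]] else Inf
  if (!is.finite(koff_cv) || koff_cv > cv_threshold) {
    firr <- fit_family(family, "irreversible", fixed = fixed, init = init,
                       n_starts = n_starts)
    fits$irreversible <- firr
    # one_step is the complex model of this nested pair (extra k_off)
    cmp_irr <- akaike_compare(list(firr, f1), alpha = alpha)
    selected <- cmp_irr$selected
  }
  list(fits = fits, comparison = cmp,
       comparison_irreversible = cmp_irr, selected = selected)
}

#' Tabulate inhibition summaries in report shape
#'
#' @param summaries named list of [inhibition_summary()] objects; names
#'   become the columns.
#' @return Data frame with rows `K_i_nM`, `k_on`, `k_off`,
#'   `t_half_on_s`, `t_half_off_min` and one column per summary.
#' @export
inhibition_report <- function(summaries) {
  stopifnot(all(vapply(summaries, inherits, TRUE, "inhibition_summary")))
  cols <- lapply(summaries, function(s)
    c(K_i_nM = s$K_i * 1e9, k_on = s$k_on, k_off = s$k_off,
      t_half_on_s = s$t_half_on_s, t_half_off_min = s$t_half_off_min))
  as.data.frame(cols, check.names = FALSE)
}
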