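# shared kinetics fixtures: Table-style rate sets and small families

rates_for <- function(enzyme, inhibitor = "textilinin-1") {
  rr <- reference_rates()
  row <- rr[rr$enzyme == enzyme & rr$inhibitor == inhibitor, ]
  rate_parameters(k_on = row$k_on, k_off = row$k_off)
}

# a design at coarser sampling than the 1 s default, for fast fits
small_design <- function(name = "plasmin", dt = 10, duration = 1800) {
  builtin_designs(duration = duration, dt = dt)[[name]]
}

fake_fit <- function(rss, n_obs, n_params, scheme = "one_step") {
  structure(list(scheme = scheme, rss = rss, n_obs = n_obs,
                 n_params = n_params, estimates = c(k_on = 1), se = c(k_on = 0)),
            class = "fit_result")
}
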