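# deterministic daily fixture: constant or supplied temperatures/deaths
make_daily <- function(n_days, start = "1949-10-02", tmean = 10,
                       deaths = 3L, flu = NULL) {
  out <- data.frame(date = as.Date(start) + 0:(n_days - 1),
                    tmean = rep_len(tmean, n_days),
                    deaths_all = rep_len(deaths, n_days))
  if (!is.null(flu)) out$deaths_flu <- rep_len(flu, n_days)
  out
}

# small synthetic expectation-mode series under a given harvesting truth
sim_expectation <- function(beta_cold = 0.02, beta_heat = 0.013, f = 0,
                            D = 60, n_years = 57, b0 = 170, seed = 1,
                            trend = NULL, flu = NULL, lag_cold = 14,
                            lag_heat = 3) {
  set.seed(seed)
  temps <- simulate_temperature(temp_sim_config(n_years = n_years))
  simulate_mortality(temps, mort_sim_config(
    b0 = b0, trend = trend, flu = flu,
    harvest = harvest_config(beta_cold = beta_cold, beta_heat = beta_heat,
                             lag_cold = lag_cold, lag_heat = lag_heat,
                             f = f, D = D),
    expectation = TRUE))
}

pct_of <- function(fit, term, col = "pct") fit$percent[[col]][fit$percent$term == term]

# n-row intercept-only design
icol <- function(n) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
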