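# Independent oracles used by the tests. These are written directly
# from the textbook definitions and never call the package's fitting
# code.

# Efron partial log-likelihood, evaluated for a vector of beta values.
oracle_efron_loglik <- function(beta_grid, x, time, status) {
  ll <- numeric(length(beta_grid))
  ex <- exp(outer(x, beta_grid)) # n x G
  for (t in unique(time[status == 1])) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    sR <- colSums(ex[R, , drop = FALSE])
    sD <- colSums(ex[D, , drop = FALSE])
    ll <- ll + colSums(outer(x[D], beta_grid))
    for (l in 0:(d - 1)) {
      ll <- ll - log(sR - (l / d) * sD)
    }
  }
  ll
}

# Brute-force grid maximizer of the Efron partial likelihood.
oracle_cox_beta <- function(x, time, status, lo = -3, hi = 3, by = 1e-4) {
  grid <- seq(lo, hi, by = by)
  grid[which.max(oracle_efron_loglik(grid, x, time, status))]
}

# small dense feature-by-sample matrix with names
named_matrix <- function(values, nr, nc, prefix_f = "f", prefix_s = "s") {
  matrix(values, nr, nc,
         dimnames = list(sprintf("%s%02d", prefix_f, seq_len(nr)),
                         sprintf("%s%02d", prefix_s, seq_len(nc))))
}

# tiny survival cohort with planted signal for risk-model tests
small_surv_cohort <- function(n = 40, p = 60, n_hazard = 4, seed = 11,
                              noise_sd = 1) {
  co <- simulate_survival_cohort(
    sim_config(n_cancer = n, n_normal = 0L, n_features = p,
               n_replicates_per_feature = 2L,
               n_hazard_features = n_hazard, hazard_log_effect = 1,
               noise_sd = noise_sd, seed = seed))
  x <- collapse_replicates(co$expression, co$probe_map)
  list(x = x, ttp = co$clinical$ttp_months, event = co$clinical$event,
       truth = co$truth, cohort = co)
}
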