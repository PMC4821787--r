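# Small fixtures built in code.

# Complete bivariate dataset with known within-study correlations.
complete_data <- function(m = 10, seed = 101, rho_b = 0.5, rho_w = 0.5,
                          tau2 = 0.5, beta = c(0, 2)) {
  withr::local_seed(seed)
  cfg <- sim_config(m = m, beta = beta, tau2 = tau2, n_reps = 1)
  generate_meta_data(cfg, rho_b, rho_w)
}

# Dataset with MCAR-deleted outcomes.
mcar_data <- function(m = 10, seed = 202, rho_b = 0.5, rho_w = 0.5,
                      tau2 = 0.5, missing_frac = 0.3) {
  withr::local_seed(seed)
  cfg <- sim_config(m = m, tau2 = tau2, missing_frac = missing_frac,
                    n_reps = 1)
  repeat {
    d <- generate_meta_data(cfg, rho_b, rho_w)
    rs <- reporting_sets(d)
    if (rs$m1 >= 2 && rs$m2 >= 2 && length(rs$r12) >= 2) return(d)
  }
}

# Brute-force inverse-variance weighted mean and Q, written independently
# of the package internals (explicit loops).
oracle_q <- function(y, s2) {
  num <- 0; den <- 0
  for (i in seq_along(y)) {
    num <- num + y[i] / s2[i]
    den <- den + 1 / s2[i]
  }
  yb <- num / den
  Q <- 0
  for (i in seq_along(y)) Q <- Q + (y[i] - yb)^2 / s2[i]
  Q
}

oracle_dl_tau2 <- function(y, s2) {
  m <- length(y)
  Q <- oracle_q(y, s2)
  S1 <- sum(1 / s2); S2 <- sum(1 / s2^2)
  max(0, (Q - (m - 1)) / (S1 - S2 / S1))
}
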