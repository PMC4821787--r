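test_that("multivariate Q statistics match hand cases and a loop oracle", {
  # zero residuals within each outcome
  d <- tibble::tibble(y1 = c(0.4, 0.4), s1 = c(0.3, 0.3),
                      y2 = c(1.1, 1.1), s2 = c(0.5, 0.5),
                      rho_w = c(0, 0))
  qv <- q_vector(d)
  expect_equal(c(qv$Q1, qv$Q12, qv$Q2), c(0, 0, 0))

  # symmetric two-study case with unit standard errors
  d2 <- tibble::tibble(y1 = c(0, 2), s1 = c(1, 1),
                       y2 = c(0, 2), s2 = c(1, 1), rho_w = c(0, 0))
  qv <- q_vector(d2)
  expect_equal(qv$Q1, 2)
  expect_equal(qv$Q2, 2)
  expect_equal(qv$Q12, 2)

  # simulated incomplete dataset vs explicit summation
  d3 <- mcar_data(m = 10, seed = 21)
  qv <- q_vector(d3)
  r1 <- which(!is.na(d3$y1)); r2 <- which(!is.na(d3$y2))
  r12 <- intersect(r1, r2)
  expect_equal(qv$Q1, oracle_q(d3$y1[r1], d3$s1[r1]^2))
  expect_equal(qv$Q2, oracle_q(d3$y2[r2], d3$s2[r2]^2))
  u <- 1 / (d3$s1[r12] * d3$s2[r12])
  yb1 <- sum(d3$y1[r12] * u) / sum(u)
  yb2 <- sum(d3$y2[r12] * u) / sum(u)
  expect_equal(qv$Q12, sum(u * (d3$y1[r12] - yb1) * (d3$y2[r12] - yb2)))
})

test_that("moment equations reproduce DL variances and the (Q12-a)/b solution", {
  d <- mcar_data(m = 25, seed = 63)
  qv <- q_vector(d)
  om <- solve_omega(qv, d)
  r1 <- which(!is.na(d$y1)); r2 <- which(!is.na(d$y2))
  expect_identical(om$tau1_2, dl_tau2(d$y1[r1], d$s1[r1]^2))
  expect_identical(om$tau2_2, dl_tau2(d$y2[r2], d$s2[r2]^2))

  # a and b recomputed by an explicit loop
  r12 <- intersect(r1, r2)
  a <- 0; su <- 0; su2 <- 0; sru <- 0
  for (i in r12) {
    u <- 1 / (d$s1[i] * d$s2[i])
    su <- su + u; su2 <- su2 + u^2; sru <- sru + d$rho_w[i] * u
  }
  a <- sum(d$rho_w[r12]) - sru / su
  b <- su - su2 / su
  expect_equal(om$a_coef, a, tolerance = 1e-10)
  expect_equal(om$b_coef, b, tolerance = 1e-10)
  expect_equal(om$cov_B, (qv$Q12 - a) / b, tolerance = 1e-10)
})

test_that("zero within-study correlation with Q12 = a gives zero covariance", {
  # two symmetric studies, rho_w = 0: a = 0; construct y so Q12 = 0
  d <- tibble::tibble(y1 = c(0, 2), s1 = c(1, 1),
                      y2 = c(1, 1), s2 = c(1, 1), rho_w = c(0, 0))
  om <- solve_omega(q_vector(d), d)
  expect_equal(om$cov_B, 0)
})

test_that("omega estimate is PSD with correlation in [-1, 1] after truncation", {
  withr::local_seed(12)
  cfg <- sim_config(m = 8, tau2 = 0.5, n_reps = 1)
  n_trunc <- 0
  for (r in 1:60) {
    d <- generate_meta_data(cfg, 0.8, 0.8)
    om <- solve_omega(q_vector(d), d)
    ev <- eigen(om$omega, symmetric = TRUE)$values
    expect_gte(min(ev), -1e-12)
    if (om$omega[1, 1] > 0 && om$omega[2, 2] > 0) {
      rho <- om$omega[1, 2] / sqrt(om$omega[1, 1] * om$omega[2, 2])
      expect_lte(abs(rho), 1 + 1e-12)
    }
    n_trunc <- n_trunc + om$truncated
  }
  expect_gt(n_trunc, 0)  # truncation does occur at strong correlations
})

test_that("GLS pooling reduces to univariate fixed-effect means when decoupled", {
  d <- complete_data(m = 8, rho_w = 0)
  fit <- blue_pool(d, matrix(0, 2, 2))
  f1 <- fit_univariate(d, 1, model = "fixed")
  f2 <- fit_univariate(d, 2, model = "fixed")
  expect_equal(unname(fit$beta), c(f1$beta, f2$beta))
  expect_equal(sqrt(diag(fit$sigma)), c(f1$se, f2$se))
})

test_that("GLS pooling handles a single study and matches a stacked GLS oracle", {
  d1 <- tibble::tibble(y1 = 0.4, s1 = 0.3, y2 = 1.2, s2 = 0.5, rho_w = 0.4)
  omega <- matrix(c(0.5, 0.2, 0.2, 0.5), 2, 2)
  fit <- blue_pool(d1, omega)
  expect_equal(unname(fit$beta), c(0.4, 1.2))
  delta1 <- matrix(c(0.09, 0.3 * 0.5 * 0.4, 0.3 * 0.5 * 0.4, 0.25), 2, 2)
  expect_equal(fit$sigma, omega + delta1)

  # stacked 2m x 2 weighted least squares oracle
  d <- complete_data(m = 10, rho_w = 0.5)
  om <- solve_omega(q_vector(d), d)
  fit <- blue_pool(d, om$omega)
  m <- nrow(d)
  X <- kronecker(rep(1, m), diag(2))
  V <- matrix(0, 2 * m, 2 * m)
  for (i in 1:m) {
    di <- matrix(c(d$s1[i]^2, d$s1[i] * d$s2[i] * d$rho_w[i],
                   d$s1[i] * d$s2[i] * d$rho_w[i], d$s2[i]^2), 2, 2)
    V[(2 * i - 1):(2 * i), (2 * i - 1):(2 * i)] <- di + om$omega
  }
  y <- as.vector(rbind(d$y1, d$y2))
  Vi <- solve(V)
  sigma <- solve(t(X) %*% Vi %*% X)
  beta <- drop(sigma %*% t(X) %*% Vi %*% y)
  expect_equal(unname(fit$beta), beta, tolerance = 1e-10)
  expect_equal(fit$sigma, sigma, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("with rho_w = 0 and diagonal omega the fit decouples into DL margins", {
  d <- complete_data(m = 12, rho_w = 0)
  f1 <- fit_univariate(d, 1); f2 <- fit_univariate(d, 2)
  fit <- blue_pool(d, diag(c(f1$tau2, f2$tau2)))
  expect_equal(unname(fit$beta), c(f1$beta, f2$beta), tolerance = 1e-12)
  expect_equal(sqrt(diag(fit$sigma)), c(f1$se, f2$se), tolerance = 1e-12)
})

test_that("missing rho_w in the overlap and degenerate overlaps raise errors", {
  d <- complete_data(m = 6)
  d$rho_w <- NA_real_
  expect_error(fit_jackson(d), "rho_w")
  # single-study overlap: the moment coefficient b vanishes
  d2 <- tibble::tibble(y1 = c(0.1, 0.4, NA), s1 = c(0.5, 0.4, NA),
                       y2 = c(1.9, NA, 2.2), s2 = c(0.5, NA, 0.4),
                       rho_w = c(0.3, NA, NA))
  expect_error(fit_jackson(d2), "unidentified")
})

test_that("empty overlap yields a diagonal omega with a flag", {
  d <- tibble::tibble(y1 = c(0.1, 0.3, NA, NA), s1 = c(0.5, 0.4, NA, NA),
                      y2 = c(NA, NA, 2.0, 2.2), s2 = c(NA, NA, 0.3, 0.4))
  om <- solve_omega(q_vector(d), d)
  expect_true(om$r12_empty)
  expect_equal(om$cov_B, 0)
  expect_equal(om$omega[1, 2], 0)
})
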