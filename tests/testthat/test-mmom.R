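test_that("pooled-estimate covariance matches hand computation and a loop oracle", {
  # disjoint reporting sets: the pooled estimates are independent
  d <- tibble::tibble(y1 = c(0.1, 0.3, NA, NA), s1 = c(0.5, 0.4, NA, NA),
                      y2 = c(NA, NA, 2.0, 2.2), s2 = c(NA, NA, 0.3, 0.4))
  f1 <- fit_univariate(d, 1); f2 <- fit_univariate(d, 2)
  expect_equal(mmom_cov(d, f1, f2), 0)
  ff <- fit_mmom(d)
  expect_equal(ff$sigma[1, 2], 0)

  # symmetric two-study case: residuals (1,-1) on both outcomes, equal
  # weights, cov = 1/4 + 1/4 = 0.5
  d2 <- tibble::tibble(y1 = c(1, -1), s1 = c(1, 1),
                       y2 = c(1, -1), s2 = c(1, 1))
  f1 <- fit_univariate(d2, 1, model = "fixed")
  f2 <- fit_univariate(d2, 2, model = "fixed")
  expect_equal(mmom_cov(d2, f1, f2), 0.5)

  # 10-study simulated dataset vs explicit term-by-term loop over the overlap
  d3 <- mcar_data(m = 10, seed = 33)
  f1 <- fit_univariate(d3, 1); f2 <- fit_univariate(d3, 2)
  r12 <- which(!is.na(d3$y1) & !is.na(d3$y2))
  w1 <- 1 / (d3$s1^2 + f1$tau2); w2 <- 1 / (d3$s2^2 + f2$tau2)
  w1p <- sum(w1, na.rm = TRUE); w2p <- sum(w2, na.rm = TRUE)
  acc <- 0
  for (i in r12) {
    acc <- acc + (w1[i] / w1p) * (w2[i] / w2p) *
      (d3$y1[i] - f1$beta) * (d3$y2[i] - f2$beta)
  }
  expect_equal(mmom_cov(d3, f1, f2), acc)
})

test_that("joint fit preserves the univariate marginals exactly", {
  for (d in list(complete_data(m = 10), mcar_data(m = 12, seed = 8))) {
    ff <- fit_mmom(d)
    f1 <- fit_univariate(d, 1); f2 <- fit_univariate(d, 2)
    expect_identical(unname(ff$beta), c(f1$beta, f2$beta))
    expect_identical(ff$marginals[[1]]$se, f1$se)
    expect_identical(ff$marginals[[2]]$se, f2$se)
    # diagonal of the (untruncated) covariance is exactly the squared SEs
    expect_identical(diag(ff$sigma_raw), c(f1$se^2, f2$se^2))
    # and augmentation does not change the marginals either
    fa <- fit_mmom(augment_mcar(d))
    expect_equal(unname(fa$beta), c(f1$beta, f2$beta), tolerance = 1e-6)
  }
})

test_that("implied correlation is within [-1, 1] after truncation", {
  withr::local_seed(44)
  cfg <- sim_config(m = 6, tau2 = 0.5, n_reps = 1)
  for (r in 1:50) {
    d <- generate_meta_data(cfg, 0.8, 0.8)
    ff <- fit_mmom(d)
    rho <- ff$sigma[1, 2] / sqrt(ff$sigma[1, 1] * ff$sigma[2, 2])
    expect_lte(abs(rho), 1 + 1e-12)
  }
})

test_that("eigenvalue truncation clamps negative eigenvalues and flags it", {
  id <- diag(2)
  out <- truncate_psd(id)
  expect_false(out$truncated)
  expect_equal(out$mat, id)

  # eigenvalues 3 and -1 with analytic eigenvectors (1, +/-1)/sqrt(2)
  out <- truncate_psd(matrix(c(1, 2, 2, 1), 2, 2))
  expect_true(out$truncated)
  expect_equal(out$mat, matrix(1.5, 2, 2))

  # random indefinite symmetric matrices: output equals the eigen-oracle
  # reconstruction and is PSD
  withr::local_seed(6)
  for (r in 1:25) {
    a <- matrix(rnorm(4), 2, 2)
    m <- (a + t(a)) / 2
    out <- truncate_psd(m)
    e <- eigen(m, symmetric = TRUE)
    ref <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
    expect_equal(out$mat, (ref + t(ref)) / 2)
    expect_gte(min(eigen(out$mat, symmetric = TRUE)$values), -1e-12)
    expect_equal(out$truncated, any(e$values < -1e-12 * max(abs(m))))
  }
  expect_error(truncate_psd(matrix(c(1, 2, 3, 1), 2, 2)), "symmetric")
})

test_that("linear combinations project the joint distribution correctly", {
  d <- complete_data(m = 10)
  ff <- fit_mmom(d)
  # c = (1, 0) recovers the outcome-1 marginal exactly
  li <- linear_combo(ff, c(1, 0))
  expect_equal(li$estimate, unname(ff$beta[1]))
  expect_equal(li$se, ff$marginals[[1]]$se)
  # hand-checkable 2x2 case via a synthetic fit
  fit <- metamargin:::new_joint_fit(beta = c(beta1 = 0, beta2 = 2),
                                    sigma = matrix(c(1, 0.5, 0.5, 1), 2),
                                    sigma_raw = matrix(c(1, 0.5, 0.5, 1), 2),
                                    truncated = FALSE, method = "mmom")
  li <- linear_combo(fit, c(1, -1))
  expect_equal(li$estimate, -2)
  expect_equal(li$se, 1)  # sqrt(1 + 1 - 2 * 0.5)
  # scalar recomputation for the average
  li <- linear_combo(ff, c(0.5, 0.5))
  expect_equal(li$se,
               sqrt(0.25 * ff$sigma[1, 1] + 0.25 * ff$sigma[2, 2] +
                      0.5 * ff$sigma[1, 2]))
  expect_error(linear_combo(ff, c(0, 0)), "Zero")
})

test_that("delta method agrees with linear algebra and analytic gradients", {
  d <- complete_data(m = 10)
  ff <- fit_mmom(d)
  # linear function: identical to linear_combo up to the numeric gradient
  dm <- delta_method(ff, function(b1, b2) 2 * b1 - 3 * b2)
  li <- linear_combo(ff, c(2, -3))
  expect_equal(dm$estimate, li$estimate, tolerance = 1e-8)
  expect_equal(dm$se, li$se, tolerance = 1e-8)

  # ratio at beta = (1, 2) with identity covariance: hand gradient
  fit <- metamargin:::new_joint_fit(beta = c(beta1 = 1, beta2 = 2),
                                    sigma = diag(2), sigma_raw = diag(2),
                                    truncated = FALSE, method = "mmom")
  dm <- delta_method(fit, function(b1, b2) b1 / b2)
  expect_equal(dm$estimate, 0.5)
  expect_equal(dm$se, sqrt(0.25 + 1 / 16), tolerance = 1e-6)

  # analytic vs numeric gradient for exp(b1 - b2)
  f <- function(b1, b2) exp(b1 - b2)
  g <- function(b1, b2) c(exp(b1 - b2), -exp(b1 - b2))
  dm_num <- delta_method(ff, f)
  dm_ana <- delta_method(ff, f, grad = g)
  expect_equal(dm_num$se, dm_ana$se, tolerance = 1e-6)
  expect_error(suppressWarnings(delta_method(ff, function(b1, b2) log(-1))),
               "finite")
})

test_that("estimated covariance tracks the Monte-Carlo covariance of the estimates", {
  withr::local_seed(555)
  cfg <- sim_config(m = 25, tau2 = 0.5, n_reps = 1)
  n <- 500
  b1 <- b2 <- cv <- numeric(n)
  for (r in 1:n) {
    d <- generate_meta_data(cfg, 0.5, 0.5)
    ff <- fit_mmom(d)
    b1[r] <- ff$beta[1]; b2[r] <- ff$beta[2]
    cv[r] <- ff$sigma_raw[1, 2]
  }
  emp <- cov(b1, b2)
  # Monte-Carlo standard error of an empirical covariance
  mc_se <- sd((b1 - mean(b1)) * (b2 - mean(b2))) / sqrt(n)
  expect_lt(abs(mean(cv) - emp), 3 * mc_se)
})

test_that("joint confidence intervals for the difference attain near-nominal coverage", {
  # pooled over three representative correlation cells of the standard
  # design; coverage improves from m = 10 to m = 25
  withr::local_seed(777)
  cells <- list(c(0, 0), c(0.4, 0.5), c(-0.4, -0.5))
  cp <- numeric(2)
  for (k in 1:2) {
    setting <- list(list(m = 10, floor = 0.85), list(m = 25, floor = 0.88))[[k]]
    cfg <- sim_config(m = setting$m, tau2 = 0.5, n_reps = 1)
    cover <- logical(0)
    for (cell in cells) {
      for (r in 1:500) {
        d <- generate_meta_data(cfg, cell[1], cell[2])
        li <- linear_combo(fit_mmom(d), c(1, -1))
        cover <- c(cover, li$ci_low <= -2 && -2 <= li$ci_high)
      }
    }
    cp[k] <- mean(cover)
    expect_gte(cp[k], setting$floor)
  }
  expect_gt(cp[2], cp[1])
})
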