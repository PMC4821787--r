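#' Multivariate Q statistics for the bivariate random-effects model
#'
#' The heterogeneity statistics used by the multivariate method of
#' moments: `Q1` and `Q2` are the usual univariate Q statistics over each
#' outcome's reporting set (inverse-variance weights), and the
#' cross-statistic
#' `Q12 = sum_{i in R12} (y_i1 - ybar1*)(y_i2 - ybar2*) / (s_i1 s_i2)`
#' runs over the studies reporting both outcomes, where `ybar_j*` are the
#' means of `y_j` over that overlap weighted by `1/(s_i1 s_i2)`.
#'
#' @param data A study-level table (see [as_meta_data()]).
#' @return A list of class `q_vector`: `Q1`, `Q12`, `Q2`, the weighted
#'   means `ybar1`, `ybar2`, `ybar1_star`, `ybar2_star`, and
#'   `r12_empty` flagging an empty overlap (then `Q12 = 0` and the
#'   starred means are `NA`).
#' @export
q_vector <- function(data) {
  d <- as_meta_data(data)
  sl1 <- outcome_slice(d, 1)
  sl2 <- outcome_slice(d, 2)
  keep1 <- !sl1$aug
  keep2 <- !sl2$aug
  y1 <- sl1$y[keep1]; v1 <- sl1$s2[keep1]
  y2 <- sl2$y[keep2]; v2 <- sl2$s2[keep2]
  Q1 <- if (length(y1)) q_statistic(y1, v1) else 0
  Q2 <- if (length(y2)) q_statistic(y2, v2) else 0
  ybar1 <- if (length(y1)) sum(y1 / v1) / sum(1 / v1) else NA_real_
  ybar2 <- if (length(y2)) sum(y2 / v2) / sum(1 / v2) else NA_real_

  idx1 <- sl1$idx[keep1]
  idx2 <- sl2$idx[keep2]
  r12 <- intersect(idx1, idx2)
  if (length(r12) == 0L) {
    out <- list(Q1 = Q1, Q12 = 0, Q2 = Q2, ybar1 = ybar1, ybar2 = ybar2,
                ybar1_star = NA_real_, ybar2_star = NA_real_,
                r12_empty = TRUE)
    return(structure(out, class = "q_vector"))
  }
  p1 <- match(r12, idx1)
  p2 <- match(r12, idx2)
  u <- 1 / sqrt(v1[p1] * v2[p2])   # 1 / (s_i1 s_i2)
  yb1s <- sum(y1[p1] * u) / sum(u)
  yb2s <- sum(y2[p2] * u) / sum(u)
  Q12 <- sum(u * (y1[p1] - yb1s) * (y2[p2] - yb2s))
  structure(
    list(Q1 = Q1, Q12 = Q12, Q2 = Q2, ybar1 = ybar1, ybar2 = ybar2,
         ybar1_star = yb1s, ybar2_star = yb2s, r12_empty = FALSE),
    class = "q_vector"
  )
}

#' Moment estimation of the between-study covariance matrix
#'
#' Equates the multivariate Q statistics with their expectations and
#' solves for the between-study variances and covariance. The diagonal
#' equations reproduce the DerSimonian-Laird univariate estimates exactly;
#' the off-diagonal equation `Q12 = a + b * cov_B` has coefficients
#' `a = sum(rho_w) - sum(rho_w * u) / sum(u)` and
#' `b = sum(u) - sum(u^2) / sum(u)` over the overlap, with
#' `u = 1/(s_i1 s_i2)`, so `cov_B = (Q12 - a) / b`. The within-study
#' correlations are required here. The assembled matrix is made positive
#' semi-definite by eigenvalue truncation ([truncate_psd()]), which in the
#' bivariate case also clips any negative variance to zero and the implied
#' between-study correlation into `[-1, 1]`.
#'
#' @param qv A `q_vector` from [q_vector()] on the same data.
#' @param data The study-level table; `rho_w` must be present on every
#'   overlap row.
#' @return A list of class `omega_estimate`: `tau1_2`, `tau2_2` (DL
#'   estimates, pre-truncation but floored at 0), `cov_B` (raw moment
#'   solution), `omega` (2x2 PSD matrix after truncation), `truncated`,
#'   `a_coef`, `b_coef`, `r12_empty`.
#' @export
solve_omega <- function(qv, data) {
  stopifnot(inherits(qv, "q_vector"))
  d <- as_meta_data(data)
  sl1 <- outcome_slice(d, 1)
  sl2 <- outcome_slice(d, 2)
  keep1 <- !sl1$aug
  keep2 <- !sl2$aug
  y1 <- sl1$y[keep1]; v1 <- sl1$s2[keep1]
  y2 <- sl2$y[keep2]; v2 <- sl2$s2[keep2]
  tau1_2 <- if (length(y1)) dl_tau2(y1, v1) else 0
  tau2_2 <- if (length(y2)) dl_tau2(y2, v2) else 0

  idx1 <- sl1$idx[keep1]
  idx2 <- sl2$idx[keep2]
  r12 <- intersect(idx1, idx2)
  if (length(r12) == 0L) {
    omega <- diag(c(tau1_2, tau2_2))
    return(structure(
      list(tau1_2 = tau1_2, tau2_2 = tau2_2, cov_B = 0, omega = omega,
           truncated = FALSE, a_coef = NA_real_, b_coef = NA_real_,
           r12_empty = TRUE),
      class = "omega_estimate"
    ))
  }
  rho_w <- d$rho_w[r12]
  if (any(is.na(rho_w))) {
    stop("Within-study correlations (rho_w) are required for every study reporting both outcomes.",
         call. = FALSE)
  }
  p1 <- match(r12, idx1)
  p2 <- match(r12, idx2)
  u <- 1 / sqrt(v1[p1] * v2[p2])
  a <- sum(rho_w) - sum(rho_w * u) / sum(u)
  b <- sum(u) - sum(u^2) / sum(u)
  if (abs(b) < 1e-12) {
    stop("Between-study covariance is unidentified: moment coefficient b = 0 ",
         "(degenerate weight configuration in the overlap set).", call. = FALSE)
  }
  cov_B <- (qv$Q12 - a) / b
  omega_raw <- matrix(c(tau1_2, cov_B, cov_B, tau2_2), 2, 2)
  tr <- truncate_psd(omega_raw)
  structure(
    list(tau1_2 = tau1_2, tau2_2 = tau2_2, cov_B = cov_B, omega = tr$mat,
         truncated = tr$truncated, a_coef = a, b_coef = b,
         r12_empty = FALSE),
    class = "omega_estimate"
  )
}

#' Generalized-least-squares (BLUE) pooling given a between-study matrix
#'
#' The best linear unbiased estimator of the overall effects for the
#' bivariate random-effects model with known between-study covariance
#' `Omega`: `beta = (sum W_i)^-1 sum W_i y_i` with
#' `W_i = (Omega + Delta_i)^-1`, and covariance `(sum W_i)^-1`. Every row
#' must be complete; incomplete datasets are first completed by
#' [augment_mcar()] (zero estimates, very large variances, zero
#' within-study correlation), which leaves the estimates unchanged in the
#' large-variance limit.
#'
#' @param data A study-level table; `rho_w` must be available on complete
#'   rows.
#' @param omega A 2x2 positive semi-definite between-study covariance
#'   matrix.
#' @param method Label stored on the returned fit.
#' @param large_variance Passed to [augment_mcar()] when rows are
#'   incomplete.
#' @return A `joint_fit` with `beta`, `sigma`, and `omega`.
#' @export
blue_pool <- function(data, omega, method = "jackson", large_variance = 1e6) {
  stopifnot(is.matrix(omega), all(dim(omega) == c(2, 2)))
  if (max(abs(omega - t(omega))) > 1e-8 * max(abs(omega), 1)) {
    stop("`omega` must be symmetric.", call. = FALSE)
  }
  d <- as_meta_data(data)
  if (anyNA(d$y1) || anyNA(d$y2)) {
    d <- augment_mcar(d, large_variance = large_variance)
  }
  rho_w <- d$rho_w
  rho_w[is.na(rho_w)] <- 0
  if (any(is.na(d$rho_w) & !(d$.aug1 | d$.aug2))) {
    stop("Within-study correlations (rho_w) are required for studies reporting both outcomes.",
         call. = FALSE)
  }
  a <- d$s1^2 + omega[1, 1]
  b <- d$s1 * d$s2 * rho_w + omega[1, 2]
  cc <- d$s2^2 + omega[2, 2]
  det <- a * cc - b^2
  bad <- which(det <= 1e-300)
  if (length(bad)) {
    stop(sprintf("Marginal covariance of study '%s' is singular.",
                 d$study[bad[1]]), call. = FALSE)
  }
  i11 <- cc / det; i12 <- -b / det; i22 <- a / det
  S <- matrix(c(sum(i11), sum(i12), sum(i12), sum(i22)), 2, 2)
  z <- c(sum(i11 * d$y1 + i12 * d$y2), sum(i12 * d$y1 + i22 * d$y2))
  detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (detS <= 0) stop("Total information matrix is singular.", call. = FALSE)
  kappa_S <- kappa(S, exact = TRUE)
  if (kappa_S >= 1e12) {
    warning(sprintf("Total information matrix is ill-conditioned (kappa = %.2e).",
                    kappa_S))
  }
  sigma <- matrix(c(S[2, 2], -S[1, 2], -S[1, 2], S[1, 1]), 2, 2) / detS
  beta <- drop(sigma %*% z)
  new_joint_fit(beta = c(beta1 = beta[1], beta2 = beta[2]), sigma = sigma,
                sigma_raw = sigma, truncated = FALSE, method = method,
                extra = list(omega = omega))
}

#' Jackson's multivariate method of moments for the bivariate model
#'
#' The non-iterative moment comparator: estimates the between-study
#' covariance matrix from the multivariate Q statistics
#' ([q_vector()], [solve_omega()]) — which requires the within-study
#' correlations — then pools by generalized least squares
#' ([blue_pool()]). Missing outcomes are handled by the large-variance
#' augmentation convention at the pooling step only; the moment equations
#' always use the actual reporting sets.
#'
#' @inheritParams blue_pool
#' @return A `joint_fit` (method `"jackson"`) carrying the
#'   `omega_estimate` as `$omega_est`; `$truncated` flags eigenvalue
#'   truncation of the between-study matrix.
#' @export
fit_jackson <- function(data, large_variance = 1e6) {
  d <- as_meta_data(data)
  qv <- q_vector(d)
  om <- solve_omega(qv, d)
  fit <- blue_pool(d, om$omega, method = "jackson",
                   large_variance = large_variance)
  fit$omega_est <- om
  fit$truncated <- om$truncated
  fit
}
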