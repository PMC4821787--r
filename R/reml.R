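#' Restricted log-likelihood of the bivariate random-effects model
#'
#' For between-study covariance `Omega`, the restricted log-likelihood is
#' `-(1/2) [ log|sum_i V_i^-1| + sum_i log|V_i| + sum_i r_i' V_i^-1 r_i ]`
#' with `V_i = Omega + Delta_i`, `r_i = y_i - beta_hat(Omega)` and
#' `beta_hat` the generalized-least-squares estimate at that `Omega`.
#' Incomplete rows are completed by large-variance augmentation
#' ([augment_mcar()]), under which the observed-data restricted likelihood
#' is recovered up to an additive constant in the large-variance limit.
#'
#' @param omega A 2x2 symmetric positive semi-definite matrix.
#' @param data A study-level table with `rho_w` on complete rows.
#' @param large_variance Augmentation variance for missing outcomes.
#' @return The restricted log-likelihood (a single finite number for PSD
#'   `omega`); an error if the value is not finite.
#' @export
restricted_loglik <- function(omega, data, large_variance = 1e6) {
  stopifnot(is.matrix(omega), all(dim(omega) == c(2, 2)))
  pre <- reml_precompute(data, large_variance)
  val <- reml_obj(omega[1, 1], omega[1, 2], omega[2, 2], pre)
  if (!is.finite(val)) {
    stop(sprintf("Restricted log-likelihood not finite at omega = [%g, %g; %g, %g].",
                 omega[1, 1], omega[1, 2], omega[2, 1], omega[2, 2]),
         call. = FALSE)
  }
  val
}

# Flatten the dataset into the vectors the likelihood needs; done once per fit.
reml_precompute <- function(data, large_variance = 1e6) {
  d <- as_meta_data(data)
  if (anyNA(d$y1) || anyNA(d$y2)) {
    d <- augment_mcar(d, large_variance = large_variance)
  }
  rho_w <- d$rho_w
  rho_w[is.na(rho_w)] <- 0
  list(y1 = d$y1, y2 = d$y2, s1sq = d$s1^2, s2sq = d$s2^2,
       d12 = d$s1 * d$s2 * rho_w, m = nrow(d))
}

# Core evaluation with closed-form 2x2 inverses, vectorized over studies.
reml_obj <- function(w11, w12, w22, pre) {
  a <- pre$s1sq + w11
  b <- pre$d12 + w12
  cc <- pre$s2sq + w22
  det <- a * cc - b^2
  if (any(det <= 0) || any(a <= 0)) return(-Inf)
  i11 <- cc / det; i12 <- -b / det; i22 <- a / det
  S11 <- sum(i11); S12 <- sum(i12); S22 <- sum(i22)
  detS <- S11 * S22 - S12^2
  if (detS <= 0) return(-Inf)
  z1 <- sum(i11 * pre$y1 + i12 * pre$y2)
  z2 <- sum(i12 * pre$y1 + i22 * pre$y2)
  b1 <- (S22 * z1 - S12 * z2) / detS
  b2 <- (S11 * z2 - S12 * z1) / detS
  r1 <- pre$y1 - b1
  r2 <- pre$y2 - b2
  quad <- sum(i11 * r1^2 + 2 * i12 * r1 * r2 + i22 * r2^2)
  -0.5 * (log(detS) + sum(log(det)) + quad)
}

# log-Cholesky parameterization: theta = (l1, l2, l3) ->
# Omega = L L' with L = [exp(l1) 0; l3 exp(l2)] (always PSD).
theta_to_omega <- function(theta) {
  e1 <- exp(theta[1]); e2 <- exp(theta[2]); l3 <- theta[3]
  c(w11 = e1^2, w12 = e1 * l3, w22 = l3^2 + e2^2)
}

#' REML fit of the bivariate random-effects model
#'
#' Estimates the between-study covariance matrix by maximizing the
#' restricted likelihood over positive semi-definite matrices (via a
#' log-Cholesky parameterization), then pools by generalized least
#' squares ([blue_pool()]) at the estimate. Optimization uses `nlminb`
#' started from the DerSimonian-Laird diagonal and, when available, from
#' Jackson's moment estimate; the better optimum is kept and convergence
#' status is always reported.
#'
#' @param data A study-level table with `rho_w` on complete rows; at least
#'   two studies per outcome.
#' @param start Optional 2x2 starting value for the between-study matrix.
#' @param max_iter Iteration cap for the optimizer.
#' @param tol Relative tolerance on the objective.
#' @param large_variance Augmentation variance for missing outcomes.
#' @return An object of class `reml_result`: `omega` (2x2 PSD), `joint`
#'   (a `joint_fit`, method `"reml"`), `converged`, `n_iter`, `loglik`.
#' @export
fit_reml <- function(data, start = NULL, max_iter = 500, tol = 1e-10,
                     large_variance = 1e6) {
  d <- as_meta_data(data)
  rs <- reporting_sets(d)
  if (rs$m1 < 2 || rs$m2 < 2) {
    stop("REML needs at least two studies per outcome.", call. = FALSE)
  }
  pre <- reml_precompute(d, large_variance)

  starts <- list()
  if (!is.null(start)) {
    stopifnot(is.matrix(start), all(dim(start) == c(2, 2)))
    starts <- c(starts, list(omega_to_theta(start)))
  }
  sl1 <- outcome_slice(d, 1)
  sl2 <- outcome_slice(d, 2)
  t1 <- max(dl_tau2(sl1$y, sl1$s2, m_eff = sl1$m_eff), 1e-4)
  t2 <- max(dl_tau2(sl2$y, sl2$s2, m_eff = sl2$m_eff), 1e-4)
  starts <- c(starts, list(c(0.5 * log(t1), 0.5 * log(t2), 0)))
  om_j <- tryCatch(solve_omega(q_vector(d), d)$omega, error = function(e) NULL)
  if (!is.null(om_j)) starts <- c(starts, list(omega_to_theta(om_j)))

  negobj <- function(theta) {
    w <- theta_to_omega(theta)
    v <- reml_obj(w[1], w[2], w[3], pre)
    if (!is.finite(v)) return(1e10)
    -v
  }
  lower <- c(log(1e-5), log(1e-5), -50)
  upper <- c(log(1e3), log(1e3), 50)
  best <- NULL
  n_iter <- 0L
  converged <- FALSE
  for (th0 in starts) {
    th0 <- pmin(pmax(th0, lower), upper)
    res <- tryCatch(
      stats::nlminb(th0, negobj, lower = lower, upper = upper,
                    control = list(iter.max = max_iter, eval.max = 4 * max_iter,
                                   rel.tol = tol)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    n_iter <- n_iter + res$iterations
    if (is.null(best) || res$objective < best$objective) {
      best <- res
      converged <- res$convergence == 0
    }
  }
  if (is.null(best)) stop("REML optimization failed from all starts.", call. = FALSE)
  w <- theta_to_omega(best$par)
  omega <- matrix(c(w[1], w[2], w[2], w[3]), 2, 2)
  joint <- blue_pool(d, omega, method = "reml", large_variance = large_variance)
  structure(
    list(omega = omega, joint = joint, converged = converged,
         n_iter = n_iter, loglik = -best$objective),
    class = "reml_result"
  )
}

# Inverse of theta_to_omega for a PSD start (diagonal floored away from 0).
omega_to_theta <- function(omega) {
  w11 <- max(omega[1, 1], 1e-8)
  l1 <- 0.5 * log(w11)
  l3 <- omega[1, 2] / sqrt(w11)
  rem <- omega[2, 2] - l3^2
  l2 <- 0.5 * log(max(rem, 1e-8))
  c(l1, l2, l3)
}

#' @export
print.reml_result <- function(x, ...) {
  cat("Bivariate random-effects meta-analysis (REML)\n")
  cat(sprintf("  converged: %s (%d iterations), restricted loglik = %.4f\n",
              x$converged, x$n_iter, x$loglik))
  cat(sprintf("  Omega: tau1^2 = %.4f, tau2^2 = %.4f, cov = %.4f\n",
              x$omega[1, 1], x$omega[2, 2], x$omega[1, 2]))
  print(x$joint)
  invisible(x)
}

#' @export
tidy.reml_result <- function(x, ...) tidy(x$joint)

#' @export
glance.reml_result <- function(x, ...) {
  tibble::tibble(
    method = "reml",
    tau1_2 = x$omega[1, 1], tau2_2 = x$omega[2, 2], cov_B = x$omega[1, 2],
    loglik = x$loglik, converged = x$converged, n_iter = x$n_iter
  )
}
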