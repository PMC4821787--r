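#' Moment estimator of the between-study variance in meta-regression
#'
#' Extends the DerSimonian-Laird moment estimator to a weighted
#' regression with design matrix `X`: with fixed-effect residuals
#' `y - X bhat_fix` (weights `1/s2`), the statistic
#' `Q = sum(r^2 / s2)` has expectation
#' `(m - p) + [tr(L^-1) - tr((X'L^-1 X)^-1 X'L^-2 X)] tau2` where
#' `L = diag(s2)`, giving
#' `tau2 = max(0, (Q - (m - p)) / (tr(L^-1) - tr((X'L^-1X)^-1 X'L^-2X)))`.
#' With an intercept-only design this is exactly [dl_tau2()].
#'
#' @param y Effect estimates.
#' @param s2 Within-study variances.
#' @param X Design matrix (full column rank, `m > ncol(X)`).
#' @param m_eff Effective study count; defaults to `length(y)` (see
#'   [dl_tau2()]).
#' @return Non-negative between-study variance estimate.
#' @export
metareg_tau2 <- function(y, s2, X, m_eff = length(y)) {
  check_ys2(y, s2)
  X <- as.matrix(X)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("Design matrix is rank deficient.", call. = FALSE)
  if (m_eff <= p) {
    stop("Need more studies than regression coefficients.", call. = FALSE)
  }
  w <- 1 / s2
  XtWX <- crossprod(X * w, X)
  bfix <- solve(XtWX, crossprod(X * w, y))
  r <- y - drop(X %*% bfix)
  Q <- sum(w * r^2)
  denom <- sum(w) - sum(diag(solve(XtWX, crossprod(X * w^2, X))))
  if (denom <= 0) return(0)
  max(0, (Q - (m_eff - p)) / denom)
}

# Weighted least squares with diagonal weights; returns coefficients and
# the (X'WX)^-1 matrix.
wls_fit <- function(y, X, w) {
  XtWX <- crossprod(X * w, X)
  XtWXi <- solve(XtWX)
  beta <- drop(XtWXi %*% crossprod(X * w, y))
  list(beta = beta, XtWXi = XtWXi)
}

# Build the design matrix for one outcome from x{j}_* columns.
metareg_design <- function(data, outcome, idx, intercept = TRUE) {
  pref <- paste0("x", outcome, "_")
  xcols <- grep(paste0("^", pref), names(data), value = TRUE)
  X <- as.matrix(data[idx, xcols, drop = FALSE])
  if (length(xcols)) {
    storage.mode(X) <- "double"
    colnames(X) <- sub(pref, "", xcols)
  }
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  if (ncol(X) == 0L) {
    stop(sprintf("Outcome %d has no design columns (add x%d_* covariates or keep the intercept).",
                 outcome, outcome), call. = FALSE)
  }
  X
}

#' Bivariate meta-regression by the marginal method of moments
#'
#' Per-outcome weighted-least-squares meta-regression with the moment
#' estimator [metareg_tau2()] for the between-study variance, joined by a
#' cross-outcome coefficient covariance built from per-study residual
#' products over the studies reporting both outcomes:
#' `cov(b1, b2) = (X1'L1*^-1 X1)^-1 X1'L1*^-1 D L2*^-1 X2 (X2'L2*^-1 X2)^-1`
#' where `Lj* = diag(s_j^2 + tau_j^2)` and `D` is diagonal with entries
#' `r_i1 r_i2` on the overlap (zero elsewhere). The residuals in `D` use
#' the fixed-effect coefficients by default (`residuals = "fixed"`);
#' `residuals = "random"` uses the random-effects coefficients instead,
#' under which an intercept-only model reproduces [fit_mmom()] exactly,
#' covariance included (point estimates reduce exactly under either
#' choice).
#'
#' Covariates are taken from columns `x1_*` (outcome 1) and `x2_*`
#' (outcome 2); an intercept is prepended unless `intercept = FALSE`.
#' Missing outcomes are handled through the reporting sets, as in
#' [fit_mmom()].
#'
#' @param data A study-level table with covariate columns.
#' @param intercept Add an intercept to both designs (default `TRUE`).
#' @param residuals Residual type for the cross-outcome covariance.
#' @return An object of class `metareg_fit`: `beta1`, `beta2` (named
#'   coefficient vectors), `sigma` ((p1+p2) x (p1+p2), PSD), `sigma_raw`,
#'   `tau2_1`, `tau2_2`, `beta_fix1`, `beta_fix2`, `truncated`.
#' @export
fit_metareg <- function(data, intercept = TRUE,
                        residuals = c("fixed", "random")) {
  residuals <- match.arg(residuals)
  d <- as_meta_data(data)
  sl <- list(outcome_slice(d, 1), outcome_slice(d, 2))
  out <- vector("list", 2)
  for (j in 1:2) {
    s <- sl[[j]]
    if (length(s$y) == 0L) {
      stop(sprintf("No studies report outcome %d.", j), call. = FALSE)
    }
    X <- metareg_design(d, j, s$idx, intercept = intercept)
    tau2 <- metareg_tau2(s$y, s$s2, X, m_eff = s$m_eff)
    wfix <- 1 / s$s2
    wstar <- 1 / (s$s2 + tau2)
    fix <- wls_fit(s$y, X, wfix)
    ran <- wls_fit(s$y, X, wstar)
    out[[j]] <- list(X = X, tau2 = tau2, wstar = wstar,
                     beta_fix = fix$beta, beta = ran$beta,
                     XtWXi = ran$XtWXi,
                     r_fix = s$y - drop(X %*% fix$beta),
                     r_ran = s$y - drop(X %*% ran$beta))
  }

  r12 <- intersect(sl[[1]]$idx, sl[[2]]$idx)
  p1 <- ncol(out[[1]]$X); p2 <- ncol(out[[2]]$X)
  cross <- matrix(0, p1, p2)
  if (length(r12)) {
    i1 <- match(r12, sl[[1]]$idx)
    i2 <- match(r12, sl[[2]]$idx)
    rr1 <- if (residuals == "fixed") out[[1]]$r_fix else out[[1]]$r_ran
    rr2 <- if (residuals == "fixed") out[[2]]$r_fix else out[[2]]$r_ran
    # X1' L1*^-1 D L2*^-1 X2 restricted to the overlap rows
    mid <- crossprod(out[[1]]$X[i1, , drop = FALSE] *
                       (out[[1]]$wstar[i1] * rr1[i1] * rr2[i2] * out[[2]]$wstar[i2]),
                     out[[2]]$X[i2, , drop = FALSE])
    cross <- out[[1]]$XtWXi %*% mid %*% out[[2]]$XtWXi
  }
  sigma_raw <- rbind(cbind(out[[1]]$XtWXi, cross),
                     cbind(t(cross), out[[2]]$XtWXi))
  nm <- c(paste0("y1:", colnames(out[[1]]$X)), paste0("y2:", colnames(out[[2]]$X)))
  dimnames(sigma_raw) <- list(nm, nm)
  tr <- truncate_psd(sigma_raw)
  structure(
    list(beta1 = stats::setNames(out[[1]]$beta, colnames(out[[1]]$X)),
         beta2 = stats::setNames(out[[2]]$beta, colnames(out[[2]]$X)),
         sigma = tr$mat, sigma_raw = sigma_raw,
         tau2_1 = out[[1]]$tau2, tau2_2 = out[[2]]$tau2,
         beta_fix1 = stats::setNames(out[[1]]$beta_fix, colnames(out[[1]]$X)),
         beta_fix2 = stats::setNames(out[[2]]$beta_fix, colnames(out[[2]]$X)),
         truncated = tr$truncated, residuals = residuals),
    class = "metareg_fit"
  )
}

#' Joint-fit view of a meta-regression coefficient pair
#'
#' Projects a `metareg_fit` onto one coefficient per outcome (by default
#' the intercepts), returning a `joint_fit` so that [linear_combo()] and
#' [delta_method()] apply, e.g. for the average of the two intercepts.
#'
#' @param fit A `metareg_fit`.
#' @param terms Length-2 character or integer: one coefficient per
#'   outcome.
#' @return A `joint_fit` (method `"metareg"`).
#' @export
metareg_joint <- function(fit, terms = c(1L, 1L)) {
  stopifnot(inherits(fit, "metareg_fit"), length(terms) == 2)
  p1 <- length(fit$beta1)
  k1 <- if (is.character(terms[1])) match(terms[1], names(fit$beta1)) else as.integer(terms[1])
  k2 <- if (is.character(terms[2])) match(terms[2], names(fit$beta2)) else as.integer(terms[2])
  if (is.na(k1) || is.na(k2)) stop("Unknown coefficient name.", call. = FALSE)
  idx <- c(k1, p1 + k2)
  sigma <- fit$sigma[idx, idx]
  new_joint_fit(
    beta = c(beta1 = unname(fit$beta1[k1]), beta2 = unname(fit$beta2[k2])),
    sigma = sigma, sigma_raw = fit$sigma_raw[idx, idx],
    truncated = fit$truncated, method = "metareg"
  )
}

#' @export
print.metareg_fit <- function(x, ...) {
  cat("Bivariate meta-regression (marginal method of moments)\n")
  cat(sprintf("  tau2: outcome 1 = %.4f, outcome 2 = %.4f%s\n",
              x$tau2_1, x$tau2_2,
              if (isTRUE(x$truncated)) "  [PSD-truncated]" else ""))
  print(as.data.frame(tidy(x)), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.metareg_fit <- function(x, ...) {
  est <- c(x$beta1, x$beta2)
  se <- sqrt(diag(x$sigma))
  tibble::tibble(
    outcome = rep(1:2, c(length(x$beta1), length(x$beta2))),
    term = c(names(x$beta1), names(x$beta2)),
    estimate = unname(est), std.error = unname(se),
    conf.low = unname(est) - 1.96 * se, conf.high = unname(est) + 1.96 * se
  )
}

#' @export
glance.metareg_fit <- function(x, ...) {
  tibble::tibble(tau2_1 = x$tau2_1, tau2_2 = x$tau2_2,
                 truncated = isTRUE(x$truncated), residuals = x$residuals)
}
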