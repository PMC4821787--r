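#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum((y - ybar_w)^2 / s2)` with `ybar_w` the inverse-variance
#' weighted mean. Zero for a single study.
#'
#' @param y Effect estimates.
#' @param s2 Within-study variances (strictly positive, same length).
#' @return The Q statistic (a single non-negative number).
#' @export
q_statistic <- function(y, s2) {
  check_ys2(y, s2)
  w <- 1 / s2
  ybar <- sum(w * y) / sum(w)
  sum(w * (y - ybar)^2)
}

#' DerSimonian-Laird between-study variance estimator
#'
#' The non-iterative moment estimator
#' `tau2 = max(0, (Q - (m - 1)) / (S1 - S2/S1))` with `S1 = sum(1/s2)`,
#' `S2 = sum(1/s2^2)`. For a single study `tau2 = 0` by convention (the
#' moment equation is degenerate there).
#'
#' @inheritParams q_statistic
#' @param m_eff Effective study count for the degrees of freedom; defaults
#'   to `length(y)`. Fits on datasets completed by [augment_mcar()] pass
#'   the count of genuinely reporting studies here, so the filled-in rows
#'   contribute (vanishing) weight but no degrees of freedom.
#' @return Non-negative between-study variance estimate.
#' @export
dl_tau2 <- function(y, s2, m_eff = length(y)) {
  check_ys2(y, s2)
  if (m_eff <= 1) return(0)
  Q <- q_statistic(y, s2)
  w <- 1 / s2
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) return(0)
  max(0, (Q - (m_eff - 1)) / denom)
}

#' Pool one outcome by inverse-variance weighting
#'
#' Weighted average `beta = sum(w*y)/sum(w)` with `w = 1/s2` under the
#' fixed-effect model or `w = 1/(s2 + tau2)` under the random-effects model
#' (DerSimonian-Laird `tau2`). The standard error is `(sum w)^(-1/2)` and
#' inference uses the normal approximation.
#'
#' @inheritParams dl_tau2
#' @param model `"random"` (default) or `"fixed"`.
#' @param tau2 Optional between-study variance override; by default the
#'   DerSimonian-Laird estimate is used under `model = "random"`. Supplying
#'   a value is the hook for alternative heterogeneity estimators.
#' @return An object of class `univariate_fit`: a list with `beta`, `se`,
#'   `tau2`, `Q`, `weights`, `model`, `m`, `ci_low`, `ci_high`.
#' @examples
#' pool(c(0.3, 0.5, 0.2), c(0.04, 0.09, 0.05))
#' @export
pool <- function(y, s2, model = c("random", "fixed"), tau2 = NULL,
                 m_eff = length(y)) {
  check_ys2(y, s2)
  model <- match.arg(model)
  Q <- q_statistic(y, s2)
  if (model == "fixed") {
    tau2 <- 0
  } else if (is.null(tau2)) {
    tau2 <- dl_tau2(y, s2, m_eff = m_eff)
  } else {
    stopifnot(is.numeric(tau2), tau2 >= 0)
  }
  w <- 1 / (s2 + tau2)
  beta <- sum(w * y) / sum(w)
  se <- 1 / sqrt(sum(w))
  structure(
    list(beta = beta, se = se, tau2 = tau2, Q = Q, weights = w,
         model = model, m = m_eff,
         ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se),
    class = "univariate_fit"
  )
}

#' Univariate random-effects meta-analysis of one outcome
#'
#' Data-frame interface to [pool()]: extracts outcome `outcome` over its
#' reporting set and fits the DerSimonian-Laird random-effects (or
#' fixed-effect) model.
#'
#' @param data A study-level table (see [as_meta_data()]).
#' @param outcome Which outcome, `1` or `2`.
#' @inheritParams pool
#' @return A `univariate_fit` object; see [pool()].
#' @export
fit_univariate <- function(data, outcome = 1, model = c("random", "fixed")) {
  d <- as_meta_data(data)
  sl <- outcome_slice(d, outcome)
  if (length(sl$y) == 0L) {
    stop(sprintf("No studies report outcome %d.", outcome), call. = FALSE)
  }
  fit <- pool(sl$y, sl$s2, model = match.arg(model), m_eff = sl$m_eff)
  fit$outcome <- outcome
  fit
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat(sprintf("Univariate %s-effects meta-analysis (%d studies)\n",
              x$model, x$m))
  cat(sprintf("  beta = %.4f  (SE %.4f)  95%% CI [%.4f, %.4f]\n",
              x$beta, x$se, x$ci_low, x$ci_high))
  cat(sprintf("  tau2 = %.4f  Q = %.3f\n", x$tau2, x$Q))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.univariate_fit <- function(x, ...) {
  tibble::tibble(
    term = paste0("beta", x$outcome %||% ""),
    estimate = x$beta, std.error = x$se,
    conf.low = x$ci_low, conf.high = x$ci_high
  )
}

#' @export
glance.univariate_fit <- function(x, ...) {
  tibble::tibble(tau2 = x$tau2, Q = x$Q, df = x$m - 1, model = x$model,
                 n.studies = x$m)
}

check_ys2 <- function(y, s2) {
  if (length(y) == 0L) stop("Empty input: no studies.", call. = FALSE)
  if (length(y) != length(s2)) {
    stop("`y` and `s2` must have equal length.", call. = FALSE)
  }
  if (any(!is.finite(y)) || any(!is.finite(s2))) {
    stop("`y` and `s2` must be finite.", call. = FALSE)
  }
  if (any(s2 <= 0)) stop("All within-study variances must be > 0.", call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
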