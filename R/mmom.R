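#' Moment estimate of the covariance between two pooled estimates
#'
#' The covariance between the univariate pooled estimates of the two
#' outcomes is estimated by the weighted sum of cross-residual products
#' over the studies reporting both outcomes:
#' `sum_{i in R12} (w_i1/w1+)(w_i2/w2+)(y_i1 - beta1)(y_i2 - beta2)`,
#' where `w_ij` are the same pooling weights used for each univariate fit
#' and `wj+` their totals over the full reporting set of outcome `j`.
#' When no study reports both outcomes the sum is empty and the pooled
#' estimates are independent, so the covariance is 0.
#'
#' @param data A study-level table (see [as_meta_data()]).
#' @param fit1,fit2 The two `univariate_fit` objects from [fit_univariate()]
#'   computed on the same dataset.
#' @return The estimated covariance (a single number).
#' @export
mmom_cov <- function(data, fit1, fit2) {
  d <- as_meta_data(data)
  s1 <- outcome_slice(d, 1)
  s2 <- outcome_slice(d, 2)
  stopifnot(length(fit1$weights) == length(s1$y),
            length(fit2$weights) == length(s2$y))
  r12 <- intersect(s1$idx, s2$idx)
  if (length(r12) == 0L) return(0)
  p1 <- match(r12, s1$idx)
  p2 <- match(r12, s2$idx)
  f1 <- fit1$weights[p1] / sum(fit1$weights)
  f2 <- fit2$weights[p2] / sum(fit2$weights)
  sum(f1 * f2 * (s1$y[p1] - fit1$beta) * (s2$y[p2] - fit2$beta))
}

#' Marginal method of moments for bivariate meta-analysis
#'
#' Fits each outcome by a conventional univariate (DerSimonian-Laird)
#' meta-analysis, then estimates the covariance between the two pooled
#' estimates from cross-residual products over the overlapping studies
#' ([mmom_cov()]). The result supports joint inference on `(beta1, beta2)`
#' and inference for functions of the two effects — without any
#' within-study correlations. Marginal estimates and standard errors are
#' exactly the univariate ones; no borrowing of strength is attempted.
#'
#' If the assembled 2x2 covariance matrix is indefinite it is replaced by
#' its eigenvalue-truncated positive semi-definite version
#' ([truncate_psd()]) for joint inference; the reported marginal standard
#' errors remain the univariate ones, and `truncated` flags the event.
#'
#' @param data A study-level table; both outcomes must be reported by at
#'   least one study each.
#' @param model `"random"` (default) or `"fixed"` pooling weights.
#' @return An object of class `joint_fit`: `beta` (length-2), `sigma`
#'   (2x2, PSD), `sigma_raw` (before any truncation), `truncated`,
#'   `method = "mmom"`, and the two `marginals`.
#' @examples
#' d <- tibble::tibble(y1 = c(0.1, 0.4, 0.3), s1 = c(0.2, 0.3, 0.25),
#'                     y2 = c(1.8, 2.1, 2.4), s2 = c(0.4, 0.3, 0.5))
#' fit_mmom(d)
#' @export
fit_mmom <- function(data, model = c("random", "fixed")) {
  model <- match.arg(model)
  d <- as_meta_data(data)
  rs <- reporting_sets(d)
  for (j in 1:2) {
    if (length(rs[[paste0("r", j)]]) == 0L) {
      stop(sprintf("No studies report outcome %d; cannot fit.", j),
           call. = FALSE)
    }
  }
  f1 <- fit_univariate(d, 1, model = model)
  f2 <- fit_univariate(d, 2, model = model)
  cv <- mmom_cov(d, f1, f2)
  sigma_raw <- matrix(c(f1$se^2, cv, cv, f2$se^2), 2, 2)
  tr <- truncate_psd(sigma_raw)
  new_joint_fit(beta = c(beta1 = f1$beta, beta2 = f2$beta),
                sigma = tr$mat, sigma_raw = sigma_raw,
                truncated = tr$truncated, method = "mmom",
                marginals = list(f1, f2))
}

new_joint_fit <- function(beta, sigma, sigma_raw, truncated, method,
                          marginals = NULL, extra = list()) {
  structure(
    c(list(beta = beta, sigma = sigma, sigma_raw = sigma_raw,
           truncated = truncated, method = method, marginals = marginals),
      extra),
    class = "joint_fit"
  )
}

#' Eigenvalue truncation to the nearest clamped PSD matrix
#'
#' Eigendecomposes a symmetric matrix, clamps negative eigenvalues to
#' zero, and reconstructs. Returns the input unchanged (flag `FALSE`) when
#' it is already positive semi-definite. This is the standard repair for
#' indefinite moment estimates of covariance matrices.
#'
#' @param mat A symmetric matrix (asymmetry beyond `1e-8` relative is an
#'   error; tiny asymmetry is symmetrised as `(M + t(M))/2`).
#' @return A list with `mat` (PSD to tolerance 1e-12) and `truncated`.
#' @examples
#' truncate_psd(matrix(c(1, 2, 2, 1), 2, 2))
#' @export
truncate_psd <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  scale <- max(abs(mat), 1e-300)
  if (max(abs(mat - t(mat))) > 1e-8 * scale) {
    stop("Matrix is not symmetric.", call. = FALSE)
  }
  m <- (mat + t(mat)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values >= -1e-12 * scale)) {
    return(list(mat = m, truncated = FALSE))
  }
  lam <- pmax(e$values, 0)
  out <- e$vectors %*% (lam * t(e$vectors))
  out <- (out + t(out)) / 2
  list(mat = out, truncated = TRUE)
}

#' Inference for a linear combination of the pooled effects
#'
#' For coefficients `c`, the estimate is `c'beta` with standard error
#' `sqrt(c' Sigma c)` using the (PSD) joint covariance, and a normal 95%
#' confidence interval.
#'
#' @param fit A `joint_fit` (from [fit_mmom()], [fit_jackson()] or
#'   [fit_reml()]).
#' @param coeffs Numeric coefficient vector matching `length(fit$beta)`;
#'   must not be all zero.
#' @return A `function_inference` object: `estimate`, `se`, `ci_low`,
#'   `ci_high`, `function_spec`.
#' @examples
#' d <- tibble::tibble(y1 = c(0.1, 0.4, 0.3), s1 = c(0.2, 0.3, 0.25),
#'                     y2 = c(1.8, 2.1, 2.4), s2 = c(0.4, 0.3, 0.5))
#' linear_combo(fit_mmom(d), c(1, -1))  # difference beta1 - beta2
#' @export
linear_combo <- function(fit, coeffs) {
  stopifnot(inherits(fit, "joint_fit"))
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != length(fit$beta)) {
    stop("`coeffs` must match the length of the coefficient vector.",
         call. = FALSE)
  }
  if (all(coeffs == 0)) stop("Zero coefficient vector.", call. = FALSE)
  est <- sum(coeffs * fit$beta)
  v <- drop(t(coeffs) %*% fit$sigma %*% coeffs)
  se <- sqrt(max(v, 0))
  new_function_inference(est, se, spec = list(type = "linear", coeffs = coeffs))
}

#' Delta-method inference for a function of the pooled effects
#'
#' First-order (delta-method) inference for a smooth scalar function
#' `f(beta1, beta2)`: `se = sqrt(g' Sigma g)` with `g` the gradient of `f`
#' at the estimates. The gradient is supplied analytically via `grad` or
#' computed by central differences with step `1e-6 * (1 + |beta_j|)`.
#'
#' @inheritParams linear_combo
#' @param f A function of two numeric arguments returning a finite scalar
#'   at the estimates.
#' @param grad Optional analytic gradient: function of two arguments
#'   returning a length-2 numeric vector.
#' @return A `function_inference` object.
#' @examples
#' d <- tibble::tibble(y1 = c(0.9, 1.1, 1.0), s1 = c(0.2, 0.3, 0.25),
#'                     y2 = c(1.8, 2.1, 2.4), s2 = c(0.4, 0.3, 0.5))
#' delta_method(fit_mmom(d), function(b1, b2) b1 / b2)
#' @export
delta_method <- function(fit, f, grad = NULL) {
  stopifnot(inherits(fit, "joint_fit"), is.function(f))
  b <- unname(fit$beta)
  est <- f(b[1], b[2])
  if (!is.finite(est)) {
    stop("Function value is not finite at the estimates.", call. = FALSE)
  }
  if (is.null(grad)) {
    g <- numeric(2)
    for (j in 1:2) {
      h <- 1e-6 * (1 + abs(b[j]))
      bp <- b; bm <- b
      bp[j] <- bp[j] + h
      bm[j] <- bm[j] - h
      g[j] <- (f(bp[1], bp[2]) - f(bm[1], bm[2])) / (2 * h)
    }
  } else {
    g <- as.numeric(grad(b[1], b[2]))
    stopifnot(length(g) == 2)
  }
  if (any(!is.finite(g))) {
    stop("Gradient is not finite at the estimates.", call. = FALSE)
  }
  v <- drop(t(g) %*% fit$sigma %*% g)
  se <- sqrt(max(v, 0))
  new_function_inference(est, se,
                         spec = list(type = "delta", f = f, gradient = g))
}

new_function_inference <- function(estimate, se, spec) {
  structure(
    list(estimate = estimate, se = se,
         ci_low = estimate - 1.96 * se, ci_high = estimate + 1.96 * se,
         function_spec = spec),
    class = "function_inference"
  )
}

#' @export
print.function_inference <- function(x, ...) {
  cat(sprintf("%s-method inference: %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$function_spec$type, x$estimate, x$se, x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
tidy.function_inference <- function(x, ...) {
  tibble::tibble(term = x$function_spec$type, estimate = x$estimate,
                 std.error = x$se, conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("Joint bivariate fit (method: %s)\n", x$method))
  tab <- tidy(x)
  print(as.data.frame(tab), row.names = FALSE, digits = 4)
  rho <- x$sigma[1, 2] / sqrt(x$sigma[1, 1] * x$sigma[2, 2])
  cat(sprintf("  cov(beta1, beta2) = %.5f  (correlation %.3f)%s\n",
              x$sigma[1, 2], rho,
              if (isTRUE(x$truncated)) "  [PSD-truncated]" else ""))
  invisible(x)
}

#' @export
tidy.joint_fit <- function(x, ...) {
  if (x$method == "mmom" && !is.null(x$marginals)) {
    se <- c(x$marginals[[1]]$se, x$marginals[[2]]$se)
  } else {
    se <- sqrt(diag(x$sigma))
  }
  tibble::tibble(
    term = c("beta1", "beta2"),
    estimate = unname(x$beta),
    std.error = se,
    conf.low = unname(x$beta) - 1.96 * se,
    conf.high = unname(x$beta) + 1.96 * se
  )
}

#' @export
glance.joint_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    cov12 = x$sigma[1, 2],
    correlation = x$sigma[1, 2] / sqrt(x$sigma[1, 1] * x$sigma[2, 2]),
    truncated = isTRUE(x$truncated)
  )
}

#' Forest-style plot of a joint bivariate fit
#'
#' Point estimates and 95% intervals for the two pooled effects.
#'
#' @param object A `joint_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.joint_fit <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.15
    ) +
    ggplot2::labs(x = "Pooled effect (95% CI)", y = NULL,
                  title = sprintf("Joint fit (%s)", object$method)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
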