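#' Configuration for the bivariate simulation study
#'
#' Encodes the two-stage hierarchical generator used throughout the
#' package's simulation study: true effects drawn from a bivariate normal
#' with between-study variances `tau2` and correlation `rho_b`, observed
#' estimates drawn around them with within-study variances sampled as the
#' square of a `N(s2_mean, s2_var)` draw (`s2_var` is the *variance*; the
#' implied median within-study variance is about 0.26 at the defaults)
#' and within-study correlation `rho_w`, and optional MCAR deletion of
#' each outcome independently.
#'
#' @param m Studies per meta-analysis (the study sizes of interest are 10
#'   and 25).
#' @param beta True overall effects; default `c(0, 2)`.
#' @param tau2 Common between-study variance (default 0.5; 0.25 and 0.1
#'   are the smaller-heterogeneity settings).
#' @param rho_b_grid Between-study correlation grid.
#' @param rho_w_grid Within-study correlation grid.
#' @param s2_mean,s2_var Mean and variance of the normal whose square is a
#'   within-study variance.
#' @param missing_frac MCAR deletion probability per outcome (0 or 0.3).
#' @param n_reps Replicates per grid cell.
#' @param seed Master seed; per-cell streams are derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m = 10, beta = c(0, 2), tau2 = 0.5,
                       rho_b_grid = c(-0.8, -0.6, -0.4, 0, 0.4, 0.6, 0.8),
                       rho_w_grid = c(-0.8, -0.5, 0, 0.5, 0.8),
                       s2_mean = 0.25, s2_var = 0.50,
                       missing_frac = 0, n_reps = 200, seed = 1) {
  stopifnot(m >= 1, length(beta) == 2, tau2 > 0,
            all(abs(rho_b_grid) <= 1), all(abs(rho_w_grid) <= 1),
            s2_var > 0, missing_frac >= 0, missing_frac <= 0.5,
            n_reps >= 1)
  structure(
    list(m = m, beta = beta, tau2 = tau2, rho_b_grid = rho_b_grid,
         rho_w_grid = rho_w_grid, s2_mean = s2_mean, s2_var = s2_var,
         missing_frac = missing_frac, n_reps = n_reps,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Named simulation presets
#'
#' Four standard configurations at `tau2 = 0.5`: `"figure1"` (m = 10,
#' complete data), `"figure2"` (m = 25, complete), `"figure3"` (m = 10,
#' 30% MCAR per outcome), `"figure4"` (m = 25, 30% MCAR).
#'
#' @param name Preset name.
#' @param n_reps,seed Passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("figure1", "figure2", "figure3", "figure4"),
                       n_reps = 200, seed = 1) {
  name <- match.arg(name)
  args <- switch(name,
    figure1 = list(m = 10, missing_frac = 0),
    figure2 = list(m = 25, missing_frac = 0),
    figure3 = list(m = 10, missing_frac = 0.3),
    figure4 = list(m = 25, missing_frac = 0.3)
  )
  do.call(sim_config, c(args, list(n_reps = n_reps, seed = seed)))
}

#' Draw one bivariate meta-analysis dataset
#'
#' Two-stage generator: study-specific true effects
#' `theta_i ~ N2(beta, Omega(tau2, rho_b))`, then observed estimates
#' `y_i | theta_i ~ N2(theta_i, Delta_i)` with within-study variances
#' `s_ij^2` drawn as squared `N(s2_mean, s2_var)` values (exact zeros are
#' redrawn) and within-study correlation `rho_w`. Each outcome is then
#' deleted independently with probability `missing_frac` (MCAR); a row
#' can lose both outcomes, and `rho_w` is recorded only on rows keeping
#' both. Uses the current RNG state.
#'
#' @param cfg A `sim_config`.
#' @param rho_b,rho_w Between- and within-study correlations for this
#'   draw.
#' @return A study-level tibble with columns `study`, `y1`, `s1`, `y2`,
#'   `s2`, `rho_w`.
#' @export
generate_meta_data <- function(cfg, rho_b, rho_w) {
  stopifnot(inherits(cfg, "sim_config"), abs(rho_b) <= 1, abs(rho_w) <= 1)
  m <- cfg$m
  tau <- sqrt(cfg$tau2)
  # between-study level, via the Cholesky factor of Omega
  z1 <- stats::rnorm(m)
  z2 <- stats::rnorm(m)
  th1 <- cfg$beta[1] + tau * z1
  th2 <- cfg$beta[2] + tau * (rho_b * z1 + sqrt(1 - rho_b^2) * z2)
  # within-study variances: square of a normal draw
  sd0 <- sqrt(cfg$s2_var)
  draw_s2 <- function(n) {
    x <- stats::rnorm(n, cfg$s2_mean, sd0)^2
    while (any(x == 0)) x[x == 0] <- stats::rnorm(sum(x == 0), cfg$s2_mean, sd0)^2
    x
  }
  s1sq <- draw_s2(m)
  s2sq <- draw_s2(m)
  e1 <- stats::rnorm(m)
  e2 <- stats::rnorm(m)
  y1 <- th1 + sqrt(s1sq) * e1
  y2 <- th2 + sqrt(s2sq) * (rho_w * e1 + sqrt(1 - rho_w^2) * e2)
  d <- tibble::tibble(
    study = as.character(seq_len(m)),
    y1 = y1, s1 = sqrt(s1sq), y2 = y2, s2 = sqrt(s2sq),
    rho_w = rep(rho_w, m)
  )
  if (cfg$missing_frac > 0) {
    drop1 <- stats::runif(m) < cfg$missing_frac
    drop2 <- stats::runif(m) < cfg$missing_frac
    d$y1[drop1] <- NA_real_; d$s1[drop1] <- NA_real_
    d$y2[drop2] <- NA_real_; d$s2[drop2] <- NA_real_
    d$rho_w[drop1 | drop2] <- NA_real_
  }
  d
}

# Fit one replicate with each requested method; returns a small list of
# per-method (delta_hat, se, trunc, nonconv) records, NULL on failure.
fit_one_rep <- function(d, methods) {
  out <- list()
  if ("mmom" %in% methods) {
    out$mmom <- tryCatch({
      f <- fit_mmom(d, model = "random")
      li <- linear_combo(f, c(1, -1))
      c(est = li$estimate, se = li$se, trunc = as.numeric(f$truncated),
        nonconv = 0)
    }, error = function(e) NULL)
  }
  if ("jackson" %in% methods) {
    out$jackson <- tryCatch({
      f <- fit_jackson(d)
      se <- sqrt(drop(t(c(1, -1)) %*% f$sigma %*% c(1, -1)))
      c(est = unname(f$beta[1] - f$beta[2]), se = se,
        trunc = as.numeric(f$truncated), nonconv = 0)
    }, error = function(e) NULL)
  }
  if ("reml" %in% methods) {
    out$reml <- tryCatch({
      f <- fit_reml(d)
      se <- sqrt(drop(t(c(1, -1)) %*% f$joint$sigma %*% c(1, -1)))
      c(est = unname(f$joint$beta[1] - f$joint$beta[2]), se = se,
        trunc = 0, nonconv = as.numeric(!f$converged))
    }, error = function(e) NULL)
  }
  out
}

#' Run one simulation cell
#'
#' Generates `n_reps` datasets at one `(rho_b, rho_w)` setting, fits the
#' requested methods, and aggregates the estimate of the effect-size
#' difference `delta = beta1 - beta2` (standard errors via
#' `sqrt((1,-1)' V (1,-1))`) into bias, empirical 95% coverage, relative
#' efficiency versus REML, and truncation / non-convergence frequencies.
#' Replicates where a method fails are excluded from that method's
#' aggregates and counted.
#'
#' Relative efficiency is the squared ratio of the Monte-Carlo standard
#' errors of the estimators,
#' `re_pct = 100 * var_emp(delta_reml) / var_emp(delta_method)`, i.e. the
#' empirical sampling variance of the REML estimator over that of the
#' method under comparison; values above 100 mean the method beats REML
#' in that cell.
#'
#' @param cfg A `sim_config`.
#' @param rho_b,rho_w Cell coordinates.
#' @param methods Subset of `c("mmom", "jackson", "reml")`. Relative
#'   efficiency is reported only when `"reml"` is included.
#' @return A tibble with one row per method: `rho_b`, `rho_w`, `method`,
#'   `bias`, `mc_se_bias`, `cp`, `re_pct`, `trunc_freq`, `nonconv_freq`,
#'   `n_used`, `n_excluded`.
#' @export
run_sim_cell <- function(cfg, rho_b, rho_w,
                         methods = c("mmom", "jackson", "reml")) {
  methods <- match.arg(methods, c("mmom", "jackson", "reml"),
                       several.ok = TRUE)
  delta_true <- cfg$beta[1] - cfg$beta[2]
  reps <- vector("list", cfg$n_reps)
  for (r in seq_len(cfg$n_reps)) {
    d <- generate_meta_data(cfg, rho_b, rho_w)
    reps[[r]] <- fit_one_rep(d, methods)
  }
  agg <- function(method) {
    recs <- purrr::compact(purrr::map(reps, method))
    n <- length(recs)
    if (n == 0L) {
      return(tibble::tibble(
        rho_b = rho_b, rho_w = rho_w, method = method,
        bias = NA_real_, mc_se_bias = NA_real_, cp = NA_real_,
        re_pct = NA_real_, trunc_freq = NA_real_, nonconv_freq = NA_real_,
        n_used = 0L, n_excluded = cfg$n_reps
      ))
    }
    est <- purrr::map_dbl(recs, "est")
    se <- purrr::map_dbl(recs, "se")
    cover <- abs(est - delta_true) <= 1.96 * se
    tibble::tibble(
      rho_b = rho_b, rho_w = rho_w, method = method,
      bias = mean(est) - delta_true,
      mc_se_bias = stats::sd(est) / sqrt(n),
      cp = mean(cover),
      re_pct = NA_real_,
      trunc_freq = mean(purrr::map_dbl(recs, "trunc")),
      nonconv_freq = mean(purrr::map_dbl(recs, "nonconv")),
      n_used = n, n_excluded = cfg$n_reps - n,
      var_emp = stats::var(est)
    )
  }
  out <- dplyr::bind_rows(purrr::map(methods, agg))
  if ("reml" %in% methods) {
    ref <- out$var_emp[out$method == "reml"]
    if (length(ref) == 1L && is.finite(ref)) {
      out$re_pct <- 100 * ref / out$var_emp
    }
  }
  out$var_emp <- NULL
  out
}

#' Run the full simulation grid
#'
#' Loops [run_sim_cell()] over the `rho_b` x `rho_w` grid of the
#' configuration. Per-cell RNG streams are derived deterministically from
#' the master seed, so results are reproducible and independent of cell
#' evaluation order.
#'
#' @inheritParams run_sim_cell
#' @param progress Print a line per cell.
#' @return A tibble of class `sim_summary` with one row per (cell,
#'   method); columns as in [run_sim_cell()] plus the configuration as
#'   attribute `"config"`.
#' @export
run_sim_grid <- function(cfg, methods = c("mmom", "jackson", "reml"),
                         progress = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  cells <- expand.grid(rho_w = cfg$rho_w_grid, rho_b = cfg$rho_b_grid,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[, c("rho_b", "rho_w")]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  res <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    set.seed(cell_seeds[k])
    res[[k]] <- run_sim_cell(cfg, cells$rho_b[k], cells$rho_w[k],
                             methods = methods)
    if (progress) {
      message(sprintf("cell %d/%d (rho_b=%.1f, rho_w=%.1f) done",
                      k, nrow(cells), cells$rho_b[k], cells$rho_w[k]))
    }
  }
  out <- dplyr::bind_rows(res)
  attr(out, "config") <- cfg
  class(out) <- c("sim_summary", class(out))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Summary plot of a simulation grid
#'
#' Bias, coverage and relative efficiency against the between-study
#' correlation, one line per method, faceted by within-study correlation.
#'
#' @param object A `sim_summary` from [run_sim_grid()].
#' @param metric One of `"re_pct"`, `"cp"`, `"bias"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_summary <- function(object, metric = c("re_pct", "cp", "bias"),
                                 ...) {
  metric <- match.arg(metric)
  lab <- c(re_pct = "Relative efficiency vs REML (%)",
           cp = "Coverage of nominal 95% CI",
           bias = "Bias of the estimated difference")[[metric]]
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rho_b, y = .data[[metric]],
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~rho_w, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Between-study correlation", y = lab,
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Write a simulation summary to CSV
#'
#' @param summary A `sim_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(summary, path) {
  readr::write_csv(tibble::as_tibble(summary), path)
  invisible(path)
}
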