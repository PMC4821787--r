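#' Validate a bivariate meta-analysis dataset
#'
#' Checks and normalises a study-level table for use with the fitting
#' functions in this package. Each row is one study; the two outcomes are
#' held in columns `y1`/`s1` and `y2`/`s2` (point estimate and within-study
#' standard error), with an optional within-study correlation `rho_w` and
#' optional covariate columns prefixed `x1_` / `x2_` for meta-regression.
#' Missing outcomes are encoded as `NA`.
#'
#' @param data A data frame with at least one complete `(y, s)` outcome pair.
#' @param quiet If `TRUE`, suppress informational messages.
#' @return A tibble with columns `study`, `y1`, `s1`, `y2`, `s2`, `rho_w`
#'   (plus any covariate columns), one row per study, in the input row
#'   order. A `study` column is created from row numbers when absent.
#'
#' @details Invariants enforced: `s_j` present iff `y_j` present and
#'   strictly positive; `rho_w` only on rows reporting both outcomes, in
#'   `[-1, 1]`. Violations raise an error naming the offending row.
#' @examples
#' d <- tibble::tibble(y1 = c(0.2, 0.5), s1 = c(0.3, 0.4),
#'                     y2 = c(1.9, NA), s2 = c(0.5, NA))
#' as_meta_data(d)
#' @export
as_meta_data <- function(data, quiet = TRUE) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame of study-level results.", call. = FALSE)
  }
  d <- tibble::as_tibble(data)
  has1 <- all(c("y1", "s1") %in% names(d))
  has2 <- all(c("y2", "s2") %in% names(d))
  if (!has1 && !has2) {
    stop("`data` must contain at least one outcome pair (y1,s1) or (y2,s2).",
         call. = FALSE)
  }
  if (!"study" %in% names(d)) d$study <- as.character(seq_len(nrow(d)))
  d$study <- as.character(d$study)
  for (nm in c("y1", "s1", "y2", "s2", "rho_w")) {
    if (!nm %in% names(d)) d[[nm]] <- NA_real_
    d[[nm]] <- as.numeric(d[[nm]])
  }
  if (nrow(d) == 0L) stop("Empty dataset: no study rows found.", call. = FALSE)

  for (j in 1:2) {
    y <- d[[paste0("y", j)]]
    s <- d[[paste0("s", j)]]
    bad <- which(is.na(y) != is.na(s))
    if (length(bad)) {
      stop(sprintf("Row %d: outcome %d must have both estimate and standard error or neither.",
                   bad[1], j), call. = FALSE)
    }
    bad <- which(!is.na(s) & s <= 0)
    if (length(bad)) {
      stop(sprintf("Row %d: standard error s%d must be strictly positive.",
                   bad[1], j), call. = FALSE)
    }
  }
  both <- !is.na(d$y1) & !is.na(d$y2)
  bad <- which(!is.na(d$rho_w) & !both)
  if (length(bad)) {
    stop(sprintf("Row %d: rho_w given but both outcomes are not reported.", bad[1]),
         call. = FALSE)
  }
  bad <- which(!is.na(d$rho_w) & (d$rho_w < -1 | d$rho_w > 1))
  if (length(bad)) {
    stop(sprintf("Row %d: rho_w must lie in [-1, 1].", bad[1]), call. = FALSE)
  }
  if (all(is.na(d$y1)) && all(is.na(d$y2))) {
    stop("Empty dataset: no parsable outcome values.", call. = FALSE)
  }
  for (nm in c(".aug1", ".aug2")) {
    if (nm %in% names(d)) d[[nm]] <- as.logical(d[[nm]]) else d[[nm]] <- FALSE
    d[[nm]][is.na(d[[nm]])] <- FALSE
  }
  core <- c("study", "y1", "s1", "y2", "s2", "rho_w")
  xcols <- grep("^x[12]_", names(d), value = TRUE)
  d <- d[, c(core, xcols, c(".aug1", ".aug2"))]
  if (!quiet) {
    rs <- reporting_sets(d)
    message(sprintf("%d studies: %d report outcome 1, %d outcome 2, %d both.",
                    nrow(d), length(rs$r1), length(rs$r2), length(rs$r12)))
  }
  d
}

#' Reporting index sets of a bivariate dataset
#'
#' @param data A study-level table (see [as_meta_data()]).
#' @return A list with integer row indices `r1`, `r2` (studies reporting
#'   outcome 1 resp. 2) and `r12 = intersect(r1, r2)`, plus `m1`, `m2`,
#'   the *effective* reporting counts, which exclude rows whose outcome
#'   values were filled in by [augment_mcar()].
#' @export
reporting_sets <- function(data) {
  r1 <- which(!is.na(data$y1))
  r2 <- which(!is.na(data$y2))
  aug1 <- if (".aug1" %in% names(data)) data$.aug1 else rep(FALSE, nrow(data))
  aug2 <- if (".aug2" %in% names(data)) data$.aug2 else rep(FALSE, nrow(data))
  list(r1 = r1, r2 = r2, r12 = intersect(r1, r2),
       m1 = sum(!is.na(data$y1) & !aug1),
       m2 = sum(!is.na(data$y2) & !aug2))
}

#' Read a bivariate meta-analysis dataset from CSV
#'
#' Expects a header row and comma separation, with columns `study`, `y1`,
#' `s1`, `y2`, `s2`, `rho_w` (any subset beyond one complete outcome pair)
#' and optional covariate columns `x1_*` / `x2_*`. Empty cells and `NA` both
#' denote a missing value. Alternative column names can be mapped via
#' `dialect`.
#'
#' @param path Path to a CSV file.
#' @param dialect Optional named character vector mapping standard names to
#'   the file's column names, e.g. `c(y1 = "logHR_cvd", s1 = "se_cvd")`.
#' @return A validated tibble (see [as_meta_data()]).
#' @export
read_meta_csv <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  d <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                       progress = FALSE)
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      if (dialect[[std]] %in% names(d)) {
        names(d)[names(d) == dialect[[std]]] <- std
      }
    }
  }
  as_meta_data(d)
}

#' Write a bivariate meta-analysis dataset to CSV
#'
#' Missing cells are written as empty strings. Round-trips through
#' [read_meta_csv()] for finite decimal inputs.
#'
#' @param data A study-level table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_meta_csv <- function(data, path) {
  d <- as_meta_data(data)
  d$.aug1 <- NULL
  d$.aug2 <- NULL
  readr::write_csv(d, path, na = "")
  invisible(path)
}

#' Complete a dataset by large-variance augmentation (MCAR)
#'
#' Under the missing-completely-at-random assumption, computations on a
#' dataset with missing outcomes can be carried out with complete-data
#' formulas by assigning a very large within-study variance to each missing
#' outcome and setting the missing estimate — and the within-study
#' correlation of any row touched — to zero. The filled cells carry
#' essentially no weight, so pooled estimates and covariances agree with
#' the direct incomplete-data formulas up to terms of order
#' `1/large_variance`.
#'
#' Augmented cells are flagged in `.aug1`/`.aug2`; degrees-of-freedom
#' counts in the moment estimators use the effective (non-augmented)
#' reporting counts, and Jackson's moment equations use the original
#' reporting sets, so augmentation never masquerades as information.
#'
#' @param data A study-level table, possibly with missing outcomes.
#' @param large_variance Within-study variance assigned to missing
#'   outcomes; default `1e6`.
#' @return A complete tibble (no missing outcome cells); the input is not
#'   modified.
#' @examples
#' d <- tibble::tibble(y1 = c(0.2, 0.5), s1 = c(0.3, 0.4),
#'                     y2 = c(1.9, NA), s2 = c(0.5, NA))
#' augment_mcar(d)
#' @export
augment_mcar <- function(data, large_variance = 1e6) {
  stopifnot(is.numeric(large_variance), large_variance > 0)
  d <- as_meta_data(data)
  miss1 <- is.na(d$y1)
  miss2 <- is.na(d$y2)
  touched <- miss1 | miss2
  d$y1[miss1] <- 0
  d$s1[miss1] <- sqrt(large_variance)
  d$y2[miss2] <- 0
  d$s2[miss2] <- sqrt(large_variance)
  d$rho_w[touched] <- 0
  d$.aug1 <- d$.aug1 | miss1
  d$.aug2 <- d$.aug2 | miss2
  d
}

# Internal: per-outcome extraction over the reporting set.
# Returns y, s2 (variances), augmented flags, effective count m_eff.
outcome_slice <- function(data, outcome) {
  stopifnot(outcome %in% 1:2)
  y <- data[[paste0("y", outcome)]]
  s <- data[[paste0("s", outcome)]]
  aug <- data[[paste0(".aug", outcome)]]
  if (is.null(aug)) aug <- rep(FALSE, length(y))
  keep <- !is.na(y)
  list(idx = which(keep), y = y[keep], s2 = s[keep]^2, aug = aug[keep],
       m_eff = sum(keep & !aug))
}
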