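# Statistics layer: age-adjusted partial Spearman correlation, paired and
# one-sample t tests with confidence intervals, Holm step-down adjustment,
# and the headline analysis battery over a cohort table.

#' Cohort table
#'
#' One row per patient: age at treatment, motor scores per timepoint and the
#' derived transduced connection-area fractions feeding the statistics
#' layer.
#'
#' @param df data frame; must contain \code{patient}, \code{age} and the
#'   AIMS columns; one row per patient.
#' @return tibble with class \code{cohort_table}.
#' @export
cohort_table <- function(df) {
  req <- c("patient", "age", "aims_baseline", "aims_6m")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$patient)) stop("one row per patient required")
  if (any(df$age <= 0)) stop("ages must be positive")
  if ("delta_aims_6m" %in% names(df) &&
      !isTRUE(all.equal(df$delta_aims_6m, df$aims_6m - df$aims_baseline)))
    stop("delta_aims_6m is inconsistent with the per-timepoint AIMS columns")
  out <- tibble::as_tibble(df)
  class(out) <- c("cohort_table", class(out))
  out
}

test_result <- function(test, unit, n, statistic, df, estimate, ci, p,
                        note = NA_character_) {
  tibble::tibble(
    test = test, unit = unit, n = as.integer(n),
    statistic = statistic, df = df, estimate = estimate,
    ci_low = ci[1], ci_high = ci[2], p = p, p_adj = NA_real_, note = note
  )
}

#' Partial Spearman correlation adjusted for a covariate
#'
#' All three variables are ranked (average ranks for ties); the partial
#' correlation of the ranks is
#' \deqn{\rho_{xy.z} = (r_{xy} - r_{xz} r_{yz}) /
#'   \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}.}
#' The default two-sided p comes from \eqn{t = \rho \sqrt{(n-3)/(1-\rho^2)}}
#' on n - 3 degrees of freedom; an exact-style permutation p (permuting x)
#' is available and preferred at very small n, where the t approximation is
#' rough.
#'
#' @param x,y,covariate numeric vectors of equal length (n >= 5).
#' @param method "approx" (t on n - 3 df) or "permutation".
#' @param n_perm permutations when \code{method = "permutation"}.
#' @return one-row tibble (test, n, statistic = rho, df, p, CI via Fisher z).
#' @export
partial_spearman <- function(x, y, covariate,
                             method = c("approx", "permutation"),
                             n_perm = 10000) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n || length(covariate) != n)
    stop("x, y and covariate must have equal length")
  if (n < 5) stop("need n >= 5 for the partial correlation")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("x and y must be nonconstant after ranking")

  if (stats::var(covariate) == 0) {
    warning("constant covariate: falling back to plain Spearman correlation")
    rho <- stats::cor(rx, ry)
  } else {
    rz <- rank(covariate)
    r_xy <- stats::cor(rx, ry); r_xz <- stats::cor(rx, rz)
    r_yz <- stats::cor(ry, rz)
    if (abs(r_xz) >= 1 || abs(r_yz) >= 1)
      stop("covariate is perfectly rank-correlated with x or y; ",
           "partial correlation undefined")
    rho <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  }
  rho <- min(1, max(-1, rho))

  df <- n - 3
  if (method == "approx") {
    if (abs(rho) == 1) {
      p <- 0
    } else {
      tval <- rho * sqrt(df / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tval), df)
    }
  } else {
    obs <- abs(rho)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      xp <- sample(x)
      rho_b <- tryCatch(
        partial_rho_only(xp, y, covariate),
        error = function(e) NA_real_)
      if (!is.na(rho_b) && abs(rho_b) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
  }
  # Fisher-z interval for the partial coefficient (n - 3 - 1 effective)
  ci <- c(NA_real_, NA_real_)
  if (abs(rho) < 1 && n > 4) {
    z <- atanh(rho); se <- 1 / sqrt(n - 4)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  test_result("partial_spearman", unit = NA_character_, n = n,
              statistic = rho, df = df, estimate = rho, ci = ci, p = p,
              note = method)
}

partial_rho_only <- function(x, y, z) {
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  r_xy <- stats::cor(rx, ry); r_xz <- stats::cor(rx, rz)
  r_yz <- stats::cor(ry, rz)
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Paired two-tailed t test
#'
#' @param before,after numeric vectors of equal length (n >= 2).
#' @param unit label carried into the result row.
#' @return one-row tibble with t, df, two-sided p and the 95 percent CI of
#'   the mean difference (after - before).
#' @export
paired_t <- function(before, after, unit = NA_character_) {
  n <- length(before)
  if (length(after) != n) stop("before/after must have equal length")
  if (n < 2) stop("need n >= 2 pairs")
  d <- after - before
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d))))
    stop("degenerate paired test: differences have zero variance (all ",
         format(d[1]), ")")
  tt <- stats::t.test(after, before, paired = TRUE)
  test_result("paired_t", unit = unit, n = n,
              statistic = unname(tt$statistic), df = unname(tt$parameter),
              estimate = unname(tt$estimate), ci = tt$conf.int,
              p = tt$p.value)
}

#' One-sample two-tailed t test
#'
#' @param values numeric vector (n >= 2), nonzero variance.
#' @param mu0 hypothesized mean (default 0).
#' @param unit label carried into the result row.
#' @return one-row tibble with t, df, p and the 95 percent CI of the mean.
#' @export
one_sample_t <- function(values, mu0 = 0, unit = NA_character_) {
  n <- length(values)
  if (n < 2) stop("need n >= 2 values")
  if (stats::var(values) == 0)
    stop("degenerate one-sample test: values have zero variance")
  tt <- stats::t.test(values, mu = mu0)
  test_result("one_sample_t", unit = unit, n = n,
              statistic = unname(tt$statistic), df = unname(tt$parameter),
              estimate = unname(tt$estimate), ci = tt$conf.int,
              p = tt$p.value)
}

#' Holm step-down multiple-comparison adjustment
#'
#' Standard Holm procedure: sort p ascending, multiply p(i) by m - i + 1,
#' enforce monotonicity by a running maximum over the sorted sequence, cap
#' at 1, and map back to the input order. Delegates to
#' \code{stats::p.adjust(method = "holm")} after range checks.
#'
#' @param pvals numeric vector of p values in [0, 1].
#' @return adjusted p values in input order.
#' @export
holm_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Headline analysis battery over a phantom (or real) cohort
#'
#' Runs the study's statistics: age-adjusted partial Spearman of the 6M
#' motor score against the transduced connection-area fraction of each
#' motor-system region and of the PFC-in-frontoparietal-control area;
#' one-sample t tests (vs 0 percent) of the transduced fractions per region
#' and per network, Holm-adjusted within each family; and paired t tests of
#' AIMS across timepoints, Holm-adjusted.
#'
#' @param cohort a \code{\link{cohort_table}} with fraction columns
#'   \code{frac_pfc}, \code{frac_pmc}, \code{frac_sma}, \code{frac_m1},
#'   \code{frac_pfc_control} and \code{net_*} columns.
#' @param outcome column used for the correlation analyses; the motor score
#'   at 6M ("aims_6m", default) or its change from baseline
#'   ("delta_aims_6m").
#' @param spearman_method p-value method for \code{\link{partial_spearman}}.
#' @return tidy tibble of test results, one row per configured test.
#' @export
run_headline_analyses <- function(cohort,
                                  outcome = c("aims_6m", "delta_aims_6m"),
                                  spearman_method = c("approx", "permutation")) {
  outcome <- match.arg(outcome)
  spearman_method <- match.arg(spearman_method)
  need <- c(outcome, "age", "frac_pfc", "frac_pmc", "frac_sma", "frac_m1",
            "frac_pfc_control")
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("cohort lacks column(s): ", paste(missing, collapse = ", "))

  y <- cohort[[outcome]]
  rows <- list()

  corr_units <- c(PFC = "frac_pfc", PMC = "frac_pmc", SMA = "frac_sma",
                  M1 = "frac_m1", `PFC in control network` = "frac_pfc_control")
  for (u in names(corr_units)) {
    xcol <- cohort[[corr_units[[u]]]]
    if (stats::var(rank(xcol)) == 0) {
      rows[[length(rows) + 1L]] <- test_result(
        "partial_spearman", unit = u, n = nrow(cohort),
        statistic = NA_real_, df = NA_real_, estimate = NA_real_,
        ci = c(NA_real_, NA_real_), p = NA_real_,
        note = "skipped: fraction constant across patients")
      next
    }
    r <- tryCatch(
      partial_spearman(xcol, y, cohort$age, method = spearman_method),
      error = function(e) test_result(
        "partial_spearman", unit = u, n = nrow(cohort),
        statistic = NA_real_, df = NA_real_, estimate = NA_real_,
        ci = c(NA_real_, NA_real_), p = NA_real_,
        note = paste("skipped:", conditionMessage(e))))
    r$unit <- u
    rows[[length(rows) + 1L]] <- r
  }

  frac_cols <- c(stats::setNames(paste0("frac_", tolower(REGIONS)), REGIONS))
  frac_cols <- frac_cols[frac_cols %in% names(cohort)]
  net_cols <- grep("^net_", names(cohort), value = TRUE)
  for (fam in list(frac_cols, stats::setNames(net_cols, sub("^net_", "", net_cols)))) {
    fam_rows <- list()
    for (u in names(fam)) {
      v <- cohort[[fam[[u]]]]
      fam_rows[[u]] <- if (stats::var(v) == 0) {
        test_result("one_sample_t", unit = u, n = length(v),
                    statistic = NA_real_, df = NA_real_, estimate = mean(v),
                    ci = c(NA_real_, NA_real_), p = NA_real_,
                    note = "skipped: zero variance")
      } else one_sample_t(v, mu0 = 0, unit = u)
    }
    fam_tbl <- do.call(rbind, fam_rows)
    ok <- !is.na(fam_tbl$p)
    fam_tbl$p_adj[ok] <- holm_adjust(fam_tbl$p[ok])
    rows[[length(rows) + 1L]] <- fam_tbl
  }

  if (all(c("aims_2y") %in% names(cohort))) {
    pt <- rbind(
      within_unit(paired_t(cohort$aims_baseline, cohort$aims_6m), "AIMS baseline vs 6M"),
      within_unit(paired_t(cohort$aims_baseline, cohort$aims_2y), "AIMS baseline vs 2Y"),
      within_unit(paired_t(cohort$aims_6m, cohort$aims_2y), "AIMS 6M vs 2Y")
    )
    pt$p_adj <- holm_adjust(pt$p)
    rows[[length(rows) + 1L]] <- pt
  }

  do.call(rbind, rows)
}

within_unit <- function(row, unit) { row$unit <- unit; row }

#' Score-model cohort without imaging (for calibration oracles)
#'
#' Simulates (fraction, age, score) triples from the designed motor-score
#' model, resampling prefrontal fractions from a supplied pool (e.g.
#' phantom-derived). Used to build large-replicate oracle estimates of the
#' designed partial correlation at negligible cost.
#'
#' @param spec a \code{phantom_spec} (score parameters are read from it).
#' @param frac_pool numeric vector of prefrontal transduced fractions
#'   (percent) to resample from.
#' @param n cohort size.
#' @param seed integer seed (mandatory).
#' @param resample draw fractions with replacement from the pool (TRUE) or
#'   recycle the pool as-is when \code{n} is a multiple of its length.
#' @return tibble (frac_pfc, age, aims_6m, delta_aims_6m).
#' @export
simulate_score_cohort <- function(spec, frac_pool, n, seed, resample = TRUE) {
  if (missing(seed)) stop("`seed` is required: generators must be reproducible")
  set.seed(seed)
  frac <- if (resample) sample(frac_pool, n, replace = TRUE)
          else rep(frac_pool, length.out = n)
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  tbl <- tibble::tibble(patient = sprintf("s%06d", seq_len(n)),
                        age = age, frac_pfc = frac)
  sc <- make_motor_scores(spec, tbl, seed = seed_stream(seed, 0, 1))
  cbind(tbl[, c("frac_pfc", "age")], sc[, c("aims_6m", "delta_aims_6m")])
}
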