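#' Z-standardize the index variables
#'
#' Centers and scales (mean 0, SD 1, \code{n - 1} denominator) each of the
#' index columns present among \code{lambda}, \code{delta}, \code{ldi},
#' \code{rec} (and \code{ground_truth_lambda} when present) over the pooled
#' analysis sample. Rows with a missing value in any of these columns are
#' dropped first (listwise exclusion), so that all models see the same
#' standardized sample.
#'
#' @param indices per-participant index table (see
#'   \code{\link{compute_indices}}).
#' @param columns which columns to standardize (default: the index columns
#'   found in the table).
#' @return The filtered table with the named columns z-scored.
#' @export
standardize_variables <- function(indices,
                                  columns = intersect(
                                    c("lambda", "delta", "ldi", "rec",
                                      "ground_truth_lambda"),
                                    names(indices))) {
  if (!length(columns)) stop("no index columns to standardize", call. = FALSE)
  keep <- stats::complete.cases(indices[, columns, drop = FALSE])
  out <- indices[keep, , drop = FALSE]
  if (nrow(out) < 3L) {
    stop("insufficient data: need at least 3 complete rows", call. = FALSE)
  }
  for (cl in columns) {
    v <- out[[cl]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("degenerate input: column '", cl, "' has zero variance",
           call. = FALSE)
    }
    out[[cl]] <- (v - mean(v)) / s
  }
  out
}

# Nakagawa-Schielzeth variance partition for a random-intercept lmer fit.
nakagawa_r2 <- function(fit) {
  vf <- stats::var(as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  vr <- sum(vapply(vc, function(m) m[1, 1], numeric(1)))
  ve <- attr(vc, "sc")^2
  tot <- vf + vr + ve
  list(marginal = vf / tot, conditional = (vf + vr) / tot,
       sigma2 = ve, tau00 = vr, icc = vr / (vr + ve))
}

# Tidy one fitted model (lm or lmerMod) into a validation_result row set.
summarize_validation_fit <- function(fit, label) {
  if (inherits(fit, "lmerMod")) {
    sm <- summary(fit)
    cf <- sm$coefficients
    est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
    r2 <- nakagawa_r2(fit)
    res <- list(model = label, engine = "lmer",
                n = stats::nobs(fit),
                sigma2 = r2$sigma2, tau00 = r2$tau00, icc = r2$icc,
                r2_marginal = r2$marginal, r2_conditional = r2$conditional)
  } else {
    sm <- summary(fit)
    cf <- sm$coefficients
    est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
    res <- list(model = label, engine = "lm",
                n = stats::nobs(fit),
                sigma2 = sm$sigma^2, tau00 = NA_real_, icc = NA_real_,
                r2_marginal = sm$r.squared, r2_conditional = sm$r.squared)
  }
  z <- stats::qnorm(0.975)
  res$coefficients <- data.frame(
    term = rownames(cf),
    estimate = est,
    ci_lower = est - z * se,
    ci_upper = est + z * se,
    p_value = 2 * stats::pnorm(-abs(est / se)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(res, class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Model %s (%s), n = %d\n", x$model, x$engine, x$n))
  print(x$coefficients, digits = 3)
  cat(sprintf("  marginal R2 = %.3f, conditional R2 = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  if (is.finite(x$icc)) cat(sprintf("  ICC = %.3f\n", x$icc))
  invisible(x)
}

#' Fit the convergent/divergent validity models
#'
#' Fits the three standardized validity models relating the curve-based
#' indices to the classic MST scores:
#' \code{ldi ~ lambda + delta}, \code{rec ~ lambda + delta} and
#' \code{lambda ~ delta}. All variables are z-scored over the pooled
#' analysis sample first (so coefficients are on a correlation-like scale).
#' When a grouping column is supplied (a study label with >= 2 levels) the
#' models are random-intercept mixed models fitted by REML with Wald 95\%
#' intervals, Nakagawa marginal/conditional R-squared and
#' ICC; otherwise ordinary least squares. Singular random-effect fits fall
#' back to OLS with a warning.
#'
#' Participants whose curve fit failed or whose \eqn{\lambda} is undefined
#' carry \code{NA} and are listwise-excluded before standardization.
#'
#' @param indices per-participant index table.
#' @param grouping optional name of a grouping column (e.g.
#'   \code{"study_id"}).
#' @return Named list of three \code{validation_result} objects
#'   (\code{ldi}, \code{rec}, \code{collinearity}).
#' @export
fit_validation_models <- function(indices, grouping = NULL) {
  std <- standardize_variables(indices)
  formulas <- list(
    ldi = ldi ~ lambda + delta,
    rec = rec ~ lambda + delta,
    collinearity = lambda ~ delta
  )
  mixed <- FALSE
  if (!is.null(grouping)) {
    if (!grouping %in% names(std)) {
      stop("grouping column '", grouping, "' not found", call. = FALSE)
    }
    if (length(unique(std[[grouping]])) < 2L) {
      stop("grouping requires at least 2 groups", call. = FALSE)
    }
    mixed <- TRUE
  }
  lapply(formulas, function(fo) {
    label <- paste(deparse(fo), collapse = "")
    if (mixed) {
      fo_m <- stats::as.formula(
        paste(deparse(fo), "+ (1 |", grouping, ")"))
      fit <- lme4::lmer(fo_m, data = std, REML = TRUE)
      if (lme4::isSingular(fit, tol = 1e-5)) {
        warning("singular random-effects fit for '", label,
                "'; falling back to OLS", call. = FALSE)
        fit <- stats::lm(fo, data = std)
      }
    } else {
      fit <- stats::lm(fo, data = std)
    }
    summarize_validation_fit(fit, label)
  })
}

#' Sweep recognition-performance thresholds
#'
#' Progressively restricts the sample to participants/agents whose fitted
#' \eqn{\Delta} index is at least each threshold, and reports the
#' R-squared of \code{lambda ~ ldi} and (when the agent truth table is
#' supplied) of \code{lambda ~ ground_truth_lambda} within each subset.
#' Rising R-squared with the threshold indicates that the \eqn{\lambda}
#' index tracks discrimination ability better in participants with intact
#' overall recognition.
#'
#' @param indices per-participant index table.
#' @param truth optional agent truth table with \code{participant_id} and
#'   \code{ground_truth_lambda} (synthetic data); not needed when
#'   \code{indices} already carries a \code{ground_truth_lambda} column.
#' @param thresholds numeric vector of \eqn{\Delta} thresholds.
#' @param min_n subsets smaller than this are skipped with a warning
#'   (default 10).
#' @return Data frame with columns \code{threshold}, \code{n},
#'   \code{r2_lambda_ldi}, \code{r2_lambda_truth} (\code{NA} without a
#'   truth table).
#' @export
delta_threshold_sweep <- function(indices, truth = NULL,
                                  thresholds = seq(0, 0.6, by = 0.1),
                                  min_n = 10L) {
  dat <- indices
  has_truth <- "ground_truth_lambda" %in% names(dat)
  if (!is.null(truth) && !has_truth) {
    dat <- merge(dat, truth[, c("participant_id", "ground_truth_lambda")],
                 by = "participant_id")
    has_truth <- TRUE
  }
  dat <- dat[stats::complete.cases(dat[, c("lambda", "delta", "ldi")]), ,
             drop = FALSE]
  rows <- lapply(thresholds, function(t) {
    sub <- dat[dat$delta >= t, , drop = FALSE]
    if (nrow(sub) < min_n) {
      warning("threshold ", t, " skipped: only ", nrow(sub), " rows",
              call. = FALSE)
      return(NULL)
    }
    r2a <- summary(stats::lm(ldi ~ lambda, data = sub))$r.squared
    r2b <- if (has_truth) {
      summary(stats::lm(ground_truth_lambda ~ lambda, data = sub))$r.squared
    } else NA_real_
    data.frame(threshold = t, n = nrow(sub), r2_lambda_ldi = r2a,
               r2_lambda_truth = r2b)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(threshold = numeric(0), n = integer(0),
                                      r2_lambda_ldi = numeric(0),
                                      r2_lambda_truth = numeric(0))
  rownames(out) <- NULL
  out
}

#' Sensitivity analysis: exclude the most similar lures
#'
#' Removes lure trials with lure bin at or below \code{max_excluded_bin}
#' (the most similar, highest-interference lures), refits every
#' participant's performance curve on the reduced log and recomputes all
#' indices. LDI and REC are recomputed on the same reduced log for
#' comparability. This emulates recognition tests that do not deliberately
#' include high-interference items.
#'
#' @param trials validated trial log.
#' @param max_excluded_bin lure bins \code{<=} this value are dropped
#'   (0 = no exclusion).
#' @param ... passed to \code{\link{compute_indices}}.
#' @return Per-participant index table computed on the reduced log.
#' @export
sensitivity_exclude_similar_lures <- function(trials, max_excluded_bin, ...) {
  trials <- validate_trial_log(trials)
  drop <- trials$condition == "lure" & trials$lure_bin <= max_excluded_bin
  compute_indices(trials[!drop, , drop = FALSE], ...)
}
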