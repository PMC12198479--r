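#' Fit the five-parameter logistic performance curve to one participant
#'
#' Fits \eqn{P_{NEW}(x) = d + (a-d)/(1+(x/c)^b)^e} to a participant's
#' trial-level (dissimilarity, binary novelty response) pairs by bounded
#' nonlinear least squares (Levenberg--Marquardt, \code{minpack.lm::nlsLM}).
#' The fit target is the raw 0/1 outcomes, not binned proportions; set
#' \code{binned = TRUE} to fit per-dissimilarity-level proportions instead
#' (a diagnostic mode).
#'
#' Starting values are data-driven: \code{a} starts at the observed novelty
#' rate at dissimilarity 0, \code{d} at the rate at dissimilarity 1, with
#' \code{b = 5}, \code{c = 0.5}, \code{e = 1}. Parameters are bounded to
#' keep the curve sigmoid-shaped and numerically stable:
#' \code{a, d} in \eqn{[-0.2, 1.2]}, \code{b} in \eqn{(0.01, 100]},
#' \code{c, e} in \eqn{(0.01, 10]}. If the first start fails to converge, a
#' 3x3 grid of restarts over \code{b} in \{1, 5, 20\} and \code{c} in
#' \{0.2, 0.5, 0.8\} is tried; if all fail the fit is flagged
#' non-converged.
#'
#' @param trials validated trial-log rows for a single participant, or any
#'   data frame with columns \code{dissimilarity} and
#'   \code{novelty_response}.
#' @param binned fit level-wise proportions instead of trial-level binaries.
#' @param min_trials minimum number of trials required (default 10).
#' @return A list with elements \code{params} (\code{\link{five_pl}} or
#'   \code{NULL}), \code{converged} (logical), \code{degenerate} (logical:
#'   all responses identical), \code{rss} (residual sum of squares) and
#'   \code{n_trials}.
#' @export
fit_pnew_curve <- function(trials, binned = FALSE, min_trials = 10L) {
  if (!all(c("dissimilarity", "novelty_response") %in% names(trials))) {
    stop("'trials' must have columns dissimilarity and novelty_response ",
         "(run validate_trial_log first)", call. = FALSE)
  }
  x <- trials$dissimilarity
  y <- trials$novelty_response
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_trials) {
    stop("insufficient data: need at least ", min_trials, " trials, got ",
         length(x), call. = FALSE)
  }
  if (length(unique(x)) < 2L) {
    stop("insufficient data: need at least two distinct dissimilarity values",
         call. = FALSE)
  }
  degenerate <- length(unique(y)) == 1L

  if (binned) {
    agg <- stats::aggregate(list(p = y), by = list(x = x), FUN = mean)
    xx <- agg$x; yy <- agg$p
  } else {
    xx <- x; yy <- y
  }

  a0 <- if (any(xx == 0)) mean(yy[xx == 0]) else min(yy)
  d0 <- if (any(xx == 1)) mean(yy[xx == 1]) else max(yy)
  lower <- c(a = -0.2, b = 0.01, c = 0.01, d = -0.2, e = 0.01)
  upper <- c(a = 1.2, b = 100, c = 10, d = 1.2, e = 10)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  a0 <- clamp(a0, -0.19, 1.19)
  d0 <- clamp(d0, -0.19, 1.19)

  starts <- list(c(a = a0, b = 5, c = 0.5, d = d0, e = 1))
  for (b0 in c(1, 5, 20)) for (c0 in c(0.2, 0.5, 0.8)) {
    starts[[length(starts) + 1L]] <- c(a = a0, b = b0, c = c0, d = d0, e = 1)
  }
  starts <- unique(starts)

  resid_fn <- function(par) {
    yy - pnew_eval(list(a = par[[1]], b = par[[2]], c = par[[3]],
                        d = par[[4]], e = par[[5]]), xx)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = st, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    # info codes 1-3 are Levenberg-Marquardt success criteria
    if (!is.null(fit) && fit$info %in% 1:3 && all(is.finite(fit$par))) {
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
      break
    }
  }
  # exhaustive restart pass if the sequential pass found nothing
  if (is.null(best)) {
    for (st in starts) {
      fit <- tryCatch(
        suppressWarnings(minpack.lm::nls.lm(
          par = st, lower = lower, upper = upper, fn = resid_fn,
          control = minpack.lm::nls.lm.control(maxiter = 400)
        )),
        error = function(e) NULL
      )
      if (!is.null(fit) && fit$info %in% 1:4 && all(is.finite(fit$par)) &&
          (is.null(best) || fit$deviance < best$deviance)) {
        best <- fit
      }
    }
  }

  if (is.null(best)) {
    return(list(params = NULL, converged = FALSE, degenerate = degenerate,
                rss = NA_real_, n_trials = length(x)))
  }
  cf <- best$par
  params <- five_pl(cf[["a"]], max(cf[["b"]], 1e-8), max(cf[["c"]], 1e-8),
                    cf[["d"]], max(cf[["e"]], 1e-8))
  list(params = params, converged = TRUE, degenerate = degenerate,
       rss = best$deviance, n_trials = length(x))
}

#' Compute all indices for one participant
#'
#' Fits the performance curve and derives the curve-based indices
#' (\eqn{\Delta}, \eqn{\lambda}, area \eqn{A}) together with the classic
#' mnemonic similarity task scores (LDI, REC) from one participant's trials.
#'
#' @param trials validated trial-log rows for one participant.
#' @param delta_floor \eqn{|\Delta|} floor below which \eqn{\lambda} is
#'   undefined (default 0.01).
#' @param ... passed to \code{\link{fit_pnew_curve}}.
#' @return A one-row data frame with columns \code{participant_id},
#'   \code{lambda}, \code{delta}, \code{area_A}, \code{ldi}, \code{rec},
#'   \code{fit_converged}, \code{lambda_defined}.
#' @export
participant_indices <- function(trials, delta_floor = 0.01, ...) {
  pid <- if ("participant_id" %in% names(trials)) {
    as.character(trials$participant_id[1])
  } else NA_character_
  fit <- fit_pnew_curve(trials, ...)
  if (fit$converged) {
    li <- lambda_index(fit$params, delta_floor = delta_floor)
    lambda <- li$lambda; delta <- li$delta; areaA <- li$area_A
    defined <- li$defined
  } else {
    lambda <- NA_real_; delta <- NA_real_; areaA <- NA_real_
    defined <- FALSE
  }
  counts <- mst_counts(trials)
  ldi <- tryCatch(compute_ldi(counts), error = function(e) NA_real_)
  rec <- tryCatch(compute_rec(counts), error = function(e) NA_real_)
  data.frame(participant_id = pid, lambda = lambda, delta = delta,
             area_A = areaA, ldi = ldi, rec = rec,
             fit_converged = fit$converged, lambda_defined = defined,
             stringsAsFactors = FALSE)
}

#' Compute indices for every participant in a trial log
#'
#' Splits a validated trial log by participant, fits each performance
#' curve, and returns the per-participant index table (one row per
#' participant: \eqn{\lambda}, \eqn{\Delta}, area \eqn{A}, LDI, REC and
#' fit flags). A \code{study_id} column is carried through for grouped
#' (mixed-model) validation analyses.
#'
#' @param trials validated trial log (see \code{\link{validate_trial_log}}).
#' @param delta_floor passed to \code{\link{participant_indices}}.
#' @param ... passed to \code{\link{fit_pnew_curve}}.
#' @return Data frame with one row per participant.
#' @export
compute_indices <- function(trials, delta_floor = 0.01, ...) {
  trials <- validate_trial_log(trials)
  parts <- split(trials, trials$participant_id)
  rows <- lapply(parts, function(tr) {
    row <- participant_indices(tr, delta_floor = delta_floor, ...)
    row$study_id <- as.character(tr$study_id[1])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id), , drop = FALSE]
}
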