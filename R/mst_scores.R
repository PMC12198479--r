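#' Tabulate three-way responses by condition
#'
#' Builds the condition-by-response count table underlying the classic
#' mnemonic similarity task scores, plus per-lure-bin response counts for
#' diagnostics. Rows with missing responses are dropped, so each
#' condition's denominator is its number of valid trials.
#'
#' @param trials data frame with columns \code{condition} (old/lure/new)
#'   and \code{response} (old/similar/new); \code{lure_bin} is used for the
#'   per-bin table when present.
#' @return An object of class \code{"mst_counts"}: a list with
#'   \code{table} (3x3 condition-by-response counts) and \code{by_bin}
#'   (lure-bin-by-response counts, or \code{NULL}).
#' @export
mst_counts <- function(trials) {
  keep <- !is.na(trials$response) & trials$response %in% c("old", "similar", "new")
  tr <- trials[keep, , drop = FALSE]
  tab <- table(factor(tr$condition, levels = c("old", "lure", "new")),
               factor(tr$response, levels = c("old", "similar", "new")))
  by_bin <- NULL
  if ("lure_bin" %in% names(tr)) {
    lures <- tr[tr$condition == "lure", , drop = FALSE]
    if (nrow(lures)) {
      by_bin <- table(factor(lures$lure_bin),
                      factor(lures$response, levels = c("old", "similar", "new")))
    }
  }
  structure(list(table = tab, by_bin = by_bin), class = "mst_counts")
}

#' @export
print.mst_counts <- function(x, ...) {
  cat("MST response counts (condition x response):\n")
  print(x$table)
  invisible(x)
}

#' Lure discrimination index (LDI)
#'
#' The classic MST mnemonic discrimination score: the probability that a
#' lure item is classified as "similar" minus the probability that a new
#' (foil) item is misclassified as "similar". Pooled across lure bins.
#'
#' @param counts an \code{\link{mst_counts}} object (or a trial-log data
#'   frame, which is tabulated first).
#' @return A number in \eqn{[-1, 1]}.
#' @export
compute_ldi <- function(counts) {
  counts <- as_mst_counts(counts)
  tab <- counts$table
  n_lure <- sum(tab["lure", ])
  n_new <- sum(tab["new", ])
  if (n_lure < 1 || n_new < 1) {
    stop("insufficient data: LDI needs at least one lure and one new trial",
         call. = FALSE)
  }
  tab["lure", "similar"] / n_lure - tab["new", "similar"] / n_new
}

#' Recognition score (REC)
#'
#' The classic MST overall recognition score: the probability that an old
#' item is classified as "old" minus the probability that a new (foil) item
#' is misclassified as "old".
#'
#' @inheritParams compute_ldi
#' @return A number in \eqn{[-1, 1]}.
#' @export
compute_rec <- function(counts) {
  counts <- as_mst_counts(counts)
  tab <- counts$table
  n_old <- sum(tab["old", ])
  n_new <- sum(tab["new", ])
  if (n_old < 1 || n_new < 1) {
    stop("insufficient data: REC needs at least one old and one new trial",
         call. = FALSE)
  }
  tab["old", "old"] / n_old - tab["new", "old"] / n_new
}

as_mst_counts <- function(x) {
  if (inherits(x, "mst_counts")) return(x)
  if (is.data.frame(x)) return(mst_counts(x))
  stop("expected an mst_counts object or a trial-log data frame", call. = FALSE)
}
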