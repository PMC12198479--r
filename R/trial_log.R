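#' Map a lure bin to a dissimilarity value
#'
#' Standardizes ordinal lure bins into a dissimilarity index in \eqn{[0,1]}
#' by dividing by the maximum bin. Old items carry bin 0 (dissimilarity 0),
#' lures carry bins 1--5, and new (foil) items carry bin 6 (dissimilarity 1).
#' The divisor is fixed at 6 by default even for tests using fewer bins, so
#' that dissimilarity values remain comparable across designs.
#'
#' @param lure_bin integer vector with values in \code{0:bin_divisor}.
#' @param bin_divisor maximum bin value (default 6).
#' @return Numeric vector \code{lure_bin / bin_divisor}.
#' @examples
#' dissimilarity_from_lure_bin(0:6)
#' @export
dissimilarity_from_lure_bin <- function(lure_bin, bin_divisor = 6) {
  if (!is.numeric(lure_bin) || any(!is.finite(lure_bin)) ||
      any(lure_bin != round(lure_bin))) {
    stop("'lure_bin' must be integer-valued", call. = FALSE)
  }
  if (any(lure_bin < 0 | lure_bin > bin_divisor)) {
    stop("'lure_bin' out of range 0..", bin_divisor, call. = FALSE)
  }
  lure_bin / bin_divisor
}

#' Encode three-way responses as binary novelty responses
#'
#' Recodes old/similar/new responses into the binary outcome modelled by the
#' performance curve: "old" responses are coded 0, "similar" and "new"
#' responses are coded 1 (the stimulus was judged novel in some degree).
#'
#' @param response character (or factor) vector with values
#'   \code{"old"}, \code{"similar"}, \code{"new"}.
#' @return Integer vector of 0/1.
#' @export
encode_novelty_response <- function(response) {
  response <- as.character(response)
  bad <- !(response %in% c("old", "similar", "new"))
  if (any(bad)) {
    stop("unknown response label(s): ",
         paste(unique(response[bad]), collapse = ", "), call. = FALSE)
  }
  as.integer(response != "old")
}

# Required columns of a trial log, in canonical order.
trial_log_columns <- function() {
  c("participant_id", "study_id", "trial_index", "condition", "lure_bin",
    "response")
}

#' Validate and normalize a trial log
#'
#' Checks the trial-log schema (one row per test-phase trial) and derives
#' the \code{dissimilarity} and \code{novelty_response} columns. Required
#' columns: \code{participant_id}, \code{study_id}, \code{trial_index},
#' \code{condition} (old/lure/new), \code{lure_bin} (0 for old, 1--5 for
#' lures, 6 for new), \code{response} (old/similar/new). Unknown columns are
#' preserved.
#'
#' Consistency rules enforced: old trials have bin 0, new trials have the
#' maximum bin, lure trials have bins strictly between.
#'
#' @param trials data frame.
#' @param bin_divisor maximum lure bin (default 6).
#' @return The input data frame with \code{dissimilarity} and
#'   \code{novelty_response} columns added (recomputed if present).
#' @export
validate_trial_log <- function(trials, bin_divisor = 6) {
  if (!is.data.frame(trials)) stop("'trials' must be a data frame", call. = FALSE)
  missing_cols <- setdiff(trial_log_columns(), names(trials))
  if (length(missing_cols)) {
    stop("trial log missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cond <- as.character(trials$condition)
  bad_cond <- !(cond %in% c("old", "lure", "new"))
  if (any(bad_cond)) {
    stop("invalid condition label(s) at row(s): ",
         paste(utils::head(which(bad_cond), 5), collapse = ", "), call. = FALSE)
  }
  bin <- trials$lure_bin
  viol <- (cond == "old" & bin != 0) |
    (cond == "new" & bin != bin_divisor) |
    (cond == "lure" & (bin < 1 | bin > bin_divisor - 1))
  if (any(viol)) {
    stop("condition/lure_bin mismatch at row(s): ",
         paste(utils::head(which(viol), 5), collapse = ", "), call. = FALSE)
  }
  trials$dissimilarity <- dissimilarity_from_lure_bin(bin, bin_divisor)
  trials$novelty_response <- encode_novelty_response(trials$response)
  trials
}

#' Read a trial log from CSV
#'
#' Reads a comma-separated UTF-8 trial log with a mandatory header. Leading
#' lines starting with \code{#} are treated as metadata comments and
#' skipped. The log is validated and the derived \code{dissimilarity} and
#' \code{novelty_response} columns are added.
#'
#' @param path file path.
#' @param bin_divisor maximum lure bin (default 6).
#' @return A validated trial-log data frame.
#' @export
read_trial_log <- function(path, bin_divisor = 6) {
  if (!file.exists(path)) stop("trial log not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  validate_trial_log(df, bin_divisor = bin_divisor)
}

#' Write a trial log (or any table) to CSV with a metadata header
#'
#' Writes comma-separated UTF-8 output with leading \code{#} comment lines
#' recording the package version and any metadata supplied (seed, number of
#' agents, configuration fingerprint). Numeric columns are printed with 9
#' significant digits so that repeated runs are byte-identical.
#'
#' @param x data frame.
#' @param path output file path.
#' @param meta named list of metadata values recorded as comments.
#' @return Invisibly, \code{path}.
#' @export
write_csv_meta <- function(x, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c(list(package = paste0("mdindex ",
                                  as.character(utils::packageVersion("mdindex")))),
            meta)
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  }
  fmt <- x
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) {
      fmt[[j]] <- vapply(fmt[[j]], function(v) {
        if (is.na(v)) "NA" else format(v, digits = 9, scientific = FALSE, trim = TRUE)
      }, character(1))
    }
  }
  utils::write.csv(fmt, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an indices or agents table written by this package
#'
#' @param path file path.
#' @return Data frame (metadata comment lines skipped).
#' @export
read_csv_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
}
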