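# Shared fixtures and independent oracles for the test suite.

# Dense composite-trapezoid quadrature on [0, 1]; the independent oracle
# for every integral computed by the package.
trapezoid_01 <- function(f, n = 1e5L) {
  x <- seq(0, 1, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2) * (x[2] - x[1])
}

# Trial-level data whose empirical novelty rate at each dissimilarity level
# matches a generating 5PL as closely as integer counts allow.
make_proportion_matched_trials <- function(params, per_level = 60L,
                                           levels = (0:6) / 6) {
  rows <- lapply(levels, function(x) {
    p <- pnew_eval(params, x)
    n1 <- round(per_level * p)
    data.frame(dissimilarity = rep(x, per_level),
               novelty_response = c(rep(1L, n1), rep(0L, per_level - n1)))
  })
  do.call(rbind, rows)
}

# Bernoulli trial-level data sampled from a generating 5PL.
make_bernoulli_trials <- function(params, per_level = 200L,
                                  levels = (0:6) / 6) {
  rows <- lapply(levels, function(x) {
    p <- pnew_eval(params, x)
    data.frame(dissimilarity = rep(x, per_level),
               novelty_response = stats::rbinom(per_level, 1L, p))
  })
  do.call(rbind, rows)
}

# Random sigmoid-shaped 5PL parameter draws (a < d so the curve is
# non-decreasing on [0, 1]).
random_five_pl <- function() {
  five_pl(a = runif(1, 0, 0.3), b = runif(1, 0.5, 20),
          c = runif(1, 0.1, 0.9), d = runif(1, 0.7, 1),
          e = runif(1, 0.3, 3))
}

# Minimal valid trial log for schema tests: one participant, 12 trials.
make_tiny_trial_log <- function(pid = "p1", study = "s1") {
  data.frame(
    participant_id = pid,
    study_id = study,
    trial_index = 1:12,
    condition = rep(c("old", "lure", "new"), each = 4),
    lure_bin = c(rep(0L, 4), 1:4, rep(6L, 4)),
    response = c("old", "old", "new", "old",
                 "similar", "old", "similar", "new",
                 "new", "new", "similar", "new"),
    stringsAsFactors = FALSE
  )
}
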