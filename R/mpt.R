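#' Multinomial-processing-tree agent parameters
#'
#' Bundles the parameters of a synthetic recognition-memory agent. On a
#' test trial the agent first attempts recognition: with probability
#' \code{rho} it recognizes an old (or lure-related) studied item, and with
#' probability \code{psi} it recognizes that a new item was not studied. On
#' a lure trial, successful recognition is followed by a discrimination
#' stage: with probability \eqn{\delta(\ell) = 1/(1+\exp(-\beta(\ell-\tau)))}
#' the agent correctly calls the lure "similar", otherwise it calls it
#' "old". If initial recognition fails the agent guesses "old", "similar"
#' or "new" with probabilities \code{gamma_O}, \code{gamma_S},
#' \code{gamma_N} (summing to 1).
#'
#' @param rho probability of recognizing a studied item.
#' @param psi probability of recognizing that a new item was not studied.
#' @param gamma_O,gamma_S,gamma_N guessing probabilities; must sum to 1.
#' @param beta discriminability-curve steepness, in \eqn{[0, 50]}.
#' @param tau discriminability-curve shift, in \eqn{[0, 1]}.
#' @return An object of class \code{"mpt_agent"} (named list) with the
#'   derived \code{ground_truth_lambda} attached.
#' @export
mpt_agent <- function(rho, psi, gamma_O, gamma_S, gamma_N, beta, tau) {
  stopifnot(rho >= 0, rho <= 1, psi >= 0, psi <= 1,
            tau >= 0, tau <= 1, beta >= 0,
            gamma_O >= 0, gamma_S >= 0, gamma_N >= 0)
  if (abs(gamma_O + gamma_S + gamma_N - 1) > 1e-12) {
    stop("guessing probabilities must sum to 1", call. = FALSE)
  }
  structure(list(rho = rho, psi = psi, gamma_O = gamma_O, gamma_S = gamma_S,
                 gamma_N = gamma_N, beta = beta, tau = tau,
                 ground_truth_lambda = ground_truth_lambda(beta, tau)),
            class = "mpt_agent")
}

#' @export
print.mpt_agent <- function(x, ...) {
  cat(sprintf(paste0("MPT agent: rho=%.3f psi=%.3f gamma=(%.3f,%.3f,%.3f) ",
                     "beta=%.2f tau=%.3f  ground-truth lambda=%.3f\n"),
              x$rho, x$psi, x$gamma_O, x$gamma_S, x$gamma_N, x$beta, x$tau,
              x$ground_truth_lambda))
  invisible(x)
}

#' Lure discriminability curve
#'
#' The agent-specific two-parameter logistic
#' \eqn{\delta(\ell) = 1/(1+\exp(-\beta(\ell-\tau)))} giving the
#' probability of correctly discriminating a lure (calling it "similar"
#' given that its studied counterpart was recognized) as a function of the
#' lure's dissimilarity \eqn{\ell \in (0,1)} from the studied item.
#'
#' @param beta steepness (\code{beta = 0} gives a flat 0.5 curve).
#' @param tau horizontal shift.
#' @param ell lure dissimilarity value(s) in \eqn{(0, 1)}.
#' @return Numeric vector of probabilities.
#' @export
lure_discriminability <- function(beta, tau, ell) {
  stats::plogis(beta * (ell - tau))
}

#' Ground-truth mnemonic discrimination of an MPT agent
#'
#' The area under the agent's discriminability curve,
#' \eqn{\int_0^1 \delta(\ell)\, d\ell}, evaluated in closed form:
#' \deqn{\frac{1}{\beta}\log\frac{1 + e^{\beta(1-\tau)}}{1 + e^{-\beta\tau}}}
#' for \eqn{\beta > 0}, and 0.5 for \eqn{\beta = 0}. This is the latent
#' quantity that both the curve-based \eqn{\lambda} index and the classic
#' LDI aim to recover from an agent's responses.
#'
#' @inheritParams lure_discriminability
#' @return A single number in \eqn{[0, 1]}.
#' @export
ground_truth_lambda <- function(beta, tau) {
  stopifnot(beta >= 0)
  if (beta == 0) return(0.5)
  # log(1 + e^z), stable for large z
  log1pexp <- function(z) ifelse(z > 35, z, log1p(exp(pmin(z, 35))))
  (log1pexp(beta * (1 - tau)) - log1pexp(-beta * tau)) / beta
}

#' Closed-form response probabilities of an MPT agent
#'
#' Returns the probabilities of responding "old", "similar" and "new" on a
#' single test trial, following the processing tree: recognition first,
#' then (for lures) discrimination, with guessing on recognition failure.
#'
#' @param agent an \code{\link{mpt_agent}}.
#' @param condition one of \code{"old"}, \code{"lure"}, \code{"new"}.
#' @param ell lure dissimilarity (required for lure trials; ignored
#'   otherwise).
#' @return Named numeric vector \code{c(old=, similar=, new=)} summing to 1.
#' @export
expected_response_probabilities <- function(agent, condition, ell = NULL) {
  stopifnot(inherits(agent, "mpt_agent"))
  g <- c(old = agent$gamma_O, similar = agent$gamma_S, new = agent$gamma_N)
  p <- switch(condition,
    old = c(old = agent$rho, similar = 0, new = 0) + (1 - agent$rho) * g,
    new = c(old = 0, similar = 0, new = agent$psi) + (1 - agent$psi) * g,
    lure = {
      if (is.null(ell) || ell <= 0 || ell >= 1) {
        stop("lure trials require ell strictly inside (0, 1)", call. = FALSE)
      }
      d <- lure_discriminability(agent$beta, agent$tau, ell)
      c(old = agent$rho * (1 - d), similar = agent$rho * d, new = 0) +
        (1 - agent$rho) * g
    },
    stop("unknown condition: ", condition, call. = FALSE)
  )
  p
}

#' Draw one categorical response from an agent
#'
#' A single draw from \code{\link{expected_response_probabilities}} using
#' the current R random stream (seed it with \code{set.seed} for
#' reproducibility).
#'
#' @inheritParams expected_response_probabilities
#' @return One of \code{"old"}, \code{"similar"}, \code{"new"}.
#' @export
simulate_response <- function(agent, condition, ell = NULL) {
  p <- expected_response_probabilities(agent, condition, ell)
  sample(names(p), size = 1L, prob = p)
}

#' Build one simulated MST test list
#'
#' Constructs a 48-stimulus test list with 16 old, 16 new and 16 lure
#' items. Lure dissimilarities are the discrete levels \eqn{k/6} for
#' \eqn{k = 1..5} (matching the empirical lure-bin mapping) allocated as
#' evenly as possible: counts (4,3,3,3,3) with the extra lure assigned to
#' the level selected by \code{rotate} (cycled per list so no level is
#' systematically favoured across a population).
#'
#' @param n_per_condition stimuli per condition (default 16).
#' @param rotate index in \code{1..5} of the lure level receiving the
#'   extra item when \code{n_per_condition} is not divisible by 5.
#' @return Data frame with columns \code{condition}, \code{lure_bin} and
#'   \code{dissimilarity} (\eqn{\ell}: 0 for old, 1 for new, \eqn{k/6} for
#'   lures). Trial order is fixed; the agents respond independently
#'   trial-by-trial, so presentation order carries no information.
#' @export
build_test_list <- function(n_per_condition = 16L, rotate = 1L) {
  levels_k <- 1:5
  n_l <- length(levels_k)
  base <- n_per_condition %/% n_l
  extra <- n_per_condition %% n_l
  counts <- rep(base, n_l)
  if (extra > 0) {
    idx <- ((rotate - 1L + seq_len(extra) - 1L) %% n_l) + 1L
    counts[idx] <- counts[idx] + 1L
  }
  lure_bins <- rep(levels_k, counts)
  df <- data.frame(
    condition = c(rep("old", n_per_condition), rep("lure", n_per_condition),
                  rep("new", n_per_condition)),
    lure_bin = c(rep(0L, n_per_condition), lure_bins,
                 rep(6L, n_per_condition)),
    stringsAsFactors = FALSE
  )
  df$dissimilarity <- df$lure_bin / 6
  df
}

#' Sample a population of MPT agents
#'
#' Draws agent parameters from the population used by the synthetic
#' experiment: \code{rho}, \code{psi}, \code{tau} uniform on \eqn{(0,1)},
#' \code{beta} uniform on \eqn{(0,50)}, and the guessing triple
#' \code{(gamma_O, gamma_S, gamma_N)} uniform on the probability simplex
#' (normalized standard-exponential draws). The ground-truth
#' \eqn{\lambda} is attached to each agent.
#'
#' @param n_agents number of agents (>= 1).
#' @return List of \code{\link{mpt_agent}} objects.
#' @export
sample_agent_population <- function(n_agents) {
  stopifnot(n_agents >= 1)
  rho <- stats::runif(n_agents)
  psi <- stats::runif(n_agents)
  tau <- stats::runif(n_agents)
  beta <- stats::runif(n_agents, 0, 50)
  gexp <- matrix(stats::rexp(3 * n_agents), ncol = 3)
  g <- gexp / rowSums(gexp)
  lapply(seq_len(n_agents), function(i) {
    mpt_agent(rho[i], psi[i], g[i, 1], g[i, 2], g[i, 3], beta[i], tau[i])
  })
}

#' Simulate a full synthetic MST experiment
#'
#' Samples \code{n_agents} MPT agents, presents each with its own 48-trial
#' test list (16 old / 16 new / 16 lures over the five discrete
#' dissimilarity levels), and records every categorical response. Returns
#' the trial log in the standard schema together with the agent truth
#' table (parameters plus ground-truth \eqn{\lambda}).
#'
#' @param n_agents number of synthetic agents.
#' @param seed optional integer seed; when supplied, \code{set.seed} is
#'   called so the whole experiment is reproducible.
#' @param n_per_condition stimuli per condition per agent (default 16).
#' @return List with \code{trials} (trial-log data frame: participant_id,
#'   study_id, trial_index, condition, lure_bin, response, dissimilarity,
#'   novelty_response) and \code{agents} (truth table data frame).
#' @export
simulate_experiment <- function(n_agents, seed = NULL, n_per_condition = 16L) {
  if (n_agents < 1) stop("'n_agents' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  agents <- sample_agent_population(n_agents)
  n_trials <- 3L * n_per_condition

  trial_chunks <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    ag <- agents[[i]]
    tl <- build_test_list(n_per_condition, rotate = ((i - 1L) %% 5L) + 1L)
    probs <- t(vapply(seq_len(nrow(tl)), function(j) {
      ell <- if (tl$condition[j] == "lure") tl$dissimilarity[j] else NULL
      expected_response_probabilities(ag, tl$condition[j], ell)
    }, numeric(3)))
    u <- stats::runif(nrow(tl))
    cum1 <- probs[, 1]; cum2 <- probs[, 1] + probs[, 2]
    resp <- ifelse(u < cum1, "old", ifelse(u < cum2, "similar", "new"))
    trial_chunks[[i]] <- data.frame(
      participant_id = sprintf("agent_%04d", i),
      study_id = "synthetic",
      trial_index = seq_len(n_trials),
      condition = tl$condition,
      lure_bin = tl$lure_bin,
      response = resp,
      stringsAsFactors = FALSE
    )
  }
  trials <- do.call(rbind, trial_chunks)
  trials <- validate_trial_log(trials)

  agents_df <- data.frame(
    participant_id = sprintf("agent_%04d", seq_len(n_agents)),
    rho = vapply(agents, `[[`, numeric(1), "rho"),
    psi = vapply(agents, `[[`, numeric(1), "psi"),
    gamma_O = vapply(agents, `[[`, numeric(1), "gamma_O"),
    gamma_S = vapply(agents, `[[`, numeric(1), "gamma_S"),
    gamma_N = vapply(agents, `[[`, numeric(1), "gamma_N"),
    beta = vapply(agents, `[[`, numeric(1), "beta"),
    tau = vapply(agents, `[[`, numeric(1), "tau"),
    ground_truth_lambda = vapply(agents, `[[`, numeric(1),
                                 "ground_truth_lambda"),
    stringsAsFactors = FALSE
  )
  list(trials = trials, agents = agents_df)
}
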