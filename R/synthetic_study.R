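#' Run the full synthetic validation study
#'
#' End-to-end driver for the synthetic experiment: simulates a population
#' of MPT agents, fits every agent's five-parameter logistic performance
#' curve, computes \eqn{\lambda}, \eqn{\Delta}, LDI and REC, and fits the
#' standardized validity models on the full population and on the
#' high-recognition subset (\eqn{\Delta \ge} \code{subset_delta}). Agents
#' whose curve fit failed or whose \eqn{\lambda} is undefined are
#' listwise-excluded from the regressions.
#'
#' @param n_agents number of synthetic agents (default 1500).
#' @param seed integer seed for the whole study.
#' @param subset_delta \eqn{\Delta} cutoff for the high-recognition subset
#'   (default 0.6).
#' @return A list with elements:
#'   \describe{
#'     \item{indices}{per-agent index table merged with the agent truth
#'       table.}
#'     \item{r2_delta_rec}{R-squared of \code{rec ~ delta} across the
#'       analysis sample.}
#'     \item{models_full, models_subset}{\code{validation_result} lists
#'       from \code{\link{fit_validation_models}} on the full sample and
#'       the subset.}
#'     \item{n_full, n_subset}{analysis sample sizes.}
#'   }
#' @examples
#' \donttest{
#' study <- run_synthetic_study(n_agents = 200, seed = 1)
#' study$r2_delta_rec
#' study$models_full$ldi
#' }
#' @export
run_synthetic_study <- function(n_agents = 1500L, seed = 1234L,
                                subset_delta = 0.6) {
  sim <- simulate_experiment(n_agents, seed = seed)
  indices <- compute_indices(sim$trials)
  indices <- merge(indices, sim$agents, by = "participant_id")
  kept <- indices[indices$fit_converged & indices$lambda_defined, ,
                  drop = FALSE]
  subset <- kept[kept$delta >= subset_delta, , drop = FALSE]
  list(
    indices = indices,
    r2_delta_rec = summary(stats::lm(rec ~ delta, data = kept))$r.squared,
    models_full = fit_validation_models(kept),
    models_subset = fit_validation_models(subset),
    n_full = nrow(kept),
    n_subset = nrow(subset)
  )
}
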