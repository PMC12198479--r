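test_that("lure discriminability is the two-parameter logistic", {
  expect_equal(lure_discriminability(7, 0.3, 0.3), 0.5)  # midpoint
  expect_equal(lure_discriminability(0, 0.9, c(0.1, 0.5, 0.9)), rep(0.5, 3))
  expect_equal(lure_discriminability(50, 0.2, 0.8), 1 / (1 + exp(-30)),
               tolerance = 1e-12)
  # strictly increasing in ell for positive beta
  v <- lure_discriminability(5, 0.4, seq(0.01, 0.99, by = 0.01))
  expect_true(all(diff(v) > 0))
})

test_that("ground-truth lambda closed form matches quadrature", {
  expect_equal(ground_truth_lambda(7, 0.5), 0.5)     # symmetry about tau
  expect_equal(ground_truth_lambda(0, 0.3), 0.5)     # flat curve
  expect_equal(ground_truth_lambda(1e4, 0.2), 0.8, tolerance = 1e-3)
  set.seed(31)
  for (i in 1:100) {
    beta <- runif(1, 0, 50); tau <- runif(1)
    oracle <- trapezoid_01(function(l) 1 / (1 + exp(-beta * (l - tau))))
    expect_equal(ground_truth_lambda(beta, tau), oracle, tolerance = 1e-8)
  }
})

test_that("ground-truth lambda does not decrease with beta when tau < 0.5", {
  for (tau in c(0.1, 0.3, 0.45)) {
    v <- vapply(seq(0, 50, by = 2), ground_truth_lambda, numeric(1),
                tau = tau)
    expect_true(all(diff(v) >= -1e-12))
  }
})

test_that("response probabilities follow the processing tree", {
  third <- rep(1 / 3, 3)
  ag <- mpt_agent(0.5, 0.5, third[1], third[2], third[3], beta = 0, tau = 0.5)
  # beta = 0 gives delta = 0.5 at any ell
  p <- expected_response_probabilities(ag, "lure", 0.4)
  expect_equal(unname(p), c(0.25 + 1 / 6, 0.25 + 1 / 6, 1 / 6))
  # pure guessing when recognition always fails
  ag0 <- mpt_agent(0, 0.5, 0.2, 0.3, 0.5, 10, 0.5)
  expect_equal(unname(expected_response_probabilities(ag0, "old")),
               c(0.2, 0.3, 0.5))
  # perfect recognition and discrimination
  ag1 <- mpt_agent(1, 1, third[1], third[2], third[3], 50, 0.01)
  expect_equal(expected_response_probabilities(ag1, "lure", 0.9)[["similar"]],
               1, tolerance = 1e-12)
  expect_equal(expected_response_probabilities(ag1, "old")[["old"]], 1)
  expect_equal(expected_response_probabilities(ag1, "new")[["new"]], 1)
})

test_that("response probability triples always sum to one", {
  set.seed(13)
  for (i in 1:50) {
    g <- rexp(3); g <- g / sum(g)
    ag <- mpt_agent(runif(1), runif(1), g[1], g[2], g[3],
                    runif(1, 0, 50), runif(1))
    for (cond in c("old", "new")) {
      expect_equal(sum(expected_response_probabilities(ag, cond)), 1)
    }
    expect_equal(sum(expected_response_probabilities(ag, "lure", runif(1))), 1)
  }
  expect_error(expected_response_probabilities(
    mpt_agent(0.5, 0.5, 1 / 3, 1 / 3, 1 / 3, 5, 0.5), "lure", 1),
    "strictly inside")
})

test_that("simulated responses match closed-form frequencies", {
  set.seed(19)
  ag <- mpt_agent(0.6, 0.7, 0.2, 0.5, 0.3, 12, 0.35)
  p <- expected_response_probabilities(ag, "lure", 0.5)
  n <- 1e5
  draws <- vapply(seq_len(n), function(i) simulate_response(ag, "lure", 0.5),
                  character(1))
  freq <- table(factor(draws, levels = names(p))) / n
  for (r in names(p)) {
    expect_lt(abs(freq[[r]] - p[[r]]), 3 * sqrt(p[[r]] * (1 - p[[r]]) / n))
  }
})

test_that("simulation is reproducible under a fixed seed", {
  ag <- mpt_agent(0.6, 0.7, 0.2, 0.5, 0.3, 12, 0.35)
  set.seed(123)
  r1 <- replicate(50, simulate_response(ag, "lure", 0.4))
  set.seed(123)
  r2 <- replicate(50, simulate_response(ag, "lure", 0.4))
  expect_identical(r1, r2)
  s1 <- simulate_experiment(5, seed = 99)
  s2 <- simulate_experiment(5, seed = 99)
  expect_identical(s1, s2)
})

test_that("test lists have the 16/16/16 composition with even lure levels", {
  for (rot in 1:5) {
    tl <- build_test_list(16L, rotate = rot)
    expect_equal(nrow(tl), 48)
    expect_equal(unname(table(tl$condition)[c("old", "lure", "new")]),
                 rep(16L, 3), ignore_attr = TRUE)
    bins <- tl$lure_bin[tl$condition == "lure"]
    expect_true(all(bins %in% 1:5))
    expect_true(all(tl$dissimilarity[tl$condition == "lure"] > 0 &
                      tl$dissimilarity[tl$condition == "lure"] < 1))
    counts <- table(factor(bins, levels = 1:5))
    expect_lte(max(counts) - min(counts), 1)
  }
  # rotation moves the extra lure across levels
  b1 <- table(build_test_list(16L, 1)$lure_bin[17:32])
  b2 <- table(build_test_list(16L, 2)$lure_bin[17:32])
  expect_false(identical(b1, b2))
})

test_that("agent populations respect the stated parameter distributions", {
  set.seed(8)
  agents <- sample_agent_population(1e5)
  rho <- vapply(agents, `[[`, numeric(1), "rho")
  beta <- vapply(agents, `[[`, numeric(1), "beta")
  tau <- vapply(agents, `[[`, numeric(1), "tau")
  gsum <- vapply(agents, function(a) a$gamma_O + a$gamma_S + a$gamma_N,
                 numeric(1))
  expect_true(all(rho >= 0 & rho <= 1))
  expect_true(all(tau >= 0 & tau <= 1))
  expect_true(all(beta >= 0 & beta <= 50))
  expect_true(all(abs(gsum - 1) < 1e-12))
  # law of large numbers: mean of rho within 3 standard errors of 0.5
  expect_lt(abs(mean(rho) - 0.5), 3 * sqrt(1 / 12 / 1e5))
  # marginal mean of each simplex coordinate is 1/3
  gO <- vapply(agents, `[[`, numeric(1), "gamma_O")
  expect_lt(abs(mean(gO) - 1 / 3), 0.005)
})

test_that("simulate_experiment emits the standard schema and truth table", {
  sim <- simulate_experiment(10, seed = 4)
  expect_equal(nrow(sim$trials), 480)
  expect_equal(nrow(sim$agents), 10)
  expect_true(all(c("dissimilarity", "novelty_response") %in%
                    names(sim$trials)))
  expect_equal(sim$trials$lure_bin, round(sim$trials$dissimilarity * 6))
  expect_true(all(c("rho", "psi", "beta", "tau", "ground_truth_lambda") %in%
                    names(sim$agents)))
  expect_error(simulate_experiment(0), "n_agents")
})

test_that("a perfect agent scores near-perfect LDI and REC", {
  set.seed(3)
  ag <- mpt_agent(1, 1, 1 / 3, 1 / 3, 1 / 3, 50, 0.01)
  tl <- build_test_list(16L, 1L)
  resp <- vapply(seq_len(nrow(tl)), function(j) {
    ell <- if (tl$condition[j] == "lure") tl$dissimilarity[j] else NULL
    simulate_response(ag, tl$condition[j], ell)
  }, character(1))
  log <- data.frame(condition = tl$condition, lure_bin = tl$lure_bin,
                    response = resp, stringsAsFactors = FALSE)
  expect_equal(compute_rec(mst_counts(log)), 1)
  expect_gt(compute_ldi(mst_counts(log)), 0.9)
})
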