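test_that("interaction sampler realizes the requested type mixture exactly", {
  m <- sample_interaction_matrix(
    10, type_mixture = c(mutual = 0.25, competitive = 0.25,
                         commensal = 0.25, amensal = 0.25, none = 0),
    seed = 42)
  A <- m$interactions
  # brute-force pair typing from the output matrix alone
  observed <- table(apply(utils::combn(10, 2), 2, function(pr) {
    x <- A[pr[1], pr[2]]; y <- A[pr[2], pr[1]]
    if (x > 0 && y > 0) "mutual"
    else if (x < 0 && y < 0) "competitive"
    else if (x > 0 || y > 0) "commensal"
    else if (x < 0 || y < 0) "amensal"
    else "none"
  }))
  # independent largest-remainder allocation of 0.25 * 45 = 11.25 each:
  # floors give 44, the one leftover pair goes to the first type
  expect_equal(as.numeric(observed[c("mutual", "competitive",
                                     "commensal", "amensal")]),
               c(12, 11, 11, 11))

  pure <- sample_interaction_matrix(
    6, type_mixture = c(mutual = 1), seed = 1)
  off <- pure$interactions[row(pure$interactions) !=
                             col(pure$interactions)]
  expect_true(all(off > 0))
  expect_true(all(diag(pure$interactions) < 0))
})

test_that("interaction sampler is deterministic and validates mixtures", {
  m1 <- sample_interaction_matrix(8, seed = 99)
  m2 <- sample_interaction_matrix(8, seed = 99)
  expect_identical(m1, m2)
  expect_error(sample_interaction_matrix(5, type_mixture = c(mutual = 0.7)),
               "sum to 1")
  expect_error(
    sample_interaction_matrix(5, type_mixture = c(mutual = 1.3,
                                                  none = -0.3)),
    "non-negative")
  expect_error(sample_interaction_matrix(1), ">= 2")
})

test_that("simulation holds fixed points and is reproducible", {
  # single taxon at its equilibrium x* = -b/a = 1
  m <- glv_model(0.5, matrix(-0.5, 1, 1))
  p <- simulate_glv(m, 1, seq(0, 10, by = 1), renormalize = FALSE)
  expect_true(all(abs(p$abundances - 1) < 1e-6))

  # 2-taxon interior fixed point, started exactly there
  A <- matrix(c(-1, -0.2, -0.2, -1), 2, 2)
  m2 <- glv_model(c(0.6, 0.6), A)
  xs <- glv_equilibrium(m2)
  p2 <- simulate_glv(m2, xs, seq(0, 5, by = 0.5), renormalize = FALSE)
  expect_true(max(abs(p2$abundances - xs)) < 1e-6)

  pa <- simulate_glv(m2, c(0.3, 0.1), seq(0, 2, 0.5), noise_sd = 0.1,
                     seed = 5)
  pb <- simulate_glv(m2, c(0.3, 0.1), seq(0, 2, 0.5), noise_sd = 0.1,
                     seed = 5)
  expect_identical(pa, pb)
  expect_equal(unname(colSums(pa$abundances)), rep(1, 5))
})

test_that("simulation agrees with a fine-step Euler oracle", {
  A <- matrix(c(-1, 0.3, -0.5, -0.8), 2, 2)
  m <- glv_model(c(0.7, 0.4), A)
  times <- seq(0, 2, by = 0.25)
  p <- simulate_glv(m, c(0.2, 0.5), times, renormalize = FALSE)
  oracle <- euler_glv(m$growth_rates, A, c(0.2, 0.5), times, h = 2e-5)
  expect_lt(max(abs(p$abundances - oracle) / oracle), 1e-4)
})

test_that("divergent trajectories abort naming the first bad time", {
  # strong mutualism overwhelming self-limitation blows up
  A <- matrix(c(-0.1, 2, 2, -0.1), 2, 2)
  m <- glv_model(c(1, 1), A)
  expect_error(
    suppressWarnings(simulate_glv(m, c(1, 1), seq(0, 50, by = 1))),
    "diverged at time")
})

test_that("count sampling is multinomial at the requested depth", {
  p <- ts_profile(matrix(c(0.5, 0.5, 0.2, 0.8), 2, 2), c(0, 1))
  tab <- counts_from_profile(p, depth = 1000, seed = 1)
  expect_equal(unname(colSums(tab$counts)), c(1000, 1000))
  expect_equal(tab$metadata$time, c(0, 1))

  # binomial 3-sigma check at large depth
  big <- counts_from_profile(
    ts_profile(matrix(c(0.5, 0.5), 2, 1), 0), depth = 1e6, seed = 2)
  expect_lt(abs(big$counts[1, 1] - 5e5), 3 * sqrt(1e6 * 0.25))

  # a zero-probability taxon never receives reads
  z <- counts_from_profile(
    ts_profile(matrix(c(0, 1), 2, 1), 0), depth = 500, seed = 3)
  expect_equal(unname(z$counts[1, 1]), 0)
})

test_that("trial generation propagates the network and keeps controls at baseline", {
  A <- diag(-1, 3)
  m <- glv_model(rep(0, 3), A, taxa = c("P", "Q", "Z"))
  baseline <- c(P = 0.02, Q = 0.18, Z = 0.8)
  des <- trial_design(list(G1 = "P", G5 = character(0)),
                      n_per_group = 3, boost = 10)

  # control composition equals baseline exactly without noise/counts
  out <- generate_trial(m, baseline, des, animal_sd = 0, depth = NULL,
                        step_days = 0)
  expect_equal(unname(out$G5$counts[, 1]), unname(baseline))

  # no coupling, zero growth: only P changes, FC of P ~ boost
  fcP <- mean(out$G1$counts["P", ]) / mean(out$G5$counts["P", ])
  boosted <- baseline; boosted["P"] <- boosted["P"] * 10
  expect_equal(fcP, unname((boosted / sum(boosted))["P"] / baseline["P"]))
  expect_gt(fcP, 8)
  expect_equal(out$G1$counts["Q", 1] / out$G1$counts["Z", 1],
               unname(baseline["Q"] / baseline["Z"]))

  # strong positive edge P -> Q lifts Q; verify against the one-step
  # propagation formula evaluated by hand
  A2 <- diag(-1, 3); A2[2, 1] <- 3  # effect of P on Q
  m2 <- glv_model(rep(0, 3), A2, taxa = c("P", "Q", "Z"))
  out2 <- generate_trial(m2, baseline, des, animal_sd = 0, depth = NULL,
                         step_days = 1)
  xb <- baseline; xb["P"] <- xb["P"] * 10; xb <- xb / sum(xb)
  hand <- xb * exp(1 * (rep(0, 3) + drop(A2 %*% xb)))
  hand["P"] <- xb["P"]  # administered taxon is sustained by dosing
  hand <- hand / sum(hand)
  expect_equal(unname(out2$G1$counts[, 1]), unname(hand))
  fcQ <- mean(out2$G1$counts["Q", ]) / mean(out2$G5$counts["Q", ])
  expect_gt(fcQ, 1)

  expect_error(
    generate_trial(m, baseline,
                   trial_design(list(G1 = "Nope", G5 = character(0))),
                   depth = NULL),
    "valid labels")
})

test_that("planted interactions overwrite pairs with the requested types", {
  sys <- make_planted_system(seed = 7)
  A <- sys$model$interactions
  expect_equal(A["T1", "T2"] > 0 && A["T2", "T1"] > 0, TRUE)  # mutual
  expect_true(A["T4", "T5"] < 0 && A["T5", "T4"] < 0)         # competitive
  expect_true(A["T8", "T1"] > 0 && A["T1", "T8"] == 0)        # commensal
  expect_true(A["T10", "T5"] < 0 && A["T5", "T10"] == 0)      # amensal
  expect_true(all(abs(sys$planted_edges$coefficient) >= 0.5))
})
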