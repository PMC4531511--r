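test_that("deterministic models follow the plain synchronous update", {
  net <- parse_rxncon(worked_example_text())
  model <- build_model(net)
  s0 <- model$initial_state
  s1 <- pbn_step(model, s0)
  # all three interactions fire immediately (components present, no absolutes)
  expect_true(all(s1[c("B_ppi_C", "A_ppi_D", "A_ppi_B")]))
  expect_false(any(s1[c("B--C", "A--D", "A--B")]))
  s2 <- pbn_step(model, s1)
  expect_true(all(s2[c("B--C", "A--B", "A--D")]))
  expect_error(pbn_step(model, s0[-1]), "missing node")
})

test_that("rule sampling frequencies match the assigned probabilities", {
  net <- parse_rxncon("A_ppi_B")
  pbn <- build_pbn(net, p_false = 0.1, k_base = 10)
  # the single reaction's base rule is always satisfiable, so its node is a
  # Bernoulli(0.9) draw at every step
  tr <- simulate_run(pbn, steps = 10000, seed = 21)
  expect_equal(mean(tr$A_ppi_B[-1]), 0.9, tolerance = 0.01)
})

test_that("ensembles are seed-reproducible and chunk/parallel invariant", {
  fx <- fixture_hog()
  pbn <- build_pbn(fx$network, p_false = 0.05, k_base = 10)
  e1 <- simulate_ensemble(pbn, steps = 30, runs = 12, seed = 5)
  e2 <- simulate_ensemble(pbn, steps = 30, runs = 12, seed = 5)
  expect_identical(e1$values, e2$values)
  e3 <- simulate_ensemble(pbn, steps = 30, runs = 12, seed = 5, chunk_size = 5)
  expect_identical(e1$values, e3$values)
  e4 <- simulate_ensemble(pbn, steps = 30, runs = 12, seed = 6)
  expect_false(identical(e1$values, e4$values))
  # a single run equals run 1 of the ensemble, and mean accumulation agrees
  r1 <- simulate_run(pbn, steps = 30, seed = 5)
  expect_equal(unname(as.matrix(r1[, -1])), unname(e1$values[1, , ]) * 1L)
  sm <- simulate_ensemble(pbn, steps = 30, runs = 12, seed = 5, keep = "mean")
  expect_equal(tidy(sm), tidy(ensemble_mean(e1)))
})

test_that("clamped nodes hold their value regardless of rules and noise", {
  fx <- fixture_hog()
  cl <- clamp_events(c(5, 20), c("Hog1-{P}", "Hog1-{P}"), c(TRUE, FALSE))
  m1 <- build_pbn(fx$network, p_false = 0.01, k_base = 10)
  m2 <- build_pbn(fx$network, p_false = 0.3, k_base = 10)
  t1 <- simulate_run(m1, steps = 40, seed = 2, clamps = cl)
  t2 <- simulate_run(m2, steps = 40, seed = 2, clamps = cl)
  expect_true(all(t1$`Hog1-{P}`[6:20] == 1))
  expect_true(all(t1$`Hog1-{P}`[21:41] == 0))
  expect_equal(t1$`Hog1-{P}`[6:41], t2$`Hog1-{P}`[6:41])
  expect_error(simulate_run(m1, steps = 10, clamps = clamp_events(1, "nope", TRUE)),
               "unknown node")
  expect_error(simulate_run(m1, steps = 10,
                            clamps = clamp_events(99, "Hog1-{P}", TRUE)),
               "within")
})

test_that("an all-FALSE start without synthesis is absorbing", {
  net <- parse_rxncon(worked_example_text())
  pbn <- build_pbn(net, p_false = 0.1, k_base = 10)
  off <- stats::setNames(rep(FALSE, nrow(pbn$nodes)), pbn$nodes$node)
  tr <- simulate_run(pbn, steps = 20, seed = 3, initial_state = off)
  expect_true(all(as.matrix(tr[, -1]) == 0))
})

test_that("the exact Markov oracle matches closed forms and point masses", {
  # deterministic model: point mass tracking the trajectory
  net <- parse_rxncon("B_ppi_C\nA_ppi_B; ! B--C")
  bbn <- build_model(net)
  ex <- exact_markov_distribution(bbn, steps = 8)
  tr <- simulate_run(bbn, steps = 8)
  long <- tidyr::pivot_longer(tr, -"time", names_to = "node", values_to = "v")
  j <- dplyr::inner_join(ex, long, by = c("time", "node"))
  expect_equal(j$prob, as.numeric(j$v))
  # Bernoulli node: stationary marginal equals its rule probability
  net1 <- parse_rxncon("A_ppi_B")
  pbn1 <- build_pbn(net1, p_false = 0.1, k_base = 10)
  ex1 <- exact_markov_distribution(pbn1, steps = 5)
  rx <- ex1[ex1$node == "A_ppi_B" & ex1$time >= 1, ]
  expect_equal(rx$prob, rep(0.9, 5), tolerance = 1e-12)
  # the interaction state lags its reaction by one step
  st <- ex1[ex1$node == "A--B", ]
  expect_equal(st$prob, c(0, 0, rep(0.9, 4)), tolerance = 1e-12)
})

test_that("ensemble means converge to exact marginals on a small fixture", {
  fx <- fixture_worked_example()
  pbn <- build_pbn(fx$network, fx$default_params)
  ex <- exact_markov_distribution(pbn, steps = 12)
  sm <- simulate_ensemble(pbn, steps = 12, runs = 20000, seed = 17, keep = "mean")
  j <- dplyr::inner_join(tidy(sm), ex, by = c("time", "node"))
  se <- sqrt(j$prob * (1 - j$prob) / 20000)
  expect_true(all(abs(j$mean - j$prob) <= 3 * se + 1e-12))
})

test_that("the oracle refuses models beyond its state-space limit", {
  net <- random_network(10, 12, seed = 3)
  pbn <- build_pbn(net, p_false = 0.1, k_base = 10)
  expect_gt(nrow(pbn$nodes), 16)
  expect_error(exact_markov_distribution(pbn, steps = 2), "limited to 16")
})
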