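test_that("bundled fixtures parse, build and document their provenance", {
  fx <- fixture_worked_example()
  expect_s3_class(fx$network, "rxncon_network")
  expect_equal(fx$default_params$k_base, 10)
  expect_match(fx$notes, "quantitatively")
  hq <- fixture_hog("qualitative")
  expect_match(hq$notes, "transcription")
  expect_silent(validate_rxncon(hq$network))
  # parse -> generate -> export -> reparse round-trip on the worked example
  back <- parse_rxncon(write_rxncon(fx$network))
  expect_equal(back$reactions$id, fx$network$reactions$id)
  expect_equal(nrow(back$contingencies), nrow(fx$network$contingencies))
})

test_that("the quantitative HOG variant differs only in contingency signs", {
  hq <- fixture_hog("qualitative")
  hk <- fixture_hog("quantitative")
  expect_identical(hq$network$reactions$id, hk$network$reactions$id)
  expect_identical(hq$network$contingencies$effector, hk$network$contingencies$effector)
  map <- c("!" = "K+", "x" = "K-")
  expect_identical(unname(map[hq$network$contingencies$sign]),
                   hk$network$contingencies$sign)
})

test_that("the qualitative HOG model oscillates deterministically", {
  fx <- fixture_hog()
  m <- build_model(fx$network)
  tr <- simulate_run(m, steps = 120)
  cyc <- detect_cycle(tr)
  expect_equal(cyc$period, 12L)
  h <- tr$`Hog1-{P}`
  expect_true(any(h == 1) && any(h == 0))
  # periodic from the cycle entry onwards
  expect_equal(h[30:60], h[(30:60) + 12])
})

test_that("random networks are reproducible, connected-sized and referentially closed", {
  n1 <- random_network(12, 20, contingency_density = 1.5,
                       quantitative_fraction = 0.4, seed = 9)
  n2 <- random_network(12, 20, contingency_density = 1.5,
                       quantitative_fraction = 0.4, seed = 9)
  expect_equal(write_rxncon(n1), write_rxncon(n2))
  expect_equal(nrow(n1$components), 12L)
  expect_equal(nrow(n1$reactions), 20L)
  expect_equal(nrow(n1$contingencies), 30L)
  expect_true(all(n1$contingencies$effector %in% n1$states$id))
  n0 <- random_network(5, 0, seed = 1)
  expect_equal(nrow(n0$reactions), 0L)
  expect_equal(nrow(n0$components), 5L)
  expect_error(random_network(3, 2, contingency_density = 50, seed = 1),
               "contingencies")
})

test_that("PBNs built from random networks satisfy the rule-set invariants", {
  for (seed in 1:100) {
    net <- random_network(6, 9, contingency_density = 1,
                          quantitative_fraction = 0.6, seed = seed)
    pbn <- build_pbn(net, p_false = 0.07, k_base = 5)
    sums <- tapply(pbn$rules$prob, pbn$rules$node, sum)
    expect_true(all(abs(sums - 1) < 1e-12), info = paste("seed", seed))
    for (rid in net$reactions$id) {
      n_mod <- nrow(quantitative_modifiers(net, rid))
      expect_equal(sum(pbn$rules$node == rid), n_mod + 2L,
                   info = paste("seed", seed, rid))
    }
    validate_bipartite(pbn)
  }
})

test_that("the command-line interface drives build, simulate and analyze", {
  dir <- withr::local_tempdir()
  netfile <- file.path(dir, "net.txt")
  expect_equal(cli_main(c("fixtures", "--name", "worked_example",
                          "--out", netfile)), 0L)
  expect_true(file.exists(netfile))

  expect_equal(cli_main(c("build", "--network", netfile, "--pbn",
                          "--pfalse", "0.1", "--kbase", "10",
                          "--out", file.path(dir, "model"))), 0L)
  lines <- readLines(file.path(dir, "model.boolnet"))
  expect_length(grep("^\\w+_ppi_\\w+,", lines), 8L)

  expect_equal(cli_main(c("build", "--network", netfile,
                          "--out", file.path(dir, "qual"))), 0L)
  expect_true(file.exists(file.path(dir, "qual.booleannet")))

  simdir <- file.path(dir, "sim")
  args <- c("simulate", "--network", netfile, "--steps", "20", "--runs", "50",
            "--seed", "4", "--pfalse", "0.1", "--kbase", "10",
            "--clamp", "A--B@5=on", "--out", simdir)
  expect_equal(cli_main(args), 0L)
  expect_equal(cli_main(args), 0L) # identical reruns
  m1 <- readLines(file.path(simdir, "means.tsv"))
  expect_equal(cli_main(c("analyze", "--means", file.path(simdir, "means.tsv"),
                          "--node", "A--B", "--period", "5",
                          "--out", file.path(dir, "metrics.tsv"))), 0L)
  metrics <- utils::read.delim(file.path(dir, "metrics.tsv"))
  expect_true(all(c("amplitude", "converged") %in% metrics$metric))
  # clamped node is held from the event onwards in the single-run output
  run1 <- utils::read.delim(file.path(simdir, "run1.tsv"), check.names = FALSE)
  expect_true(all(run1$`A--B`[run1$time >= 5] == 1))

  expect_equal(cli_main(c("simulate", "--out", simdir)), 1L)
  expect_equal(cli_main(c("frobnicate")), 1L)
  expect_equal(cli_main(c("fixtures", "--name", "nope",
                          "--out", file.path(dir, "x"))), 1L)
})
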