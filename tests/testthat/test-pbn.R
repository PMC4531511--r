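test_that("probability assignment reproduces the reference cases exactly", {
  expect_equal(as.numeric(assign_probabilities(2, p_false = 0.1, k_base = 10)),
               c(0.008108, 0.08108, 0.810812, 0.1), tolerance = 1e-12)
  expect_equal(as.numeric(assign_probabilities(0, p_false = 0.1, k_base = 10)),
               c(0.9, 0.1), tolerance = 1e-12)
  expect_equal(as.numeric(assign_probabilities(2, p_false = 0.1, k_base = 1)),
               c(0.3, 0.3, 0.3, 0.1), tolerance = 1e-12)
  ex <- attr(assign_probabilities(3, p_false = 0.25, k_base = 7), "exact")
  expect_equal(sum(ex), 1, tolerance = 1e-12)
  expect_equal(ex[2] / ex[1], 7, tolerance = 1e-12)
})

test_that("invalid parameters are rejected and k < 1 warns", {
  expect_error(assign_probabilities(-1, 0.1, 10))
  expect_error(assign_probabilities(2, 1, 10))
  expect_error(assign_probabilities(2, -0.1, 10))
  expect_error(assign_probabilities(2, 0.1, 0))
  expect_warning(assign_probabilities(2, 0.1, 0.5), "k_base < 1")
})

test_that("reported probabilities sum to exactly 1 across a parameter sweep", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(0:6, 1)
    pf <- stats::runif(1, 0, 0.9)
    k <- stats::runif(1, 1, 200)
    p <- assign_probabilities(n, pf, k)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    expect_length(p, n + 2L)
    if (k > 1 && n > 0) {
      expect_true(all(diff(attr(p, "exact")[seq_len(n + 1L)]) > 0))
    }
  }
})

test_that("the worked example yields the printed rule set for A_ppi_B", {
  net <- parse_rxncon(worked_example_text())
  rr <- build_quantitative_rules(net, "A_ppi_B", p_false = 0.1, k_base = 10)
  expect_equal(rr$prob, c(0.008108, 0.08108, 0.810812, 0.1), tolerance = 1e-12)
  A <- b_lit("A"); B <- b_lit("B"); BC <- b_lit("B--C"); AD <- b_lit("A--D")
  expect_expr_equal(rr$expr[[1]], b_and(A, B))
  expect_expr_equal(rr$expr[[2]], b_and(A, B, b_or(BC, b_not(AD))))
  expect_expr_equal(rr$expr[[3]], b_and(A, B, b_and(BC, b_not(AD))))
  expect_equal(rr$expr[[4]]$op, "false")
  # contingency-free reactions still get the FALSE rule
  rr0 <- build_quantitative_rules(net, "B_ppi_C", p_false = 0.1, k_base = 10)
  expect_equal(rr0$prob, c(0.9, 0.1))
  expect_expr_equal(rr0$expr[[1]], b_and(b_lit("B"), b_lit("C")))
})

test_that("absolute contingencies appear in every non-false rule of a mixed reaction", {
  net <- spectrum_network()
  rr <- build_quantitative_rules(net, "E_ppi_F", p_false = 0.1, k_base = 10)
  expect_equal(nrow(rr), 6L) # f0..f4 + FALSE
  mods <- c("U2--S2", "U3--S3", "U4--S4", "U5--S5")
  vars <- c("E", "F", "U1--S1", "U6--S6", mods)
  tt <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(vars))))
  colnames(tt) <- vars
  fulfilled <- tt[, "U2--S2"] + tt[, "U3--S3"] + (!tt[, "U4--S4"]) + (!tt[, "U5--S5"])
  base_ok <- tt[, "E"] & tt[, "F"] & tt[, "U1--S1"] & !tt[, "U6--S6"]
  for (i in 0:4) {
    vals <- expr_eval(rr$expr[[i + 1L]], tt)
    # absolute requirement and inhibition are never relaxed
    expect_false(any(vals & !base_ok))
    # f_i holds exactly when the base holds and >= i modifiers are fulfilled
    expect_equal(vals, unname(base_ok & fulfilled >= i))
  }
})

test_that("rule count follows the n + 2 law", {
  for (n in 0:6) {
    lines <- c(sprintf("U%d_ppi_S%d", seq_len(max(n, 1)), seq_len(max(n, 1))),
               paste(c("E_ppi_F",
                       sprintf("%s U%d--S%d", rep_len(c("K+", "K-"), n),
                               seq_len(n), seq_len(n))),
                     collapse = "; "))
    net <- parse_rxncon(paste(lines, collapse = "\n"))
    rr <- build_quantitative_rules(net, "E_ppi_F", p_false = 0.1, k_base = 10)
    expect_equal(nrow(rr), n + 2L, info = paste("n =", n))
  }
})

test_that("update functions are monotonically nested in stringency", {
  for (n in 1:5) {
    lines <- c(sprintf("U%d_ppi_S%d", seq_len(n), seq_len(n)),
               paste(c("E_ppi_F",
                       sprintf("%s U%d--S%d", rep_len(c("K+", "K-"), n),
                               seq_len(n), seq_len(n))),
                     collapse = "; "))
    net <- parse_rxncon(paste(lines, collapse = "\n"))
    rr <- build_quantitative_rules(net, "E_ppi_F", p_false = 0.05, k_base = 3)
    vars <- unique(unlist(lapply(rr$expr, expr_vars)))
    tt <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(vars))))
    colnames(tt) <- vars
    for (i in seq_len(n)) {
      fi <- expr_eval(rr$expr[[i + 1L]], tt)
      fprev <- expr_eval(rr$expr[[i]], tt)
      expect_false(any(fi & !fprev), info = sprintf("n=%d i=%d", n, i))
    }
  }
})

test_that("large k concentrates mass on the most restrictive rule", {
  p <- attr(assign_probabilities(3, p_false = 0.2, k_base = 1e6), "exact")
  expect_equal(p[4], 1 - 0.2, tolerance = 1e-5)
  expect_lt(sum(p[1:3]), 1e-5)
})

test_that("the full PBN keeps deterministic state rules and accepts overrides", {
  net <- parse_rxncon(worked_example_text())
  pbn <- build_pbn(net, p_false = 0.1, k_base = 10)
  type_of <- stats::setNames(pbn$nodes$type, pbn$nodes$node)
  per_node <- table(pbn$rules$node)
  for (nd in names(per_node)) {
    if (type_of[[nd]] == "reaction") {
      expect_gte(per_node[[nd]], 2L)
    } else {
      expect_equal(per_node[[nd]], 1L)
      expect_equal(pbn$rules$prob[pbn$rules$node == nd], 1)
    }
  }
  # per-node probability sums are exactly 1
  sums <- tapply(pbn$rules$prob, pbn$rules$node, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # drop the FALSE rule of A_ppi_B and renormalize
  p <- pbn$rules$prob[pbn$rules$node == "A_ppi_B"]
  p[4] <- 0; p <- p / sum(p)
  over <- build_pbn(net, p_false = 0.1, k_base = 10, overrides = list(A_ppi_B = p))
  expect_equal(sum(over$rules$prob[over$rules$node == "A_ppi_B"]), 1)
  expect_equal(over$rules$prob[over$rules$node == "A_ppi_B"][4], 0)
  expect_error(build_pbn(net, overrides = list(A_ppi_B = c(1, 1, 1, 1))),
               "sum to 1")
  expect_error(build_pbn(net, overrides = list(Nope = c(1))), "unknown node")
})

test_that("degenerate parameters reduce the PBN to the qualitative model", {
  net <- parse_rxncon("B_ppi_C\nA_ppi_B; ! B--C")
  pbn <- build_pbn(net, p_false = 0, k_base = 10)
  bbn <- build_model(net)
  for (nd in net$reactions$id) {
    rr <- pbn$rules[pbn$rules$node == nd, ]
    expect_equal(rr$prob, c(1, 0))
    expect_expr_equal(rr$expr[[1]], bbn$rules$expr[[match(nd, bbn$rules$node)]])
  }
})

test_that("the BoolNet writer reproduces the printed worked-example rows", {
  fx <- fixture_worked_example()
  pbn <- build_pbn(fx$network, fx$default_params)
  f <- withr::local_tempfile(fileext = ".boolnet")
  write_boolnet(pbn, f)
  lines <- readLines(f)
  expect_equal(lines[1], "targets, factors, probabilities")
  reaction_rows <- grep("^\\w+_ppi_\\w+,", lines, value = TRUE)
  expect_length(reaction_rows, 8L)
  expect_setequal(
    grep("^A_ppi_B", reaction_rows, value = TRUE),
    c("A_ppi_B, A & B, 0.008108",
      "A_ppi_B, A & B & (B__C | !A__D), 0.08108",
      "A_ppi_B, A & B & B__C & !A__D, 0.810812",
      "A_ppi_B, 0, 0.1")
  )
  expect_setequal(grep("^A_ppi_D", reaction_rows, value = TRUE),
                  c("A_ppi_D, A & D, 0.9", "A_ppi_D, 0, 0.1"))
  expect_setequal(grep("^B_ppi_C", reaction_rows, value = TRUE),
                  c("B_ppi_C, B & C, 0.9", "B_ppi_C, 0, 0.1"))
})
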