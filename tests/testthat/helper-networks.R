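# Small networks and oracles shared across tests.

worked_example_text <- function() {
  "B_ppi_C\nA_ppi_D\nA_ppi_B; K+ B--C; K- A--D"
}

# Reaction with the full contingency spectrum: one absolute requirement,
# two positive and two negative quantitative modifiers, one absolute
# inhibition. States S1..S6 are produced by auxiliary interactions.
spectrum_network <- function() {
  parse_rxncon(paste(
    c(sprintf("U%d_ppi_S%d", 1:6, 1:6),
      "E_ppi_F; ! U1--S1; K+ U2--S2; K+ U3--S3; K- U4--S4; K- U5--S5; x U6--S6"),
    collapse = "\n"
  ))
}

# Brute-force oracle for the memory-state rule: enumerate the 8 assignments
# of (producer, consumer, self) and derive next(state) from the verbal
# constraints: production wins; TRUE persists unless a consumer fires
# without a producer; FALSE only turns TRUE by production.
memory_rule_oracle <- function(prod, cons, self) {
  ifelse(prod, TRUE, self & !cons)
}

expect_expr_equal <- function(e1, e2) {
  expect_true(expr_equivalent(e1, e2),
              label = sprintf("'%s' equivalent to '%s'",
                              expr_to_string(e1), expr_to_string(e2)))
}
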