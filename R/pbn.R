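# Probabilistic rule-set generation: the quantitative extension of the
# bipartite Boolean model. Every reaction node receives an ordered list of
# update functions f0..fn (n = number of K+/K- modifiers) plus a constant
# FALSE rule modeling random reaction failure; f_i requires at least i
# modifiers to be fulfilled (K+ effector TRUE, K- effector FALSE) and is
# k times more probable than f_{i-1}.

#' Global parameters of the probabilistic model
#'
#' @param p_false False-rate in `[0, 1)`: probability of the constant-FALSE
#'   update rule of every reaction node (random reaction failure; 0 = no
#'   noise).
#' @param k_base Scaling factor `k > 0`: each more restrictive update
#'   function is `k` times more probable than the previous one. `k = 1`
#'   gives equal weights; large `k` approaches the qualitative
#'   absolute-contingency model. Values below 1 invert the preference
#'   ordering and trigger a warning.
#' @return A list of class `pbn_params`.
#' @export
pbn_params <- function(p_false = 0.1, k_base = 10) {
  stopifnot(is.numeric(p_false), length(p_false) == 1L,
            p_false >= 0, p_false < 1,
            is.numeric(k_base), length(k_base) == 1L, k_base > 0)
  if (k_base < 1) {
    warning("k_base < 1 inverts the preference for restrictive update functions",
            call. = FALSE)
  }
  structure(list(p_false = p_false, k_base = k_base), class = "pbn_params")
}

#' Probabilities of the ordered update functions
#'
#' For a reaction with `n` quantitative modifiers the probabilities are
#' `p0 = (1 - p_false) / sum(k^i, i = 0..n)` and `p_i = p0 * k^i`, plus
#' `p_false` for the constant-FALSE rule: `n + 2` values in total.
#'
#' Reported values follow a sum-to-one rounding convention: `p0` is rounded
#' to six decimals, intermediate probabilities are `p0 * k^i` of the rounded
#' `p0`, and the most restrictive non-false rule absorbs the residue
#' `1 - p_false - sum(others)` so the reported list sums to exactly 1.
#' Full-precision values are attached as attribute `"exact"` and are what
#' the simulator uses.
#'
#' @param n Number of quantitative (K+/K-) modifiers, `n >= 0`.
#' @param p_false,k_base See [pbn_params()]; a `pbn_params` object may be
#'   passed as `p_false`.
#' @return Numeric vector of length `n + 2`: `p0, ..., pn, p_false`.
#' @examples
#' assign_probabilities(2, p_false = 0.1, k_base = 10)
#' # 0.008108 0.081080 0.810812 0.100000
#' @export
assign_probabilities <- function(n, p_false = 0.1, k_base = 10) {
  if (inherits(p_false, "pbn_params")) {
    k_base <- p_false$k_base
    p_false <- p_false$p_false
  }
  params <- pbn_params(p_false, k_base)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == round(n))
  k <- params$k_base
  pf <- params$p_false
  p0 <- (1 - pf) / sum(k^(0:n))
  exact <- c(p0 * k^(0:n), pf)
  p0r <- round(p0, 6)
  reported <- c(p0r * k^(0:n), pf)
  # most restrictive non-false rule takes the rounding residue
  reported[n + 1L] <- 1 - pf - sum(reported[seq_len(n)])
  attr(reported, "exact") <- exact
  reported
}

subset_disjunction <- function(lits, i) {
  # OR over all i-subsets of the modifier literals, each an AND
  combos <- utils::combn(length(lits), i, simplify = FALSE)
  do.call(b_or, lapply(combos, function(ix) do.call(b_and, lits[ix])))
}

modifier_literal <- function(effector, sign) {
  if (sign == "K+") b_lit(effector) else b_not(b_lit(effector))
}

#' Probabilistic rule set of one reaction
#'
#' Builds the ordered update functions of a reaction node. The base rule
#' `f0` is the conjunction of substrate-presence literals, absolute
#' requirements and negated absolute inhibitions (absolutes appear verbatim
#' in every non-false rule). `f_i` (1 <= i <= n) additionally requires at
#' least `i` of the `n` quantitative modifiers to be fulfilled (a K+
#' effector TRUE, a K- effector FALSE), via the disjunction over all
#' i-subsets of modifier conjunctions; `f_i` TRUE implies `f_{i-1}` TRUE.
#' The final rule is constant FALSE with probability `p_false`.
#'
#' @param network A `rxncon_network`.
#' @param reaction Reaction id.
#' @param p_false,k_base See [pbn_params()].
#' @return Tibble with columns `node`, `rule_index` (1-based), `n_required`
#'   (`NA` for the FALSE rule), `prob` (reported, sums to 1), `prob_exact`,
#'   `label`, `expr` (list-column of `bool_expr`).
#' @examples
#' net <- parse_rxncon("B_ppi_C\nA_ppi_D\nA_ppi_B; K+ B--C; K- A--D")
#' build_quantitative_rules(net, "A_ppi_B", p_false = 0.1, k_base = 10)
#' @export
build_quantitative_rules <- function(network, reaction, p_false = 0.1, k_base = 10) {
  base <- build_reaction_rule(network, reaction)
  mods <- quantitative_modifiers(network, reaction)
  n <- nrow(mods)
  lits <- purrr::map2(mods$effector, mods$sign, modifier_literal)
  exprs <- c(
    list(base),
    lapply(seq_len(n), function(i) b_and(base, subset_disjunction(lits, i))),
    list(b_false())
  )
  probs <- assign_probabilities(n, p_false, k_base)
  tibble::tibble(
    node = reaction,
    rule_index = seq_len(n + 2L),
    n_required = c(0:n, NA_integer_),
    prob = as.numeric(probs),
    prob_exact = attr(probs, "exact"),
    label = vapply(exprs, expr_to_string, character(1)),
    expr = exprs
  )
}

#' Build the probabilistic bipartite Boolean model
#'
#' Every reaction node receives its probabilistic rule set (all reactions
#' get the FALSE rule, including contingency-free ones); state and
#' component-presence nodes keep their single deterministic rule with
#' probability 1 (states never fail at random - noise enters through the
#' reactions).
#'
#' @param network A validated `rxncon_network`.
#' @param p_false,k_base See [pbn_params()]; a `pbn_params` object may be
#'   passed as `p_false`.
#' @param overrides Optional named list: per-node numeric vectors replacing
#'   the node's rule probabilities (same length as the rule set). Each
#'   vector must sum to 1; vectors summing to something else within reach of
#'   renormalization can be prepared with `x / sum(x)` by the caller. A
#'   validation error is raised otherwise.
#' @return An object of class `c("pbn_model", "boolean_model")`, same shape
#'   as [build_model()] but with multi-row rule sets for reaction nodes.
#' @examples
#' net <- parse_rxncon("B_ppi_C\nA_ppi_D\nA_ppi_B; K+ B--C; K- A--D")
#' pbn <- build_pbn(net, p_false = 0.1, k_base = 10)
#' tidy(pbn)
#' @export
build_pbn <- function(network, p_false = 0.1, k_base = 10, overrides = NULL) {
  if (inherits(p_false, "pbn_params")) {
    k_base <- p_false$k_base
    p_false <- p_false$p_false
  }
  params <- pbn_params(p_false, k_base)
  base_model <- build_model(network)
  keep <- base_model$rules[base_model$nodes$type[
    match(base_model$rules$node, base_model$nodes$node)] != "reaction", ]
  keep$n_required <- NA_integer_
  keep <- keep[, c("node", "rule_index", "n_required", "prob", "prob_exact", "label", "expr")]
  rx_rules <- purrr::map_dfr(network$reactions$id, function(rid) {
    build_quantitative_rules(network, rid, params$p_false, params$k_base)
  })
  rules <- dplyr::bind_rows(keep, rx_rules)
  # stable ordering: follow the node order of the model
  rules <- rules[order(match(rules$node, base_model$nodes$node), rules$rule_index), ]

  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    for (nd in names(overrides)) {
      ix <- which(rules$node == nd)
      if (length(ix) == 0L) stop(sprintf("override for unknown node '%s'", nd), call. = FALSE)
      p <- overrides[[nd]]
      if (length(p) != length(ix)) {
        stop(sprintf("override for '%s' has %d probabilities, rule set has %d",
                     nd, length(p), length(ix)), call. = FALSE)
      }
      if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
        stop(sprintf("override probabilities for '%s' must be non-negative and sum to 1", nd),
             call. = FALSE)
      }
      rules$prob[ix] <- p
      rules$prob_exact[ix] <- p
    }
  }

  model <- structure(
    list(nodes = base_model$nodes, rules = rules,
         initial_state = base_model$initial_state,
         network = network, params = params),
    class = c("pbn_model", "boolean_model")
  )
  validate_bipartite(model)
  model
}

format_prob6 <- function(p) {
  s <- sprintf("%.6f", p)
  s <- sub("0+$", "", s)
  sub("\\.$", ".0", s)
}

#' Write a probabilistic model in the BoolNet text dialect
#'
#' Header `targets, factors, probabilities`, then one row per rule:
#' `node, <expr with & | !>, <probability>`. Constant rules are written as
#' `1`/`0`; probabilities use the reported six-decimal residue convention,
#' so each node's rows sum to exactly 1. Node ids are sanitized, with the
#' name map written as a TSV sidecar.
#'
#' @param model A `boolean_model` (deterministic nodes get probability 1).
#' @param file Output path.
#' @param map_file Path for the name map; default `<file>.names.tsv`.
#' @return `file`, invisibly.
#' @export
write_boolnet <- function(model, file, map_file = paste0(file, ".names.tsv")) {
  san <- sanitize_node_names(model$nodes$node)
  rename <- stats::setNames(san, model$nodes$node)
  rows <- vapply(seq_len(nrow(model$rules)), function(i) {
    expr <- model$rules$expr[[i]]
    sprintf("%s, %s, %s", rename[[model$rules$node[i]]],
            expr_to_string(expr, "boolnet", rename = rename),
            format_prob6(model$rules$prob[i]))
  }, character(1))
  writeLines(c("targets, factors, probabilities", rows), file, useBytes = TRUE)
  utils::write.table(
    data.frame(original = model$nodes$node, sanitized = san),
    map_file, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(file)
}
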