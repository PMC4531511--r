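# Qualitative bipartite Boolean model generation.
#
# The generated network has two node classes: reaction nodes, whose update
# rules read only state and component-presence nodes, and state/presence
# nodes, whose rules read only reaction nodes (plus themselves, as memory).

state_producers <- function(network, state_id) {
  rx <- network$reactions
  rx$id[rx$action == "produce" & !is.na(rx$state_id) & rx$state_id == state_id]
}

state_consumers <- function(network, state_id) {
  rx <- network$reactions
  rx$id[rx$action == "consume" & !is.na(rx$state_id) & rx$state_id == state_id]
}

presence_reactions <- function(network, component, action) {
  rx <- network$reactions
  rx$id[rx$kind == "presence" & rx$action == action &
          component_of(rx$rhs) == component]
}

#' Update rule of a reaction node
#'
#' A reaction fires iff its substrate components are present, all its
#' absolute requirements (`!`) hold and none of its absolute inhibitions
#' (`x`) hold. Quantitative modifiers (K+/K-) and the inert signs (0/?) are
#' ignored in the qualitative model.
#'
#' @param network A `rxncon_network`.
#' @param reaction Reaction id.
#' @return A `bool_expr`.
#' @examples
#' net <- parse_rxncon("B_ppi_C\nA_ppi_B; ! B--C")
#' build_reaction_rule(net, "A_ppi_B")  # A & B & B--C
#' @export
build_reaction_rule <- function(network, reaction) {
  rx <- network$reactions[network$reactions$id == reaction, ]
  if (nrow(rx) != 1L) stop(sprintf("unknown reaction id '%s'", reaction), call. = FALSE)
  comps <- component_of(c(rx$lhs, rx$rhs))
  if (rx$substrates == "lhs") comps <- component_of(rx$lhs)
  cg <- network$contingencies[network$contingencies$target == reaction, ]
  req <- cg$effector[cg$sign == "!"]
  inh <- cg$effector[cg$sign == "x"]
  b_and(
    do.call(b_and, lapply(unique(comps), b_lit)),
    do.call(b_and, lapply(req, b_lit)),
    do.call(b_and, lapply(inh, function(s) b_not(b_lit(s))))
  )
}

#' Component-availability factor of a state rule
#'
#' A state cannot be TRUE if one of its member components is being degraded
#' and not synthesized at the same time: for each member component `c` the
#' factor is `!(deg_c & !syn_c)` where `deg_c`/`syn_c` are the disjunctions
#' of the degradation/synthesis reactions targeting `c`. Networks without
#' degradation reactions get the constant TRUE (rules unchanged).
#'
#' @param network A `rxncon_network`.
#' @param state State id (or a character vector of member components).
#' @return A `bool_expr`.
#' @export
component_availability_term <- function(network, state) {
  if (state %in% network$states$id) {
    members <- network$states$members[[match(state, network$states$id)]]
  } else {
    members <- state
  }
  factors <- lapply(unique(members), function(comp) {
    degs <- presence_reactions(network, comp, "consume")
    if (length(degs) == 0L) return(b_true())
    syns <- presence_reactions(network, comp, "produce")
    b_not(b_and(do.call(b_or, lapply(degs, b_lit)),
                b_not(do.call(b_or, lapply(syns, b_lit)))))
  })
  do.call(b_and, factors)
}

#' Update rule of a state node
#'
#' Products of reversible reactions track their producing reactions directly
#' (`state := OR(producers)`, additionally blocked by active consumers):
#' they decay as soon as no producer fires. Products of irreversible
#' reactions have memory, implemented as self-dependence: they stay TRUE
#' unless a consumer fires while no producer does
#' (`state := OR(producers) | (state & !OR(consumers))`). Both forms are
#' conjoined with the component-availability factor.
#'
#' @param network A `rxncon_network`.
#' @param state State id.
#' @return A `bool_expr`.
#' @examples
#' net <- parse_rxncon("B_ppi_C")
#' build_state_rule(net, "B--C")  # B_ppi_C
#' @export
build_state_rule <- function(network, state) {
  if (!state %in% network$states$id) stop(sprintf("unknown state id '%s'", state), call. = FALSE)
  producers <- state_producers(network, state)
  consumers <- state_consumers(network, state)
  avail <- component_availability_term(network, state)
  reversible <- length(producers) > 0L &&
    all(network$reactions$reversible[match(producers, network$reactions$id)])
  if (reversible) {
    core <- b_and(do.call(b_or, lapply(producers, b_lit)),
                  do.call(b_and, lapply(consumers, function(r) b_not(b_lit(r)))))
  } else {
    core <- b_or(do.call(b_or, lapply(producers, b_lit)),
                 b_and(b_lit(state),
                       b_not(do.call(b_or, lapply(consumers, b_lit)))))
  }
  b_and(core, avail)
}

presence_rule <- function(network, comp) {
  syns <- presence_reactions(network, comp, "produce")
  degs <- presence_reactions(network, comp, "consume")
  if (length(syns) == 0L && length(degs) == 0L) return(b_lit(comp))
  b_or(do.call(b_or, lapply(syns, b_lit)),
       b_and(b_lit(comp), b_not(do.call(b_or, lapply(degs, b_lit)))))
}

#' Build the qualitative bipartite Boolean model
#'
#' Creates one node per component (a presence node), per elemental state and
#' per elemental reaction, each with exactly one update rule. Presence nodes
#' are constant at their initial value unless the component is targeted by
#' synthesis/degradation reactions, in which case they get memory rules like
#' irreversible states. The default start state sets component-presence
#' nodes TRUE and everything else FALSE.
#'
#' @param network A validated `rxncon_network`.
#' @return An object of class `c("bbn_model", "boolean_model")` with fields
#'   `nodes` (tibble `node`, `type`), `rules` (tibble `node`, `rule_index`,
#'   `prob`, `prob_exact`, `label`, `expr` list-column) and `initial_state`
#'   (named logical).
#' @examples
#' net <- parse_rxncon("B_ppi_C\nA_ppi_B; ! B--C")
#' model <- build_model(net)
#' tidy(model)
#' @export
build_model <- function(network) {
  validate_rxncon(network)
  nodes <- tibble::tibble(
    node = c(network$components$name, network$states$id, network$reactions$id),
    type = rep(c("component", "state", "reaction"),
               c(nrow(network$components), nrow(network$states), nrow(network$reactions)))
  )
  if (anyDuplicated(nodes$node)) {
    stop("node id collision between components, states and reactions", call. = FALSE)
  }
  rules <- purrr::pmap_dfr(nodes, function(node, type) {
    expr <- switch(type,
      component = presence_rule(network, node),
      state = build_state_rule(network, node),
      reaction = build_reaction_rule(network, node)
    )
    tibble::tibble(node = node, rule_index = 1L, prob = 1, prob_exact = 1,
                   label = expr_to_string(expr), expr = list(expr))
  })
  initial <- stats::setNames(nodes$type == "component", nodes$node)
  model <- structure(
    list(nodes = nodes, rules = rules, initial_state = initial,
         network = network, params = NULL),
    class = c("bbn_model", "boolean_model")
  )
  validate_bipartite(model)
  model
}

#' Check the bipartite wiring of a model
#'
#' Reaction rules may reference only state and component-presence nodes;
#' state and presence rules may reference only reaction nodes and the node
#' itself (memory).
#'
#' @param model A `boolean_model`.
#' @return The model, invisibly; stops on a violation.
#' @export
validate_bipartite <- function(model) {
  type_of <- stats::setNames(model$nodes$type, model$nodes$node)
  for (i in seq_len(nrow(model$rules))) {
    node <- model$rules$node[i]
    refs <- expr_vars(model$rules$expr[[i]])
    unknown <- refs[!refs %in% names(type_of)]
    if (length(unknown) > 0L) {
      stop(sprintf("rule for '%s' references undeclared node '%s'", node, unknown[1]),
           call. = FALSE)
    }
    if (type_of[[node]] == "reaction") {
      bad <- refs[type_of[refs] == "reaction"]
      if (length(bad) > 0L) {
        stop(sprintf("reaction rule for '%s' references reaction node '%s'",
                     node, bad[1]), call. = FALSE)
      }
    } else {
      bad <- refs[type_of[refs] != "reaction" & refs != node]
      if (length(bad) > 0L) {
        stop(sprintf("state rule for '%s' references non-reaction node '%s'",
                     node, bad[1]), call. = FALSE)
      }
    }
  }
  invisible(model)
}

#' @export
print.boolean_model <- function(x, ...) {
  cat(sprintf("<%s> %d nodes (%d reactions, %d states, %d components), %d rules\n",
              class(x)[1], nrow(x$nodes),
              sum(x$nodes$type == "reaction"), sum(x$nodes$type == "state"),
              sum(x$nodes$type == "component"), nrow(x$rules)))
  if (!is.null(x$params)) {
    cat(sprintf("  p_false = %g, k_base = %g\n", x$params$p_false, x$params$k_base))
  }
  invisible(x)
}

#' @method tidy boolean_model
#' @export
tidy.boolean_model <- function(x, ...) {
  dplyr::select(x$rules, "node", "rule_index", "prob", "label")
}

#' @method glance boolean_model
#' @export
glance.boolean_model <- function(x, ...) {
  tibble::tibble(
    nodes = nrow(x$nodes),
    reaction_nodes = sum(x$nodes$type == "reaction"),
    state_nodes = sum(x$nodes$type == "state"),
    component_nodes = sum(x$nodes$type == "component"),
    rules = nrow(x$rules),
    probabilistic = inherits(x, "pbn_model")
  )
}

sanitize_node_names <- function(ids) {
  clean <- gsub("[^A-Za-z0-9_]", "_", ids)
  clean <- ifelse(grepl("^[0-9]|^$", clean), paste0("n_", clean), clean)
  make.unique(clean, sep = "_")
}

#' Write a qualitative model in the BooleanNet text dialect
#'
#' One line per node, `Node* = <expr>` with `and`/`or`/`not` keywords. Node
#' ids are sanitized to identifiers; the original-to-sanitized map is
#' written as a two-column TSV sidecar.
#'
#' @param model A `bbn_model`.
#' @param file Output path.
#' @param map_file Path for the name map; default `<file>.names.tsv`.
#' @return `file`, invisibly.
#' @export
write_booleannet <- function(model, file, map_file = paste0(file, ".names.tsv")) {
  san <- sanitize_node_names(model$nodes$node)
  rename <- stats::setNames(san, model$nodes$node)
  lines <- vapply(seq_len(nrow(model$rules)), function(i) {
    expr <- model$rules$expr[[i]]
    sprintf("%s* = %s", rename[[model$rules$node[i]]],
            expr_to_string(expr, "booleannet", rename = rename))
  }, character(1))
  writeLines(lines, file, useBytes = TRUE)
  utils::write.table(
    data.frame(original = model$nodes$node, sanitized = san),
    map_file, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(file)
}
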