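# Parsing and validation of reaction-contingency network definitions.
#
# Dialect: UTF-8 text, `#` starts a comment, one elemental reaction per line,
# optionally followed by `;`-separated contingencies, each `SIGN STATE`:
#
#   B_ppi_C
#   A_ppi_B; K+ B--C; K- A--D
#
# Components and elemental states are derived from the reaction ids; nothing
# is declared separately.

CONTINGENCY_SIGNS <- c("!", "x", "K+", "K-", "0", "?")

normalize_sign <- function(s) {
  s <- ifelse(s == "×", "x", s) # accept the multiplication sign for 'x'
  s
}

# Split a reaction id LHS_code_RHS using the registry codes. Codes are
# matched longest-first so e.g. a hypothetical "P" type cannot shadow "P+".
parse_reaction_id <- function(id, registry) {
  codes <- registry$code[order(-nchar(registry$code))]
  for (code in codes) {
    pat <- paste0("^(.+)_", escape_regex(code), "_(.+)$")
    m <- regmatches(id, regexec(pat, id))[[1]]
    if (length(m) == 3L) {
      return(list(lhs = m[2], code = code, rhs = m[3]))
    }
  }
  NULL
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# A component token is a name with an optional opaque site suffix `_[...]`,
# carried along in ids but without structural semantics.
component_of <- function(token) sub("_\\[.*$", "", token)

# Derive the elemental state(s) a reaction produces/consumes, from its type.
reaction_effects <- function(lhs, code, rhs, registry) {
  row <- registry[registry$code == code, ]
  state_id <- switch(row$kind,
    interaction = paste0(lhs, "--", rhs),
    modification = paste0(rhs, "-{", row$tag, "}"),
    localization = paste0(rhs, "-{", row$tag, "}"),
    presence = NA_character_
  )
  list(
    kind = row$kind, reversible = row$reversible, action = row$action,
    state_id = state_id, substrates = row$substrates
  )
}

#' Parse a reaction-contingency network definition
#'
#' Reads the line-based dialect (one elemental reaction per line with an
#' optional `;`-separated contingency list) and returns a validated network.
#' Components and elemental states are auto-derived from the reaction ids:
#' `A_ppi_B` declares components `A` and `B` and the interaction state
#' `A--B`; `X_P+_Y` declares the modification state `Y-{P}`.
#'
#' @param text Character: either the definition as a (possibly multi-line)
#'   string, or a character vector of lines.
#' @param file Alternatively, path to a definition file.
#' @param registry Reaction-type registry, see [reaction_registry()].
#' @return An object of class `rxncon_network`: a list of tibbles
#'   `components` (`name`), `states` (`id`, `kind`, `members`), `reactions`
#'   (`id`, `code`, `lhs`, `rhs`, `reversible`, `produced`, `consumed`,
#'   `substrates`) and `contingencies` (`target`, `sign`, `effector`).
#' @examples
#' net <- parse_rxncon("B_ppi_C\nA_ppi_B; ! B--C")
#' net$components$name
#' @export
parse_rxncon <- function(text = NULL, file = NULL, registry = default_reaction_types()) {
  if (is.null(text) && is.null(file)) stop("supply `text` or `file`")
  if (!is.null(file)) text <- readLines(file, warn = FALSE, encoding = "UTF-8")
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines_clean <- sub("#.*$", "", lines)
  lines_clean <- trimws(lines_clean)

  reactions <- list()
  contingencies <- list()
  for (i in seq_along(lines_clean)) {
    line <- lines_clean[[i]]
    if (!nzchar(line)) next
    parts <- trimws(strsplit(line, ";", fixed = TRUE)[[1]])
    rid <- parts[[1]]
    parsed <- parse_reaction_id(rid, registry)
    if (is.null(parsed)) {
      stop(sprintf("line %d: malformed reaction id '%s' (no registered reaction type found)",
                   i, rid), call. = FALSE)
    }
    if (rid %in% names(reactions)) {
      stop(sprintf("line %d: duplicate reaction id '%s'", i, rid), call. = FALSE)
    }
    reactions[[rid]] <- c(parsed, list(line = i))
    if (length(parts) > 1L) {
      for (ctok in parts[-1]) {
        if (!nzchar(ctok)) next
        m <- regmatches(ctok, regexec("^(\\S+)\\s+(\\S+)$", ctok))[[1]]
        if (length(m) != 3L || !(normalize_sign(m[2]) %in% CONTINGENCY_SIGNS)) {
          stop(sprintf("line %d: malformed contingency '%s' (expected 'SIGN STATE')",
                       i, ctok), call. = FALSE)
        }
        contingencies[[length(contingencies) + 1L]] <-
          list(target = rid, sign = normalize_sign(m[2]), effector = m[3], line = i)
      }
    }
  }

  rx <- purrr::map2_dfr(reactions, names(reactions), function(p, id) {
    eff <- reaction_effects(p$lhs, p$code, p$rhs, registry)
    tibble::tibble(
      id = id, code = p$code, lhs = p$lhs, rhs = p$rhs,
      kind = eff$kind, reversible = eff$reversible, action = eff$action,
      state_id = eff$state_id, substrates = eff$substrates, line = p$line
    )
  })
  if (nrow(rx) == 0L) {
    rx <- tibble::tibble(id = character(), code = character(), lhs = character(),
                         rhs = character(), kind = character(), reversible = logical(),
                         action = character(), state_id = character(),
                         substrates = character(), line = integer())
  }

  comp_names <- unique(c(component_of(rx$lhs), component_of(rx$rhs)))
  components <- tibble::tibble(name = comp_names)

  st <- rx[!is.na(rx$state_id), ]
  state_ids <- unique(st$state_id)
  states <- tibble::tibble(
    id = state_ids,
    kind = st$kind[match(state_ids, st$state_id)],
    members = purrr::map(state_ids, function(sid) {
      r <- st[st$state_id == sid, ][1, ]
      if (r$kind == "interaction") {
        c(component_of(r$lhs), component_of(r$rhs))
      } else {
        component_of(r$rhs)
      }
    })
  )

  cg <- purrr::map_dfr(contingencies, tibble::as_tibble)
  if (nrow(cg) == 0L) {
    cg <- tibble::tibble(target = character(), sign = character(),
                         effector = character(), line = integer())
  }

  net <- structure(
    list(components = components, states = states,
         reactions = rx, contingencies = cg, registry = registry),
    class = "rxncon_network"
  )
  validate_rxncon(net)
  net
}

#' Validate a reaction-contingency network
#'
#' Checks referential integrity: every contingency targets a declared
#' reaction and names a declared elemental state; no duplicate
#' (target, effector) contingency pairs. Warns for elemental states that are
#' consumed or referenced but never produced (legitimate boundary states in
#' large curated networks).
#'
#' @param network A `rxncon_network`.
#' @return The network, invisibly; stops on violations.
#' @export
validate_rxncon <- function(network) {
  cg <- network$contingencies
  if (nrow(cg) > 0L) {
    bad <- !(cg$target %in% network$reactions$id)
    if (any(bad)) {
      stop(sprintf("contingency on line %d targets unknown reaction '%s'",
                   cg$line[bad][1], cg$target[bad][1]), call. = FALSE)
    }
    bad <- !(cg$effector %in% network$states$id)
    if (any(bad)) {
      stop(sprintf("contingency on line %d references undeclared state '%s'",
                   cg$line[bad][1], cg$effector[bad][1]), call. = FALSE)
    }
    key <- paste(cg$target, cg$effector)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      stop(sprintf("duplicate contingency for (reaction, effector) pair '%s'", d),
           call. = FALSE)
    }
  }
  produced <- unique(network$reactions$state_id[network$reactions$action == "produce"])
  orphan <- setdiff(network$states$id, produced)
  if (length(orphan) > 0L) {
    warning(sprintf("state(s) never produced by any reaction: %s",
                    paste(orphan, collapse = ", ")), call. = FALSE)
  }
  invisible(network)
}

#' Serialize a network back to the line dialect
#'
#' Reactions appear in input order; each reaction's contingencies are sorted
#' by sign (`!`, `x`, `K+`, `K-`, `0`, `?`) then effector, giving a canonical
#' form so that parse -> write -> parse round-trips exactly.
#'
#' @param network A `rxncon_network`.
#' @param file Optional path; if `NULL` the text is returned.
#' @return The definition text (invisibly if written to `file`).
#' @export
write_rxncon <- function(network, file = NULL) {
  sign_rank <- stats::setNames(seq_along(CONTINGENCY_SIGNS), CONTINGENCY_SIGNS)
  lines <- vapply(seq_len(nrow(network$reactions)), function(i) {
    rid <- network$reactions$id[i]
    cg <- network$contingencies[network$contingencies$target == rid, ]
    if (nrow(cg) > 0L) {
      cg <- cg[order(sign_rank[cg$sign], cg$effector), ]
      paste(c(rid, paste(cg$sign, cg$effector)), collapse = "; ")
    } else {
      rid
    }
  }, character(1))
  text <- paste(lines, collapse = "\n")
  if (is.null(file)) return(text)
  writeLines(text, file, useBytes = TRUE)
  invisible(text)
}

#' Quantitative modifiers of a reaction
#'
#' Returns the ordered (input-order) list of K+/K- contingencies on a
#' reaction. Absolute contingencies (`!`, `x`) and the inert signs (`0`, `?`)
#' are excluded: the inert signs are treated as no effect throughout.
#'
#' @param network A `rxncon_network`.
#' @param reaction Reaction id.
#' @return Tibble with columns `effector`, `sign`; `nrow()` is the modifier
#'   count n used by the probabilistic rule construction.
#' @examples
#' net <- parse_rxncon("B_ppi_C\nA_ppi_D\nA_ppi_B; K+ B--C; K- A--D")
#' quantitative_modifiers(net, "A_ppi_B")
#' @export
quantitative_modifiers <- function(network, reaction) {
  if (!reaction %in% network$reactions$id) {
    stop(sprintf("unknown reaction id '%s'", reaction), call. = FALSE)
  }
  cg <- network$contingencies
  cg <- cg[cg$target == reaction & cg$sign %in% c("K+", "K-"), c("effector", "sign")]
  tibble::as_tibble(cg)
}

#' @export
print.rxncon_network <- function(x, ...) {
  cat(sprintf("<rxncon_network> %d components, %d states, %d reactions, %d contingencies\n",
              nrow(x$components), nrow(x$states), nrow(x$reactions), nrow(x$contingencies)))
  invisible(x)
}

#' Strengthen or soften contingency signs
#'
#' Programmatic sign substitution, e.g. to derive the quantitative variant of
#' a qualitative model (`! -> K+`, `x -> K-`) or the reverse strengthening.
#'
#' @param network A `rxncon_network`.
#' @param map Named character vector, names = old signs, values = new signs.
#' @return The modified network.
#' @export
transform_signs <- function(network, map = c("!" = "K+", "x" = "K-")) {
  stopifnot(all(map %in% CONTINGENCY_SIGNS))
  cg <- network$contingencies
  hit <- cg$sign %in% names(map)
  cg$sign[hit] <- unname(map[cg$sign[hit]])
  network$contingencies <- cg
  network
}

#' @method tidy rxncon_network
#' @export
tidy.rxncon_network <- function(x, ...) {
  dplyr::select(x$reactions, "id", "code", "lhs", "rhs", "kind", "reversible",
                "action", "state_id")
}

#' @method glance rxncon_network
#' @export
glance.rxncon_network <- function(x, ...) {
  tibble::tibble(
    components = nrow(x$components), states = nrow(x$states),
    reactions = nrow(x$reactions), contingencies = nrow(x$contingencies),
    quantitative = sum(x$contingencies$sign %in% c("K+", "K-"))
  )
}
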