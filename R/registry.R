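# Reaction-type registry. Each elemental reaction type determines what the
# reaction does to elemental states or component presence, and whether it is
# reversible. The registry is deliberately user-extensible: the formalism's
# type ontology is open-ended and unknown codes can be declared with their
# properties rather than guessed.

#' Declare a reaction type
#'
#' @param code Token appearing in reaction ids, e.g. `"ppi"`, `"P+"`.
#' @param reversible Is the reaction reversible? Products of reversible
#'   reactions persist only while the reaction fires; products of
#'   irreversible reactions have memory and need an active consumer to be
#'   lost.
#' @param kind What the reaction acts on: an `"interaction"` state between
#'   its two partners, a `"modification"` or `"localization"` state of its
#'   right-hand component, or the `"presence"` of its right-hand component
#'   (synthesis/degradation).
#' @param action `"produce"` or `"consume"`.
#' @param tag Modifier/compartment tag used in generated state ids
#'   (e.g. `"P"` gives `X-{P}`, `"nuc"` gives `X-{nuc}`); ignored for
#'   interaction and presence kinds.
#' @param substrates `"both"` if both named components must be present for
#'   the reaction to fire, `"lhs"` if only the left-hand one (synthesis can
#'   create an absent component).
#' @return A one-row tibble suitable for [reaction_registry()].
#' @export
reaction_type <- function(code, reversible = FALSE,
                          kind = c("interaction", "modification", "presence", "localization"),
                          action = c("produce", "consume"),
                          tag = NA_character_, substrates = c("both", "lhs")) {
  kind <- match.arg(kind)
  action <- match.arg(action)
  substrates <- match.arg(substrates)
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  tibble::tibble(code = code, reversible = reversible, kind = kind,
                 action = action, tag = tag, substrates = substrates)
}

#' Default reaction-type registry
#'
#' Ships the types needed for the bundled examples: `ppi` (reversible
#' protein-protein interaction), `P+`/`P-` (irreversible
#' phosphorylation/dephosphorylation), `TRSC`/`TRSL`
#' (transcription/translation, producing component presence), `DEG`
#' (degradation, consuming presence) and `NIMP`/`NEXP` (nuclear
#' import/export as a localization tag). Extend with [reaction_registry()].
#'
#' @return A tibble with one row per reaction type.
#' @export
default_reaction_types <- function() {
  dplyr::bind_rows(
    reaction_type("ppi", reversible = TRUE, kind = "interaction", action = "produce"),
    reaction_type("P+", kind = "modification", action = "produce", tag = "P"),
    reaction_type("P-", kind = "modification", action = "consume", tag = "P"),
    reaction_type("TRSC", kind = "presence", action = "produce", substrates = "lhs"),
    reaction_type("TRSL", kind = "presence", action = "produce", substrates = "lhs"),
    reaction_type("DEG", kind = "presence", action = "consume"),
    reaction_type("NIMP", kind = "localization", action = "produce", tag = "nuc"),
    reaction_type("NEXP", kind = "localization", action = "consume", tag = "nuc")
  )
}

#' Combine the default registry with user-declared types
#'
#' @param ... One-row tibbles from [reaction_type()]. A user type with the
#'   same code as a default overrides it.
#' @param defaults Include [default_reaction_types()]?
#' @return Registry tibble.
#' @export
reaction_registry <- function(..., defaults = TRUE) {
  extra <- dplyr::bind_rows(...)
  base <- if (defaults) default_reaction_types() else extra[0, ]
  if (nrow(extra) > 0L) {
    base <- dplyr::bind_rows(extra, base)
    base <- base[!duplicated(base$code), ]
  }
  if (anyDuplicated(base$code)) stop("duplicate reaction-type codes in registry")
  base
}
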