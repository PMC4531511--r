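# Bundled fixtures and the random network generator. Fixtures ship as
# plain-text network definitions under inst/extdata and are parsed on
# demand, so everything downstream of the parser is exercised on them.

fixture_file <- function(name) {
  path <- system.file("extdata", name, package = "pbbn")
  if (!nzchar(path)) stop(sprintf("bundled fixture file '%s' not found", name), call. = FALSE)
  path
}

new_fixture <- function(name, network_text, default_params, notes) {
  structure(
    list(name = name, network_text = network_text,
         network = parse_rxncon(network_text),
         default_params = default_params, notes = notes),
    class = "fixture_spec"
  )
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf("<fixture_spec> %s (p_false = %g, k_base = %g)\n%s\n",
              x$name, x$default_params$p_false, x$default_params$k_base, x$notes))
  invisible(x)
}

#' Worked three-reaction example network
#'
#' The small interaction network used throughout the documentation:
#' `B_ppi_C` and `A_ppi_D` are contingency-free, while `A_ppi_B` carries
#' one positive (`K+ B--C`) and one negative (`K- A--D`) quantitative
#' modifier, so its probabilistic rule set has n = 2 and four update
#' functions. Default parameters `k = 10`, `p_false = 0.1`.
#'
#' @return A `fixture_spec`: fields `name`, `network_text`, `network`
#'   (parsed), `default_params`, `notes`.
#' @examples
#' fx <- fixture_worked_example()
#' build_pbn(fx$network, fx$default_params)
#' @export
fixture_worked_example <- function() {
  text <- paste(readLines(fixture_file("worked_example.txt"), warn = FALSE),
                collapse = "\n")
  new_fixture(
    "worked_example", text, pbn_params(p_false = 0.1, k_base = 10),
    notes = paste("Three protein-protein interactions; A_ppi_B is quantitatively",
                  "modified by the B--C complex (positive) and the A--D complex",
                  "(negative).")
  )
}

#' Simplified HOG-pathway oscillator fixture
#'
#' A minimal two-module model of the yeast high-osmolarity glycerol (HOG)
#' pathway with negative feedback: a phosphotransfer module (Sln1/Ypd1 ->
#' Ssk1-\{P\}) that, while active, keeps the MAP kinase module off; a MAPK
#' module (Pbs2 -> Hog1-\{P\}, reset by Ptp2) that activates when the
#' phosphotransfer module runs dry; and feedback closure through turgor:
#' Hog1-\{P\} drives glycerol accumulation, restoring turgor and thereby
#' Sln1 activity, which re-activates the phosphotransfer module. The
#' qualitative variant uses absolute contingencies (`!`/`x`); the
#' quantitative variant is derived programmatically by substituting every
#' `!` with `K+` and every `x` with `K-`.
#'
#' This network is a synthetic transcription of the published simplified
#' HOG oscillator: the exact published line set is not reproduced here, and
#' the transcription choices (documented in the methods vignette) were made
#' once so that the deterministic qualitative model shows a sustained
#' oscillation from the components-TRUE start state. Its deterministic
#' cycle length is 12 steps.
#'
#' @param variant `"qualitative"` (absolute contingencies) or
#'   `"quantitative"` (every `!`/`x` replaced by `K+`/`K-`).
#' @return A `fixture_spec`; default parameters `p_false = 0.01`,
#'   `k_base = 100`.
#' @examples
#' fx <- fixture_hog()
#' model <- build_model(fx$network)
#' @export
fixture_hog <- function(variant = c("qualitative", "quantitative")) {
  variant <- match.arg(variant)
  text <- paste(readLines(fixture_file("hog_qualitative.txt"), warn = FALSE),
                collapse = "\n")
  fx <- new_fixture(
    paste0("hog_", variant), text, pbn_params(p_false = 0.01, k_base = 100),
    notes = paste("Synthetic transcription of the simplified two-module HOG",
                  "oscillator (phosphotransfer + MAPK modules, feedback via",
                  "glycerol/turgor); see the methods vignette for the",
                  "transcription assumptions.")
  )
  if (variant == "quantitative") {
    fx$network <- transform_signs(fx$network, c("!" = "K+", "x" = "K-"))
    fx$network_text <- write_rxncon(fx$network)
  }
  fx
}

#' Random reaction-contingency network
#'
#' Generates a connected random network of `ppi` and `P+` reactions with
#' contingencies drawn only among produced states, as a reproducible
#' scalability surrogate for large curated signaling networks. The first
#' `n_components - 1` reactions attach each component to an
#' already-connected one (spanning construction); further reactions join
#' random component pairs.
#'
#' @param n_components Number of components.
#' @param n_reactions Number of elemental reactions (>= `n_components - 1`
#'   recommended for connectivity).
#' @param contingency_density Expected contingencies per reaction; the
#'   generated count is `round(contingency_density * n_reactions)`.
#' @param quantitative_fraction Share of contingencies drawn as `K+`/`K-`
#'   (the rest are `!`/`x`), each sign equally likely within its class.
#' @param seed RNG seed; identical arguments give identical networks.
#' @return A `rxncon_network`.
#' @examples
#' net <- random_network(10, 15, seed = 1)
#' glance(net)
#' @export
random_network <- function(n_components, n_reactions, contingency_density = 1,
                           quantitative_fraction = 0.5, seed = 1L) {
  stopifnot(n_components >= 0, n_reactions >= 0,
            contingency_density >= 0,
            quantitative_fraction >= 0, quantitative_fraction <= 1)
  if (n_reactions > 0 && n_components < 2) {
    stop("need at least 2 components to draw reactions", call. = FALSE)
  }
  set.seed(seed)
  comps <- sprintf("C%03d", seq_len(n_components))
  if (n_reactions == 0L) {
    # components only: an empty definition plus isolated components is not
    # expressible in the dialect; return an empty network with components.
    net <- parse_rxncon("")
    net$components <- tibble::tibble(name = comps)
    return(net)
  }
  ids <- character(0)
  lines <- character(n_reactions)
  connected <- comps[1]
  pending <- setdiff(comps, connected)
  for (i in seq_len(n_reactions)) {
    repeat {
      if (length(pending) > 0L) {
        a <- sample(connected, 1L)
        b <- pending[1L]
      } else {
        ab <- sample(comps, 2L)
        a <- ab[1L]; b <- ab[2L]
      }
      type <- sample(c("ppi", "P+"), 1L)
      rid <- paste0(a, "_", type, "_", b)
      if (!rid %in% ids) break
    }
    if (length(pending) > 0L) {
      connected <- c(connected, b)
      pending <- pending[-1L]
    }
    ids <- c(ids, rid)
    lines[i] <- rid
  }
  net0 <- parse_rxncon(paste(lines, collapse = "\n"))
  states <- net0$states$id
  own <- net0$reactions$state_id
  n_cont <- round(contingency_density * n_reactions)
  capacity <- sum(vapply(seq_len(n_reactions), function(i) {
    length(setdiff(states, own[i]))
  }, numeric(1)))
  if (n_cont > capacity) {
    stop(sprintf("requested %d contingencies but only %d (reaction, state) pairs available",
                 n_cont, capacity), call. = FALSE)
  }
  used <- character(0)
  cont <- vector("list", n_cont)
  j <- 0L
  while (j < n_cont) {
    ti <- sample(n_reactions, 1L)
    eff <- sample(setdiff(states, own[ti]), 1L)
    key <- paste(ids[ti], eff)
    if (key %in% used) next
    used <- c(used, key)
    quant <- stats::runif(1) < quantitative_fraction
    sign <- if (quant) sample(c("K+", "K-"), 1L) else sample(c("!", "x"), 1L)
    j <- j + 1L
    cont[[j]] <- list(target = ti, sign = sign, effector = eff)
  }
  for (cc in cont) {
    lines[cc$target] <- paste0(lines[cc$target], "; ", cc$sign, " ", cc$effector)
  }
  parse_rxncon(paste(lines, collapse = "\n"))
}
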