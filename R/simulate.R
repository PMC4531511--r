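# Synchronous stochastic simulation of probabilistic bipartite Boolean
# models, with ensemble averaging, perturbation (clamp) schedules and an
# exact Markov-chain oracle for small models.
#
# Sampling semantics: the network is an instantaneously random PBN - for
# every node independently, one of its update functions is drawn at every
# time step according to its probabilities, and all nodes are then updated
# simultaneously from the pre-step state.
#
# Reproducibility: run r of an ensemble with master seed s uses the r-th
# L'Ecuyer-CMRG substream derived from s (a counter-based scheme), so
# sequential, chunked and parallel execution give bit-identical ensembles,
# and a single run equals the first run of an ensemble with the same master
# seed. Substreams are used because consecutively seeded default-RNG streams
# are not independent enough for ensemble statistics.

#' Perturbation (clamp) events
#'
#' A clamp holds a node at a fixed Boolean value from its event time until
#' the next event on the same node (or the end of the simulation),
#' overriding the node's update rules. Used to model input switching, e.g.
#' turning turgor off at one time point and on again later.
#'
#' @param time Integer step indices (>= 0) at which each clamp takes effect.
#' @param node Node ids.
#' @param value Logical clamp values.
#' @return A tibble with columns `time`, `node`, `value`.
#' @export
clamp_events <- function(time, node, value) {
  stopifnot(length(time) == length(node), length(node) == length(value))
  tibble::tibble(time = as.integer(time), node = as.character(node),
                 value = as.logical(value))
}

# Compiled form of a model for fast repeated evaluation.
compile_model <- function(model) {
  nodes <- model$nodes$node
  rules_by_node <- split(model$rules, factor(model$rules$node, levels = nodes))
  fns <- lapply(rules_by_node, function(rr) lapply(rr$expr, expr_compile))
  probs <- lapply(rules_by_node, function(rr) {
    p <- rr$prob_exact
    p / sum(p)
  })
  n_rules <- vapply(rules_by_node, nrow, integer(1))
  stoch <- which(n_rules > 1L)
  list(
    nodes = nodes, n = length(nodes), fns = fns, probs = probs,
    cums = lapply(probs, cumsum), n_rules = n_rules,
    stoch = stoch, det = which(n_rules == 1L),
    initial = model$initial_state
  )
}

resolve_initial <- function(cm, initial_state) {
  init <- cm$initial
  if (!is.null(initial_state)) {
    unknown <- setdiff(names(initial_state), cm$nodes)
    if (length(unknown) > 0L) {
      stop(sprintf("initial state names unknown node '%s'", unknown[1]), call. = FALSE)
    }
    init[names(initial_state)] <- as.logical(initial_state)
  }
  init
}

check_clamps <- function(cm, clamps, steps) {
  if (is.null(clamps) || nrow(clamps) == 0L) return(NULL)
  stopifnot(all(c("time", "node", "value") %in% names(clamps)))
  unknown <- setdiff(clamps$node, cm$nodes)
  if (length(unknown) > 0L) {
    stop(sprintf("clamp on unknown node '%s'", unknown[1]), call. = FALSE)
  }
  if (any(clamps$time < 0 | clamps$time > steps)) {
    stop("clamp times must lie within [0, steps]", call. = FALSE)
  }
  clamps
}

# Value of each clamped node active at time t, as a named logical vector
# (nodes without an active clamp are absent).
active_clamps <- function(clamps, t) {
  if (is.null(clamps)) return(NULL)
  cc <- clamps[clamps$time <= t, ]
  if (nrow(cc) == 0L) return(NULL)
  cc <- cc[order(cc$time), ]
  last <- !duplicated(cc$node, fromLast = TRUE)
  stats::setNames(cc$value[last], cc$node[last])
}

apply_clamps <- function(S, clamps, t) {
  ac <- active_clamps(clamps, t)
  if (is.null(ac)) return(S)
  for (nd in names(ac)) S[, nd] <- ac[[nd]]
  S
}

eval_rules_matrix <- function(fns, S) {
  m <- length(fns)
  out <- matrix(FALSE, nrow = nrow(S), ncol = m)
  for (j in seq_len(m)) out[, j] <- fns[[j]](S)
  out
}

# Per-run RNG substreams: the r-th L'Ecuyer-CMRG stream derived from the
# master seed. Restores the caller's RNG state afterwards.
run_streams <- function(seed, runs) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  suppressWarnings(set.seed(seed, kind = "L'Ecuyer-CMRG"))
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", runs)
  for (r in seq_len(runs)) {
    s <- parallel::nextRNGStream(s)
    streams[[r]] <- s
  }
  streams
}

draw_uniforms <- function(stream, n) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  assign(".Random.seed", stream, envir = globalenv())
  u <- stats::runif(n)
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
  u
}

# Simulate one chunk of runs with per-run pre-drawn uniforms.
sim_chunk <- function(cm, run_ids, steps, streams, init, clamps, accum = NULL) {
  Rc <- length(run_ids)
  N <- cm$n
  n_st <- length(cm$stoch)
  U <- NULL
  if (n_st > 0L) {
    U <- array(NA_real_, dim = c(Rc, steps, n_st))
    for (r in seq_len(Rc)) {
      U[r, , ] <- matrix(draw_uniforms(streams[[run_ids[r]]], steps * n_st),
                         nrow = steps)
    }
  }
  S <- matrix(rep(init, each = Rc), nrow = Rc, ncol = N,
              dimnames = list(NULL, cm$nodes))
  S <- apply_clamps(S, clamps, 0L)
  keep_runs <- is.null(accum)
  out <- NULL
  if (keep_runs) {
    out <- array(FALSE, dim = c(Rc, steps + 1L, N),
                 dimnames = list(NULL, 0:steps, cm$nodes))
    out[, 1L, ] <- S
  } else {
    accum[1L, ] <- accum[1L, ] + colSums(S)
  }
  idxR <- seq_len(Rc)
  for (t in seq_len(steps)) {
    newS <- S
    for (j in cm$det) {
      newS[, j] <- cm$fns[[j]][[1L]](S)
    }
    for (jj in seq_along(cm$stoch)) {
      j <- cm$stoch[[jj]]
      vals <- eval_rules_matrix(cm$fns[[j]], S)
      cum <- cm$cums[[j]]
      ridx <- findInterval(U[, t, jj], cum[-length(cum)]) + 1L
      newS[, j] <- vals[cbind(idxR, ridx)]
    }
    newS <- apply_clamps(newS, clamps, t)
    S <- newS
    if (keep_runs) {
      out[, t + 1L, ] <- S
    } else {
      accum[t + 1L, ] <- accum[t + 1L, ] + colSums(S)
    }
  }
  if (keep_runs) out else accum
}

#' Single synchronous update step
#'
#' Samples one update function per node from the current RNG stream and
#' applies all updates simultaneously from the given state. Deterministic
#' models (one rule per node) reduce to the plain synchronous Boolean
#' update.
#'
#' @param model A `boolean_model`.
#' @param state Named logical vector covering all nodes.
#' @return The next state, as a named logical vector.
#' @export
pbn_step <- function(model, state) {
  cm <- compile_model(model)
  missing <- setdiff(cm$nodes, names(state))
  if (length(missing) > 0L) {
    stop(sprintf("state is missing node '%s'", missing[1]), call. = FALSE)
  }
  S <- matrix(state[cm$nodes], nrow = 1L, dimnames = list(NULL, cm$nodes))
  newS <- S
  for (j in seq_len(cm$n)) {
    fns <- cm$fns[[j]]
    if (length(fns) == 1L) {
      newS[, j] <- fns[[1L]](S)
    } else {
      cum <- cm$cums[[j]]
      r <- findInterval(stats::runif(1L), cum[-length(cum)]) + 1L
      newS[, j] <- fns[[r]](S)
    }
  }
  stats::setNames(as.logical(newS), cm$nodes)
}

#' Simulate a single trajectory
#'
#' @param model A `boolean_model`.
#' @param steps Number of synchronous update steps (>= 1); the returned
#'   series has `steps + 1` rows, with time 0 the initial state.
#' @param seed Master seed; the run uses the first RNG substream derived
#'   from it (it is run 1 of an ensemble with the same master seed).
#' @param initial_state Optional named logical vector overriding entries of
#'   the model's default start state (components TRUE, all else FALSE).
#' @param clamps Optional [clamp_events()] tibble.
#' @return A tibble with column `time` and one integer 0/1 column per node.
#' @export
simulate_run <- function(model, steps, seed = 1L, initial_state = NULL,
                         clamps = NULL) {
  ens <- simulate_ensemble(model, steps = steps, runs = 1L, seed = seed,
                           initial_state = initial_state, clamps = clamps)
  vals <- ens$values[1L, , , drop = TRUE]
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1L, dimnames = list(NULL, ens$nodes))
  out <- tibble::as_tibble(as.data.frame(vals * 1L, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(time = 0:steps), out)
}

#' Simulate an ensemble of independent runs
#'
#' Runs are independent realizations of the same probabilistic model from
#' the same start state; run `r` uses the `r`-th L'Ecuyer-CMRG substream
#' derived from the master seed, so results are identical whether runs are
#' executed sequentially, in chunks or in parallel, and run `r` is
#' reproducible on its own.
#'
#' @inheritParams simulate_run
#' @param runs Ensemble size (>= 1).
#' @param keep `"runs"` returns the full runs x time x node Boolean array
#'   (class `trajectory_ensemble`); `"mean"` accumulates only the per-step
#'   per-node ensemble means (class `ensemble_summary`), useful for large
#'   models.
#' @param chunk_size Runs simulated per vectorized block; affects speed and
#'   memory only, never results.
#' @return A `trajectory_ensemble` (fields `values`, `nodes`, `steps`,
#'   `runs`, `seed`) or an `ensemble_summary` tibble, per `keep`.
#' @export
simulate_ensemble <- function(model, steps, runs = 1L, seed = 1L,
                              initial_state = NULL, clamps = NULL,
                              keep = c("runs", "mean"), chunk_size = 256L) {
  keep <- match.arg(keep)
  stopifnot(steps >= 1L, runs >= 1L)
  cm <- compile_model(model)
  init <- resolve_initial(cm, initial_state)
  clamps <- check_clamps(cm, clamps, steps)
  chunks <- split(seq_len(runs), ceiling(seq_len(runs) / chunk_size))
  streams <- run_streams(seed, runs)
  if (keep == "runs") {
    values <- array(FALSE, dim = c(runs, steps + 1L, cm$n),
                    dimnames = list(NULL, 0:steps, cm$nodes))
    for (ch in chunks) {
      values[ch, , ] <- sim_chunk(cm, ch, steps, streams, init, clamps)
    }
    structure(
      list(values = values, nodes = cm$nodes, steps = steps, runs = runs,
           seed = seed, clamps = clamps),
      class = "trajectory_ensemble"
    )
  } else {
    accum <- matrix(0, nrow = steps + 1L, ncol = cm$n,
                    dimnames = list(0:steps, cm$nodes))
    for (ch in chunks) {
      accum <- sim_chunk(cm, ch, steps, streams, init, clamps, accum = accum)
    }
    new_ensemble_summary(accum / runs, runs = runs)
  }
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d runs x %d time points x %d nodes (seed %d)\n",
              x$runs, x$steps + 1L, length(x$nodes), x$seed))
  invisible(x)
}

#' @method tidy trajectory_ensemble
#' @export
tidy.trajectory_ensemble <- function(x, ...) {
  grid <- expand.grid(run = seq_len(x$runs), time = 0:x$steps,
                      node = x$nodes, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$value <- as.vector(x$values) * 1L
  tibble::as_tibble(grid)
}

#' @method glance trajectory_ensemble
#' @export
glance.trajectory_ensemble <- function(x, ...) {
  tibble::tibble(runs = x$runs, steps = x$steps, nodes = length(x$nodes),
                 seed = x$seed, clamped = length(unique(x$clamps$node)))
}

#' Exact per-step marginal activation probabilities (Markov-chain oracle)
#'
#' Propagates the full state distribution of the synchronous PBN (a Markov
#' chain over the 2^N Boolean states) and returns the exact per-node
#' marginal activation probability at every step. Exponential in the node
#' count; restricted to models with at most 16 nodes. Serves as the
#' independent oracle that ensemble means converge to at rate ~1/sqrt(runs).
#'
#' @param model A `boolean_model` with <= 16 nodes.
#' @param steps Number of steps to propagate.
#' @param initial_state Optional named logical overrides of the start state.
#' @return A tibble with columns `time` (0..steps), `node`, `prob`.
#' @export
exact_markov_distribution <- function(model, steps, initial_state = NULL) {
  cm <- compile_model(model)
  N <- cm$n
  if (N > 16L) {
    stop(sprintf("model has %d nodes; the exact oracle is limited to 16", N),
         call. = FALSE)
  }
  init <- resolve_initial(cm, initial_state)
  nstates <- 2^N
  idx <- 0:(nstates - 1L)
  bits <- matrix(FALSE, nstates, N, dimnames = list(NULL, cm$nodes))
  for (j in seq_len(N)) bits[, j] <- bitwAnd(idx, 2^(j - 1L)) > 0L
  bits_num <- bits * 1

  # per-state next-value data
  det_next <- NULL
  if (length(cm$det) > 0L) {
    det_next <- vapply(cm$det, function(j) cm$fns[[j]][[1L]](bits), logical(nstates))
    if (is.null(dim(det_next))) det_next <- matrix(det_next, nrow = nstates)
  }
  K <- length(cm$stoch)
  Q <- NULL
  if (K > 0L) {
    Q <- matrix(0, nstates, K)
    for (jj in seq_len(K)) {
      j <- cm$stoch[[jj]]
      vals <- eval_rules_matrix(cm$fns[[j]], bits)
      Q[, jj] <- as.vector(vals %*% cm$probs[[j]])
    }
  }
  det_part <- if (is.null(det_next)) numeric(nstates) else
    as.vector(det_next %*% 2^(cm$det - 1L))
  patt <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), K)))
  offsets <- if (K > 0L) as.vector(patt %*% 2^(cm$stoch - 1L)) else 0

  p <- numeric(nstates)
  p[sum(2^(which(init) - 1L)) + 1L] <- 1
  marg <- matrix(0, steps + 1L, N, dimnames = list(0:steps, cm$nodes))
  marg[1L, ] <- as.vector(crossprod(bits_num, p))
  for (t in seq_len(steps)) {
    p2 <- numeric(nstates)
    act <- which(p > 0)
    for (b in seq_len(max(1L, nrow(patt)))) {
      w <- p[act]
      if (K > 0L) {
        for (jj in seq_len(K)) {
          w <- w * (if (patt[b, jj]) Q[act, jj] else 1 - Q[act, jj])
        }
      }
      tgt <- det_part[act] + (if (K > 0L) offsets[b] else 0) + 1
      agg <- rowsum(w, tgt)
      ti <- as.numeric(rownames(agg))
      p2[ti] <- p2[ti] + agg[, 1L]
    }
    p <- p2 / sum(p2)
    marg[t + 1L, ] <- as.vector(crossprod(bits_num, p))
  }
  marg <- pmin(pmax(marg, 0), 1)
  tibble::tibble(
    time = rep(0:steps, times = N),
    node = rep(cm$nodes, each = steps + 1L),
    prob = as.vector(marg)
  )
}
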