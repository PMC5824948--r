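## Closed-system (deterministic) analysis: iterate the synchronous update map
## over an exhaustive or sampled set of initial states, detect point/cyclic
## attractors, and measure basins of attraction.

EXHAUSTIVE_LIMIT <- 24L

#' Enumerate or sample the binary state space
#'
#' `enumerate_states()` yields the codes of all `2^N` states in ascending
#' order; it refuses networks above the exhaustive limit (default 24 nodes)
#' and advises sampling instead. `sample_states()` draws `k` states uniformly
#' (with replacement) from `{0,1}^N`, optionally holding some nodes at given
#' values, reproducibly for a given seed.
#'
#' @param n_nodes number of nodes.
#' @param limit exhaustive-enumeration capacity limit.
#' @param k sample size.
#' @param seed integer seed (the sampler restores the caller's RNG state).
#' @param fixed optional named vector of node-value constraints, names being
#'   node indices (or node names when `spec` is given).
#' @param spec optional [network_spec()] used to resolve constraint names.
#' @return `enumerate_states()`: numeric vector of state codes;
#'   `sample_states()`: 0/1 matrix with one state per column.
#' @export
enumerate_states <- function(n_nodes, limit = EXHAUSTIVE_LIMIT) {
  if (n_nodes > limit) {
    stop("exhaustive enumeration of 2^", n_nodes, " states exceeds the ",
         "capacity limit (", limit, " nodes); use sample_states() instead",
         call. = FALSE)
  }
  seq(0, 2^n_nodes - 1)
}

#' @rdname enumerate_states
#' @export
sample_states <- function(n_nodes, k, seed = NULL, fixed = NULL, spec = NULL) {
  stopifnot(k >= 1)
  idx <- NULL
  if (!is.null(fixed)) {
    nm <- names(fixed)
    if (is.null(nm)) stop("'fixed' must be a named vector")
    idx <- if (!is.null(spec)) node_index(spec, nm) else as.integer(nm)
    if (anyDuplicated(idx)) {
      dup <- idx[duplicated(idx)]
      if (any(tapply(fixed, idx, function(v) length(unique(v)) > 1L))) {
        stop("contradictory constraints on node(s) ", paste(unique(dup), collapse = ", "))
      }
    }
    if (!all(fixed %in% c(0, 1))) stop("constraint values must be 0 or 1")
  }
  with_local_seed(seed, {
    S <- matrix(sample(c(0, 1), n_nodes * k, replace = TRUE), nrow = n_nodes)
    if (!is.null(idx)) S[idx, ] <- fixed
    S
  })
}

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## ---- attractor containers --------------------------------------------------

# Canonical rotation: cycle states rotated so the minimum key (numeric code
# when N <= 53, lexicographic bit-key otherwise) comes first. Precomputed
# state keys can be passed to avoid re-deriving them per attractor.
make_attractor <- function(S, nodes, keys = NULL) {
  S <- as.matrix(S)
  if (is.null(keys)) keys <- state_key(S)
  L <- ncol(S)
  codes <- if (nrow(S) <= 53) state_code(S) else NULL
  start <- if (is.null(codes)) which(keys == min(keys))[1L] else which.min(codes)
  ord <- ((start - 1L + seq_len(L) - 1L) %% L) + 1L
  S <- S[, ord, drop = FALSE]
  rownames(S) <- nodes
  structure(
    list(kind = if (L == 1L) "point" else "cyclic",
         states = S,
         length = L,
         codes = codes[ord],
         id_key = paste(keys[ord], collapse = ";")),
    class = "attractor"
  )
}

#' @export
print.attractor <- function(x, ...) {
  cat(x$kind, "attractor, cycle length", x$length)
  if (!is.null(x$codes)) cat(", state code(s):", paste(x$codes, collapse = " -> "))
  cat("\n")
  invisible(x)
}

#' Trajectory from a start state to its attractor
#'
#' Iterates the deterministic synchronous map from `start` until a state
#' repeats; because the map is total on a finite space this terminates in at
#' most `2^N` steps. The trajectory runs from `start` up to (and including)
#' the first revisited state's predecessor; the attractor is the cycle that
#' was entered, in canonical rotation.
#'
#' @param start 0/1 state vector.
#' @param spec a [network_spec()].
#' @param mode `"weighted"` or `"rules"`.
#' @return list with elements `trajectory` (0/1 matrix, one state per
#'   column) and `attractor` (an `attractor` object, without basin data).
#' @export
find_attractor <- function(start, spec, mode = c("weighted", "rules")) {
  mode <- match.arg(mode)
  stepf <- step_matrix_fun(spec, mode)
  s <- as_state_matrix(start, spec)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  traj <- list()
  repeat {
    key <- state_key(s)
    if (!is.null(pos <- seen[[key]])) {
      cyc <- do.call(cbind, traj[pos:length(traj)])
      return(list(
        trajectory = do.call(cbind, traj),
        attractor = make_attractor(cyc, spec$nodes)
      ))
    }
    traj[[length(traj) + 1L]] <- s
    seen[[key]] <- length(traj)
    s <- stepf(s)
  }
}

## ---- full analysis ---------------------------------------------------------

#' Deterministic attractor and basin analysis
#'
#' Runs the synchronous deterministic map over a set of initial states --
#' either the exhaustive `2^N` state space or `k` uniformly sampled states --
#' assigns every analyzed state to the attractor its trajectory reaches, and
#' aggregates basin counts. Attractors are deduplicated by their canonical
#' cycle, so each distinct cycle appears once. Basin fractions are counts
#' divided by the number of analyzed initial states (duplicates in a sample
#' count each time) and always sum to 1.
#'
#' Two result-equivalent engines are available: `"batch"` advances all
#' trajectories in lock step with matrix updates (cycle detection by
#' tortoise-and-hare), `"walk"` follows one trajectory at a time and may
#' memoize visited states. They produce identical results; `"batch"` is the
#' default for speed.
#'
#' @param spec a [network_spec()].
#' @param space `"exhaustive"` or `"sample"`.
#' @param mode `"weighted"` or `"rules"`.
#' @param k sample size when `space = "sample"`.
#' @param seed RNG seed for sampling (required for `space = "sample"`).
#' @param states optional explicit 0/1 matrix of initial states (one per
#'   column), overriding `space`.
#' @param engine `"batch"` or `"walk"`.
#' @param memoize (walk engine) reuse attractor assignments of previously
#'   visited states; never changes results.
#' @param limit exhaustive capacity limit, see [enumerate_states()].
#' @return a `da_result`: list with `attractors` (each with `basin_count`
#'   and `basin_fraction`), `assignment` (attractor index per analyzed
#'   state), `n_states`, and the space descriptor.
#' @examples
#' spec <- network_spec(c("A", "B"), W = rbind(c(0, -1), c(-1, 0)))
#' deterministic_analysis(spec)  # mutual inhibition: bistable
#' @export
deterministic_analysis <- function(spec, space = c("exhaustive", "sample"),
                                   mode = c("weighted", "rules"),
                                   k = NULL, seed = NULL, states = NULL,
                                   engine = c("batch", "walk"),
                                   memoize = TRUE,
                                   limit = EXHAUSTIVE_LIMIT) {
  space <- match.arg(space)
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  n <- n_nodes(spec)

  if (is.null(states)) {
    if (space == "exhaustive") {
      codes <- enumerate_states(n, limit)
      states <- decode_state(codes, n)
      descr <- list(space = "exhaustive", n = n)
    } else {
      if (is.null(k)) stop("space = 'sample' requires a sample size k")
      if (is.null(seed)) stop("space = 'sample' requires a seed")
      states <- sample_states(n, k, seed = seed)
      descr <- list(space = "sample", k = k, seed = seed)
    }
  } else {
    states <- as_state_matrix(states, spec)
    descr <- list(space = "explicit", k = ncol(states))
  }

  res <- if (engine == "batch") {
    da_engine_batch(states, spec, mode)
  } else {
    da_engine_walk(states, spec, mode, memoize)
  }

  m <- ncol(states)
  counts <- tabulate(res$assignment, nbins = length(res$attractors))
  for (i in seq_along(res$attractors)) {
    res$attractors[[i]]$basin_count <- counts[i]
    res$attractors[[i]]$basin_fraction <- counts[i] / m
  }
  structure(
    list(attractors = res$attractors, assignment = res$assignment,
         n_states = m, space = descr, mode = mode, nodes = spec$nodes),
    class = "da_result"
  )
}

# Batch engine: tortoise/hare in lock step over all trajectories, then the
# (few) unique in-cycle meeting states are walked individually to extract
# and canonicalize their cycles.
da_engine_batch <- function(states, spec, mode) {
  stepf <- step_matrix_fun(spec, mode)
  m <- ncol(states)
  slow <- states
  fast <- stepf(states)
  meet <- matrix(0, nrow(states), m)
  active <- rep(TRUE, m)
  done <- colSums(abs(slow - fast)) == 0
  if (any(done)) {
    meet[, done] <- slow[, done]
    active[done] <- FALSE
  }
  while (any(active)) {
    slow[, active] <- stepf(slow[, active, drop = FALSE])
    fast[, active] <- stepf(stepf(fast[, active, drop = FALSE]))
    nowdone <- active
    nowdone[active] <- colSums(abs(slow[, active, drop = FALSE] -
                                   fast[, active, drop = FALSE])) == 0
    if (any(nowdone)) {
      meet[, nowdone] <- slow[, nowdone]
      active[nowdone] <- FALSE
    }
  }
  keys <- state_key(meet)
  uk <- unique(keys)
  # extract all cycles in lock step: walk the unique meeting states until
  # each returns to its start; keep the key matrix alongside
  S0 <- meet[, match(uk, keys), drop = FALSE]
  cyc_states <- list(S0)
  cyc_keys <- list(uk)
  open <- rep(TRUE, length(uk))
  S <- stepf(S0)
  K <- state_key(S)
  while (any(open)) {
    closed_now <- which(open)[K[open] == uk[open]]
    open[closed_now] <- FALSE
    if (!any(open)) break
    cyc_states[[length(cyc_states) + 1L]] <- S
    cyc_keys[[length(cyc_keys) + 1L]] <- K
    S[, open] <- stepf(S[, open, drop = FALSE])
    K[open] <- state_key(S[, open, drop = FALSE])
  }
  KM <- do.call(rbind, cyc_keys)  # snapshots x unique meeting states
  attractors <- list()
  attr_of_key <- new.env(hash = TRUE, parent = emptyenv())
  id_index <- new.env(hash = TRUE, parent = emptyenv())
  for (u in seq_along(uk)) {
    ck <- KM[, u]
    L <- match(uk[u], ck[-1L])  # first return to start after step 1
    if (is.na(L)) L <- length(ck)
    cyc <- vapply(cyc_states[seq_len(L)], function(m) m[, u],
                  numeric(nrow(meet)))
    cyc <- matrix(cyc, nrow = nrow(meet))
    a <- make_attractor(cyc, spec$nodes, keys = ck[seq_len(L)])
    if (is.null(id_index[[a$id_key]])) {
      attractors[[length(attractors) + 1L]] <- a
      id_index[[a$id_key]] <- length(attractors)
    }
    attr_of_key[[uk[u]]] <- id_index[[a$id_key]]
  }
  assignment <- vapply(keys, function(k) attr_of_key[[k]], integer(1L),
                       USE.NAMES = FALSE)
  list(attractors = attractors, assignment = assignment)
}

# Walk engine: one trajectory at a time; optional memo table
# state-key -> attractor id shared across trajectories.
da_engine_walk <- function(states, spec, mode, memoize) {
  stepf <- step_matrix_fun(spec, mode)
  stepv <- function(s) stepf(matrix(s, ncol = 1L))[, 1L]
  m <- ncol(states)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  id_index <- new.env(hash = TRUE, parent = emptyenv())
  attractors <- list()
  assignment <- integer(m)
  for (j in seq_len(m)) {
    s <- states[, j]
    path_keys <- character(0)
    pos <- new.env(hash = TRUE, parent = emptyenv())
    aid <- NA_integer_
    repeat {
      key <- state_key(s)
      if (memoize && !is.null(hit <- memo[[key]])) { aid <- hit; break }
      if (!is.null(p <- pos[[key]])) {
        # new cycle: states path_keys[p:end]
        cyc_keys <- path_keys[p:length(path_keys)]
        cyc <- vapply(cyc_keys,
                      function(kk) as.numeric(strsplit(kk, "")[[1L]]),
                      numeric(n_nodes(spec)))
        a <- make_attractor(matrix(cyc, nrow = n_nodes(spec)), spec$nodes)
        if (is.null(id_index[[a$id_key]])) {
          attractors[[length(attractors) + 1L]] <- a
          id_index[[a$id_key]] <- length(attractors)
        }
        aid <- id_index[[a$id_key]]
        break
      }
      path_keys <- c(path_keys, key)
      pos[[key]] <- length(path_keys)
      s <- stepv(s)
    }
    if (memoize) for (kk in path_keys) memo[[kk]] <- aid
    assignment[j] <- aid
  }
  list(attractors = attractors, assignment = assignment)
}

#' @export
print.da_result <- function(x, ...) {
  cat("Deterministic analysis over ", x$n_states, " initial states (",
      x$space$space, " space, ", x$mode, " mode)\n", sep = "")
  cat(length(x$attractors), "attractor(s):\n")
  print(da_table(x))
  invisible(x)
}

#' Tabulate a deterministic-analysis result
#'
#' @param result a `da_result` from [deterministic_analysis()].
#' @return data frame with one row per attractor: id, kind, cycle length,
#'   basin count, basin fraction and semicolon-joined cycle state codes.
#' @export
da_table <- function(result) {
  a <- result$attractors
  data.frame(
    attractor_id = seq_along(a),
    kind = vapply(a, `[[`, "", "kind"),
    cycle_length = vapply(a, `[[`, 0L, "length"),
    basin_count = vapply(a, `[[`, 0L, "basin_count"),
    basin_fraction = vapply(a, `[[`, 0, "basin_fraction"),
    cycle_states = vapply(a, function(x) {
      if (is.null(x$codes)) x$id_key else paste(x$codes, collapse = ";")
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' @rdname da_table
#' @param path output CSV path.
#' @export
export_da <- function(result, path) {
  utils::write.csv(da_table(result), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
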