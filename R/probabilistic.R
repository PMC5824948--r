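## Open-system (probabilistic) analysis. The deterministic threshold update
## is softened by a noise parameter mu (an inverse-temperature): a node with
## net input h switches on with probability 1 / (1 + exp(-2*mu*h)). A node
## receiving no net regulation (h == 0) spontaneously flips with odds c (the
## degradation constant), i.e. retains its current state with probability
## 1 / (1 + c): c = 0 freezes unregulated nodes (the deterministic hold),
## c = 0.01 flips them about once per hundred steps, c = 1 is a fair coin.
## As mu -> Inf the h != 0 case recovers the deterministic threshold rule,
## and for c < 1 the most likely successor equals the deterministic one.

PA_EXHAUSTIVE_LIMIT <- 14L

#' Noise parameters for probabilistic analysis
#'
#' @param mu noise level (inverse temperature), finite and positive.
#' @param c degradation constant, non-negative: the per-step odds that an
#'   unregulated (`h == 0`) node flips spontaneously.
#' @return a `noise_params` object.
#' @export
noise_params <- function(mu, c = 0) {
  if (!is.finite(mu) || mu <= 0) stop("mu must be finite and positive")
  if (!is.finite(c) || c < 0) stop("c must be finite and non-negative")
  structure(list(mu = mu, c = c), class = "noise_params")
}

#' Per-node switching probability under noise
#'
#' Probability that a node is ON at the next step, given its net input `h`
#' and current state `s_current`: `1 / (1 + exp(-2 mu h))` for `h != 0`;
#' for `h == 0` (an unregulated node) the node retains its current state
#' with probability `1 / (1 + c)` -- the degradation constant `c` is the
#' odds of a spontaneous flip per step. Overflow is saturated
#' (probabilities reach exactly 0/1 for very large `|h|`).
#'
#' @param h net input(s), finite.
#' @param s_current current state(s), 0/1.
#' @param params a [noise_params()].
#' @return probability (vectorized over `h` and `s_current`).
#' @export
node_on_probability <- function(h, s_current, params) {
  stopifnot(inherits(params, "noise_params"))
  p <- 1 / (1 + exp(-2 * params$mu * h))
  r <- 1 / (1 + params$c)
  hold <- h == 0
  p[hold] <- (s_current * r + (1 - s_current) * (1 - r))[hold]
  p
}

# Matrix of P(node i ON at t+1) for a batch of states (columns).
# Fixed nodes switch on with probability equal to their fixed value.
on_probability_matrix <- function(S, spec, params) {
  H <- spec$W %*% S + spec$b
  P <- node_on_probability(H, S, params)
  fx <- which(!is.na(spec$fixed))
  if (length(fx)) P[fx, ] <- spec$fixed[fx]
  P
}

#' Transition probability between two states
#'
#' Synchronous noisy updating makes nodes conditionally independent given
#' the current state, so `T(s'|s)` is the product over nodes of the per-node
#' probabilities from [node_on_probability()]. A fixed node contributes
#' factor 1 when `s'` matches its fixed value and 0 otherwise. Rows of `T`
#' are stochastic: the probabilities over all `2^N` successors sum to 1.
#'
#' @param s,s_next 0/1 state vectors of equal length.
#' @param spec a [network_spec()].
#' @param params a [noise_params()].
#' @return the probability `T(s_next | s)`.
#' @export
transition_probability <- function(s, s_next, spec, params) {
  p_on <- on_probability_matrix(as_state_matrix(s, spec), spec, params)[, 1L]
  s_next <- as_state_matrix(s_next, spec)[, 1L]
  prod(ifelse(s_next == 1, p_on, 1 - p_on))
}

#' Full transition matrix over the state space
#'
#' Dense `2^N x 2^N` matrix with `T[to + 1, from + 1] = T(to | from)` (codes
#' as in [state_code()]). Only feasible for small networks; guarded by the
#' probabilistic-analysis capacity limit.
#'
#' @inheritParams transition_probability
#' @param limit capacity limit (number of nodes).
#' @return column-stochastic transition matrix.
#' @export
transition_matrix <- function(spec, params, limit = PA_EXHAUSTIVE_LIMIT) {
  n <- n_nodes(spec)
  if (n > limit) {
    stop("exhaustive probabilistic analysis of 2^", n, " states exceeds the ",
         "capacity limit (", limit, " nodes); use heuristic_steady_state()",
         call. = FALSE)
  }
  S <- decode_state(enumerate_states(n, limit = limit), n)  # n x M
  P <- on_probability_matrix(S, spec, params)               # n x M
  B <- t(S)                                                 # M x n bits of 'to'
  # log T = B %*% log P + (1 - B) %*% log(1 - P); clamp -Inf so that exp()
  # underflows to an exact 0 instead of producing 0 * Inf = NaN.
  clamp <- function(x) pmax(x, -1e6)
  logT <- B %*% clamp(log(P)) + (1 - B) %*% clamp(log1p(-P))
  exp(logT)
}

## ---- steady states ---------------------------------------------------------

new_steady_state <- function(p, n, params, method, meta) {
  structure(
    list(p = p, n_nodes = n, params = params, method = method, meta = meta),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat("Steady-state distribution (", x$method, " PA, mu = ", x$params$mu,
      ", c = ", x$params$c, ") over ", length(x$p), " states\n", sep = "")
  top <- utils::head(sort(x$p, decreasing = TRUE), 5L)
  cat("top states:\n")
  print(round(top, 5))
  invisible(x)
}

#' Steady state by master-equation iteration
#'
#' Iterates the master equation `p_{t+1}(s') = sum_s T(s'|s) p_t(s)` from
#' the uniform distribution until the L1 residual between successive
#' distributions drops below `tol` (or `max_iter` is reached, in which case
#' the result is returned with a non-convergence flag in the metadata).
#'
#' @param spec a [network_spec()].
#' @param params a [noise_params()].
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @param limit capacity limit, see [transition_matrix()].
#' @return a `steady_state` object whose `p` is a named vector indexed by
#'   state code (names `"0" ... "2^N - 1"`), normalized to sum 1, with
#'   convergence metadata (`iterations`, `residual`, `converged`).
#' @export
exhaustive_steady_state <- function(spec, params, tol = 1e-10,
                                    max_iter = 10000L,
                                    limit = PA_EXHAUSTIVE_LIMIT) {
  TT <- transition_matrix(spec, params, limit = limit)
  m <- ncol(TT)
  p <- rep(1 / m, m)
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    p2 <- as.vector(TT %*% p)
    p2 <- p2 / sum(p2)
    res <- sum(abs(p2 - p))
    p <- p2
    it <- it + 1L
    if (res < tol) break
  }
  converged <- res < tol
  if (!converged) {
    warning("master equation did not reach tol = ", tol, " after ",
            max_iter, " iterations (residual ", signif(res, 3), ")")
  }
  names(p) <- as.character(seq(0, m - 1))
  new_steady_state(p, n_nodes(spec), params, "exhaustive",
                   list(iterations = it, residual = res,
                        converged = converged, tol = tol))
}

#' Steady state by stochastic trajectory sampling
#'
#' Simulates `n_traj` noisy trajectories from uniformly random initial
#' states and estimates the steady-state distribution from all post-burn-in
#' state visits. Works on networks of any size (memory scales with the
#' number of distinct visited states, not `2^N`).
#'
#' @inheritParams exhaustive_steady_state
#' @param n_traj number of trajectories.
#' @param burn_in discarded initial steps per trajectory.
#' @param steps recorded steps per trajectory.
#' @param seed integer seed; identical seeds give identical estimates.
#' @return a `steady_state` object; `p` is named by state code for networks
#'   of at most 53 nodes and by the 0/1 state key otherwise.
#' @export
heuristic_steady_state <- function(spec, params, n_traj = 1000L,
                                   burn_in = 50L, steps = 200L, seed = NULL) {
  stopifnot(n_traj >= 1L, steps >= 1L)
  n <- n_nodes(spec)
  counts <- with_local_seed(seed, {
    S <- matrix(sample(c(0, 1), n * n_traj, replace = TRUE), nrow = n)
    S <- apply_fixed(S, spec)
    acc <- new.env(hash = TRUE, parent = emptyenv())
    for (t in seq_len(burn_in + steps)) {
      P <- on_probability_matrix(S, spec, params)
      S <- (matrix(stats::runif(n * n_traj), nrow = n) < P) * 1
      if (t > burn_in) {
        for (key in state_key(S)) {
          acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + 1
        }
      }
    }
    acc
  })
  keys <- ls(counts)
  cnt <- vapply(keys, function(k) counts[[k]], numeric(1L))
  p <- cnt / sum(cnt)
  if (n <= 53) {
    names(p) <- as.character(state_code(vapply(keys, function(k)
      as.numeric(strsplit(k, "")[[1L]]), numeric(n))))
    p <- p[order(as.numeric(names(p)))]
  } else {
    names(p) <- keys
    p <- p[order(names(p))]
  }
  new_steady_state(p, n, params, "heuristic",
                   list(n_traj = n_traj, burn_in = burn_in, steps = steps,
                        seed = seed))
}

#' Greedy most-probable path
#'
#' From `start`, repeatedly moves to the successor state with the highest
#' transition probability. Under synchronous noisy updating the argmax
#' successor is obtained per node: take the more probable next value of each
#' node independently; exact per-node ties (probability 1/2) are resolved
#' toward state 0, which makes the overall tie-break "lowest state code".
#' The path stops at the first revisited state or after `max_len` states.
#'
#' @param start 0/1 state vector.
#' @param spec a [network_spec()].
#' @param params a [noise_params()].
#' @param max_len maximum path length.
#' @return 0/1 matrix, one state per column, starting at `start`.
#' @export
most_probable_path <- function(start, spec, params, max_len = 2^16) {
  s <- as_state_matrix(start, spec)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  path <- list()
  while (length(path) < max_len) {
    key <- state_key(s)
    if (!is.null(seen[[key]])) break
    path[[length(path) + 1L]] <- s
    seen[[key]] <- TRUE
    P <- on_probability_matrix(s, spec, params)
    s <- (P > 0.5) * 1
    storage.mode(s) <- "double"
  }
  out <- do.call(cbind, path)
  rownames(out) <- spec$nodes
  out
}

#' Export a steady-state distribution
#'
#' Writes `state_code,probability,potential` as CSV plus a JSON metadata
#' sidecar (`<path>.meta.json`) recording the noise parameters, method and
#' convergence/sampling metadata.
#'
#' @param ssd a `steady_state`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_steady_state <- function(ssd, path) {
  d <- data.frame(state_code = names(ssd$p), probability = as.numeric(ssd$p),
                  potential = potential(as.numeric(ssd$p)),
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  meta <- c(list(mu = ssd$params$mu, c = ssd$params$c, method = ssd$method),
            ssd$meta)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
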