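## Potential-energy landscapes: U = -ln p over the steady-state
## distribution, projected to 2-D by Sammon mapping (distance-preserving,
## O(n^2)) or a naive probability-sorted grid (scalable, no distance
## preservation).

#' Potential energy of a state
#'
#' `U = -ln(p)`, the (dimensionless) Waddington-style potential: high
#' probability = deep well. States with `p == 0` get `zero_cap`, which
#' defaults to the potential of the smallest positive probability plus 1.
#'
#' @param p probabilities in `[0, 1]` (vectorized).
#' @param zero_cap potential assigned to zero-probability states.
#' @return numeric potential(s); strictly decreasing in `p` on the support.
#' @export
potential <- function(p, zero_cap = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities must be in [0, 1]")
  u <- -log(p)
  if (any(z <- p == 0, na.rm = TRUE)) {
    if (is.null(zero_cap)) {
      pos <- p[p > 0]
      if (!length(pos)) stop("no positive probabilities to derive a cap from")
      zero_cap <- -log(min(pos)) + 1
    }
    u[z] <- zero_cap
  }
  u
}

#' Sammon projection of binary states
#'
#' Projects states into the plane by minimizing the Sammon stress
#' `E = (1 / sum delta_ij) * sum (delta_ij - d_ij)^2 / delta_ij`, where
#' `delta` is the pairwise Hamming distance between state bit-vectors and
#' `d` the output Euclidean distance. Optimization runs from a seeded
#' random-uniform initialization in `[0, 1]^2` (step factor 0.3; iteration
#' cap and stopping tolerance configurable).
#'
#' @param states 0/1 matrix, one state per column; states must be distinct.
#' @param iterations maximum iterations.
#' @param seed seed for the random initialization.
#' @param tol relative stress-change stopping tolerance.
#' @param magic Sammon step ("magic") factor.
#' @return list with `points` (n x 2 coordinates), `stress` (final Sammon
#'   stress) and `stress0` (stress of the initialization).
#' @export
sammon_project <- function(states, iterations = 500L, seed = NULL,
                           tol = 1e-9, magic = 0.3) {
  S <- as.matrix(states)
  n <- ncol(S)
  if (n < 2L) stop("Sammon projection needs at least 2 states")
  if (anyDuplicated(state_key(S))) {
    stop("states must be distinct (zero Hamming distances are degenerate)")
  }
  D <- stats::dist(t(S), method = "manhattan")  # Hamming on 0/1 vectors
  if (all(D == 0)) stop("all states identical; nothing to project")
  init <- with_local_seed(seed, matrix(stats::runif(2L * n), ncol = 2L))
  stress0 <- sammon_stress(D, init)
  if (n == 2L) {
    # exact embedding: place the pair at their input distance
    pts <- rbind(c(0, 0), c(as.numeric(D), 0))
    return(list(points = pts, stress = 0, stress0 = stress0))
  }
  fit <- MASS::sammon(D, y = init, k = 2L, niter = iterations, tol = tol,
                      magic = magic, trace = FALSE)
  list(points = fit$points, stress = sammon_stress(D, fit$points),
       stress0 = stress0)
}

#' @rdname sammon_project
#' @param d a `dist` of input distances.
#' @param y candidate coordinates (n x 2).
#' @export
sammon_stress <- function(d, y) {
  dd <- as.numeric(d)
  e <- as.numeric(stats::dist(y))
  sum((dd - e)^2 / dd) / sum(dd)
}

#' Naive grid projection
#'
#' Deterministic scalable layout: states are sorted by descending
#' probability (ties by ascending state order) and placed row-major on a
#' `ceiling(sqrt(n))`-column grid, the most probable state at `(0, 0)`.
#' Distances are not preserved; the layout exists so that large state
#' spaces can still be rendered. The map is a bijection onto grid cells and
#' independent of input order.
#'
#' @param p probability vector.
#' @param order_key secondary sort key for ties (default: input position;
#'   pass state codes to make the layout permutation-invariant).
#' @return integer matrix `n x 2` of `(x, y)` grid coordinates, one row per
#'   input state (in input order).
#' @export
naive_project <- function(p, order_key = seq_along(p)) {
  n <- length(p)
  stopifnot(n >= 1L)
  ncols <- ceiling(sqrt(n))
  rank <- order(order(-p, order_key))  # rank of each input point
  cbind(x = (rank - 1L) %% ncols, y = (rank - 1L) %/% ncols)
}

#' Build landscape points from a steady-state distribution
#'
#' Selects the `top_k` most probable states, computes potentials, and
#' attaches 2-D coordinates from the requested projection. Sammon mapping
#' cost grows quadratically in the number of states, hence the default
#' truncation to the 500 most probable states; the naive grid has no such
#' limit.
#'
#' @param ssd a `steady_state` (see [exhaustive_steady_state()]).
#' @param method `"naive"` or `"sammon"`.
#' @param top_k number of most-probable states to retain (`Inf` for all).
#' @param ... passed to [sammon_project()].
#' @return a `landscape_points` data frame: `state_code`, `probability`,
#'   `potential`, `x`, `y`.
#' @export
landscape_points <- function(ssd, method = c("naive", "sammon"),
                             top_k = 500L, ...) {
  method <- match.arg(method)
  stopifnot(inherits(ssd, "steady_state"))
  p <- ssd$p
  if (is.finite(top_k) && length(p) > top_k) {
    keep <- order(-p)[seq_len(top_k)]
    p <- p[sort(keep)]
  }
  codes <- names(p)
  if (method == "naive") {
    xy <- naive_project(as.numeric(p), order_key = codes)
  } else {
    if (ssd$n_nodes > 53) {
      S <- vapply(codes, function(k) as.numeric(strsplit(k, "")[[1L]]),
                  numeric(ssd$n_nodes))
    } else {
      S <- decode_state(as.numeric(codes), ssd$n_nodes)
    }
    xy <- sammon_project(S, ...)$points
  }
  out <- data.frame(state_code = codes, probability = as.numeric(p),
                    potential = potential(as.numeric(p)),
                    x = xy[, 1L], y = xy[, 2L], stringsAsFactors = FALSE)
  class(out) <- c("landscape_points", "data.frame")
  out
}

#' Export landscape points to CSV
#'
#' Writes `state_code,probability,potential,x,y`; [read_landscape()] reads
#' the file back into an identical `landscape_points` object.
#'
#' @param points a `landscape_points` data frame.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
export_landscape <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_landscape
#' @export
read_landscape <- function(path) {
  out <- utils::read.csv(path, colClasses = c(state_code = "character"))
  class(out) <- c("landscape_points", "data.frame")
  out
}
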