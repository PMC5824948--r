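#' Construct a Boolean network specification
#'
#' The canonical in-memory network model. A network has `N` named nodes, an
#' `N x N` weight matrix `W` with `W[i, j]` the weight of the edge from node
#' `j` to node `i` (so the net input of every node in state `s` is the single
#' matrix-vector product `W %*% s + b`), a basal-value vector `b`, an optional
#' set of compiled per-node Boolean update rules, and a fixed-node mask.
#'
#' Two synchronous update semantics operate on a spec: the weighted-sum
#' threshold rule ([weighted_step()]) and per-node Boolean logic
#' ([rules_step()]). Fixed nodes (mask value `0` or `1`) keep their fixed
#' value under every update, overriding both semantics.
#'
#' @param nodes character vector of unique, non-empty node names.
#' @param W numeric `N x N` matrix, `W[i, j]` = weight of edge `j -> i`.
#'   Defaults to the zero matrix.
#' @param b numeric length-`N` basal values; default all zero.
#' @param rules optional compiled rules, as returned by [parse_rules()].
#' @param fixed integer length-`N` mask: `NA` = free, `0`/`1` = fixed value.
#' @param init optional length-`N` 0/1 vector of initial node states.
#' @return an object of class `network_spec`.
#' @seealso [parse_network()], [apply_perturbations()], [weighted_step()]
#' @export
network_spec <- function(nodes, W = NULL, b = NULL, rules = NULL,
                         fixed = NULL, init = NULL) {
  nodes <- as.character(nodes)
  n <- length(nodes)
  if (n < 1L) stop("network must have at least one node")
  if (anyDuplicated(nodes)) {
    stop("duplicate node name: ", nodes[duplicated(nodes)][1L])
  }
  if (any(!nzchar(nodes))) stop("node names must be non-empty")
  if (is.null(W)) W <- matrix(0, n, n)
  W <- as.matrix(W)
  if (!all(dim(W) == c(n, n))) stop("W must be ", n, " x ", n)
  if (any(!is.finite(W))) stop("W must be finite")
  if (is.null(b)) b <- numeric(n)
  if (length(b) != n || any(!is.finite(b))) {
    stop("b must be a finite length-", n, " vector")
  }
  if (is.null(fixed)) fixed <- rep(NA_integer_, n)
  fixed <- as.integer(fixed)
  if (length(fixed) != n || any(!is.na(fixed) & !(fixed %in% c(0L, 1L)))) {
    stop("fixed mask entries must be NA, 0 or 1")
  }
  if (is.null(init)) init <- integer(n)
  init <- as.integer(init)
  if (length(init) != n || !all(init %in% c(0L, 1L))) {
    stop("init must be a length-", n, " 0/1 vector")
  }
  dimnames(W) <- list(nodes, nodes)
  names(b) <- names(fixed) <- names(init) <- nodes
  structure(
    list(nodes = nodes, W = W, b = b, rules = rules, fixed = fixed,
         init = init),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  n_edge <- sum(x$W != 0)
  cat("Boolean network:", length(x$nodes), "nodes,", n_edge, "weighted edges")
  if (!is.null(x$rules)) cat(",", sum(!vapply(x$rules, is.null, TRUE)),
                             "update rules")
  n_fix <- sum(!is.na(x$fixed))
  if (n_fix) cat(",", n_fix, "fixed nodes")
  cat("\n")
  invisible(x)
}

n_nodes <- function(spec) length(spec$nodes)

node_index <- function(spec, name) {
  i <- match(name, spec$nodes)
  if (anyNA(i)) stop("unknown node: ", paste(name[is.na(i)], collapse = ", "))
  i
}

## ---- state encoding --------------------------------------------------------

#' Encode and decode network states
#'
#' A network state is a length-`N` vector of 0/1 node activities. States are
#' canonically encoded as integers with node 1 as the least-significant bit,
#' so codes range over `[0, 2^N)`. Integer codes are exact only for
#' `N <= 53` (double precision); for larger networks use [state_key()].
#'
#' @param bits 0/1 vector, or a matrix with one state per column.
#' @param code numeric state code(s).
#' @param n_nodes number of nodes.
#' @return `state_code()` returns numeric code(s); `decode_state()` returns a
#'   0/1 matrix with `n_nodes` rows and one column per code; `state_key()`
#'   returns a character key usable for any `N`.
#' @examples
#' state_code(c(1, 0, 1))    # 5
#' decode_state(5, 3)
#' @export
state_code <- function(bits) {
  bits <- as.matrix(bits)
  n <- nrow(bits)
  if (n > 53) stop("integer state codes require <= 53 nodes; use state_key()")
  as.vector(2^(seq_len(n) - 1) %*% bits)
}

#' @rdname state_code
#' @export
decode_state <- function(code, n_nodes) {
  m <- vapply(seq_len(n_nodes),
              function(i) floor(code / 2^(i - 1)) %% 2,
              numeric(length(code)))
  if (length(code) == 1L) matrix(m, ncol = 1L) else t(m)
}

#' @rdname state_code
#' @export
state_key <- function(bits) {
  bits <- as.matrix(bits)
  do.call(paste0, lapply(seq_len(nrow(bits)), function(i) bits[i, ]))
}

as_state_matrix <- function(state, spec) {
  s <- as.matrix(state)
  if (nrow(s) != n_nodes(spec)) {
    stop("state has ", nrow(s), " entries; network has ", n_nodes(spec),
         " nodes")
  }
  if (!all(s %in% c(0, 1))) stop("state entries must be 0 or 1")
  storage.mode(s) <- "double"
  s
}

## ---- update semantics ------------------------------------------------------

#' Net regulatory input of a node
#'
#' `h_i = sum_j W[i, j] * s_j + b[i]`: the weighted sum of the states of the
#' regulators of node `i` plus its basal value.
#'
#' @param state 0/1 state vector.
#' @param i node index or name.
#' @param spec a [network_spec()].
#' @return the numeric net input `h_i`.
#' @export
net_input <- function(state, i, spec) {
  if (is.character(i)) i <- node_index(spec, i)
  s <- as_state_matrix(state, spec)
  unname(drop(spec$W[i, , drop = FALSE] %*% s)) + spec$b[[i]]
}

# Synchronous weighted-threshold update of a batch of states (columns).
# s_i(t+1) = 1 if h_i > 0, 0 if h_i < 0, s_i(t) if h_i == 0.
weighted_step_matrix <- function(S, spec) {
  H <- spec$W %*% S + spec$b
  S2 <- (H > 0) + (H == 0) * S
  storage.mode(S2) <- "double"
  apply_fixed(S2, spec)
}

apply_fixed <- function(S, spec) {
  fx <- which(!is.na(spec$fixed))
  if (length(fx)) S[fx, ] <- spec$fixed[fx]
  S
}

#' Synchronous state updates
#'
#' `weighted_step()` applies the weighted-sum threshold rule: every free node
#' `i` takes state 1 if its net input `h_i > 0`, state 0 if `h_i < 0`, and
#' holds its current state when `h_i == 0`. `rules_step()` instead evaluates
#' every node's Boolean update rule on the current state. Both are
#' synchronous (all nodes update together) and total: every state has exactly
#' one successor. Fixed nodes keep their fixed value in either mode.
#' `step_state()` dispatches on `mode`.
#'
#' @param state 0/1 vector, or matrix of states (one per column).
#' @param spec a [network_spec()]; `rules_step()` requires `spec$rules`.
#' @param mode `"weighted"` or `"rules"`.
#' @return the successor state(s), same shape as `state`.
#' @examples
#' spec <- network_spec(c("A", "B"), W = rbind(c(0, 0), c(1, 0)))
#' weighted_step(c(1, 0), spec)  # B switches on
#' @export
weighted_step <- function(state, spec) {
  s <- as_state_matrix(state, spec)
  out <- weighted_step_matrix(s, spec)
  if (is.matrix(state)) out else unname(drop(out))
}

#' @rdname weighted_step
#' @export
rules_step <- function(state, spec) {
  if (is.null(spec$rules)) stop("network has no update rules; use weighted_step()")
  s <- as_state_matrix(state, spec)
  out <- rules_step_matrix(s, spec)
  if (is.matrix(state)) out else unname(drop(out))
}

# Batch rules evaluation: each compiled rule is evaluated once against the
# whole batch, with node names bound to logical row-vectors.
rules_step_matrix <- function(S, spec) {
  nodes <- spec$nodes
  env <- new.env(parent = baseenv())
  for (i in seq_along(nodes)) assign(nodes[i], S[i, ] > 0, envir = env)
  out <- S
  for (i in seq_along(nodes)) {
    r <- spec$rules[[nodes[i]]]
    if (is.null(r) || r$type == "identity") next
    if (r$type == "expr") {
      out[i, ] <- as.numeric(eval(r$expr, env))
    } else { # truth table
      idx <- 1
      for (k in seq_along(r$inputs)) {
        idx <- idx + S[node_index(spec, r$inputs[k]), ] * 2^(k - 1)
      }
      out[i, ] <- r$table[idx]
    }
  }
  apply_fixed(out, spec)
}

#' @rdname weighted_step
#' @export
step_state <- function(state, spec, mode = c("weighted", "rules")) {
  mode <- match.arg(mode)
  if (mode == "weighted") weighted_step(state, spec) else rules_step(state, spec)
}

step_matrix_fun <- function(spec, mode) {
  if (mode == "weighted") {
    function(S) weighted_step_matrix(S, spec)
  } else {
    if (is.null(spec$rules)) stop("mode 'rules' requires spec$rules")
    function(S) rules_step_matrix(S, spec)
  }
}

## ---- perturbations ---------------------------------------------------------

#' Apply a perturbation set to a network
#'
#' Perturbations model mutations and drug action as network edits: fixing a
#' node's state (sustained activation/knock-out), changing a basal value,
#' deleting an edge, or re-weighting an edge. Directives are applied in file
#' order, so a later directive on the same target overrides an earlier one;
#' application is idempotent. The input spec is not modified.
#'
#' In rules mode a fixed node overrides its update rule's output.
#'
#' @param spec a [network_spec()].
#' @param perts a `perturbation_set` from [parse_perturbations()] or
#'   [perturbation_set()].
#' @return a new, edited `network_spec`.
#' @export
apply_perturbations <- function(spec, perts) {
  stopifnot(inherits(spec, "network_spec"))
  perts <- as_perturbation_set(perts)
  for (k in seq_len(nrow(perts))) {
    p <- perts[k, ]
    switch(p$op,
      fix = {
        i <- node_index(spec, p$node)
        spec$fixed[i] <- as.integer(p$value)
      },
      basal = {
        i <- node_index(spec, p$node)
        spec$b[i] <- p$value
      },
      delete_edge = {
        j <- node_index(spec, p$src)
        i <- node_index(spec, p$dst)
        spec$W[i, j] <- 0
      },
      set_weight = {
        j <- node_index(spec, p$src)
        i <- node_index(spec, p$dst)
        spec$W[i, j] <- p$value
      },
      stop("unknown perturbation op: ", p$op)
    )
  }
  spec
}

#' Build a perturbation set programmatically
#'
#' @param op character vector of directives: `"fix"`, `"basal"`,
#'   `"delete_edge"`, `"set_weight"`.
#' @param node target node for `fix`/`basal` (NA otherwise).
#' @param src,dst edge endpoints for `delete_edge`/`set_weight`.
#' @param value fixed state, basal value or weight (NA for `delete_edge`).
#' @return a `perturbation_set` data frame.
#' @export
perturbation_set <- function(op = character(), node = NA_character_,
                             src = NA_character_, dst = NA_character_,
                             value = NA_real_) {
  n <- length(op)
  d <- data.frame(op = as.character(op),
                  node = rep_len(as.character(node), n),
                  src = rep_len(as.character(src), n),
                  dst = rep_len(as.character(dst), n),
                  value = rep_len(as.numeric(value), n),
                  stringsAsFactors = FALSE)
  class(d) <- c("perturbation_set", "data.frame")
  d
}

as_perturbation_set <- function(x) {
  if (!inherits(x, "perturbation_set")) {
    stop("expected a perturbation_set (see parse_perturbations())")
  }
  x
}
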