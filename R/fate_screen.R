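## Mapping attractors and steady states to cell-fate labels, and running
## perturbation screens over those fates.

#' Cell-fate classification rules
#'
#' An ordered list of `(label, predicate)` pairs; predicates are Boolean
#' expressions over node names (operators AND, OR, NOT, parentheses). The
#' first rule whose predicate holds classifies the attractor, so rule order
#' expresses precedence (e.g. a compound fate such as "tumor progression =
#' abnormal proliferation AND metastasis" must be listed before its
#' components). For cyclic attractors the `policy` decides how states of the
#' cycle aggregate: `"any"` (a marker active anywhere in the cycle counts,
#' the default), `"all"`, or `"majority"`. Unmatched attractors receive the
#' `fallback` label.
#'
#' @param labels character vector of fate labels.
#' @param predicates character vector of Boolean expressions.
#' @param policy `"any"`, `"all"` or `"majority"`.
#' @param fallback label for attractors matching no rule.
#' @return a `fate_rules` object.
#' @export
fate_rules <- function(labels, predicates,
                       policy = c("any", "all", "majority"),
                       fallback = "unclassified") {
  policy <- match.arg(policy)
  stopifnot(length(labels) == length(predicates), all(nzchar(labels)))
  rules <- lapply(seq_along(labels), function(i) {
    list(label = labels[i],
         pred = compile_bool_expr(predicates[i],
                                  paste0("fate rule '", labels[i], "'")))
  })
  structure(list(rules = rules, policy = policy, fallback = fallback),
            class = "fate_rules")
}

#' Parse a fate-logic file
#'
#' Ordered lines `FATE <label>: <boolean expression over node names>`.
#'
#' @param text character lines, or one string with newlines.
#' @param path path to a fate-logic file.
#' @inheritParams fate_rules
#' @return a [fate_rules()] object.
#' @export
parse_fate_rules <- function(text, policy = "any", fallback = "unclassified") {
  lines <- strip_comments(as_lines(text))
  labels <- character(0); preds <- character(0)
  for (ln in which(nzchar(lines))) {
    m <- regmatches(lines[ln],
                    regexec("^FATE\\s+([^:]+):\\s*(.+)$", lines[ln],
                            ignore.case = TRUE))[[1L]]
    if (length(m) != 3L) {
      stop("fate-logic file, line ", ln, ": expected 'FATE <label>: <expr>'",
           call. = FALSE)
    }
    labels <- c(labels, trimws(m[2])); preds <- c(preds, m[3])
  }
  fate_rules(labels, preds, policy = policy, fallback = fallback)
}

#' @rdname parse_fate_rules
#' @export
read_fate_rules <- function(path, policy = "any", fallback = "unclassified") {
  if (!file.exists(path)) stop("fate-logic file not found: ", path, call. = FALSE)
  parse_fate_rules(readLines(path, warn = FALSE), policy = policy,
                   fallback = fallback)
}

check_fate_nodes <- function(rules, nodes) {
  for (r in rules$rules) {
    bad <- setdiff(r$pred$inputs, nodes)
    if (length(bad)) {
      stop("fate rule '", r$label, "' references unknown node(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
}

# Evaluate one predicate on a batch of states: logical vector per column.
eval_pred <- function(pred, S, nodes) {
  env <- new.env(parent = baseenv())
  for (i in seq_along(nodes)) assign(nodes[i], S[i, ] > 0, envir = env)
  as.logical(eval(pred$expr, env))
}

#' Classify an attractor into a fate
#'
#' Applies the ordered fate rules to the attractor's cycle states under the
#' aggregation policy; the first matching rule wins, otherwise the fallback
#' label is returned.
#'
#' @param a an `attractor` (from [deterministic_analysis()] or
#'   [find_attractor()]).
#' @param rules a [fate_rules()].
#' @param nodes node names of the network the attractor came from; defaults
#'   to the attractor's own state rownames.
#' @return the fate label (character scalar).
#' @export
classify_attractor <- function(a, rules, nodes = rownames(a$states)) {
  stopifnot(inherits(rules, "fate_rules"))
  if (is.null(nodes)) stop("node names are required to classify an attractor")
  check_fate_nodes(rules, nodes)
  for (r in rules$rules) {
    hit <- eval_pred(r$pred, a$states, nodes)
    ok <- switch(rules$policy,
                 any = any(hit),
                 all = all(hit),
                 majority = mean(hit) > 0.5)
    if (ok) return(r$label)
  }
  rules$fallback
}

#' Classify every attractor of an analysis at once
#'
#' Batched equivalent of calling [classify_attractor()] on each attractor:
#' all cycle states are pooled into one matrix and every predicate is
#' evaluated once, which matters for large sampled analyses with thousands
#' of attractors.
#'
#' @param result a `da_result`.
#' @param rules a [fate_rules()].
#' @return character vector of labels, one per attractor.
#' @export
classify_attractors <- function(result, rules) {
  stopifnot(inherits(result, "da_result"), inherits(rules, "fate_rules"))
  check_fate_nodes(rules, result$nodes)
  a <- result$attractors
  if (!length(a)) return(character(0))
  lens <- vapply(a, `[[`, 0L, "length")
  S <- do.call(cbind, lapply(a, `[[`, "states"))
  grp <- rep(seq_along(a), lens)
  labels <- rep(rules$fallback, length(a))
  unset <- rep(TRUE, length(a))
  for (r in rules$rules) {
    hit <- eval_pred(r$pred, S, result$nodes)
    ok <- switch(rules$policy,
                 any = tapply(hit, grp, any),
                 all = tapply(hit, grp, all),
                 majority = tapply(hit, grp, mean) > 0.5)
    take <- unset & as.logical(ok)
    labels[take] <- r$label
    unset[take] <- FALSE
  }
  labels
}

#' Aggregate fates into a fate landscape
#'
#' From a deterministic-analysis result, the propensity of a fate is the
#' total basin fraction of the attractors classified into it (propensities
#' sum to 1). From a steady-state distribution, it is the total probability
#' of the states matching the fate's predicate (first matching rule per
#' state; networks above 53 nodes classify by state key).
#'
#' @param x a `da_result` or `steady_state`.
#' @param rules a [fate_rules()].
#' @param nodes node names; required for a `steady_state`, taken from the
#'   result otherwise.
#' @return a `fate_landscape` data frame (`fate`, `propensity`) with an
#'   `attractors` attribute mapping fates to contributing attractor ids
#'   (deterministic input only).
#' @export
fate_landscape <- function(x, rules, nodes = NULL) {
  stopifnot(inherits(rules, "fate_rules"))
  labels <- unique(c(vapply(rules$rules, `[[`, "", "label"), rules$fallback))
  prop <- stats::setNames(numeric(length(labels)), labels)
  contrib <- stats::setNames(vector("list", length(labels)), labels)
  if (inherits(x, "da_result")) {
    labs <- classify_attractors(x, rules)
    bf <- vapply(x$attractors, `[[`, 0, "basin_fraction")
    for (lab in labels) {
      prop[lab] <- sum(bf[labs == lab])
      contrib[[lab]] <- which(labs == lab)
    }
  } else if (inherits(x, "steady_state")) {
    if (is.null(nodes)) stop("fate_landscape() needs 'nodes' for a steady_state")
    check_fate_nodes(rules, nodes)
    S <- if (x$n_nodes <= 53) {
      decode_state(as.numeric(names(x$p)), x$n_nodes)
    } else {
      vapply(names(x$p), function(k) as.numeric(strsplit(k, "")[[1L]]),
             numeric(x$n_nodes))
    }
    assigned <- rep(FALSE, length(x$p))
    for (r in rules$rules) {
      hit <- eval_pred(r$pred, S, nodes) & !assigned
      prop[r$label] <- prop[r$label] + sum(x$p[hit])
      assigned <- assigned | hit
    }
    prop[rules$fallback] <- sum(x$p[!assigned])
  } else {
    stop("x must be a da_result or steady_state")
  }
  out <- data.frame(fate = labels, propensity = as.numeric(prop),
                    stringsAsFactors = FALSE)
  attr(out, "attractors") <- contrib
  class(out) <- c("fate_landscape", "data.frame")
  out
}

#' Apoptosis (or any fate-group) rate as a percentage
#'
#' `100 * sum(propensity)` over the given labels -- e.g. the predicted rate
#' of cell death as the combined basin share of death attractors.
#'
#' @param landscape a `fate_landscape`.
#' @param death_labels labels to sum; must exist in the landscape.
#' @return percentage in `[0, 100]`.
#' @export
apoptosis_rate <- function(landscape, death_labels) {
  missing <- setdiff(death_labels, landscape$fate)
  if (length(missing)) {
    stop("unknown fate label(s): ", paste(missing, collapse = ", "))
  }
  100 * sum(landscape$propensity[landscape$fate %in% death_labels])
}

#' Perturbation screen over cell fates
#'
#' Runs the configured deterministic analysis on the unperturbed network
#' (the control) and on each perturbed arm, classifies fates, and reports
#' absolute and control-relative propensities. When the state space is
#' sampled, the identical sampled initial-state set is reused across all
#' arms so that sampling noise cancels from the relative values. A fate with
#' zero control propensity gets `NA` (undefined) relative values. An arm
#' that fails (e.g. a perturbation naming an unknown node) is recorded with
#' `NA` propensities and its error message; remaining arms still run.
#'
#' @param spec a [network_spec()] (the control network).
#' @param perturbations named list of `perturbation_set`s, one per arm.
#' @param rules a [fate_rules()].
#' @param space `"exhaustive"` or `"sample"`.
#' @param mode `"weighted"` or `"rules"`.
#' @param k,seed sampling configuration (see [deterministic_analysis()]).
#' @param limit exhaustive capacity limit.
#' @return a `screen_result` data frame with columns `arm`, `fate`,
#'   `propensity`, `relative_to_control` and `error`.
#' @export
screen_perturbations <- function(spec, perturbations, rules,
                                 space = c("exhaustive", "sample"),
                                 mode = c("weighted", "rules"),
                                 k = NULL, seed = NULL,
                                 limit = EXHAUSTIVE_LIMIT) {
  space <- match.arg(space)
  mode <- match.arg(mode)
  if (is.null(names(perturbations)) || any(!nzchar(names(perturbations)))) {
    stop("'perturbations' must be a named list of perturbation sets")
  }
  states <- if (space == "sample") {
    if (is.null(k) || is.null(seed)) stop("sampled screens need k and seed")
    sample_states(n_nodes(spec), k, seed = seed)
  } else {
    decode_state(enumerate_states(n_nodes(spec), limit), n_nodes(spec))
  }
  arm_landscape <- function(s) {
    fate_landscape(deterministic_analysis(s, states = states, mode = mode),
                   rules)
  }
  control <- arm_landscape(spec)
  rows <- data.frame(arm = "control", fate = control$fate,
                     propensity = control$propensity,
                     relative_to_control = ifelse(control$propensity > 0, 1, NA),
                     error = NA_character_, stringsAsFactors = FALSE)
  for (arm in names(perturbations)) {
    fl <- tryCatch(arm_landscape(apply_perturbations(spec, perturbations[[arm]])),
                   error = function(e) conditionMessage(e))
    if (is.character(fl)) {
      rows <- rbind(rows, data.frame(
        arm = arm, fate = control$fate, propensity = NA_real_,
        relative_to_control = NA_real_, error = fl, stringsAsFactors = FALSE))
    } else {
      rel <- ifelse(control$propensity > 0,
                    fl$propensity / control$propensity, NA_real_)
      rows <- rbind(rows, data.frame(
        arm = arm, fate = fl$fate, propensity = fl$propensity,
        relative_to_control = rel, error = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  class(rows) <- c("screen_result", "data.frame")
  rows
}

#' @rdname screen_perturbations
#' @param result a `screen_result`.
#' @param path output CSV path.
#' @export
export_screen <- function(result, path) {
  utils::write.csv(result[, c("arm", "fate", "propensity",
                              "relative_to_control")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
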