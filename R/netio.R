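## File formats.
##
## Network files (CSV or whitespace-delimited flat text) have two sections,
## each introduced by a header line:
##   node,initial_state,basal_value
##   <name>,<0|1|empty>,<real|empty>
##   source,target,weight,type
##   <name>,<name>,<real>,<activation|inhibition|empty>
## '#' starts a comment; unset initial states and basal values default to 0.
##
## Rules files: one `TARGET = <expr>` per line (operators AND, OR, NOT,
## parentheses) or `TABLE TARGET: in1,in2 / 00->0 / 01->1 / ...`.
##
## Perturbation files: `FIX <node> <0|1>`, `BASAL <node> <real>`,
## `DELETE_EDGE <src> <dst>`, `SET_WEIGHT <src> <dst> <real>`.
##
## Fate-logic files: ordered `FATE <label>: <expr>` lines.

as_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  text
}

strip_comments <- function(lines) {
  lines <- sub("#.*$", "", lines)
  trimws(lines)
}

split_fields <- function(line, dialect) {
  if (dialect == "csv") {
    trimws(strsplit(line, ",", fixed = TRUE)[[1L]])
  } else {
    strsplit(trimws(line), "[ \t]+")[[1L]]
  }
}

fmt_error <- function(lineno, msg) {
  stop("network file, line ", lineno, ": ", msg, call. = FALSE)
}

#' Parse a network definition file
#'
#' Reads the two-section node/edge format described under *File formats* in
#' the package vignette: a node section (`node,initial_state,basal_value`)
#' followed by an edge section (`source,target,weight[,type]`). Unset
#' initial states and basal values default to 0 ("off unless stated").
#'
#' @param text character vector of lines (or one string with newlines).
#' @param dialect `"csv"` (comma-separated) or `"flat"` (whitespace).
#' @param path path to a network file; dialect is guessed from the
#'   extension (`.csv` => csv) unless given.
#' @return `parse_network()` returns a `network_file_record` (validated node
#'   and edge tables); `read_network()` returns a [network_spec()].
#' @examples
#' rec <- parse_network(c("node,initial_state,basal_value", "A,0,0", "B,0,0",
#'                        "source,target,weight", "A,B,1"))
#' spec <- as_network_spec(rec)
#' @export
parse_network <- function(text, dialect = c("csv", "flat")) {
  dialect <- match.arg(dialect)
  raw <- as_lines(text)
  lines <- strip_comments(raw)
  keep <- which(nzchar(lines))

  nodes <- data.frame(name = character(), initial_state = integer(),
                      basal_value = numeric(), stringsAsFactors = FALSE)
  edges <- data.frame(source = character(), target = character(),
                      weight = numeric(), type = character(),
                      stringsAsFactors = FALSE)
  section <- NA_character_
  for (ln in keep) {
    f <- split_fields(lines[ln], dialect)
    low <- tolower(f)
    if (identical(low[1:2], c("node", "initial_state")) ||
        identical(low[1], "node") && length(f) <= 3L && any(low == "basal_value")) {
      section <- "node"; next
    }
    if (identical(low[1:2], c("source", "target"))) { section <- "edge"; next }
    if (is.na(section)) fmt_error(ln, "expected a section header line")
    if (section == "node") {
      if (length(f) < 1L || !nzchar(f[1])) fmt_error(ln, "missing node name")
      if (f[1] %in% nodes$name) fmt_error(ln, paste0("duplicate node name '", f[1], "'"))
      ini <- if (length(f) >= 2L && nzchar(f[2])) f[2] else "0"
      if (!ini %in% c("0", "1")) fmt_error(ln, "initial state must be 0 or 1")
      bas <- if (length(f) >= 3L && nzchar(f[3])) suppressWarnings(as.numeric(f[3])) else 0
      if (is.na(bas)) fmt_error(ln, "non-numeric basal value")
      nodes[nrow(nodes) + 1L, ] <- list(f[1], as.integer(ini), bas)
    } else {
      if (length(f) < 3L) fmt_error(ln, "edge line needs source, target, weight")
      w <- suppressWarnings(as.numeric(f[3]))
      if (is.na(w)) fmt_error(ln, paste0("non-numeric weight '", f[3], "'"))
      ty <- if (length(f) >= 4L && nzchar(f[4])) tolower(f[4]) else NA_character_
      if (!is.na(ty) && !ty %in% c("activation", "inhibition")) {
        fmt_error(ln, paste0("unknown interaction type '", f[4], "'"))
      }
      if (!is.na(ty)) {
        ok <- (ty == "activation" && w > 0) || (ty == "inhibition" && w < 0)
        if (!ok) fmt_error(ln, "interaction type disagrees with weight sign")
      }
      for (endp in f[1:2]) {
        if (!endp %in% nodes$name) {
          fmt_error(ln, paste0("edge references undeclared node '", endp, "'"))
        }
      }
      edges[nrow(edges) + 1L, ] <- list(f[1], f[2], w, ty)
    }
  }
  if (nrow(nodes) == 0L) stop("network file declares no nodes", call. = FALSE)
  structure(list(nodes = nodes, edges = edges, dialect = dialect),
            class = "network_file_record")
}

#' @rdname parse_network
#' @export
as_network_spec <- function(rec, rules = NULL) {
  stopifnot(inherits(rec, "network_file_record"))
  nn <- rec$nodes$name
  W <- matrix(0, length(nn), length(nn), dimnames = list(nn, nn))
  for (k in seq_len(nrow(rec$edges))) {
    W[rec$edges$target[k], rec$edges$source[k]] <- rec$edges$weight[k]
  }
  spec <- network_spec(nn, W = W, b = rec$nodes$basal_value,
                       init = rec$nodes$initial_state)
  if (!is.null(rules)) spec <- attach_rules(spec, rules)
  spec
}

#' @rdname parse_network
#' @export
read_network <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "flat"
  }
  as_network_spec(parse_network(readLines(path, warn = FALSE), dialect))
}

#' Serialize a network back to its file format
#'
#' Writes the node and edge sections in the CSV dialect. Round-trip stable:
#' parsing the output yields a record equal to the input.
#'
#' @param x a `network_file_record` or [network_spec()].
#' @param path optional output file; if `NULL` the lines are returned.
#' @return character vector of lines, invisibly when `path` is given.
#' @export
write_network <- function(x, path = NULL) {
  rec <- if (inherits(x, "network_spec")) spec_to_record(x) else x
  stopifnot(inherits(rec, "network_file_record"))
  nl <- sprintf("%s,%d,%s", rec$nodes$name, rec$nodes$initial_state,
                format(rec$nodes$basal_value, trim = TRUE, scientific = FALSE))
  el <- character(0)
  if (nrow(rec$edges)) {
    ty <- ifelse(is.na(rec$edges$type), "", rec$edges$type)
    el <- sprintf("%s,%s,%s,%s", rec$edges$source, rec$edges$target,
                  format(rec$edges$weight, trim = TRUE, scientific = FALSE), ty)
  }
  out <- c("node,initial_state,basal_value", nl,
           "source,target,weight,type", el)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

spec_to_record <- function(spec) {
  idx <- which(spec$W != 0, arr.ind = TRUE)
  edges <- data.frame(
    source = spec$nodes[idx[, "col"]],
    target = spec$nodes[idx[, "row"]],
    weight = spec$W[idx],
    type = ifelse(spec$W[idx] > 0, "activation", "inhibition"),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    nodes = data.frame(name = spec$nodes, initial_state = spec$init,
                       basal_value = spec$b, row.names = NULL,
                       stringsAsFactors = FALSE),
    edges = edges, dialect = "csv"
  ), class = "network_file_record")
}

#' Canonicalize node order
#'
#' Reorders the nodes of a spec into sorted-name order (permuting `W`, `b`,
#' the fixed mask and initial states accordingly), so that specs parsed from
#' permuted node sections compare equal.
#'
#' @param spec a [network_spec()].
#' @return the reordered `network_spec`.
#' @export
canonicalize_network <- function(spec) {
  o <- order(spec$nodes)
  network_spec(spec$nodes[o], W = spec$W[o, o, drop = FALSE], b = spec$b[o],
               rules = spec$rules, fixed = spec$fixed[o], init = spec$init[o])
}

## ---- Boolean rules ---------------------------------------------------------

tokenize_expr <- function(expr, where) {
  pat <- "[A-Za-z0-9_.]+|\\(|\\)"
  toks <- regmatches(expr, gregexpr(pat, expr))[[1L]]
  left <- gsub(pat, "", expr)
  left <- gsub("[ \t]", "", left)
  if (nzchar(left)) {
    stop(where, ": unexpected character(s) '", left, "' in expression",
         call. = FALSE)
  }
  toks
}

compile_bool_expr <- function(expr, where) {
  toks <- tokenize_expr(expr, where)
  if (!length(toks)) stop(where, ": empty expression", call. = FALSE)
  out <- character(length(toks))
  inputs <- character(0)
  for (k in seq_along(toks)) {
    t <- toks[k]
    out[k] <- switch(toupper(t),
      "AND" = "&", "OR" = "|", "NOT" = "!",
      "(" = "(", ")" = ")",
      "0" = "FALSE", "1" = "TRUE",
      { inputs <- c(inputs, t); paste0("`", t, "`") }
    )
  }
  code <- paste(out, collapse = " ")
  parsed <- tryCatch(str2lang(code), error = function(e) {
    stop(where, ": malformed expression near '", expr, "'", call. = FALSE)
  })
  list(type = "expr", expr = parsed, inputs = unique(inputs), text = expr)
}

#' Parse a Boolean rules file
#'
#' Each line defines one node's synchronous update rule, either as an
#' expression (`B = A AND NOT C`) or as an explicit truth table
#' (`TABLE B: A,C / 00->0 / 01->0 / 10->1 / 11->0`, first listed input =
#' first digit). Expressions are compiled to an internal truth
#' representation; nodes without a rule keep their current state (identity
#' rule), so partial rule files remain usable.
#'
#' @param text character lines, or one string with newlines.
#' @param path path to a rules file.
#' @return a named list of compiled rules (class `rule_set`).
#' @export
parse_rules <- function(text) {
  lines <- strip_comments(as_lines(text))
  rules <- list()
  for (ln in which(nzchar(lines))) {
    line <- lines[ln]
    where <- paste0("rules file, line ", ln)
    if (grepl("^TABLE\\b", line, ignore.case = TRUE)) {
      body <- sub("^TABLE\\s+", "", line, ignore.case = TRUE)
      parts <- strsplit(body, ":", fixed = TRUE)[[1L]]
      if (length(parts) < 2L) stop(where, ": expected 'TABLE target: ...'", call. = FALSE)
      target <- trimws(parts[1L])
      segs <- trimws(strsplit(paste(parts[-1L], collapse = ":"), "/", fixed = TRUE)[[1L]])
      inputs <- trimws(strsplit(segs[1L], ",", fixed = TRUE)[[1L]])
      k <- length(inputs)
      rows <- segs[-1L]
      if (length(rows) != 2^k) {
        stop(where, ": truth table for ", k, " inputs needs ", 2^k,
             " rows, got ", length(rows), call. = FALSE)
      }
      tab <- rep(NA_real_, 2^k)
      for (r in rows) {
        m <- regmatches(r, regexec("^([01]+)\\s*->\\s*([01])$", r))[[1L]]
        if (length(m) != 3L || nchar(m[2]) != k) {
          stop(where, ": malformed truth-table row '", r, "'", call. = FALSE)
        }
        bits <- as.integer(strsplit(m[2], "")[[1L]])
        idx <- 1L + sum(bits * 2^(seq_len(k) - 1L))
        if (!is.na(tab[idx])) stop(where, ": duplicate truth-table row '", r, "'", call. = FALSE)
        tab[idx] <- as.numeric(m[3])
      }
      rules[[target]] <- list(type = "table", inputs = inputs, table = tab)
    } else {
      parts <- regmatches(line, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", line))[[1L]]
      if (length(parts) != 3L) {
        stop(where, ": expected 'target = expression'", call. = FALSE)
      }
      rules[[parts[2L]]] <- compile_bool_expr(parts[3L], where)
    }
  }
  structure(rules, class = "rule_set")
}

#' @rdname parse_rules
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop("rules file not found: ", path, call. = FALSE)
  parse_rules(readLines(path, warn = FALSE))
}

#' Attach compiled rules to a network
#'
#' Validates that every name referenced by a rule (target and inputs) is a
#' declared node, then stores the rules on the spec for [rules_step()].
#' Nodes with no rule get the identity rule and are reported via a warning.
#'
#' @param spec a [network_spec()].
#' @param rules a `rule_set` from [parse_rules()].
#' @param warn_missing warn about nodes falling back to the identity rule.
#' @return the spec with `spec$rules` set.
#' @export
attach_rules <- function(spec, rules, warn_missing = TRUE) {
  stopifnot(inherits(rules, "rule_set"))
  for (target in names(rules)) {
    if (!target %in% spec$nodes) {
      stop("rule target '", target, "' is not a declared node", call. = FALSE)
    }
    bad <- setdiff(rules[[target]]$inputs, spec$nodes)
    if (length(bad)) {
      stop("rule for '", target, "' references undeclared node(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  missing <- setdiff(spec$nodes, names(rules))
  if (length(missing) && warn_missing) {
    warning(length(missing), " node(s) without a rule use the identity rule: ",
            paste(utils::head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ..." else "", call. = FALSE)
  }
  spec$rules <- rules
  spec
}

## ---- perturbation files ----------------------------------------------------

#' Parse a perturbation file
#'
#' One directive per line: `FIX <node> <0|1>`, `BASAL <node> <real>`,
#' `DELETE_EDGE <src> <dst>`, `SET_WEIGHT <src> <dst> <real>`. Directives
#' are kept in file order; a later directive on the same target overrides an
#' earlier one when applied. Targets are resolved at application time
#' ([apply_perturbations()]), not at parse time.
#'
#' @param text character lines, or one string with newlines.
#' @param path path to a perturbation file.
#' @return a `perturbation_set` (possibly empty: the identity perturbation).
#' @export
parse_perturbations <- function(text) {
  lines <- strip_comments(as_lines(text))
  out <- perturbation_set()
  for (ln in which(nzchar(lines))) {
    f <- strsplit(lines[ln], "[ \t]+")[[1L]]
    where <- paste0("perturbation file, line ", ln)
    kw <- toupper(f[1L])
    num <- function(x) {
      v <- suppressWarnings(as.numeric(x))
      if (is.na(v)) stop(where, ": non-numeric value '", x, "'", call. = FALSE)
      v
    }
    row <- switch(kw,
      FIX = {
        if (length(f) != 3L || !f[3] %in% c("0", "1")) {
          stop(where, ": expected 'FIX <node> <0|1>'", call. = FALSE)
        }
        perturbation_set("fix", node = f[2], value = num(f[3]))
      },
      BASAL = {
        if (length(f) != 3L) stop(where, ": expected 'BASAL <node> <real>'", call. = FALSE)
        perturbation_set("basal", node = f[2], value = num(f[3]))
      },
      DELETE_EDGE = {
        if (length(f) != 3L) stop(where, ": expected 'DELETE_EDGE <src> <dst>'", call. = FALSE)
        perturbation_set("delete_edge", src = f[2], dst = f[3])
      },
      SET_WEIGHT = {
        if (length(f) != 4L) stop(where, ": expected 'SET_WEIGHT <src> <dst> <real>'", call. = FALSE)
        perturbation_set("set_weight", src = f[2], dst = f[3], value = num(f[4]))
      },
      stop(where, ": unknown directive '", f[1L], "'", call. = FALSE)
    )
    out <- rbind(out, row)
  }
  class(out) <- c("perturbation_set", "data.frame")
  out
}

#' @rdname parse_perturbations
#' @export
read_perturbations <- function(path) {
  if (!file.exists(path)) stop("perturbation file not found: ", path, call. = FALSE)
  parse_perturbations(readLines(path, warn = FALSE))
}

## ---- DOT export ------------------------------------------------------------

#' Export a network to Graphviz DOT
#'
#' Emits a syntactically valid `digraph` with node labels equal to node
#' names, activating edges drawn with normal arrowheads and inhibiting edges
#' with tee arrowheads (the conventional blunt inhibition symbol). Output
#' ordering is deterministic: nodes and edges sorted by name.
#'
#' @param spec a [network_spec()].
#' @param path optional output file.
#' @param name graph name.
#' @return character vector of DOT lines, invisibly when `path` is given.
#' @export
write_dot <- function(spec, path = NULL, name = "network") {
  stopifnot(inherits(spec, "network_spec"))
  rec <- spec_to_record(spec)
  q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  nl <- paste0("  ", q(sort(spec$nodes)), ";")
  e <- rec$edges
  el <- character(0)
  if (nrow(e)) {
    style <- ifelse(e$weight > 0,
                    "[arrowhead=normal, color=black",
                    "[arrowhead=tee, color=red")
    el <- sprintf("  %s -> %s %s, label=\"%s\"];", q(e$source), q(e$target),
                  style, format(e$weight, trim = TRUE))
  }
  out <- c(paste0("digraph ", name, " {"), nl, el, "}")
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}
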