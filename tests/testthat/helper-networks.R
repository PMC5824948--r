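# Small networks built in code, shared across test files.

# A -> B, weight 1
chain_spec <- function() {
  network_spec(c("A", "B"), W = rbind(c(0, 0), c(1, 0)))
}

# mutual inhibition: classic bistable toggle
toggle_spec <- function() {
  network_spec(c("A", "B"), W = rbind(c(0, -1), c(-1, 0)))
}

# rules-based 2-node oscillator: A = NOT B, B = A  (period 4)
oscillator_spec <- function() {
  spec <- network_spec(c("A", "B"))
  attach_rules(spec, parse_rules(c("A = NOT B", "B = A")),
               warn_missing = FALSE)
}

minimal_network_lines <- function() {
  c("node,initial_state,basal_value",
    "A,0,0",
    "B,0,0",
    "source,target,weight",
    "A,B,1")
}

# enumerate the full successor map of a small spec by brute force
successor_codes <- function(spec, mode = "weighted") {
  n <- length(spec$nodes)
  S <- decode_state(0:(2^n - 1), n)
  state_code(step_state(S, spec, mode))
}

expect_same_da <- function(r1, r2) {
  t1 <- da_table(r1)[order(da_table(r1)$cycle_states), ]
  t2 <- da_table(r2)[order(da_table(r2)$cycle_states), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1[, -1], t2[, -1])  # drop arbitrary id column
}
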