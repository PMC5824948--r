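test_that("state enumeration is exhaustive, ordered and capacity-guarded", {
  expect_equal(enumerate_states(2), c(0, 1, 2, 3))
  for (n in c(4, 9, 12)) expect_length(enumerate_states(n), 2^n)
  expect_error(enumerate_states(30), "sample_states")
})

test_that("state sampling is reproducible, constrained and unbiased", {
  s1 <- sample_states(8, 100, seed = 11)
  s2 <- sample_states(8, 100, seed = 11)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_states(8, 100, seed = 12)))

  s3 <- sample_states(5, 200, seed = 3, fixed = c("2" = 1, "5" = 0))
  expect_true(all(s3[2, ] == 1))
  expect_true(all(s3[5, ] == 0))
  expect_error(sample_states(5, 10, seed = 1, fixed = c("2" = 1, "2" = 0)),
               "contradictory")

  # free-bit frequency ~ Binomial(k, 1/2): 4 SE band at k = 10,000
  s4 <- sample_states(6, 10000, seed = 4)
  expect_true(all(abs(rowMeans(s4) - 0.5) < 4 * sqrt(0.25 / 10000)))
})

test_that("trajectories terminate at canonical point or cyclic attractors", {
  # start at a fixed point: trajectory of length 1
  fa <- find_attractor(c(1, 0), toggle_spec())
  expect_equal(ncol(fa$trajectory), 1L)
  expect_equal(fa$attractor$kind, "point")
  expect_equal(fa$attractor$codes, 1)

  # 2-node rules oscillator: cyclic attractor, canonical rotation from the
  # minimum state code
  fb <- find_attractor(c(0, 0), oscillator_spec(), mode = "rules")
  expect_equal(fb$attractor$kind, "cyclic")
  expect_equal(fb$attractor$length, 4L)
  expect_equal(fb$attractor$codes[1], min(fb$attractor$codes))
  # applying one step to cycle state k gives cycle state k+1
  st <- fb$attractor$states
  for (k in 1:4) {
    expect_equal(unname(rules_step(st[, k], oscillator_spec())),
                 unname(st[, (k %% 4) + 1]))
  }
})

test_that("basin fractions partition the analyzed space", {
  for (seed in 1:5) {
    spec <- random_network(7, edge_density = 0.4, seed = seed)
    res <- deterministic_analysis(spec)
    tab <- da_table(res)
    expect_equal(sum(tab$basin_fraction), 1)
    expect_equal(sum(tab$basin_count), 2^7)
    expect_length(res$assignment, 2^7)
    expect_false(anyNA(res$assignment))
  }
})

test_that("batch and walk engines agree, with and without memoization", {
  for (seed in 1:4) {
    spec <- random_network(6, edge_density = 0.5, seed = seed)
    r_batch <- deterministic_analysis(spec, engine = "batch")
    r_walk <- deterministic_analysis(spec, engine = "walk", memoize = TRUE)
    r_plain <- deterministic_analysis(spec, engine = "walk", memoize = FALSE)
    expect_same_da(r_batch, r_walk)
    expect_same_da(r_walk, r_plain)
    expect_identical(r_walk$assignment, r_plain$assignment)
  }
  # also on a rules network with a cyclic attractor
  r1 <- deterministic_analysis(oscillator_spec(), mode = "rules")
  r2 <- deterministic_analysis(oscillator_spec(), mode = "rules",
                               engine = "walk")
  expect_same_da(r1, r2)
})

test_that("sampled basin fractions converge to exhaustive fractions", {
  spec <- random_network(9, edge_density = 0.35, seed = 42)
  ex <- deterministic_analysis(spec)
  k <- 4000
  sa <- deterministic_analysis(spec, space = "sample", k = k, seed = 99)
  ex_tab <- da_table(ex)
  sa_tab <- da_table(sa)
  for (i in seq_len(nrow(sa_tab))) {
    p <- ex_tab$basin_fraction[match(sa_tab$cycle_states[i],
                                     ex_tab$cycle_states)]
    se <- sqrt(p * (1 - p) / k)
    expect_lt(abs(sa_tab$basin_fraction[i] - p), 4 * se + 2 / k)
  }
})

test_that("explicit state sets and duplicate samples count per occurrence", {
  spec <- toggle_spec()
  states <- cbind(c(1, 0), c(1, 0), c(0, 1))  # duplicate initial state
  res <- deterministic_analysis(spec, states = states)
  tab <- da_table(res)
  expect_equal(sum(tab$basin_count), 3L)
  expect_equal(sort(tab$basin_count), c(1L, 2L))
})

test_that("results export to the documented CSV contract", {
  res <- deterministic_analysis(toggle_spec())
  path <- withr::local_tempfile(fileext = ".csv")
  export_da(res, path)
  back <- utils::read.csv(path, colClasses = c(cycle_states = "character"))
  expect_equal(names(back),
               c("attractor_id", "kind", "cycle_length", "basin_count",
                 "basin_fraction", "cycle_states"))
  expect_equal(nrow(back), length(res$attractors))
})
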