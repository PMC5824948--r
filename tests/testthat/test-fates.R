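make_point_attractor <- function(bits, nodes) {
  attractorscape:::make_attractor(matrix(bits, ncol = 1), nodes)
}

test_that("attractors classify by first matching rule with policy semantics", {
  nodes <- c("CASP3", "CYCE")
  rules <- fate_rules(c("Apoptosis", "Proliferation"), c("CASP3", "CYCE"))
  a_on <- make_point_attractor(c(1, 0), nodes)
  expect_equal(classify_attractor(a_on, rules), "Apoptosis")
  a_off <- make_point_attractor(c(0, 0), nodes)
  expect_equal(classify_attractor(a_off, rules), "unclassified")

  # cyclic attractor with the marker on in 1 of 2 states
  cyc <- attractorscape:::make_attractor(cbind(c(1, 1), c(0, 1)), nodes)
  any_pol <- fate_rules(c("Apoptosis", "Growth"), c("CASP3", "CYCE"),
                        policy = "any")
  all_pol <- fate_rules(c("Apoptosis", "Growth"), c("CASP3", "CYCE"),
                        policy = "all")
  maj_pol <- fate_rules(c("Apoptosis", "Growth"), c("CASP3", "CYCE"),
                        policy = "majority")
  expect_equal(classify_attractor(cyc, any_pol), "Apoptosis")
  expect_equal(classify_attractor(cyc, all_pol), "Growth")  # falls through
  expect_equal(classify_attractor(cyc, maj_pol), "Growth")  # 1/2 not majority

  bad <- fate_rules("X", "NOSUCHNODE")
  expect_error(classify_attractor(a_on, bad), "unknown node")
})

test_that("fate propensities aggregate basins additively and sum to one", {
  spec <- toggle_spec()   # two point attractors + 11/00 basins
  res <- deterministic_analysis(spec)
  rules <- fate_rules(c("Afate", "Bfate"), c("A", "B"))
  fl <- fate_landscape(res, rules)
  expect_equal(sum(fl$propensity), 1)
  # two attractors with the same label pool their basins
  pooled <- fate_landscape(res, fate_rules("On", "A OR B"))
  tab <- da_table(res)
  expect_equal(pooled$propensity[pooled$fate == "On"],
               sum(tab$basin_fraction[tab$cycle_states %in% c("1", "2")]))
})

test_that("fate propensities from a distribution sum matching-state mass", {
  spec <- network_spec(c("A", "B"))
  ss <- exhaustive_steady_state(spec, noise_params(2, 1))  # uniform chain
  rules <- fate_rules(c("Aon"), c("A"))
  fl <- fate_landscape(ss, rules, nodes = spec$nodes)
  on_codes <- c(1, 3)  # states with A = 1
  expect_equal(fl$propensity[fl$fate == "Aon"],
               sum(ss$p[as.character(on_codes)]))
  expect_equal(sum(fl$propensity), 1)
})

test_that("apoptosis rate is the percentage basin share of death labels", {
  fl <- structure(data.frame(fate = c("death1", "death2", "grow"),
                             propensity = c(0.1, 0.15, 0.75)),
                  class = c("fate_landscape", "data.frame"))
  expect_equal(apoptosis_rate(fl, c("death1", "death2")), 25)
  expect_equal(apoptosis_rate(fl, character(0)), 0)
  expect_error(apoptosis_rate(fl, "nope"), "unknown fate label")
})

test_that("perturbation screens report control-relative propensities", {
  spec <- toggle_spec()
  rules <- fate_rules(c("Afate", "Bfate"), c("A", "B"))
  perts <- list(
    identity = perturbation_set(),
    a_on = perturbation_set("fix", node = "A", value = 1),
    broken = perturbation_set("fix", node = "ZZZ", value = 1))
  res <- screen_perturbations(spec, perts, rules)
  ctl <- res[res$arm == "control", ]
  expect_true(all(ctl$relative_to_control[ctl$propensity > 0] == 1))
  # zero-propensity control fates are undefined, not infinite
  expect_true(all(is.na(ctl$relative_to_control[ctl$propensity == 0])))
  # identity arm reproduces control exactly
  idn <- res[res$arm == "identity", ]
  expect_equal(idn$propensity, ctl$propensity)
  # per-arm failure recorded, remaining arms intact
  broken <- res[res$arm == "broken", ]
  expect_true(all(is.na(broken$propensity)))
  expect_match(broken$error[1], "ZZZ")
  a_on <- res[res$arm == "a_on", ]
  expect_false(anyNA(a_on$propensity))

  # determinism of sampled screens under a fixed seed
  s1 <- screen_perturbations(spec, perts["a_on"], rules, space = "sample",
                             k = 100, seed = 9)
  s2 <- screen_perturbations(spec, perts["a_on"], rules, space = "sample",
                             k = 100, seed = 9)
  expect_identical(s1, s2)
})

test_that("fate logic files parse in precedence order", {
  rules <- parse_fate_rules(c("# header",
                              "FATE TP: AP AND M",
                              "FATE AP: AP"))
  expect_equal(vapply(rules$rules, `[[`, "", "label"), c("TP", "AP"))
  nodes <- c("AP", "M")
  both <- make_point_attractor(c(1, 1), nodes)
  only_ap <- make_point_attractor(c(1, 0), nodes)
  expect_equal(classify_attractor(both, rules), "TP")
  expect_equal(classify_attractor(only_ap, rules), "AP")
  expect_error(parse_fate_rules("FATE broken"), "expected 'FATE")
})
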