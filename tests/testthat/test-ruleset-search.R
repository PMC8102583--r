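# Ruleset variant space and constraint-guided search.

test_that("variant counts follow the closed form", {
  topo1 <- list(T1 = c("A", "B"))
  base1 <- parse_model(c("var A:2 input", "var B:2 input", "var T1:2",
                         "rule T1 = A"))
  sp1 <- variant_space(topo1, base = base1, free = "T1")
  expect_equal(sp1$count, 8)  # 2 signs^2 x 2 combiners

  topo2 <- list(T1 = c("A"))
  base2 <- parse_model(c("var A:2 input", "var T1:2", "rule T1 = A"))
  sp2 <- variant_space(topo2, base = base2, free = "T1")
  expect_equal(sp2$count, 2)  # sign only

  sp_full <- variant_space(switch_topology())
  # per-target closed form: injury edges carry 4 options, mediator edges 2,
  # combiner counted for >= 2 regulators
  expected <- 4 * 8 * 16 * 8 * 32 * 32 * 8 * 16
  expect_equal(sp_full$count, expected)
  expect_equal(sp_full$count, prod(as.numeric(sp_full$sizes)))

  expect_error(variant_space(list(T1 = character(0)), base = base2),
               "empty regulator")
})

test_that("variant ids decode deterministically and cover the space", {
  topo <- list(T1 = c("A", "B"))
  base <- parse_model(c("var A:2 input", "var B:2 input", "var T1:2",
                        "rule T1 = A"))
  sp <- variant_space(topo, base = base, free = "T1")
  texts <- vapply(seq_len(sp$count), function(id)
    variant_model(sp, id)$rule_text[["T1"]], character(1))
  expect_length(unique(texts), 8L)  # all distinct for a 2-regulator target
  expect_identical(texts,
                   vapply(seq_len(sp$count), function(id)
                     variant_model(sp, id)$rule_text[["T1"]], character(1)))
})

test_that("the reference ruleset is a member of its own variant space", {
  ref <- reference_model()
  sp <- variant_space(switch_topology(), base = ref)
  id <- variant_id_of(sp, ref)
  expect_false(is.na(id))
  decoded <- variant_model(sp, id)
  st <- zero_state(ref, 2L)
  expect_identical(simulate_model(decoded, st, 10L),
                   simulate_model(ref, st, 10L))
  for (bit in names(ref$rules)) {
    expect_true(chemoswitch:::cs_exprs_equivalent(
      decoded$rules[[bit]], ref$rules[[bit]], ref), info = bit)
  }
})

test_that("scoring separates the reference from broken variants", {
  ref <- reference_model()
  sc <- score_ruleset(ref)
  expect_equal(sc$required, 10L)
  expect_equal(sc$distance, 0)

  sc_mig <- score_ruleset(mig_selfloop_model())
  expect_lte(sc_mig$required, 9L)
  expect_false(sc_mig$report$pass[sc_mig$report$id == "B6"])

  txt <- write_model(ref)
  txt[grepl("^rule", txt)] <- sub("= .*$", "= 0", txt[grepl("^rule", txt)])
  all_zero <- parse_model(txt)
  rep0 <- check_constraints(all_zero)
  expect_true(rep0$pass[rep0$id == "B1"])
  expect_false(rep0$pass[rep0$id == "B2"])
  expect_false(rep0$pass[rep0$id == "B3"])
})

test_that("search ranks exhaustively and reproducibly", {
  ref <- reference_model()
  sp <- variant_space(switch_topology(), base = ref, free = "MIG")
  expect_equal(sp$count, 8)
  res <- search_rulesets(sp, budget = 8)
  expect_equal(nrow(res), 8L)
  # best-first: required passes non-increasing down the ranking
  expect_true(all(diff(res$required) <= 0))
  expect_equal(res$required[1], 10)
  expect_equal(res$distance[1], 0)

  sp2 <- variant_space(switch_topology(), base = ref,
                       free = c("MIG", "IL6_low"))
  r1 <- search_rulesets(sp2, budget = 10, seed = 4L)
  r2 <- search_rulesets(sp2, budget = 10, seed = 4L)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 10L)
})
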