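# Rule grammar, level/bit encoding and the synchronous stepping engine.

test_that("parser reads the reference ruleset and tiny models", {
  m <- reference_model()
  expect_equal(nrow(m$vars), 6L)
  expect_equal(length(m$rules), 8L)
  expect_equal(m$vars$role[m$vars$name == "I"], "input")
  expect_equal(sort(m$vars$arity), c(2L, 2L, 3L, 3L, 3L, 3L))

  idm <- identity_model()
  expect_equal(nrow(idm$vars), 1L)
  expect_equal(names(idm$rules), "A")
})

test_that("parser rejects malformed and inconsistent models", {
  expect_error(parse_model(c("var A:2", "rule B = A")), "B")
  expect_error(parse_model(c("var A:2", "rule A = A", "rule A = A")),
               "duplicate rule")
  expect_error(parse_model(c("var A:2 input", "rule A = A")), "input")
  expect_error(parse_model(c("var A:2", "rule A = A or")), "line 2")
  expect_error(parse_model(c("var A:2", "var A:3", "rule A = A")),
               "duplicate variable")
  # a bare three-level name is only legal inside a comparison
  expect_error(parse_model(c("var A:3", "var B:2",
                             "rule A_low = A", "rule A_high = 0",
                             "rule B = 0")),
               "comparison")
  expect_error(parse_model(c("var A:3", "rule A_low = A >= 5",
                             "rule A_high = 0")), "out of range")
})

test_that("models round-trip through serialization", {
  m <- reference_model()
  m2 <- parse_model(write_model(m))
  expect_identical(write_model(m), write_model(m2))
  st <- zero_state(m, 2L)
  expect_identical(simulate_model(m, st, 8L), simulate_model(m2, st, 8L))
})

test_that("level encoding is canonical and decoding sums the bits", {
  m <- reference_model()
  st <- zero_state(m, 1L)
  st[["MCP1"]] <- 2L
  bits <- encode_state(st, m)
  expect_equal(unname(bits[c("MCP1_low", "MCP1_high")]), c(1L, 1L))
  st[["MCP1"]] <- 0L
  expect_equal(unname(encode_state(st, m)[c("MCP1_low", "MCP1_high")]),
               c(0L, 0L))
  st[["MCP1"]] <- 1L
  expect_equal(unname(encode_state(st, m)[c("MCP1_low", "MCP1_high")]),
               c(1L, 0L))
  # the non-canonical pattern (low = 0, high = 1) still decodes to level 1
  bits <- encode_state(st, m)
  bits[["MCP1_low"]] <- 0L
  bits[["MCP1_high"]] <- 1L
  expect_equal(decode_state(bits, m)[["MCP1"]], 1L)
  st[["MCP1"]] <- 3L
  expect_error(encode_state(st, m), "out of range")
})

test_that("encode/decode round-trips over the whole state space", {
  m <- reference_model()
  for (inj in 0:2) {
    states <- enumerate_initial_states(m, fixed = list(I = inj))
    for (r in seq_len(nrow(states))) {
      st <- states[r, ]
      expect_identical(decode_state(encode_state(st, m), m), st)
    }
  }
})

test_that("one synchronous step matches the hand-traced reference behavior", {
  m <- reference_model()
  z0 <- zero_state(m, 0L)
  expect_identical(step_state(m, z0), z0)  # mild: rest is a fixed point
  z2 <- zero_state(m, 2L)
  s1 <- step_state(m, z2)
  expect_equal(unname(s1[c("X", "MCP1", "MIG", "IP10", "IL6")]),
               c(1L, 1L, 0L, 0L, 0L))
  expect_identical(step_state(m, z2), s1)  # purity
})

test_that("stepping agrees with an independent rule-by-rule interpreter", {
  m <- reference_model()
  set.seed(11)
  for (k in 1:40) {
    st <- c(I = sample(0:2, 1), X = sample(0:1, 1), MIG = sample(0:1, 1),
            MCP1 = sample(0:2, 1), IP10 = sample(0:2, 1),
            IL6 = sample(0:2, 1))
    got <- step_state(m, st)
    expect_identical(got, unlist(naive_step(m, as.list(st)))[names(got)],
                     info = paste(st, collapse = ","))
  }
})

test_that("rule declaration order does not affect the update", {
  m <- reference_model()
  set.seed(3)
  shuffled <- m
  ord <- sample(seq_along(m$rules))
  shuffled$rules <- m$rules[ord]
  shuffled$rule_text <- m$rule_text[ord]
  for (k in 1:10) {
    st <- c(I = sample(0:2, 1), X = sample(0:1, 1), MIG = sample(0:1, 1),
            MCP1 = sample(0:2, 1), IP10 = sample(0:2, 1),
            IL6 = sample(0:2, 1))
    expect_identical(step_state(m, st), step_state(shuffled, st))
  }
})

test_that("zero-init trajectories reproduce the published level sequences", {
  m <- reference_model()
  tr1 <- simulate_model(m, zero_state(m, 1L), 10L, clamps = list(I = 1L))
  expect_equal(unname(tr1[1:6, "IP10"]), c(0L, 0L, 1L, 2L, 2L, 2L))
  expect_true(all(tr1[, c("MIG", "MCP1", "IL6")] == 0L))

  tr2 <- simulate_model(m, zero_state(m, 2L), 10L, clamps = list(I = 2L))
  expect_equal(unname(tr2[1:6, "MCP1"]), c(0L, 1L, 2L, 2L, 1L, 1L))
  expect_equal(unname(tr2[1:6, "IL6"]), c(0L, 0L, 1L, 2L, 1L, 1L))
  expect_equal(unname(tr2[1:5, "IP10"]), c(0L, 0L, 1L, 2L, 2L))
})

test_that("simulation handles degenerate and clamped schedules", {
  m <- reference_model()
  z <- zero_state(m, 1L)
  tr0 <- simulate_model(m, z, 0L)
  expect_equal(nrow(tr0), 1L)
  expect_equal(unname(tr0[1, ]), unname(z))
  expect_error(simulate_model(m, z, 10L, clamps = list(X = c(0L, 1L))),
               "shorter")
  # fixed-point detection repeats the trailing state
  trf <- simulate_model(m, z, 15L, clamps = list(I = 1L),
                        stop_at_fixpoint = TRUE)
  expect_identical(unname(trf[16, ]), unname(trf[4, ]))
  expect_identical(trf, simulate_model(m, z, 15L, clamps = list(I = 1L)))
})

test_that("initial-state enumeration is exhaustive, ordered, deterministic", {
  m <- reference_model()
  st <- enumerate_initial_states(m, fixed = list(I = 1L))
  expect_equal(nrow(st), 108L)  # 2 * 2 * 3 * 3 * 3
  expect_equal(nrow(unique(st)), 108L)
  expect_identical(st, enumerate_initial_states(m, fixed = list(I = 1L)))
  # lexicographic: first declared internal variable varies slowest
  expect_true(all(diff(st[, "X"]) >= 0))
  expect_equal(unname(st[1, ]), c(1L, 0L, 0L, 0L, 0L, 0L)[match(
    colnames(st), c("I", "X", "MIG", "MCP1", "IP10", "IL6"))])

  single <- parse_model(c("var A:2", "rule A = A"))
  expect_equal(nrow(enumerate_initial_states(single)), 2L)
  expect_error(enumerate_initial_states(m), "input")
})

test_that("ensemble summaries compute means and standard errors", {
  m <- reference_model()
  tr <- simulate_model(m, zero_state(m, 1L), 5L, clamps = list(I = 1L))
  s <- ensemble_summary(list(tr, tr, tr))
  expect_true(all(s$se == 0))
  expect_equal(s$mean, matrix(as.numeric(tr), nrow = nrow(tr),
                              dimnames = dimnames(tr)), ignore_attr = TRUE)

  tr2 <- tr
  tr2[2, "IL6"] <- 2L
  s2 <- ensemble_summary(list(tr, tr2))
  expect_equal(s2$mean[2, "IL6"], 1)

  states <- enumerate_initial_states(m, fixed = list(I = 1L))
  ens <- simulate_ensemble(m, states, 20L)
  s3 <- ensemble_summary(ens)
  expect_equal(s3$n, 108L)
  expect_equal(unname(s3$mean[21, "IL6"]), 0)

  expect_error(ensemble_summary(list()), "empty")
  expect_error(ensemble_summary(list(tr, tr[1:3, ])), "mismatch")
})

test_that("every trajectory enters a cycle within the state-space size", {
  for (m in list(identity_model(), two_bit_model())) {
    states <- enumerate_initial_states(m)
    n <- nrow(states)
    for (r in seq_len(n)) {
      tr <- simulate_model(m, states[r, ], n + 1L)
      keys <- apply(tr, 1, paste, collapse = ",")
      expect_true(anyDuplicated(keys) > 0)
    }
  }
  m <- reference_model()
  tta <- time_to_attractor(m, 2L)
  expect_true(all(tta$time <= 108L))
})
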