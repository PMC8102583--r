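# Synthetic trauma cohort: concentration mapping, schedules, subgroups.

test_that("the sampling schedule covers the clinical design", {
  sch <- default_schedule()
  expect_true(all(diff(sch$times_h) > 0))
  expect_equal(sum(sch$times_h <= 24), 4L)  # admission + 8h + 16h + 24h
  expect_equal(max(sch$times_h), 168)
  expect_equal(max(sch$steps), 21L)  # 8 h per step
  expect_error(default_schedule(times_h = c(0, 7)), "multiples")
})

test_that("noise-free concentrations are exactly the mapped levels", {
  m <- reference_model()
  map0 <- default_mediator_map(0)
  # all-zero latent trajectory: every concentration equals its baseline
  p0 <- simulate_patient(m, 0L, map0, seed = 2L, init = zero_state(m, 0L))
  merged <- merge(p0$data, map0, by = "mediator")
  expect_equal(merged$value_pg_ml, merged$baseline)
  # severe zero-init patient: MCP-1 concentration follows 100 * 6^level
  p2 <- simulate_patient(m, 2L, map0, seed = 2L, init = zero_state(m, 2L))
  mcp <- p2$data[p2$data$mediator == "MCP1", ]
  expect_equal(mcp$value_pg_ml[1:5], c(100, 600, 3600, 3600, 600))
  expect_equal(mcp$value_pg_ml, 100 * 6^mcp$latent_level)
  # IFN-gamma tracks the latent X trajectory
  ifn <- p2$data[p2$data$mediator == "IFNg", ]
  expect_equal(ifn$value_pg_ml, 10 * 4^p2$trajectory[
    default_schedule()$steps + 1L, "X"], ignore_attr = TRUE)
})

test_that("patients and cohorts are reproducible from their seeds", {
  m <- reference_model()
  p1 <- simulate_patient(m, 2L, seed = 77L)
  p2 <- simulate_patient(m, 2L, seed = 77L)
  expect_identical(p1$data, p2$data)
  co1 <- generate_cohort(5L, 5L, 5L, seed = 9L, n_healthy = 2L)
  co2 <- generate_cohort(5L, 5L, 5L, seed = 9L, n_healthy = 2L)
  expect_identical(co1, co2)
})

test_that("default cohort matches the study group sizes", {
  co <- generate_cohort(seed = 1L)
  pts <- unique(co[, c("patient_id", "group")])
  counts <- table(pts$group)
  expect_equal(unname(counts[c("mild", "moderate", "severe")]),
               c(48L, 47L, 47L), ignore_attr = TRUE)
  expect_equal(sum(counts[c("mild", "moderate", "severe")]), 142L)
  empty <- generate_cohort(0L, 0L, 0L, seed = 1L, n_healthy = 0L)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("patient_id", "group", "time_h", "mediator",
                    "value_pg_ml") %in% names(empty)))
})

test_that("noise-free cohorts decode exactly back to latent levels", {
  map0 <- default_mediator_map(0)
  co <- generate_cohort(4L, 4L, 4L, seed = 3L, mediator_map = map0,
                        n_healthy = 0L)
  dec <- decode_levels(co, map0)
  tracked <- dec[dec$mediator %in% c("MCP1", "MIG", "IP10", "IL6", "IFNg"), ]
  expect_equal(tracked$decoded_level, tracked$latent_level)
})

test_that("the low-MCP-1 subgroup filter thresholds the first sample", {
  map0 <- default_mediator_map(0)
  co <- generate_cohort(0L, 10L, 10L, seed = 4L, mediator_map = map0,
                        n_healthy = 0L)
  sub <- subgroup_low_mcp1(co, threshold = 1000)
  first <- co[co$mediator == "MCP1" & co$time_h == 0, ]
  keep_expected <- first$patient_id[first$latent_level <= 1L]  # 100 or 600
  expect_setequal(unique(sub$patient_id), keep_expected)
  # idempotent; infinite threshold keeps everyone; empty in, empty out
  expect_identical(subgroup_low_mcp1(sub), sub)
  expect_equal(sort(unique(subgroup_low_mcp1(co, Inf)$patient_id)),
               sort(unique(co$patient_id)))
  empty <- generate_cohort(0L, 0L, 0L, seed = 1L, n_healthy = 0L)
  expect_equal(nrow(subgroup_low_mcp1(empty)), 0L)
})

test_that("group summaries report raw-scale means with SE", {
  m <- reference_model()
  map0 <- default_mediator_map(0)
  co1 <- generate_cohort(0L, 0L, 1L, seed = 5L, mediator_map = map0,
                         n_healthy = 0L)
  gs1 <- group_summary(co1)
  expect_true(all(gs1$se == 0))  # single patient
  # severe group at steady-state times: MCP-1 settles at level 1 -> 600
  co <- generate_cohort(0L, 0L, 12L, seed = 6L, mediator_map = map0,
                        n_healthy = 0L)
  gs <- group_summary(co)
  late <- gs[gs$mediator == "MCP1" & gs$time_h >= 96, ]
  expect_true(all(late$mean == 600))
  expect_error(group_summary(generate_cohort(0L, 0L, 0L, seed = 1L,
                                             n_healthy = 0L)), "empty")
})

test_that("severe exceeds moderate IL-6 at the final sample for sigma <= 0.5", {
  for (sigma in c(0.3, 0.5)) {
    co <- generate_cohort(0L, 47L, 47L, seed = 1L,
                          mediator_map = default_mediator_map(sigma),
                          n_healthy = 0L)
    gs <- group_summary(co)
    final <- gs[gs$mediator == "IL6" & gs$time_h == 168, ]
    expect_gt(final$mean[final$group == "severe"],
              final$mean[final$group == "moderate"])
  }
})

test_that("low-MCP-1 subgroup separates severe from moderate late MCP-1", {
  co <- generate_cohort(seed = 1L)
  gs <- group_summary(subgroup_low_mcp1(co))
  late <- gs[gs$mediator == "MCP1" & gs$time_h == 168, ]
  expect_gt(late$mean[late$group == "severe"],
            late$mean[late$group == "moderate"])
})
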