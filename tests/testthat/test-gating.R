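test_that("debris gate keeps events at or above the scatter bounds", {
  ev <- toy_events(fsc = c(1e5, 2e4, 9e4, 1e4, 5e4, 3e4),
                   ssc = c(5e4, 5e4, 5e4, 5e4, 5e4, 5e4))
  cfg <- gate_config(fsc_min = 3e4, ssc_min = 1e4)
  kept <- remove_debris(ev, cfg)
  expect_equal(kept$event_id, c(1, 3, 5, 6))  # hand-filtered

  # bound at the channel floor is a no-op
  expect_identical(remove_debris(ev, gate_config(fsc_min = 0, ssc_min = 0)), ev)
  # bound above everything empties the table
  none <- remove_debris(ev, gate_config(fsc_min = 1e7, ssc_min = 0))
  expect_equal(nrow(none), 0)
  expect_error(remove_debris(data.frame(reporter = 1), cfg),
               class = "schema_error")
})

test_that("edge gate removes exact channel-limit clamps only", {
  ev <- toy_events(fsc = 1e5, reporter = c(100, 1e6, 100, 100, 0, 100,
                                           100, 100, 100, 100),
                   reference = c(200, 200, 1e6, 200, 200, 200,
                                 200, 200, 200, 200))
  cfg <- gate_config(channel_min = 0, channel_max = 1e6)
  kept <- remove_edge_events(ev, cfg)
  expect_equal(kept$event_id, c(1, 4, 6, 7, 8, 9, 10))  # 3 clamped of 10
  clean <- toy_events(fsc = 1e5, reporter = c(10, 20), reference = c(30, 40))
  expect_identical(remove_edge_events(clean, cfg), clean)
})

test_that("reference-positive threshold is the mock percentile, strictly exceeded", {
  mock <- toy_events(fsc = 1e5, reference = rep(100, 50))
  ev <- toy_events(fsc = 1e5, reference = c(100, 101, 99, 100, 250))
  g <- reference_positive_gate(ev, mock, gate_config(mock_percentile = 99.9))
  expect_equal(g$threshold, 100)
  expect_equal(g$events$event_id, c(2, 5))
  expect_equal(g$removed[["reference_negative"]], 3)

  # all-below-threshold survivor set is empty but well-formed
  low <- toy_events(fsc = 1e5, reference = c(10, 20))
  g0 <- reference_positive_gate(low, mock, gate_config())
  expect_equal(nrow(g0$events), 0)
  expect_equal(g0$removed[["reference_negative"]], 2)

  expect_error(reference_positive_gate(ev, mock[0, ], gate_config()),
               class = "insufficient_data_error")
})

test_that("survivor fraction of the reference gate matches the transfection rate", {
  pop <- cell_population_model(transfection_frac = 0.7, debris_frac = 0,
                               edge_frac = 0)
  panel <- build_ground_truth_panel(1, "OFF", 0.1)
  mock <- simulate_sample(NULL, NA, NULL, pop, 10000, seed = 21)
  ev <- simulate_sample(panel, "sw01", NULL, pop, 10000, seed = 22)
  g <- reference_positive_gate(ev, mock, gate_config_for(pop))
  expect_equal(nrow(g$events) / nrow(ev), 0.70, tolerance = 0.02 / 0.70)
})

test_that("standard gating composes the three steps in order and conserves counts", {
  pop <- cell_population_model()
  panel <- build_ground_truth_panel(1, "OFF", 0.1)
  mock <- simulate_sample(NULL, NA, NULL, pop, 10000, seed = 31)
  ev <- simulate_sample(panel, "sw01", "Cas01", pop, 10000, seed = 32)
  cfg <- gate_config_for(pop)

  g <- apply_standard_gating(ev, mock, cfg)
  expect_equal(nrow(g$events) + sum(g$removed), g$n_input)

  # equals sequential application of the three operations
  s1 <- remove_debris(ev, cfg)
  s2 <- remove_edge_events(s1, cfg)
  mock_clean <- remove_edge_events(remove_debris(mock, cfg), cfg)
  s3 <- reference_positive_gate(s2, mock_clean, cfg)
  expect_identical(g$events, s3$events)
  expect_equal(g$threshold, s3$threshold)

  # disabled steps are a pure identity
  g_open <- apply_standard_gating(ev, mock, open_gate())
  expect_identical(g_open$events, ev)
  expect_equal(sum(g_open$removed), 0)
})

test_that("gating is idempotent and never modifies channel values", {
  pop <- cell_population_model()
  panel <- build_ground_truth_panel(1, "OFF", 0.1)
  mock <- simulate_sample(NULL, NA, NULL, pop, 5000, seed = 41)
  ev <- simulate_sample(panel, "sw01", NULL, pop, 5000, seed = 42)
  cfg <- gate_config_for(pop)

  g1 <- apply_standard_gating(ev, mock, cfg)
  g2 <- apply_standard_gating(g1$events, mock, cfg)
  expect_identical(g1$events, g2$events)
  expect_equal(g2$removed[["debris"]], 0)
  expect_equal(g2$removed[["edge"]], 0)
  expect_equal(g2$removed[["reference_negative"]], 0)

  # membership only: surviving rows are untouched rows of the input
  expect_true(all(g1$events$event_id %in% ev$event_id))
  merged <- merge(g1$events, ev, by = "event_id")
  expect_equal(merged$reporter.x, merged$reporter.y)
  expect_equal(merged$reference.x, merged$reference.y)
})

test_that("planted debris and edge fractions are recovered by the gate counts", {
  pop <- cell_population_model(debris_frac = 0.05, edge_frac = 0.01)
  panel <- build_ground_truth_panel(1, "OFF", 0.1)
  mock <- simulate_sample(NULL, NA, NULL, pop, 10000, seed = 51)
  ev <- simulate_sample(panel, "sw01", NULL, pop, 10000, seed = 52)
  g <- apply_standard_gating(ev, mock, gate_config_for(pop))
  n <- nrow(ev)
  expect_equal(g$removed[["debris"]] / n, 0.05, tolerance = 0.01 / 0.05)
  expect_equal(g$removed[["edge"]] / n, 0.01, tolerance = 0.01 / 0.01)
})

test_that("gating report serializes counts and threshold", {
  pop <- cell_population_model()
  panel <- build_ground_truth_panel(1, "OFF", 0.1)
  mock <- simulate_sample(NULL, NA, NULL, pop, 2000, seed = 61)
  ev <- simulate_sample(panel, "sw01", NULL, pop, 2000, seed = 62)
  g <- apply_standard_gating(ev, mock, gate_config_for(pop))
  rep <- gating_report(g)
  expect_equal(rep$n_input, 2000)
  expect_equal(rep$n_surviving + Reduce(`+`, rep$removed), rep$n_input)
  expect_true(is.numeric(rep$reference_threshold))
  json <- jsonlite::toJSON(rep, auto_unbox = TRUE)
  expect_true(jsonlite::validate(json))
})
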