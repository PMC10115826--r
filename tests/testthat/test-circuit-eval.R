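test_that("canonical truth tables follow the fixed state order", {
  expect_equal(truth_table("AND")$ideal, c(0, 0, 0, 1))
  expect_equal(truth_table("NOR")$ideal, c(1, 0, 0, 0))
  expect_equal(truth_table("XOR")$ideal, c(0, 1, 1, 0))
  expect_equal(truth_table("OR")$ideal, c(0, 1, 1, 1))
  expect_equal(truth_table("NAND")$ideal, c(1, 1, 1, 0))
  expect_equal(truth_table("NIMPLY")$ideal, c(0, 1, 0, 0))  # A AND NOT B
  expect_equal(rownames(truth_table("AND")$states),
               c("[0,0]", "[1,0]", "[0,1]", "[1,1]"))
  expect_error(truth_table("XNOR"), class = "invalid_parameter_error")
  expect_error(truth_table("NIMPLY", 3), class = "invalid_parameter_error")
})

test_that("net fold-change divides the ON mean by the OFF mean", {
  tt <- truth_table("AND")
  expect_equal(net_fold_change(c(1, 1, 1, 1), tt), 1)
  expect_equal(net_fold_change(c(1, 1, 1, 10), tt), 10)
  expect_equal(net_fold_change(c(2, 1, 3, 12), tt), 6)  # 12 / mean(2,1,3)
  # stated generalization: multi-ON tables average their ON states
  expect_equal(net_fold_change(c(1, 4, 6, 1), truth_table("XOR")), 5)
  expect_error(net_fold_change(c(0, 0, 0, 5), tt),
               class = "division_domain_error")
  expect_error(net_fold_change(c(1, 2, 3), tt),
               class = "invalid_parameter_error")
})

test_that("vector proximity angle spans 0 (ideal) to 90 degrees (complement)", {
  tt <- truth_table("AND")
  expect_equal(vector_proximity_angle(c(0, 0, 0, 3), tt), 0)
  expect_equal(vector_proximity_angle(c(1, 1, 1, 0), tt), 90)
  expect_equal(vector_proximity_angle(c(2, 2, 2, 2), tt), 60)  # arccos(1/2)
  expect_error(vector_proximity_angle(c(0, 0, 0, 0), tt),
               class = "degenerate_measurement_error")

  # scale invariance of theta; net fold-change invariant to global rescale
  set.seed(3)
  for (i in 1:10) {
    ni <- runif(4, 0.01, 20)
    k <- runif(1, 0.01, 100)
    expect_equal(vector_proximity_angle(ni * k, tt),
                 vector_proximity_angle(ni, tt))
    expect_equal(net_fold_change(ni * k, tt), net_fold_change(ni, tt))
  }

  # complement is worst for any scoreable table
  for (g in c("AND", "OR", "NOR", "NAND", "XOR", "NIMPLY")) {
    tg <- truth_table(g)
    expect_equal(vector_proximity_angle(1 - tg$ideal, tg), 90)
  }
})

test_that("gate panels pass at the inclusive 20-degree cutoff", {
  tt <- truth_table("AND")
  ideal <- list(g1 = c(0, 0, 0, 7), g2 = c(0, 0, 0, 2))
  scores <- evaluate_gate_panel(ideal, tt)
  expect_true(all(scores$pass))
  expect_equal(attr(scores, "pass_count"), 2)

  # an observation engineered to sit exactly on the boundary passes
  on_axis <- c(0, 0, 0, 1)
  tilt <- tan(20 * pi / 180)
  boundary <- c(tilt, 0, 0, 1)  # angle to (0,0,0,1) is exactly 20 degrees
  expect_equal(vector_proximity_angle(boundary, tt), 20)
  sc <- evaluate_gate_panel(list(b = boundary, off = c(1, 1, 1, 1)), tt)
  expect_equal(sc$pass, c(TRUE, FALSE))

  # data-frame ingestion matches the list form
  df <- data.frame(circuit_id = rep(c("g1", "g2"), each = 4),
                   state = rep(1:4, 2),
                   ni = c(ideal$g1, ideal$g2))
  expect_equal(evaluate_gate_panel(df, tt)$theta_deg, scores$theta_deg)
})

test_that("AND-gate assignments enumerate unordered inputs with a distinct mediator", {
  a3 <- enumerate_and_gate_assignments(c("x", "y", "z"))
  expect_equal(nrow(a3), 3)
  expect_equal(a3$mediator, c("z", "y", "x"))
  expect_equal(nrow(enumerate_and_gate_assignments(letters[1:4])), 12)
  a6 <- enumerate_and_gate_assignments(sprintf("sw%02d", 1:6))
  expect_equal(nrow(a6), 60)
  expect_equal(anyDuplicated(a6$circuit_id), 0)
  # unordered inputs: every {A,B} pair appears with input_a < input_b
  expect_true(all(a6$input_a < a6$input_b))
  expect_error(enumerate_and_gate_assignments(c("a", "b")),
               class = "invalid_parameter_error")
  expect_error(enumerate_and_gate_assignments(c("a", "b", "b")),
               class = "invalid_parameter_error")
})

test_that("half-subtractor outputs score against XOR and NIMPLY after [0,0] normalization", {
  # ideal difference and borrow, with a nonzero floor in the [0,0] state
  d <- c(0.05, 5, 5, 0.05)
  bo <- c(0.05, 5, 0.05, 0.05)
  res <- evaluate_half_subtractor(d, bo)
  expect_lt(res$difference$theta_deg, 2)
  expect_lt(res$borrow$theta_deg, 2)
  expect_equal(res$difference$nfi[1], 1)  # control state maps to exactly 1

  # all-equal outputs: arccos(k / (sqrt(k) * 2)) with k ON states
  flat <- c(2, 2, 2, 2)
  res_flat <- evaluate_half_subtractor(flat, flat)
  expect_equal(res_flat$difference$theta_deg, 45)  # XOR, k = 2
  expect_equal(res_flat$borrow$theta_deg, 60)      # NIMPLY, k = 1

  # swapping the operand order moves the borrow's hot state
  swapped <- evaluate_half_subtractor(d, c(0.05, 0.05, 5, 0.05),
                                      borrow = "second_nimply_first")
  expect_lt(swapped$borrow$theta_deg, 2)
  expect_error(evaluate_half_subtractor(c(0, 1, 1, 0), bo),
               class = "division_domain_error")
})

test_that("leaky simulated gates land within 5 degrees of the closed-form angle", {
  tt <- truth_table("AND")
  on <- 10; leak <- 0.8
  gp <- simulate_gate_panel(
    list(list(truth_table = tt, on_level = on, leak_levels = leak)),
    pop = cell_population_model(), n_events = 3000, seed = 17)
  meas <- summarize_gate_panel(gp)
  theta <- evaluate_gate_panel(meas, tt)$theta_deg
  expected <- acos(on / sqrt(3 * leak^2 + on^2)) * 180 / pi
  expect_lt(abs(theta - expected), 5)
})

test_that("a simulated repression cascade alternates reporter direction per stage", {
  pop <- cell_population_model()
  lv <- cascade_expected_levels(4, 0.1)
  mock <- simulate_sample(NULL, NA, NULL, pop, 4000, seed = 90)
  cfg <- gate_config_for(pop)
  ni <- vapply(seq_along(lv), function(k) {
    panel <- build_ground_truth_panel(1, "OFF", lv[k], basal_sd_log10 = 0)
    ev <- simulate_sample(panel, "sw01", "Cas01", pop, 4000, seed = 90 + k)
    normalized_intensity(apply_standard_gating(ev, mock, cfg))$NI
  }, numeric(1))
  fa <- ni / ni[1]  # fold activation against the no-stage baseline
  expect_equal(sign(diff(fa)), c(-1, 1, -1, 1))
})
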