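test_that("asymmetric pacing covers the stated region and schedule", {
  g <- tissue_grid(448, 448)
  p <- asymmetric_pacing(g)
  sites <- eadclump:::protocol_sites(p, g)
  expect_length(sites, 150 * 7)   # 3 cm x 0.14 cm at dx = 0.02
  # abuts the lower-right boundary
  ix <- (sites - 1) %% 448 + 1
  iy <- (sites - 1) %/% 448 + 1
  expect_equal(max(ix), 448)
  expect_equal(min(iy), 1)
  expect_equal(max(iy), 7)

  # 15 pulses in a 15 s run at PCL 1000
  expect_length(eadclump:::pulse_times(p, 15000), 15)
  # schedules are idempotent under re-query
  expect_identical(eadclump:::pulse_times(p, 15000),
                   eadclump:::pulse_times(p, 15000))

  expect_error(stimulus_protocol(pulse_duration = 0), "> 0")
  expect_error(stimulus_protocol(pcl = 2, pulse_duration = 3), "smaller")
})

test_that("the tissue stimulus elicits a propagating wave", {
  run <- control_cable_run()
  # activation detected >= 1 cm away from the stimulated end
  expect_true(is.finite(run$activation_map[100]))  # site 100 = 2 cm
  expect_gt(max(run$traces[, 2]), 0)               # full AP at 6 cm
})

test_that("S1-S2 schedule construction", {
  g <- tissue_grid(100, 100)
  s <- s1s2_cross_field(g)
  expect_named(s, c("s1", "s2"))
  expect_gt(attr(s, "s2_time"), s$s1$first_ms)
  # S2 covers the lower half-domain, S1 a left-edge strip
  s2sites <- eadclump:::protocol_sites(s$s2, g)
  expect_equal(length(s2sites), 100 * 50)
  s1sites <- eadclump:::protocol_sites(s$s1, g)
  expect_true(all((s1sites - 1) %% 100 + 1 <= 5))
  # explicit s2_time overrides the rule; ordering enforced
  expect_equal(attr(s1s2_cross_field(g, s2_time = 432), "s2_time"), 432)
  expect_error(s1s2_cross_field(g, s1_time = 100, s2_time = 50), "after")
  expect_error(s1s2_cross_field(tissue_grid(50, 1)), "2D")

  # S2 with zero amplitude: tissue returns to rest after the S1 wave
  gs <- tissue_grid(48, 16)
  sch <- s1s2_cross_field(gs, s2_time = 120)
  sch$s2$amplitude <- 0
  run <- run_simulation(gs, sch, duration_ms = 600,
                        sensors = c(24L + 48L * 8L))
  expect_true(all(run$v_final < -80))
})

test_that("sensor placement schemes", {
  g <- tissue_grid(448, 448)
  fc <- place_sensors(g, "four-corners")
  expect_equal(nrow(fc), 4)
  # one sensor per quadrant
  qx <- fc$x_cm > 448 * 0.02 / 2
  qy <- fc$y_cm > 448 * 0.02 / 2
  expect_equal(sort(paste(qx, qy)),
               sort(c("FALSE FALSE", "TRUE FALSE", "FALSE TRUE", "TRUE TRUE")))

  ring <- place_sensors(g, "clump-ring", R = 2, margin = 0.2, n = 32)
  expect_equal(nrow(ring), 32)
  d <- sqrt((ring$x_cm - 4.48)^2 + (ring$y_cm - 4.48)^2)
  expect_true(all(abs(d - 2.2) <= g$dx * 1.5))

  cab <- tissue_grid(280, 1)
  expect_equal(nrow(place_sensors(cab, "cable-every-site")), 280)

  # sensors on obstacles are relocated with a warning
  ob <- rep(FALSE, 448 * 448)
  corner <- as.vector(outer(1:60, 0:59 * 448, `+`))
  ob[corner] <- TRUE
  gob <- tissue_grid(448, 448, obstacle = ob)
  expect_warning(s <- place_sensors(gob, "four-corners"), "relocated")
  expect_true(all(!gob$obstacle[s$index]))
})
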