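span <- channel_span(-10, 10)

test_that("a monotone crossing gives exactly one outward event", {
  traj <- ion_traj(seq(-30, 30, length.out = 61))
  ev <- detect_events(traj, span)
  expect_events(ev, 1, 0)
  expect_equal(ev$completion_frame, which(seq(-30, 30, length.out = 61) > 10)[1])
  # reversed-time trajectory swaps direction
  ev_r <- detect_events(ion_traj(rev(seq(-30, 30, length.out = 61))), span)
  expect_events(ev_r, 0, 1)
})

test_that("re-entries on the same side emit nothing (hysteresis)", {
  # enter from below to z = 0 and retreat, five times
  one <- c(seq(-15, 0, by = 1), seq(-1, -15, by = -1))
  traj <- ion_traj(rep(one, 5))
  expect_events(detect_events(traj, span), 0, 0)
  # ... but a full traversal after teasing still counts once
  traj2 <- ion_traj(c(rep(one, 3), seq(-15, 15, by = 1)))
  expect_events(detect_events(traj2, span), 1, 0)
})

test_that("periodic reservoir recycling is not a permeation event", {
  # bulk ion wrapped by PBC: z jumps +34 -> -34 with box_z = 70
  traj <- ion_traj(c(30, 32, 34, -34, -32, -30))
  expect_events(detect_events(traj, span), 0, 0)
  # wrap while approaching from one side, then a real crossing
  traj2 <- ion_traj(c(33, -33, -20, -5, 0, 5, 20))
  expect_events(detect_events(traj2, span), 1, 0)
})

test_that("event counting is invariant under frame thinning and time reversal", {
  model <- pore_model(well_depths = c(2, 2), n_ions = 2, voltage = 0.6,
                      seed = 11)
  traj <- gen_pore_trajectory(model, 40000, 5e-4)
  ev <- detect_events(traj, span, check_step = FALSE)
  # thinning by 2
  thin <- new_trajectory(traj$atoms,
                         traj$coords[seq(1, 40000, by = 2), , , drop = FALSE],
                         traj$times[seq(1, 40000, by = 2)],
                         traj$box[seq(1, 40000, by = 2), ])
  ev_thin <- detect_events(thin, span, check_step = FALSE)
  expect_equal(nrow(ev_thin), nrow(ev))
  # reversal swaps outward and inward exactly
  rev_traj <- new_trajectory(traj$atoms,
                             traj$coords[40000:1, , , drop = FALSE],
                             traj$times, traj$box)
  ev_rev <- detect_events(rev_traj, span, check_step = FALSE)
  expect_equal(sum(ev_rev$direction == "outward"),
               sum(ev$direction == "inward"))
  expect_equal(sum(ev_rev$direction == "inward"),
               sum(ev$direction == "outward"))
})

test_that("conductance arithmetic matches the closed form", {
  # 10 outward events, q = 2e, t = 250 ns, V = 0.6 V
  g <- conductance(10, sim_time = 250, voltage = 0.6, ion_charge = 2)
  expect_equal(g$conductance_pS, 10 * 2 * 1.602176634e-19 /
                 (250e-9 * 0.6) * 1e12, tolerance = 1e-12)
  expect_equal(round(g$conductance_pS, 2), 21.36)
  expect_equal(conductance(0, 250, 0.6)$conductance_pS, 0)
  # 5 outward + 5 inward -> 0 net
  ev <- data.frame(ion_id = 1, completion_frame = 1:10,
                   direction = rep(c("outward", "inward"), 5))
  expect_equal(conductance(ev, 250, 0.6)$conductance_pS, 0)
  expect_gt(conductance(ev, 250, 0.6, counting = "outward")$conductance_pS, 0)
  expect_error(conductance(10, 250, 0), "zero voltage")
  expect_error(conductance(10, 0, 0.6), "positive")
})

test_that("conductance is linear in events, inverse in time and voltage", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:50, 1); t <- runif(1, 10, 500); v <- runif(1, 0.1, 1)
    g <- conductance(n, t, v)$conductance_pS
    expect_equal(conductance(2 * n, t, v)$conductance_pS, 2 * g,
                 tolerance = 1e-12)
    expect_equal(conductance(n, 2 * t, v)$conductance_pS, g / 2,
                 tolerance = 1e-12)
    expect_equal(conductance(n, t, 2 * v)$conductance_pS, g / 2,
                 tolerance = 1e-12)
  }
})

test_that("replicate statistics use the sample (n-1) standard deviation", {
  expect_equal(replicate_stats(c(20, 20, 20)), list(mean = 20, sd = 0, n = 3))
  rs <- replicate_stats(c(10, 30))
  expect_equal(rs$mean, 20)
  expect_equal(rs$sd, sqrt(200), tolerance = 1e-12)  # 14.142
  expect_true(is.na(replicate_stats(5)$sd))
  expect_error(replicate_stats(numeric(0)), "no replicas")
})

test_that("trace_table unwraps periodic jumps into a continuous column", {
  traj <- ion_traj(c(20, 30, 34, -34, -30, -20))
  tt <- trace_table(traj)
  expect_equal(nrow(tt), 6)
  expect_equal(tt$z_unwrapped, c(20, 30, 34, 36, 40, 50))
  expect_equal(tt$z[4], -34)  # wrapped column untouched
  # window filter drops bulk frames
  tt_w <- trace_table(traj, span = span, window = 15)
  expect_true(all(tt_w$z >= -25 & tt_w$z <= 25))
  expect_lt(nrow(tt_w), 6)
})

test_that("spans and selections are validated", {
  expect_error(channel_span(10, -10), "z_lower")
  expect_error(channel_span(-10, 10, lateral_radius = -1), "positive")
  traj <- ion_traj(c(0, 1))
  expect_error(detect_events(traj, span, ion_selection = "protein"), "empty")
  expect_error(detect_events(traj, channel_span(-100, 100)), "wider than")
})
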