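test_that("Poiseuille resistance matches the closed form and its scalings", {
  # 8 * 5 * 0.035 / (pi * 0.05^4), evaluated independently
  expect_equal(vessel_resistance(0.05, 5.0, 3.5), 71301.41, tolerance = 1e-6)
  # r^4 law: doubling the radius divides resistance by 16
  r <- vessel_resistance(0.05, 5, 3.5)
  expect_equal(vessel_resistance(0.10, 5, 3.5), r / 16)
  # linear in length and viscosity; zero-length limit
  expect_equal(vessel_resistance(0.05, 10, 3.5), 2 * r)
  expect_equal(vessel_resistance(0.05, 5, 7.0), 2 * r)
  expect_equal(vessel_resistance(0.05, 0, 3.5), 0)
  expect_error(vessel_resistance(0, 5, 3.5), "radius")
  expect_error(vessel_resistance(0.05, 5, -1), "viscosity")
})

test_that("single-vessel circuit obeys the Ohm analogy exactly", {
  net <- make_single(0.05, 5)
  sol <- solve_flows(net)
  R <- vessel_resistance(0.05, 5, 3.5)
  expect_equal(sol$vessels$flow, (74 - 5) * MMHG / R * 60, tolerance = 1e-12)
  expect_equal(sol$vessels$drop, 69, tolerance = 1e-12)
  expect_equal(sol$total_flow, sol$vessels$flow)
})

test_that("series and parallel configurations match closed forms", {
  net <- make_series(3)
  sol <- solve_flows(net)
  # equal flows along the chain; drops sum to source - sink
  expect_equal(diff(range(sol$vessels$flow)), 0, tolerance = 1e-12)
  expect_equal(sum(sol$vessels$drop), 69, tolerance = 1e-9)

  net <- make_parallel(2)
  sol <- solve_flows(net)
  # two identical parallel vessels carry exactly half the total each
  expect_equal(sol$vessels$flow[1], sol$vessels$flow[2], tolerance = 1e-12)
  expect_equal(sol$vessels$flow[1] + sol$vessels$flow[2],
               sol$vessels$flow[3], tolerance = 1e-9)
})

test_that("Wheatstone bridge matches an independently assembled dense solve", {
  net <- make_bridge()
  sol <- solve_flows(net)
  oracle <- dense_oracle_solve(net)
  expect_equal(sol$vessels$flow, unname(oracle$flow[sol$vessels$id]),
               tolerance = 1e-9)
  # balanced bridge: equal products of opposite arm resistances kill the
  # bridge-arm flow
  bal <- make_bridge(radii = rep(0.05, 5), lengths = c(5, 5, 5, 5, 3))
  sol_bal <- solve_flows(bal)
  expect_equal(sol_bal$vessels$flow[5], 0, tolerance = 1e-9)
})

test_that("production solver agrees with the dense nodal oracle on random networks", {
  for (seed in 1:100) {
    net <- random_small_net(seed)
    sol <- solve_flows(net)
    oracle <- dense_oracle_solve(net)
    expect_equal(sol$vessels$flow, unname(oracle$flow[sol$vessels$id]),
                 tolerance = 1e-9)
    expect_lt(sol$residual, 1e-6 * max(abs(sol$total_flow), 1e-9))
  }
})

test_that("flow = drop / R holds per vessel and conservation residual is tiny", {
  net <- random_small_net(42)
  sol <- solve_flows(net)
  R <- sol$vessels$resistance
  expect_equal(sol$vessels$flow,
               sol$vessels$drop * MMHG / R * 60, tolerance = 1e-9)
  expect_lt(sol$residual, 1e-6 * sol$total_flow)
})

test_that("flows scale linearly with the boundary pressure difference", {
  net <- random_small_net(7)
  sol1 <- solve_flows(net)
  net2 <- net
  # double the (source - sink) difference while keeping the sink at 5
  net2$boundary$source_pressure <- 5 + 2 * (74 - 5)
  sol2 <- solve_flows(net2)
  expect_equal(sol2$vessels$flow, 2 * sol1$vessels$flow, tolerance = 1e-9)
  expect_equal(sol2$vessels$drop, 2 * sol1$vessels$drop, tolerance = 1e-9)
})

test_that("energy balance: sum(flow x drop) equals total flow x boundary drop", {
  for (seed in c(3, 17, 23)) {
    net <- random_small_net(seed)
    sol <- solve_flows(net)
    # all quantities converted to CGS for the power balance
    power <- sum((sol$vessels$flow / 60) * (sol$vessels$drop * MMHG))
    expect_equal(power, (sol$total_flow / 60) * (74 - 5) * MMHG,
                 tolerance = 1e-9)
  }
})

test_that("occluding a vessel never increases total flow", {
  for (seed in c(5, 9)) {
    net <- random_small_net(seed)
    base <- solve_flows(net)$total_flow
    for (k in seq_len(nrow(net$vessels))) {
      occ <- net
      occ$vessels$occluded[k] <- TRUE
      tf <- tryCatch(solve_flows(occ)$total_flow, error = function(e) NULL)
      if (!is.null(tf)) expect_lte(tf, base + 1e-9 * base)
    }
  }
})

test_that("occluded vessels carry exactly zero flow; anchored components solve", {
  net <- make_bridge()
  net$vessels$occluded[5] <- TRUE
  sol <- solve_flows(net)
  expect_identical(sol$vessels$flow[5], 0)
  # fully severed middle: chain S - N1 - K with both vessels occluded around
  # N1 leaves N1 unanchored in no component with vessels -> pressure NA
  ch <- make_series(2)
  ch$vessels$occluded <- c(TRUE, TRUE)
  expect_error(solve_flows(ch), "no patent vessels")
  # floating component with vessels but no anchor errors
  nodes <- node_tbl(c("S", "K", "A", "B"),
                    c("pressure-source", "pressure-sink", "nidus", "nidus"))
  v <- vessel_tbl(c("S", "A"), c("K", "B"))
  expect_error(solve_flows(toy_net(nodes, v)), "anchor")
})

test_that("summarize_nidus totals and per-class statistics are consistent", {
  net <- canonical_net()
  sol <- solve_flows(net)
  sm <- summarize_nidus(sol, net)
  # feeder inflow equals drainer outflow equals the reported total
  drn <- sol$vessels$flow[match(net$drainers, sol$vessels$id)]
  expect_equal(sm$total_nidus_flow, sum(drn), tolerance = 1e-6)
  expect_setequal(sm$stats$class, c("plexiform", "fistulous"))
  expect_true(all(sm$stats$flow_min <= sm$stats$flow_mean))
  expect_true(all(sm$stats$flow_mean <= sm$stats$flow_max))
  # all feeders occluded: zero nidus throughput
  occ <- occlude_feeders(net, names(net$feeders))
  sm0 <- summarize_nidus(solve_flows(occ), occ)
  expect_equal(sm0$total_nidus_flow, 0, tolerance = 1e-9)
  expect_equal(max(sm0$stats$flow_max), 0, tolerance = 1e-9)
})
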