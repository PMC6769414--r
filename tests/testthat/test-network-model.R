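test_that("canonical build satisfies the structural invariants", {
  net <- canonical_net()
  v <- net$vessels
  expect_equal(sum(v$class == "plexiform"), 93)
  expect_equal(sum(v$class == "fistulous"), 4)
  expect_equal(sum(v$class == "feeder"), 4)
  expect_equal(sum(v$class == "drainer"), 3)
  expect_equal(sum(net$nodes$role == "pressure-source"), 1)
  expect_equal(sum(net$nodes$role == "pressure-sink"), 1)
  expect_silent(validate_network(net))
  # the fistula is a simple 4-segment path from AF2's entry to DV2's exit
  f <- v[v$class == "fistulous", ]
  af2_entry <- v$head[v$id == net$feeders[["AF2"]]]
  dv2_exit <- v$tail[v$id == net$drainers[["DV2"]]]
  path <- af2_entry
  for (i in seq_len(nrow(f))) {
    nxt <- f$head[f$tail == path[length(path)]]
    expect_length(nxt, 1)
    path <- c(path, nxt)
  }
  expect_identical(path[length(path)], dv2_exit)
  # nidus nodes carry 3-D coordinates
  nid <- net$nodes[net$nodes$role == "nidus", ]
  expect_true(all(is.finite(nid$x) & is.finite(nid$y) & is.finite(nid$z)))
})

test_that("build invariants hold across many seeds and builds are deterministic", {
  cfg0 <- nidus_config()
  for (seed in seq_len(60)) {
    cfg <- cfg0
    cfg$seed <- seed
    net <- build_canonical_network(cfg, calibrate = FALSE)
    v <- net$vessels
    expect_equal(sum(v$class %in% c("plexiform", "fistulous")), 97)
    expect_silent(validate_network(net))
  }
  a <- build_canonical_network(calibrate = FALSE)
  b <- build_canonical_network(calibrate = FALSE)
  expect_identical(a, b)
  # different seeds give different intranidal edge sets, same counts
  cfg2 <- nidus_config()
  cfg2$seed <- 2L
  c2 <- build_canonical_network(cfg2, calibrate = FALSE)
  ekey <- function(n) {
    v <- n$vessels[n$vessels$class == "plexiform", ]
    sort(paste(v$tail, v$head))
  }
  expect_false(identical(ekey(a), ekey(c2)))
})

test_that("a purely plexiform nidus (no fistula) is valid", {
  cfg <- nidus_config(n_plexiform = 97, n_fistulous = 0)
  net <- build_canonical_network(cfg, calibrate = FALSE)
  expect_equal(sum(net$vessels$class == "fistulous"), 0)
  expect_equal(sum(net$vessels$class == "plexiform"), 97)
  expect_silent(validate_network(net))
})

test_that("calibration drives feeder and drainer pressures to their targets", {
  net <- canonical_net()
  sol <- solve_flows(net)
  p <- stats::setNames(sol$nodes$pressure, sol$nodes$id)
  inlets <- net$vessels$tail[match(net$feeders, net$vessels$id)]
  outlets <- net$vessels$head[match(net$drainers, net$vessels$id)]
  targets <- c(47, 47, 50, 50)
  expect_true(all(abs(p[inlets] - targets) < 2))
  expect_true(all(abs(p[outlets] - 17) < 2))
  expect_gt(p[inlets][1], 45)
  expect_lt(p[inlets][1], 49)
  # a calibrated network is a fixed point of re-calibration
  net2 <- calibrate_extranidal(net)
  sol2 <- solve_flows(net2)
  expect_equal(sol2$total_flow, sol$total_flow, tolerance = 1e-3)
})

test_that("two-vessel voltage divider calibrates to the closed-form ratio", {
  # source --(adjustable artery)--> inlet --(feeder, then drainer)--> sink;
  # at the target inlet pressure 47 the divider equation gives
  # R_art / R_down = (74 - 47) / (47 - 5)
  nodes <- node_tbl(c("S", "AF1in", "M", "K"),
                    c("pressure-source", "arterial", "venous",
                      "pressure-sink"))
  v <- tibble::tibble(
    id = c("art_S_AF1in", "AF1", "ven_M_K"),
    tail = c("S", "AF1in", "M"), head = c("AF1in", "M", "K"),
    class = c("systemic-artery", "feeder", "systemic-vein"),
    radius = c(0.1, 0.05, 0.1), length = c(5, 5, 4),
    occluded = FALSE, emf = 0
  )
  net <- toy_net(node_tbl(c("S", "AF1in", "M", "K"),
                          c("pressure-source", "arterial", "venous",
                            "pressure-sink")), v,
                 feeders = c(AF1 = "AF1"), drainers = character(0))
  net$vessels <- v
  cal <- calibrate_extranidal(net, tol = 0.01)
  sol <- solve_flows(cal)
  p <- stats::setNames(sol$nodes$pressure, sol$nodes$id)
  expect_equal(unname(p["AF1in"]), 47, tolerance = 0.01)
  Rart <- vessel_resistance(cal$vessels$radius[1], cal$vessels$length[1], 3.5)
  Rdown <- sum(vessel_resistance(cal$vessels$radius[2:3],
                                 cal$vessels$length[2:3], 3.5))
  expect_equal(Rart / Rdown, (74 - 47) / (47 - 5), tolerance = 1e-3)
})

test_that("occlusion is pure, composable, and respects unknown ids", {
  net <- canonical_net()
  before <- net$vessels$occluded
  a <- occlude_feeders(net, c("AF1", "AF3"))
  expect_identical(net$vessels$occluded, before) # input untouched
  b <- occlude_feeders(occlude_feeders(net, "AF1"), "AF3")
  expect_identical(a$vessels$occluded, b$vessels$occluded)
  expect_identical(occlude_feeders(net, character(0)), net)
  expect_error(occlude_feeders(net, "AF9"), "unknown feeder")
  # occluding AF1, AF3, AF4 leaves the fistula fed by AF2: DV2 still flows
  occ <- occlude_feeders(net, c("AF1", "AF3", "AF4"))
  sol <- solve_flows(occ)
  expect_gt(sol$vessels$flow[sol$vessels$id == net$drainers[["DV2"]]], 0)
})

test_that("perturb_geometry stays in its support and reproduces under a seed", {
  net <- canonical_net()
  expect_identical(perturb_geometry(net, 0, seed = 1), net)
  p1 <- perturb_geometry(net, 0.10, seed = 5)
  p2 <- perturb_geometry(net, 0.10, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1$vessels$radius >= 0.9 * net$vessels$radius - 1e-12))
  expect_true(all(p1$vessels$radius <= 1.1 * net$vessels$radius + 1e-12))
  expect_true(all(p1$vessels$length >= 0.9 * net$vessels$length - 1e-12))
  expect_true(all(p1$vessels$length <= 1.1 * net$vessels$length + 1e-12))
  p3 <- perturb_geometry(net, 0.10, seed = 6)
  expect_false(identical(p1$vessels$radius, p3$vessels$radius))
  expect_error(perturb_geometry(net, -0.1, 1), "rel_halfwidth")
})

test_that("rewire_nidus changes exactly the requested vessels and keeps invariants", {
  net <- canonical_net()
  expect_identical(rewire_nidus(net, 0, seed = 1), net)
  rw <- rewire_nidus(net, 0.5, seed = 3)
  expect_identical(rewire_nidus(net, 0.5, seed = 3), rw) # reproducible
  nidus <- net$vessels$class %in% c("plexiform", "fistulous")
  expect_equal(sum(nidus), 97)
  changed <- net$vessels$tail != rw$vessels$tail |
    net$vessels$head != rw$vessels$head
  expect_equal(sum(changed), round(0.5 * 97))
  expect_false(any(changed & !nidus)) # only nidus vessels move
  # classes and geometry preserved (fistulous keep radius/length)
  expect_identical(net$vessels$class, rw$vessels$class)
  expect_identical(net$vessels$radius, rw$vessels$radius)
  expect_identical(net$vessels$length, rw$vessels$length)
  # simple graph: no self-loops, no duplicate edges
  expect_true(all(rw$vessels$tail != rw$vessels$head))
  keys <- paste(pmin(rw$vessels$tail, rw$vessels$head),
                pmax(rw$vessels$tail, rw$vessels$head))
  expect_false(any(duplicated(keys)))
  expect_silent(validate_network(rw))
  # solves after rewiring
  expect_s3_class(solve_flows(rw), "avm_flow")
})
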