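test_that("zero injection with no occlusion leaves every delta map at zero", {
  net <- canonical_net()
  ssa <- simulate_ssa(net, "AF1", 0, occlude_others = FALSE)
  expect_equal(max(abs(ssa$deltas$delta_p_abs)), 0, tolerance = 1e-9)
  expect_equal(max(abs(ssa$deltas$delta_p_pct)), 0, tolerance = 1e-7)
  expect_equal(max(abs(ssa$node_delta$delta_p)), 0, tolerance = 1e-9)
})

test_that("positive injection raises every nidus and venous pressure", {
  # the series injection source raises everything downstream of the feeder;
  # upstream arterial nodes may dip slightly (the injection draws extra flow
  # through the feeding artery), so the maximum principle is asserted over
  # the nidus and venous sides
  net <- canonical_net()
  down <- net$nodes$id[net$nodes$role %in% c("nidus", "venous")]
  for (occl in c(FALSE, TRUE)) {
    ssa <- simulate_ssa(net, "AF2", 15, occlude_others = occl)
    d <- ssa$node_delta$delta_p[ssa$node_delta$id %in% down]
    expect_true(all(d[!is.na(d)] > -1e-9))
  }
})

test_that("node pressure response is monotone in injection strength", {
  net <- canonical_net()
  down <- net$nodes$id[net$nodes$role %in% c("nidus", "venous")]
  pick <- function(s) s$node_delta$delta_p[s$node_delta$id %in% down]
  d10 <- pick(simulate_ssa(net, "AF1", 10))
  d20 <- pick(simulate_ssa(net, "AF1", 20))
  d30 <- pick(simulate_ssa(net, "AF1", 30))
  ok <- !is.na(d10)
  expect_true(all(d20[ok] >= d10[ok] - 1e-9))
  expect_true(all(d30[ok] >= d20[ok] - 1e-9))
  # linear network: the response is exactly proportional to the injection
  expect_equal(d20[ok], 2 * d10[ok], tolerance = 1e-9)
})

test_that("with other feeders occluded all nidus inflow comes through the injected feeder", {
  net <- canonical_net()
  ssa <- simulate_ssa(net, "AF1", 20, occlude_others = TRUE)
  v <- ssa$injected$vessels
  feeder_flows <- v$flow[match(net$feeders, v$id)]
  expect_equal(sum(feeder_flows[-1]), 0, tolerance = 1e-12) # occluded
  drn <- sum(v$flow[match(net$drainers, v$id)])
  expect_equal(feeder_flows[1], drn, tolerance = 1e-6)
})

test_that("delta maps are equivariant under vessel relabeling", {
  net <- canonical_net()
  ssa <- simulate_ssa(net, "AF3", 10)
  # permute nidus vessel rows of the network; deltas follow the ids
  perm <- net
  nidx <- which(perm$vessels$class %in% c("plexiform", "fistulous"))
  shuffled <- sample(nidx)
  perm$vessels[nidx, ] <- perm$vessels[shuffled, ]
  ssa_p <- simulate_ssa(perm, "AF3", 10)
  a <- ssa$deltas[order(ssa$deltas$id), ]
  b <- ssa_p$deltas[order(ssa_p$deltas$id), ]
  expect_equal(a$delta_p_pct, b$delta_p_pct, tolerance = 1e-9)
})

test_that("matched and patent baselines differ only under occlusion", {
  net <- canonical_net()
  m <- simulate_ssa(net, "AF1", 20, occlude_others = FALSE,
                    baseline = "matched")
  p <- simulate_ssa(net, "AF1", 20, occlude_others = FALSE,
                    baseline = "patent")
  expect_equal(m$deltas$delta_p_pct, p$deltas$delta_p_pct, tolerance = 1e-12)
  m2 <- simulate_ssa(net, "AF1", 20, occlude_others = TRUE,
                     baseline = "matched")
  p2 <- simulate_ssa(net, "AF1", 20, occlude_others = TRUE,
                     baseline = "patent")
  expect_false(isTRUE(all.equal(m2$deltas$delta_p_pct,
                                p2$deltas$delta_p_pct)))
  # matched baseline keeps the nidus injection response non-negative
  down <- net$nodes$id[net$nodes$role %in% c("nidus", "venous")]
  d <- m2$node_delta$delta_p[m2$node_delta$id %in% down]
  expect_true(all(d > -1e-9, na.rm = TRUE))
})

test_that("injection errors are informative", {
  net <- canonical_net()
  occ <- occlude_feeders(net, "AF1")
  expect_error(simulate_ssa(occ, "AF1", 10), "occluded")
  expect_error(simulate_ssa(net, "AF7", 10), "unknown feeder")
  expect_error(simulate_ssa(net, "AF1", -5), "non-negative")
})
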