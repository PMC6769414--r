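test_that("exact Otsu matches hand-worked examples", {
  # {1,1,1,9,9,9}: the only sensible split is between the two level sets
  expect_equal(otsu_threshold(c(1, 1, 1, 9, 9, 9)), 5)
  expect_equal(otsu_threshold(c(0, 10)), 5)
  expect_error(otsu_threshold(c(7, 7, 7, 7)), "not all equal")
  expect_error(otsu_threshold(3), "2 values")
  # ties break toward the lowest qualifying threshold
  expect_equal(otsu_threshold(c(0, 5, 10)), 2.5)
})

test_that("exact Otsu equals the brute-force within-class-variance minimiser", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(3:50, 1)
    x <- switch(1 + i %% 3,
                rnorm(n),
                c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), mean = 6)),
                sample(0:5, n, replace = TRUE) + 0) # heavy ties
    if (diff(range(x)) == 0) next
    expect_equal(otsu_threshold(x), brute_otsu(x), tolerance = 1e-12)
  }
})

test_that("binned Otsu induces the same partition as exact Otsu on separated data", {
  # thresholds may differ inside the empty gap between modes, but the
  # resulting two-class partition must agree
  set.seed(1)
  x <- c(rnorm(50, 0, 0.3), rnorm(50, 8, 0.3))
  expect_identical(x > otsu_threshold_binned(x), x > otsu_threshold(x))
})

test_that("Welch mean-separation p-value matches the hand formula", {
  set.seed(9)
  a <- 1 + 0.01 * rnorm(20)
  b <- 9 + 0.01 * rnorm(20)
  p <- bimodality_pvalue(c(a, b))
  # independent evaluation of the Welch statistic
  se2 <- var(a) / 20 + var(b) / 20
  t <- (mean(b) - mean(a)) / sqrt(se2)
  df <- se2^2 / ((var(a) / 20)^2 / 19 + (var(b) / 20)^2 / 19)
  p_hand <- 2 * pt(-abs(t), df)
  expect_equal(p, p_hand, tolerance = 1e-12)
  expect_lt(p, 1e-6)
})

test_that("bimodality p-value flags degenerate class splits", {
  # 1 vs 96: upper class has a single member -> undefined
  x <- c(rep(0, 96), 100)
  p <- bimodality_pvalue(x)
  expect_true(is.na(p))
  expect_match(attr(p, "reason"), "2 members")
  expect_true(is.na(bimodality_pvalue(rep(3, 10))))
  # two zero-variance but distinct classes: perfect separation
  expect_equal(bimodality_pvalue(c(1, 1, 1, 9, 9, 9)), 0)
})

test_that("Welch-on-Otsu-classes is significant even for unimodal data", {
  # the Otsu split maximises mean separation, so the test rejects on any
  # continuous sample; this calibration fact is frozen by simulation
  set.seed(123)
  ps <- replicate(200, bimodality_pvalue(rnorm(97)))
  expect_equal(mean(ps < 0.05, na.rm = TRUE), 1)
})

test_that("detect_compartment reproduces designed block structure", {
  # two-block synthetic SSA: half the nidus responds strongly
  net <- canonical_net()
  ssa <- simulate_ssa(net, "AF1", 10)
  fake <- ssa
  n <- nrow(fake$deltas)
  hi <- seq_len(floor(n / 2))
  fake$deltas$delta_p_pct <- 0.5 + 0.01 * seq_len(n)
  fake$deltas$delta_p_pct[hi] <- 40 + 0.01 * seq_len(length(hi))
  cmp <- detect_compartment(fake)
  expect_false(cmp$degenerate)
  expect_equal(sort(cmp$members$id[cmp$members$member]),
               sort(fake$deltas$id[hi]))
  expect_equal(cmp$size_pct, 100 * length(hi) / n, tolerance = 1e-9)
  expect_lt(cmp$bimodality_p, 1e-10)
  # membership rule is strictly-above-threshold
  expect_true(all(cmp$members$value[cmp$members$member] > cmp$threshold))
  expect_true(all(cmp$members$value[!cmp$members$member] <= cmp$threshold))
})

test_that("degenerate response distributions are reported as such", {
  net <- canonical_net()
  ssa <- simulate_ssa(net, "AF1", 0)
  cmp <- detect_compartment(ssa)
  expect_true(cmp$degenerate)
  expect_true(is.na(cmp$size_pct))
  expect_true(is.na(cmp$threshold))
})

test_that("compartment size is invariant under positive affine transforms", {
  net <- canonical_net()
  ssa <- simulate_ssa(net, "AF2", 20, occlude_others = TRUE)
  cmp <- detect_compartment(ssa)
  for (ab in list(c(2, 0), c(0.5, 3), c(10, -7))) {
    tr <- ssa
    tr$deltas$delta_p_pct <- ab[1] * ssa$deltas$delta_p_pct + ab[2]
    cmp_tr <- detect_compartment(tr)
    expect_equal(cmp_tr$size_pct, cmp$size_pct)
    expect_identical(cmp_tr$members$member, cmp$members$member)
  }
})
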