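test_that("without cutting the single ribbon has length exactly v * t", {
  p <- coarse_params(v = 2, Delta = 1, lambda = 0, t_max = 5)
  tr <- simulate_population(p, seed = 1)
  expect_identical(tr$counts[length(tr$counts)], 1L)
  expect_identical(tr$lengths[[length(tr$lengths)]], 10)
  expect_identical(tr$mass[length(tr$mass)], 10)
  am <- amplification_metrics(tr)
  expect_true(is.na(am$doubling_time))
  expect_true(am$low_confidence)
})

test_that("instantaneous cutting is binary fission: doubling every Delta/v, fragments below 2 Delta", {
  ## horizon strictly inside an epoch: a horizon on an epoch boundary
  ## truncates the final cut cascade and distorts the tail of the fit
  p <- coarse_params(v = 1.5, Delta = 2, lambda = Inf, t_max = (2 / 1.5) * 8.75)
  tr <- simulate_population(p, seed = 4)
  am <- amplification_metrics(tr)
  expect_false(am$low_confidence)
  expect_lt(abs(am$doubling_time - p$Delta / p$v) / (p$Delta / p$v), 0.05)
  ## every fragment ever produced stays below 2 Delta
  expect_true(all(unlist(tr$lengths) <= 2 * p$Delta + 1e-9))
  expect_true(all(c(tr$cuts$child1, tr$cuts$child2) <= 2 * p$Delta + 1e-9))
  ## final mass concentrated in [Delta, 2 Delta)
  fin <- am$final_lengths
  expect_gte(mean(fin >= p$Delta - 1e-9 & fin < 2 * p$Delta + 1e-9), 1)
})

test_that("mass is conserved exactly at every cut and counts never decrease", {
  p <- coarse_params(v = 1, Delta = 2, lambda = 0.7, t_max = 22)
  tr <- simulate_population(p, seed = 11)
  expect_gt(nrow(tr$cuts), 5)
  expect_identical(tr$cuts$child1 + tr$cuts$child2, tr$cuts$parent)
  expect_true(all(diff(tr$counts) >= 0L))
  ## total mass equals the per-ribbon sum at every sample
  expect_equal(tr$mass, vapply(tr$lengths, sum, 0))
})

test_that("identical seeds reproduce the trajectory exactly", {
  p <- coarse_params(v = 1, Delta = 1, lambda = 1.5, t_max = 12)
  t1 <- simulate_population(p, seed = 8)
  t2 <- simulate_population(p, seed = 8)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$lengths, t2$lengths)
  t3 <- simulate_population(p, seed = 9)
  expect_false(identical(t1$times, t3$times))
})

test_that("mean fragment length at fixed time is nonincreasing in the cut hazard", {
  lams <- c(0.05, 0.3, 1, 5, Inf)
  means <- vapply(lams, function(l) {
    tr <- simulate_population(coarse_params(v = 1, Delta = 1, lambda = l, t_max = 9),
                              seed = 21)
    mean(tr$lengths[[length(tr$lengths)]])
  }, 0)
  expect_true(all(diff(means) <= 1e-9))
})

test_that("invalid coarse parameters are rejected", {
  expect_error(coarse_params(v = 0), "growth rate")
  expect_error(coarse_params(Delta = -1), "cut interval")
  expect_error(coarse_params(lambda = -0.1), "cut hazard")
})

test_that("amplification metrics flag fewer than three doublings as low confidence", {
  p <- coarse_params(v = 1, Delta = 1, lambda = Inf, t_max = 2.5)
  tr <- simulate_population(p, seed = 2)
  am <- amplification_metrics(tr)
  expect_true(am$low_confidence)
})
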