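test_that("equal large counts center the ratio on the initial mix", {
  est <- ratio_posterior(rep(1000, 5), rep(1000, 5), initial_ratio = 1,
                         seed = 1)
  expect_gt(est$median, 0.9)
  expect_lt(est$median, 1.1)
  expect_gt(est$p_exc, 0.3)
  expect_lt(est$p_exc, 0.7)
})

test_that("a fourfold excess is called with overwhelming confidence", {
  est <- ratio_posterior(rep(4000, 5), rep(1000, 5), initial_ratio = 1,
                         n_draws = 20000, seed = 2)
  expect_gt(est$median, 3.6)
  expect_lt(est$median, 4.4)
  expect_lt(est$p_exc, 1e-4)  # Pr(ratio <= 1)
})

test_that("zero numerator counts give a near-zero ratio with a tight bound", {
  est <- ratio_posterior(0, 100, initial_ratio = 1, seed = 3)
  expect_lt(est$median, 0.01)
  expect_lt(est$hi90, 0.05)
  ## analytic oracle: X ~ Gamma(1/2), Y ~ Gamma(100.5) independent =>
  ## Pr(X/Y <= t) = pbeta(t / (1 + t), 1/2, 100.5); invert for the quantiles
  qratio <- function(p) {
    b <- stats::qbeta(p, 0.5, 100.5)
    b / (1 - b)
  }
  expect_equal(est$lo90, qratio(0.05), tolerance = 0.25)
  expect_equal(est$hi90, qratio(0.95), tolerance = 0.1)
  expect_equal(est$median, qratio(0.5), tolerance = 0.1)
})

test_that("all-zero denominators are an error; counts must be nonnegative", {
  expect_error(ratio_posterior(c(10, 10), c(0, 0)), "ratio undefined")
  expect_error(ratio_posterior(-1, 10), ">= 0")
})

test_that("tenfold larger counts narrow the interval around the same median", {
  a <- ratio_posterior(rep(200, 5), rep(100, 5), seed = 4)
  b <- ratio_posterior(rep(2000, 5), rep(1000, 5), seed = 4)
  expect_lt(b$hi90 - b$lo90, a$hi90 - a$lo90)
  expect_equal(a$median, b$median, tolerance = 0.15)
})

test_that("identical inputs and seed reproduce the estimate exactly", {
  a <- ratio_posterior(c(120, 80, 95), c(100, 90, 110), seed = 11)
  b <- ratio_posterior(c(120, 80, 95), c(100, 90, 110), seed = 11)
  expect_identical(a[c("median", "lo90", "hi90", "p_exc")],
                   b[c("median", "lo90", "hi90", "p_exc")])
})

test_that("location comparisons flag only real differences, with direction", {
  same <- lapply(c(NFB = 101, proximal = 102), function(s)
    ratio_posterior(rep(500, 5), rep(500, 5), seed = s))
  cmp <- compare_ratio_over_locations(same)
  expect_false(cmp$distinguishable)
  expect_identical(cmp$direction, "none")
  expect_gt(cmp$median, 0.8)
  expect_lt(cmp$median, 1.25)

  diff4 <- list(
    NFB = ratio_posterior(rep(2000, 5), rep(500, 5), seed = 201),
    distal = ratio_posterior(rep(500, 5), rep(500, 5), seed = 202))
  cmp4 <- compare_ratio_over_locations(diff4)
  expect_true(cmp4$distinguishable)
  expect_identical(cmp4$direction, "a_higher")

  small <- list(
    NFB = ratio_posterior(rep(500, 5), rep(500, 5), seed = 301),
    distal = ratio_posterior(rep(50, 5), rep(50, 5), seed = 302))
  w_big <- same$NFB$hi90 - same$NFB$lo90
  w_small <- small$distal$hi90 - small$distal$lo90
  expect_gt(w_small, w_big)  # fewer cells, wider interval

  bad <- list(a = ratio_posterior(10, 10, n_draws = 100, seed = 1),
              b = ratio_posterior(10, 10, n_draws = 200, seed = 1))
  expect_error(compare_ratio_over_locations(bad), "mismatched draw counts")
})

make_counts <- function(tab) {
  ## tab: list of list(replicate, time_h, strain, rods, tcs, spores)
  do.call(rbind, lapply(tab, function(r) tibble::tibble(
    replicate = r$replicate, time_h = r$time_h, strain = r$strain,
    class = c("rod", "transitioning", "spore"),
    count = c(r$rods, r$tcs, r$spores))))
}

test_that("a 0 to 600 spore jump over 6 h gives a rate near 100 per hour", {
  counts <- make_counts(list(
    list(replicate = 1, time_h = 24, strain = "WT", rods = 900, tcs = 100,
         spores = 0),
    list(replicate = 1, time_h = 30, strain = "WT", rods = 300, tcs = 100,
         spores = 600)))
  est <- estimate_rates(counts, seed = 5)
  spor <- est$summary[est$summary$measure == "sporulation", ]
  expect_equal(spor$median, 100, tolerance = 2)
  expect_equal(spor$midpoint_h, 27)
})

test_that("constant counts center both rates near zero", {
  counts <- make_counts(list(
    list(replicate = 1, time_h = 24, strain = "WT", rods = 500, tcs = 50,
         spores = 200),
    list(replicate = 1, time_h = 30, strain = "WT", rods = 500, tcs = 50,
         spores = 200)))
  est <- estimate_rates(counts, seed = 6)
  expect_true(all(est$summary$median < 0.5))  # Jeffreys floor, ~0.08 cells/h
})

test_that("no posterior draw sporulates more cells than existed", {
  counts <- make_counts(list(
    list(replicate = 1, time_h = 30, strain = "WT", rods = 50, tcs = 10,
         spores = 500),
    list(replicate = 1, time_h = 36, strain = "WT", rods = 0, tcs = 0,
         spores = 560)))
  est <- estimate_rates(counts, n_draws = 5000, seed = 7)
  expect_true(all(est$draws$WT$sporulation <= est$draws$WT$pool + 1e-9))
})

test_that("non-monotone replicates trigger a warning and a flag", {
  counts <- make_counts(list(
    list(replicate = 1, time_h = 24, strain = "WT", rods = 100, tcs = 0,
         spores = 500),
    list(replicate = 1, time_h = 30, strain = "WT", rods = 100, tcs = 0,
         spores = 300)))  # spores dropped by 200 >> Poisson noise
  expect_warning(est <- estimate_rates(counts, seed = 8), "monotonicity")
  expect_true(all(est$summary$flagged))
})

test_that("rate comparisons are symmetric, complementary, and decisive", {
  sym_counts <- make_counts(list(
    list(replicate = 1, time_h = 24, strain = "WT", rods = 800, tcs = 100,
         spores = 0),
    list(replicate = 1, time_h = 30, strain = "WT", rods = 500, tcs = 100,
         spores = 250),
    list(replicate = 1, time_h = 24, strain = "csgA", rods = 800, tcs = 100,
         spores = 0),
    list(replicate = 1, time_h = 30, strain = "csgA", rods = 500, tcs = 100,
         spores = 250)))
  est <- estimate_rates(sym_counts, seed = 9)
  p <- compare_rates(est, "csgA", "WT", measure = "sporulation")$p
  expect_gt(p, 0.4)
  expect_lt(p, 0.6)
  p_rev <- compare_rates(est, "WT", "csgA", measure = "sporulation")$p
  expect_equal(p + p_rev, 1)

  two_x <- make_counts(list(
    list(replicate = 1, time_h = 24, strain = "WT", rods = 20000, tcs = 0,
         spores = 0),
    list(replicate = 1, time_h = 30, strain = "WT", rods = 15000, tcs = 0,
         spores = 5000),
    list(replicate = 1, time_h = 24, strain = "csgA", rods = 20000, tcs = 0,
         spores = 0),
    list(replicate = 1, time_h = 30, strain = "csgA", rods = 10000, tcs = 0,
         spores = 10000)))
  est2 <- estimate_rates(two_x, seed = 10)
  expect_gt(compare_rates(est2, "csgA", "WT", measure = "sporulation")$p, 0.99)
  expect_error(compare_rates(est2, "csgA", "WT", intervals = 99),
               "no overlapping intervals")
})

test_that("credible intervals are equal-tailed on an analytic Gamma case", {
  ## single replicate, sporulation increment 50: rate posterior is
  ## Gamma(50.5, 1) / 6 capped by a much larger pool, so quantiles must match
  ## the Gamma quantiles to Monte-Carlo accuracy
  counts <- make_counts(list(
    list(replicate = 1, time_h = 24, strain = "WT", rods = 100000, tcs = 0,
         spores = 0),
    list(replicate = 1, time_h = 30, strain = "WT", rods = 99950, tcs = 0,
         spores = 50)))
  est <- estimate_rates(counts, n_draws = 40000, seed = 12)
  spor <- est$summary[est$summary$measure == "sporulation", ]
  expect_equal(spor$lo90, stats::qgamma(0.05, 50.5) / 6, tolerance = 0.05)
  expect_equal(spor$hi90, stats::qgamma(0.95, 50.5) / 6, tolerance = 0.05)
  expect_equal(spor$median, stats::qgamma(0.5, 50.5) / 6, tolerance = 0.05)
})
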