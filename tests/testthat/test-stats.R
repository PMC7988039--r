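test_that("exact binomial tails match closed forms", {
  expect_equal(binomial_test(10, 10, 0.5), 0.5^10, tolerance = 1e-12)
  expect_equal(binomial_test(0, 48, 0.5), 1)
  expect_lt(binomial_test(89, 96, 0.25), 0.01)
  expect_equal(binomial_test(24, 48, 0.5), 0.5572833, tolerance = 1e-6)
  expect_error(binomial_test(5, 4, 0.5))
  expect_error(binomial_test(2, 4, 0))
})

test_that("tail sums match brute-force outcome enumeration", {
  # enumerate every binary outcome sequence; fully independent of the
  # binomial-coefficient route used by the implementation
  brute <- function(k, n, p) {
    grid <- expand.grid(rep(list(c(0, 1)), n))
    succ <- rowSums(grid)
    prob <- p^succ * (1 - p)^(n - succ)
    sum(prob[succ >= k])
  }
  for (cs in list(c(3, 5, 0.5), c(7, 9, 0.25), c(6, 12, 0.5),
                  c(10, 16, 0.25))) {
    expect_equal(binomial_test(cs[1], cs[2], cs[3]),
                 brute(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  }
  # and against the stats-package implementation for larger n
  for (cs in list(c(30, 48, 0.5), c(89, 96, 0.25), c(56, 96, 0.25))) {
    expect_equal(binomial_test(cs[1], cs[2], cs[3]),
                 stats::binom.test(cs[1], cs[2], cs[3],
                                   alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
})

test_that("two-sided p-values match the minlike convention", {
  for (cs in list(c(30, 48, 0.5), c(89, 96, 0.25), c(10, 48, 0.25))) {
    expect_equal(binomial_test(cs[1], cs[2], cs[3], "two_sided"),
                 stats::binom.test(cs[1], cs[2], cs[3])$p.value,
                 tolerance = 1e-9)
  }
})

test_that("case summaries reproduce the matching analysis", {
  tr <- simulate_trials("AF", 96, 1.0, 4, seed = 7)
  s <- summarize_case(tr)
  expect_equal(s$accuracy, 1)
  expect_equal(s$p_value, 0.25^96, tolerance = 1e-9)
  expect_true(s$significant)
  expect_equal(s$chance_level, 0.25)

  tr2 <- simulate_trials("WF", 48, 0.5, 2, seed = 3)
  tr2$correct <- rep(c(TRUE, FALSE), 24)  # force 24 of 48
  s2 <- summarize_case(tr2)
  expect_equal(s2$accuracy, 0.5)
  expect_equal(s2$p_value, 0.5573, tolerance = 1e-4)
  expect_false(s2$significant)

  mixed <- rbind(simulate_trials("WF", 10, 0.6, 2, seed = 1),
                 simulate_trials("WF", 10, 0.6, 4, seed = 1))
  expect_error(summarize_case(mixed), "stratum")
  expect_error(summarize_case(tr[0, ]), "empty")
})

test_that("trial simulation honors its seed and probability contracts", {
  t1 <- simulate_trials("WF", 48, 0.625, 2, seed = 1)
  t2 <- simulate_trials("WF", 48, 0.625, 2, seed = 1)
  expect_identical(t1, t2)
  expect_true(all(simulate_trials("AF", 96, 1.0, 4, seed = 7)$correct))
  expect_error(simulate_trials("AF", 10, 1.5, 4), "probability")
  expect_error(simulate_trials("AF", 10, 0.5, 3), "2 or 4")
  # Monte-Carlo mean accuracy within 3 standard errors of the target
  accs <- vapply(seq_len(10000), function(s) {
    mean(simulate_trials("WF", 48, 0.625, 2, seed = s)$correct)
  }, numeric(1))
  se <- sqrt(0.625 * 0.375 / 48) / sqrt(10000)
  expect_lt(abs(mean(accs) - 0.625), 3 * se)
})

test_that("trial records round-trip through CSV", {
  tr <- simulate_trials("FB", 20, 0.583, 2, seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, f)
  expect_identical(read_trials(f), tr)
})

test_that("the exact test is conservative and powerful where expected", {
  # type-I error at the null stays at or below the nominal level
  for (cfg in list(c(48, 0.5), c(96, 0.25), c(48, 0.25), c(96, 0.5))) {
    pw <- power_curve(cfg[1], cfg[2], cfg[2], n_replicates = 10000,
                      seed = 101)
    expect_lte(pw$power, 0.05)
  }
  # certain rejection at perfect accuracy
  expect_equal(power_curve(96, 0.25, 1.0, n_replicates = 200,
                           seed = 5)$power, 1)
  # more trials never hurt (shared seed)
  grid <- seq(0.35, 0.9, by = 0.05)
  p96 <- power_curve(96, 0.25, grid, n_replicates = 3000, seed = 17)
  p48 <- power_curve(48, 0.25, grid, n_replicates = 3000, seed = 17)
  expect_true(all(p96$power >= p48$power - 0.02))
  # monotone non-decreasing in true accuracy up to Monte-Carlo noise
  expect_true(all(diff(p96$power) > -0.02))
  expect_error(power_curve(96, 0.25, 0.5, n_replicates = 50), ">= 100")
})

test_that("the high-accuracy four-alternative regime is detectable", {
  hits <- vapply(seq_len(1000), function(s) {
    tr <- simulate_trials("AF", 96, 0.927, 4, seed = 1000 + s)
    summarize_case(tr)$significant
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
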