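test_that("solve_drake inverts the forward map across the parameter grid", {
  # forward: f = mu * ln(N mu); the solver must recover mu
  for (mu in 10^seq(-9, -3, length.out = 13))
    for (N in 10^seq(6, 10, length.out = 9)) {
      if (N * mu <= exp(1)) next
      f <- mu * log(N * mu)
      expect_equal(solve_drake(f, N), mu, tolerance = 1e-8)
    }
  # the worked case N = 1e8, mu = 1e-6
  expect_equal(solve_drake(4.60517e-6, 1e8), 1e-6, tolerance = 1e-5)
})

test_that("solve_drake edge cases: zero, no root, monotonicity", {
  z <- solve_drake(0, 1e8)
  expect_equal(as.numeric(z), 0)
  expect_equal(attr(z, "flag"), "no revertants")
  expect_error(solve_drake(1e-9, 1e8), "no root")
  f <- 1e-6
  expect_gt(solve_drake(2 * f, 1e8), solve_drake(f, 1e8))
})

test_that("estimate_rate reduces to solve_drake for identical cultures", {
  ct <- culture_table(data.frame(strain = "s", revertants = rep(12L, 15),
                                 viable = rep(2e8, 15)))
  e <- estimate_rate(ct)
  expect_equal(e$mu, as.numeric(solve_drake(12 / 2e8, 2e8)))
  expect_equal(e$ci_low, e$mu)   # CI collapses to the point
  expect_equal(e$ci_high, e$mu)
})

test_that("estimate_rate median convention matches a sorting oracle", {
  for (n in c(7L, 8L)) {          # odd and even culture counts
    set.seed(n)
    r <- sample(0:40, n, replace = TRUE)
    N <- round(runif(n, 1e8, 3e8))
    ct <- culture_table(data.frame(strain = "s", revertants = r, viable = N))
    e <- estimate_rate(ct)
    f_sorted <- sort(r / N)
    f_med <- if (n %% 2 == 1) f_sorted[(n + 1) / 2]
             else mean(f_sorted[n / 2 + 0:1])
    expect_equal(e$f, f_med)
    expect_equal(e$N, median(N))
  }
})

test_that("all-zero cultures give rate 0 with a flag", {
  ct <- culture_table(data.frame(strain = "s", revertants = rep(0L, 10),
                                 viable = rep(1e8, 10)))
  e <- estimate_rate(ct)
  expect_equal(e$mu, 0)
  expect_true("no revertants" %in% e$flags)
})

test_that("estimate_rate ignores culture order and batch labels", {
  set.seed(2)
  df <- data.frame(strain = "s", batch = rep(1:2, 10),
                   revertants = rpois(20, 8), viable = round(runif(20, 1e8, 3e8)))
  e1 <- estimate_rate(culture_table(df))
  df2 <- df[sample(nrow(df)), ]
  df2$batch <- 99L
  e2 <- estimate_rate(culture_table(df2))
  expect_equal(e1[c("mu", "ci_low", "ci_high", "f", "N")],
               e2[c("mu", "ci_low", "ci_high", "f", "N")])
})

test_that("median-method recovery is within a factor 1.5 over simulations", {
  est <- vapply(1:100, function(s)
    estimate_rate(simulate_cultures(sim_config(s, mu = 1e-7)))$mu,
    numeric(1L))
  expect_lt(abs(log(median(est) / 1e-7)), log(1.5))
})

test_that("order-statistic CI ranks follow the stated formula", {
  expect_equal(ci95_median_ranks(25L), c(7L, 19L))
  r <- ci95_median_ranks(5L)
  expect_true(all(is.na(r)))
  expect_equal(attr(r, "flag"), "n too small")
  # CI always brackets the median
  set.seed(4)
  for (rep in 1:20) {
    x <- rexp(sample(6:40, 1))
    ci <- ci95_median(x)
    expect_lte(ci$low, median(x))
    expect_gte(ci$high, median(x))
  }
})

test_that("CI coverage of the true rate is at least 85% in simulation", {
  cover <- vapply(1:100, function(s) {
    e <- estimate_rate(simulate_cultures(sim_config(1000L + s, mu = 1e-7)))
    e$ci_low <= 1e-7 && e$ci_high >= 1e-7
  }, logical(1L))
  expect_gte(mean(cover), 0.85)
})

test_that("Mann-Whitney exact and approximate branches behave", {
  # disjoint samples: U = 0, exact two-sided p = 2/20
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  # identical samples: p = 1 by symmetry
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # the normal branch tracks the exact branch at n = 8
  set.seed(6)
  for (rep in 1:20) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    exact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    approx <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(exact - approx), 0.02)
    expect_equal(mann_whitney(a, b)$p, exact)
  }
})

test_that("relative rates round to 3 significant figures, half to even", {
  r <- relative_rate(6.24e-6, 1.03e-6)
  expect_equal(r$rounded, 6.06)
  expect_equal(r$raw, 6.24 / 1.03)
  expect_equal(relative_rate(5, 5)$rounded, 1)
  expect_equal(relative_rate(18900e-7, 2.99e-7)$rounded, 6320)
  expect_error(relative_rate(1, 0), "positive")
})

test_that("fluctuation_analysis assembles the per-strain report", {
  ct <- rbind(
    simulate_cultures(sim_config(51, mu = 1e-7, n_cultures = 15L), "WT"),
    simulate_cultures(sim_config(52, mu = 6e-7, n_cultures = 15L), "mut"))
  res <- fluctuation_analysis(culture_table(ct), reference = "WT")
  expect_setequal(res$strain, c("WT", "mut"))
  expect_equal(res$relative_to_reference[res$strain == "WT"], 1)
  expect_gt(res$relative_raw[res$strain == "mut"], 1)
  expect_true(all(res$ci_low <= res$mu & res$mu <= res$ci_high))
  expect_error(fluctuation_analysis(ct, reference = "absent"), "not in table")
})
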