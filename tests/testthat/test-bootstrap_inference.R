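test_that("resample_censored draws pairs from the original multiset", {
  set.seed(1)
  s <- random_censored_sample(n = 20)
  r <- resample_censored(s)
  expect_length(r$time, 20)
  orig <- paste(s$time, s$event)
  expect_true(all(paste(r$time, r$event) %in% orig))
  # size-1 sample can only reproduce itself
  s1 <- censored_sample(3.2, TRUE)
  r1 <- resample_censored(s1)
  expect_identical(r1, s1)
  # fixed seed: bit-identical resample
  set.seed(99); a <- resample_censored(s)
  set.seed(99); b <- resample_censored(s)
  expect_identical(a, b)
})

test_that("bootstrap_differences is reproducible and validates B", {
  set.seed(2)
  s1 <- random_censored_sample_with_event(n = 25)
  s2 <- random_censored_sample_with_event(n = 30)
  expect_error(bootstrap_differences(s1, s2, B = 0), "positive integer")
  b1 <- bootstrap_differences(s1, s2, B = 5, seed = 123)
  b2 <- bootstrap_differences(s1, s2, B = 5, seed = 123)
  expect_identical(b1$p_stars, b2$p_stars)
  expect_identical(b1$replicates, b2$replicates)
  expect_equal(b1$B, 5L)
  # seed = 0 derives and records a usable seed
  b0 <- bootstrap_differences(s1, s2, B = 3, seed = 0)
  expect_true(b0$seed > 0L)
  b0b <- bootstrap_differences(s1, s2, B = 3, seed = b0$seed)
  expect_identical(b0$p_stars, b0b$p_stars)
})

test_that("resampling a constant sample reproduces the observed curve", {
  s1 <- censored_sample(rep(2, 6), rep(TRUE, 6))
  s2 <- censored_sample(rep(5, 4), rep(TRUE, 4))
  b <- bootstrap_differences(s1, s2, B = 10, seed = 4)
  for (r in b$replicates) {
    expect_equal(r$levels, b$observed$levels)
    expect_equal(r$values, b$observed$values)
    expect_equal(r$p0, b$observed$p0)
  }
})

test_that("p_star_max takes the maximum over defined replicates", {
  expect_equal(p_star_max(constant_bundle(c(1, 1, 1), c(0, 0.1, 0.25))),
               0.25)
  expect_equal(p_star_max(constant_bundle(c(1, 1), c(0, 0))), 0)
  expect_equal(p_star_max(constant_bundle(1, 0.3)), 0.3)
  expect_equal(p_star_max(constant_bundle(c(1, 1), c(0.2, NA))), 0.2)
  expect_error(p_star_max(constant_bundle(1, NA)), "no replicate")
})

test_that("p_star_upper_quantile implements the upper-endpoint rule", {
  # integer case: r = 95 -> 96th order statistic
  expect_equal(p_star_upper_quantile(c(rep(0.1, 95), rep(0.2, 5)), 0.05),
               0.2)
  # non-integer case: r = 7.5 -> ceil -> 8th
  expect_equal(p_star_upper_quantile(seq(0.01, 0.10, by = 0.01), 0.25),
               0.08)
  # degenerate list
  expect_equal(p_star_upper_quantile(rep(0.3, 7), 0.05), 0.3)
  # clipped to the largest order statistic when r + 1 > B
  expect_equal(p_star_upper_quantile(c(0.1, 0.2), 0.5), 0.2)
  expect_error(p_star_upper_quantile(numeric(0), 0.05), "empty")
  expect_error(p_star_upper_quantile(c(0.1), 1.5), "alpha")
})

test_that("weighted_quantile is the left-continuous inverse weighted CDF", {
  v <- c(-4, -1, 2, 3, 4)
  w <- c(0.125, 0.25, 0.25, 0.25, 0.125)
  expect_equal(weighted_quantile(v, w, 0.25), -1)
  expect_equal(weighted_quantile(v, w, 0.5), 2)
  expect_equal(weighted_quantile(v, w, 0.975), 4)
  # equal weights reduce to order statistics
  expect_equal(weighted_quantile(1:100, rep(0.01, 100), 0.025), 3)
  expect_equal(weighted_quantile(1:100, rep(0.01, 100), 0.975), 98)
  expect_error(weighted_quantile(v, w * 2, 0.5), "sum to 1")
  expect_error(weighted_quantile(v, w[-1], 0.5), "equal length")
  expect_error(weighted_quantile(v, w, 0), "\\(0, 1\\)")
})

test_that("undefined replicates push band endpoints onto the sentinels", {
  # three defined values (-1, 2, 3) and one undefined: M = 4, both weighted
  # quantiles land on +-M at alpha = 0.05 -> both endpoints undefined
  qs <- kmdiff:::band_quantiles_int(c(-1, 2, 3, NA), B = 4, alpha = 0.05)
  expect_true(all(is.na(qs)))
  # with all replicates defined the equal-weight order statistics come back
  set.seed(8)
  x <- rnorm(100)
  qs2 <- kmdiff:::band_quantiles_int(x, B = 100, alpha = 0.05)
  expect_equal(qs2, c(order_stat_quantile(x, 0.025),
                      order_stat_quantile(x, 0.975)))
})

test_that("band_at handles core, extended and degenerate cases", {
  # degenerate: all replicates identical -> zero width, core
  bz <- constant_bundle(rep(1.5, 50), rep(0, 50))
  rz <- band_at(bz, 0.5, 0.05)
  expect_equal(rz$lower, 1.5)
  expect_equal(rz$upper, 1.5)
  expect_equal(rz$region, "core")

  # extended region: verify against a by-hand weighted computation
  vals <- seq(-2, 2, length.out = 10)
  ps <- seq(0.01, 0.10, by = 0.01)
  b <- constant_bundle(vals, ps)
  p <- 0.085  # replicates with p* in {0.09, 0.10} undefined here
  r <- band_at(b, p, alpha = 0.25)
  expect_equal(r$region, "extended")
  expect_equal(r$p_star_max, 0.10)
  expect_equal(r$p_star_1_alpha, 0.08)
  def <- vals[ps <= p]
  M <- max(abs(def)) + 1
  vv <- c(def, -M, M, -M, M)
  ww <- c(rep(1 / 10, 8), rep(0.5 / 10, 4))
  lo <- weighted_quantile(vv, ww, 0.125)
  up <- weighted_quantile(vv, ww, 0.875)
  expect_equal(r$lower, if (lo == -M) NA_real_ else lo)
  expect_equal(r$upper, if (up == M) NA_real_ else up)
  expect_equal(r$n_undefined, 2L)
  expect_error(band_at(b, 0.05, 0.25), "below p\\*")
})

test_that("band endpoints are invariant to the choice of sentinel M", {
  set.seed(21)
  s1 <- random_censored_sample_with_event(n = 30, event_prob = 0.5)
  s2 <- random_censored_sample_with_event(n = 30, event_prob = 0.5)
  b <- bootstrap_differences(s1, s2, B = 150, seed = 77)
  p1a <- p_star_upper_quantile(b$p_stars, 0.05)
  psm <- p_star_max(b)
  for (p in unique(c(p1a, (p1a + psm) / 2, psm, (psm + 1) / 2, 1))) {
    r1 <- band_at(b, p, 0.05)
    r10 <- band_at(b, p, 0.05, sentinel_inflate = 10)
    expect_identical(r1[c("lower", "upper")], r10[c("lower", "upper")])
  }
})

test_that("confidence_band flags regions and respects its invariants", {
  set.seed(31)
  s1 <- random_censored_sample_with_event(n = 40, event_prob = 0.5)
  s2 <- random_censored_sample_with_event(n = 40, event_prob = 0.5)
  b <- bootstrap_differences(s1, s2, B = 200, seed = 13)
  cb <- confidence_band(b, alpha = 0.05)
  expect_lte(cb$p_star_1_alpha, cb$p_star_max)
  tol <- 1e-12
  core <- cb$grid >= cb$p_star_max - tol
  ext <- !core & cb$grid >= cb$p_star_1_alpha - tol
  expect_identical(cb$region == "core", core)
  expect_identical(cb$region == "extended", ext)
  expect_identical(cb$region == "undefined", !core & !ext)
  ok <- !is.na(cb$lower) & !is.na(cb$upper)
  expect_true(all(cb$lower[ok] <= cb$upper[ok]))
  expect_true(all(is.na(cb$lower[cb$region == "undefined"])))
  # estimate lies inside its own band over the core region
  dd <- kmdiff:::eval_step_int(b$observed$levels, b$observed$values,
                               b$observed$p0, cb$grid)
  inc <- core & ok & !is.na(dd)
  expect_true(mean(cb$lower[inc] <= dd[inc] & dd[inc] <= cb$upper[inc]) > 0.99)
  expect_error(confidence_band(b, alpha = 1.2), "alpha")
  expect_error(confidence_band(b, grid = c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("bands are nested in alpha", {
  set.seed(41)
  s1 <- random_censored_sample_with_event(n = 35, event_prob = 0.6)
  s2 <- random_censored_sample_with_event(n = 35, event_prob = 0.6)
  b <- bootstrap_differences(s1, s2, B = 200, seed = 5)
  g <- seq(0, 1, by = 0.01)
  cb05 <- confidence_band(b, alpha = 0.05, grid = g)
  cb10 <- confidence_band(b, alpha = 0.10, grid = g)
  ok <- !is.na(cb05$lower) & !is.na(cb10$lower) &
    !is.na(cb05$upper) & !is.na(cb10$upper)
  expect_true(any(ok))
  expect_true(all(cb10$lower[ok] >= cb05$lower[ok]))
  expect_true(all(cb10$upper[ok] <= cb05$upper[ok]))
})

test_that("band at p = 1 summarises first-event-time differences", {
  set.seed(51)
  s1 <- random_censored_sample_with_event(n = 30)
  s2 <- random_censored_sample_with_event(n = 30)
  b <- bootstrap_differences(s1, s2, B = 120, seed = 6)
  cb <- confidence_band(b, alpha = 0.05, grid = 1)
  d1 <- vapply(b$replicates,
               function(r) r$values[1L], numeric(1))  # D*(1) = t*_1 - u*_1
  expect_equal(cb$lower, order_stat_quantile(d1, 0.025))
  expect_equal(cb$upper, order_stat_quantile(d1, 0.975))
})

test_that("no-event replicates are excluded from p* but add sentinel mass", {
  # 9 defined constant curves + 1 no-events marker
  b <- constant_bundle(c(1:9, NA), c(rep(0, 9), NA))
  expect_equal(b$n_no_events, 1L)
  expect_equal(p_star_max(b), 0)
  r <- band_at(b, 0.5, alpha = 0.10)
  expect_equal(r$n_undefined, 1L)
  # by-hand weighted check: M = 10, masses 1/10 each + two half-masses
  M <- 10
  vv <- c(1:9, -M, M)
  ww <- c(rep(0.1, 9), 0.05, 0.05)
  lo <- weighted_quantile(vv, ww, 0.05)
  expect_equal(r$lower, if (lo == -M) NA_real_ else lo)
  up <- weighted_quantile(vv, ww, 0.95)
  expect_equal(r$upper, if (up == M) NA_real_ else up)
})
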