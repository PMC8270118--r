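test_that("raw_proportion reproduces published proportions with a valid Wilson CI", {
  r <- raw_proportion(138, 702)
  expect_equal(round(r$proportion, 3), 0.197)
  expect_true(r$ci_lower <= r$proportion && r$proportion <= r$ci_upper)

  expect_equal(round(raw_proportion(12, 59)$proportion, 3), 0.203)
  expect_equal(round(raw_proportion(12, 140)$proportion, 3), 0.086)

  r0 <- raw_proportion(0, 50)
  expect_equal(r0$proportion, 0)
  expect_equal(r0$ci_lower, 0)
  expect_error(raw_proportion(5, 0), "positive|integers")
  expect_error(raw_proportion(10, 5), "exceed")
})

test_that("corrected_proportion: published values under both variants", {
  expect_equal(round(corrected_proportion(138, 702, 0.016, 0.47), 3), 0.365)
  expect_equal(round(corrected_proportion(138, 702, 0.016, 0.399), 3), 0.322)
  expect_equal(round(corrected_proportion(138, 702, 0.016, 0.47, "printed"), 4), 0.3407)
  expect_equal(round(corrected_proportion(138, 702, 0.016, 0.399, "printed"), 4), 0.3005)
  # Fp = Fn = 0 is the identity for either variant
  expect_equal(corrected_proportion(138, 702, 0, 0), 138 / 702)
  expect_equal(corrected_proportion(138, 702, 0, 0, "printed"), 138 / 702)
  expect_warning(out <- corrected_proportion(1, 100, 0.5, 0, "printed"), "negative")
  expect_equal(out, 0)
  expect_error(corrected_proportion(1, 10, 0.1, 1), "Fn")
})

test_that("corrected_proportion is strictly increasing in Fn when E > T*Fp", {
  fns <- seq(0, 0.9, by = 0.05)
  for (variant in c("results-consistent", "printed")) {
    vals <- vapply(fns, function(fn)
      corrected_proportion(30, 100, 0.05, fn, variant), numeric(1))
    vals <- vals[vals < 1]  # clamping at 1 flattens the tail by design
    expect_true(all(diff(vals) > 0))
  }
})

test_that("resample_null: degenerate pools, determinism, recount oracle", {
  all_in <- resample_null(rep(TRUE, 30), m = 10, reps = 50, seed = 1)
  expect_true(all(all_in$draws == 1))
  none_in <- resample_null(rep(FALSE, 30), m = 10, reps = 50, seed = 1)
  expect_true(all(none_in$draws == 0))

  a <- resample_null(rep(c(TRUE, FALSE), 50), m = 20, reps = 200, seed = 9)
  b <- resample_null(rep(c(TRUE, FALSE), 50), m = 20, reps = 200, seed = 9)
  expect_identical(a$draws, b$draws)

  expect_error(resample_null(rep(TRUE, 5), m = 6, reps = 10), "exceeds")

  # empirical probability equals a direct recount over the stored draws
  p <- empirical_probability(a, 0.45, "le")
  expect_equal(p$raw, mean(a$draws <= 0.45))
  expect_equal(p$plus_one, (sum(a$draws <= 0.45) + 1) / (a$reps + 1))
  expect_equal(empirical_probability(a, min(a$draws) - 0.01, "le")$raw, 0)
  expect_equal(empirical_probability(a, max(a$draws), "le")$raw, 1)
  expect_equal(empirical_probability(a, 0.45, "ge")$raw, mean(a$draws >= 0.45))
})

test_that("resampling null matches the hypergeometric law (small pool)", {
  K <- 38; N <- 200; m <- 20; reps <- 20000
  null <- resample_null(rep(c(TRUE, FALSE), c(K, N - K)), m = m,
                        reps = reps, seed = 13)
  for (x in c(0.1, 0.2, 0.3)) {
    q <- phyper(floor(m * x), K, N - K, m)
    emp <- empirical_probability(null, x, "le")$raw
    expect_lt(abs(emp - q), 3 * sqrt(q * (1 - q) / reps))
  }
})

test_that("fisher_exact: trivial and closed-form cases", {
  # proportionally identical rows -> p = 1
  expect_equal(fisher_exact(matrix(c(10, 20, 5, 10), 2)), 1)
  # perfectly discordant table: 2 / C(20, 10)
  expect_equal(fisher_exact(matrix(c(0, 10, 10, 0), 2)), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2)), "degenerate")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("fisher_exact agrees with enumeration oracle and stats::fisher.test", {
  set.seed(31)
  for (i in 1:60) {
    m <- matrix(rpois(4, 6) + 1, 2)
    p <- fisher_exact(m)
    expect_equal(p, fisher_oracle_two_sided(m), tolerance = 1e-9)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-7)
    expect_equal(fisher_exact(m, "less"),
                 stats::fisher.test(m, alternative = "less")$p.value,
                 tolerance = 1e-7)
  }
  # the published KK (12/140) vs GD (12/59) comparison, both sidednesses
  kk_gd <- matrix(c(12, 128, 12, 47), 2)
  expect_equal(fisher_exact(kk_gd), fisher_oracle_two_sided(kk_gd),
               tolerance = 1e-12)
  expect_equal(fisher_exact(kk_gd), stats::fisher.test(kk_gd)$p.value,
               tolerance = 1e-7)
})

test_that("Wilson CI empirical coverage is >= 93% at nominal 95% (p=0.2, n=150)", {
  set.seed(77)
  n <- 150; p <- 0.2; sims <- 2000
  hits <- vapply(rbinom(sims, n, p), function(e) {
    ci <- raw_proportion(e, n)
    ci$ci_lower <= p && p <= ci$ci_upper
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("compare_groups reports strata with BH adjustment and flags enrichment", {
  set.seed(55)
  pool <- rbinom(600, 1, 0.2) == 1
  strata <- data.frame(stratum = c("flat1", "flat2", "enriched"),
                       E = c(21, 19, 40), T = c(100, 100, 100))
  res <- compare_groups(strata, pool, Fp = 0, Fn = 0, reps = 500, seed = 2)
  expect_equal(nrow(res), 3L)
  expect_equal(res$raw_proportion, strata$E / strata$T)
  expect_true(all(res$fisher_p_bh >= res$fisher_p - 1e-12))
  # planted 2x enrichment is detected at BH-FDR 0.05; flat strata are not
  expect_lt(res$fisher_p_bh[res$stratum == "enriched"], 0.05)
  expect_gt(min(res$fisher_p_bh[res$stratum != "enriched"]), 0.05)
  expect_error(compare_groups(strata, logical(0)), "pool")
})
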