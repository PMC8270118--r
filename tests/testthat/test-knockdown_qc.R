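test_that("delta-delta-Ct basics: identity, one-cycle shift, hand example", {
  # identical Cts in both conditions -> 100%
  w <- wells_from_dct(c(3, 3, 3), c(3, 3, 3))
  expect_equal(relative_expression(w)$percent_of_control, 100)

  # target +1 cycle in knockdown -> 50%
  w <- wells_from_dct(c(4, 4, 4), c(3, 3, 3))
  expect_equal(relative_expression(w)$percent_of_control, 50)

  # dCt(kd) = {5.0, 5.1, 4.9}, dCt(ctrl) = {3,3,3} -> 100 * 2^-2 = 25%
  w <- wells_from_dct(c(5.0, 5.1, 4.9), c(3, 3, 3))
  expect_equal(relative_expression(w)$percent_of_control, 25, tolerance = 1e-12)
})

test_that("relative_expression validates its inputs", {
  w <- wells_from_dct(c(3, 3), c(3, 3))
  expect_error(relative_expression(w[w$condition == "control", ]), "knockdown")
  expect_error(relative_expression(w[w$gene_role == "target", ]), "reference")
  w$ct[1] <- -1
  expect_error(relative_expression(w), "positive")
})

test_that("plate-shift invariance: adding a constant to all Cts changes nothing", {
  set.seed(5)
  for (i in 1:20) {
    w <- simulate_qpcr(runif(1, 5, 150), n_reps = 3, noise_sd = 0.3)
    base <- relative_expression(w)
    w2 <- w; w2$ct <- w2$ct + runif(1, -5, 5)
    shifted <- relative_expression(w2)
    expect_equal(shifted$percent_of_control, base$percent_of_control,
                 tolerance = 1e-9)
    expect_equal(shifted$se_percent, base$se_percent, tolerance = 1e-9)
  }
})

test_that("efficiency_summary: means, inclusive thresholds, monotonicity", {
  rec <- data.frame(library = rep(c("GD", "KK"), c(4, 3)),
                    percent_of_control = c(10, 20, 30, 100, 20, 50, 80))
  s <- efficiency_summary(rec, thresholds = c(20, 30, 50))
  gd <- s[s$library == "GD", ]
  expect_equal(gd$mean_percent, 40)
  expect_equal(gd$p_le_20, 0.5)   # inclusive at the boundary
  expect_equal(gd$p_le_30, 0.75)
  # proportions monotone non-decreasing in threshold
  for (i in seq_len(nrow(s))) {
    expect_true(all(diff(as.numeric(s[i, c("p_le_20", "p_le_30", "p_le_50")])) >= 0))
  }
  expect_equal(efficiency_summary(data.frame(library = "KK",
                                             percent_of_control = rep(100, 5)))$p_le_30, 0)
  expect_error(efficiency_summary(rec[0, ]), "no efficiency records")
})

test_that("threshold proportions of a Beta sample match the closed-form CDF", {
  set.seed(19)
  a <- 0.574271; b <- 0.607357
  n <- 4000
  rec <- data.frame(library = "KK", percent_of_control = 100 * rbeta(n, a, b))
  s <- efficiency_summary(rec, thresholds = c(20, 30))
  for (t in c(20, 30)) {
    q <- pbeta(t / 100, a, b)
    expect_lt(abs(s[[paste0("p_le_", t)]] - q), 3 * sqrt(q * (1 - q) / n))
  }
})

test_that("compare_distributions: trivial cases and z-score standardization", {
  set.seed(8)
  x <- rnorm(30, 50, 10)
  same <- compare_distributions(x, x)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$max_qq_deviation, 0)

  shifted <- compare_distributions(x, x + 7)
  expect_equal(shifted$max_qq_deviation, 7, tolerance = 1e-9)

  for (g in shifted$z) {
    expect_equal(mean(g), 0, tolerance = 1e-9)
    expect_equal(sd(g), 1, tolerance = 1e-9)
  }

  degen <- compare_distributions(rep(5, 3), rep(5, 4))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$t_statistic))
})

test_that("Welch t matches an independent formula evaluation on random samples", {
  set.seed(21)
  for (i in 1:100) {
    a <- rnorm(sample(3:12, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    got <- compare_distributions(a, b, probs = c(0.25, 0.5, 0.75))
    want <- welch_oracle(a, b)
    expect_equal(got$t_statistic, want$t, tolerance = 1e-9)
    expect_equal(got$df, want$df, tolerance = 1e-9)
    expect_equal(got$p_value, want$p, tolerance = 1e-9)
  }
})

test_that("off_target_flag applies the margin rule", {
  expect_false(off_target_flag(20, 100))
  expect_true(off_target_flag(20, 18))
  expect_true(off_target_flag(20, 25))           # 25 <= 1.25 * 20, boundary
  expect_false(off_target_flag(20, 25, margin = 1))
  expect_error(off_target_flag(-1, 10), "positive")
})

test_that("off_target_flag isolates planted off-target lines in a 14-line panel", {
  # synthetic reconstruction of the duplicate-pair panel: two lines whose
  # paralogs drop to (or below) the target's level, twelve that do not
  set.seed(4)
  target <- runif(14, 15, 80)
  paralog <- pmin(200, target * runif(14, 2, 5))
  planted <- c(3L, 11L)
  paralog[planted] <- target[planted] * c(0.9, 0.6)
  flags <- off_target_flag(target, paralog)
  expect_identical(which(flags), planted)
})

test_that("compensation_test verdicts: none, compensation, ambiguous", {
  set.seed(12)
  wt <- c(1.00, 1.02, 0.98)
  expect_equal(compensation_test(wt, wt)$verdict, "none")

  # 2x upregulation with ~5% CV, n = 3, clean controls
  mut <- 2 * c(1.01, 0.97, 1.03)
  ctrl <- list(unrelated = list(mutant = c(0.99, 1.04, 0.98), wt = c(1.01, 0.97, 1.02)))
  res <- compensation_test(mut, wt, ctrl)
  expect_equal(res$verdict, "compensation")
  expect_equal(res$fold_change, mean(mut) / mean(wt))
  expect_lt(res$p_value, 0.01)

  # paralog up but a control shifts too -> ambiguous
  ctrl_bad <- list(unrelated = list(mutant = 3 * wt, wt = wt))
  expect_equal(compensation_test(mut, wt, ctrl_bad)$verdict, "ambiguous")

  expect_error(compensation_test(c(1, 2), wt), "3 replicates")
})

test_that("efficiency_records processes a multi-line qPCR table", {
  q1 <- simulate_qpcr(25, n_reps = 3, noise_sd = 0)
  q1$line_id <- "L1"; q1$gene_id <- "g1"; q1$library <- "GD"
  q2 <- simulate_qpcr(80, n_reps = 3, noise_sd = 0)
  q2$line_id <- "L2"; q2$gene_id <- "g2"; q2$library <- "KK"
  rec <- efficiency_records(rbind(q1, q2))
  expect_equal(nrow(rec), 2L)
  expect_equal(sort(rec$percent_of_control), c(25, 80), tolerance = 1e-9)
})
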