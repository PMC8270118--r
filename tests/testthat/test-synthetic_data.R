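fast_cfg <- function(...) {
  # small, screen-only config for unit tests
  simulation_config(n_genes = 300, n_screen_replicates = 1, n_qpcr_lines = 5,
                    n_knockout_genes = 2, ...)
}

test_that("simulation_config validates probabilities and shapes", {
  expect_error(simulation_config(n_genes = 0), "positive")
  expect_error(simulation_config(branch_probs = rep(0.2, 7)), "sum to 1")
  expect_error(simulation_config(branch_probs = rep(1 / 3, 3)), "length")
  expect_error(simulation_config(mechanism_probs = c(a = 0.5, b = 0.5)),
               "mechanism_probs")
  expect_error(simulation_config(detection_threshold = 0), "0, 100")
  expect_error(simulation_config(ct_noise_sd = -1), "ct_noise_sd")
  expect_error(simulation_config(compensation_factor = 0.5), "compensation_factor")
  expect_error(simulation_config(fp_rate = 1.5), "\\[0, 1\\]")
  expect_s3_class(simulation_config(detection_threshold = 100), "simulation_config")
})

test_that("simulate_dataset is deterministic given the seed (byte-identical files)", {
  cfg <- fast_cfg(seed = 17)
  d1 <- file.path(tempdir(), "bundle_a"); d2 <- file.path(tempdir(), "bundle_b")
  write_bundle(simulate_dataset(cfg), d1)
  write_bundle(simulate_dataset(cfg), d2)
  files <- list.files(d1)
  expect_identical(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed changes the data
  d3 <- simulate_dataset(fast_cfg(seed = 18))
  expect_false(identical(d3$truth_genes$essential,
                         simulate_dataset(cfg)$truth_genes$essential))
})

test_that("perfect detection: observed lethal fraction equals true essential fraction", {
  cfg <- fast_cfg(fp_rate = 0, detection_threshold = 100, p_40d3 = 0, seed = 5)
  b <- simulate_dataset(cfg)
  sc <- b$screens[[1]]
  expect_equal(mean(sc$phenotype == "lethal"), mean(b$truth_genes$essential))
})

test_that("no essentiality and no false positives yields zero lethal calls", {
  cfg <- fast_cfg(p_essential_per_branch = 0, fp_rate = 0, p_40d3 = 0, seed = 6)
  b <- simulate_dataset(cfg)
  expect_equal(sum(b$screens[[1]]$phenotype == "lethal"), 0L)
})

test_that("observed lethal proportion matches the closed-form expectation", {
  # E[lethal] = p_ess * P(eff <= tau) + (1 - p_ess) * fp
  # GD-only, tau = 30: P(eff <= tau) = 0.53 by construction of the Beta fit
  n <- 5000
  cfg <- simulation_config(n_genes = n, p_essential_per_branch = 0.35,
                           fp_rate = 0.016, p_40d3 = 0,
                           library_probs = c(GD = 1, KK = 0),
                           n_screen_replicates = 1, n_qpcr_lines = 0,
                           n_knockout_genes = 0, paralog_fraction = 0,
                           seed = 1)
  b <- simulate_dataset(cfg)
  expected <- 0.35 * 0.53 + 0.65 * 0.016
  obs <- mean(b$screens[[1]]$phenotype == "lethal")
  expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("40D3 artifact lines are always lethal unless recombined", {
  cfg <- fast_cfg(p_essential_per_branch = 0, fp_rate = 0, p_40d3 = 0.5,
                  p_recombined = 0.5, library_probs = c(GD = 0, KK = 1),
                  seed = 9)
  b <- simulate_dataset(cfg)
  sc <- b$screens[[1]]
  artifact <- sc$has_40D3 & !sc$recombined
  expect_true(all(sc$phenotype[artifact] == "lethal"))
  expect_true(all(sc$phenotype[!artifact] == "non-lethal"))
})

test_that("presence matrix is consistent with single-gain evolution at loss_rate 0", {
  cfg <- fast_cfg(seed = 21)
  b <- simulate_dataset(cfg)
  tr <- species_tree(b$tree, b$focal)
  ages <- assign_gene_ages(b$presence, tr)
  expect_equal(ages$branch, b$truth_genes$branch)
  expect_true(all(ages$n_inferred_losses == 0))
})

test_that("stochastic losses are recorded and never remove the focal species", {
  cfg <- fast_cfg(loss_rate = 0.2, seed = 22)
  b <- simulate_dataset(cfg)
  expect_true(all(b$presence[[b$focal]] == 1))
  tr <- species_tree(b$tree, b$focal)
  ages <- assign_gene_ages(b$presence, tr)
  expect_gt(sum(ages$n_inferred_losses), 0)
})

test_that("line conservation: called classes partition all simulated lines", {
  cfg <- fast_cfg(seed = 23)
  b <- simulate_dataset(cfg)
  sc <- b$screens[[1]]
  calls <- merge_semi_lethal(call_phenotype(sc$gfp_count, sc$nongfp_count))
  expect_equal(sum(calls == "lethal") + sum(calls == "non-lethal") +
                 sum(calls == "invalid"), nrow(sc))
  expect_equal(nrow(b$truth_genes), cfg$n_genes)
  expect_true(all(sc$gene_id %in% b$truth_genes$gene_id))
})

test_that("simulate_qpcr round-trips through relative_expression", {
  # exact with zero noise
  for (eff in c(7, 25, 50, 100, 150)) {
    w <- simulate_qpcr(eff, n_reps = 3, noise_sd = 0)
    expect_equal(relative_expression(w)$percent_of_control, eff,
                 tolerance = 1e-9)
  }
  # efficiency 50, zero noise: knockdown target is exactly +1 cycle
  w <- simulate_qpcr(50, n_reps = 2, noise_sd = 0)
  kd <- w$ct[w$gene_role == "target" & w$condition == "knockdown"]
  ctrl <- w$ct[w$gene_role == "target" & w$condition == "control"]
  expect_equal(unique(kd - mean(ctrl)), 1)
  # efficiency 100 -> ddCt of exactly 0
  w <- simulate_qpcr(100, n_reps = 2, noise_sd = 0)
  expect_equal(relative_expression(w)$ddct, 0)

  # noisy round trip within 3x the propagated SE
  w <- simulate_qpcr(25, n_reps = 3, noise_sd = 0.2, seed = 7)
  se_theory <- 25 * log(2) * sqrt(4 * 0.2^2 / 3)
  expect_lt(abs(relative_expression(w)$percent_of_control - 25), 3 * se_theory)

  expect_error(simulate_qpcr(0), "efficiency")
  expect_error(simulate_qpcr(50, n_reps = 0), "n_reps")
})

test_that("knockout table plants compensation only above the similarity threshold", {
  cfg <- simulation_config(n_genes = 300, n_screen_replicates = 1,
                           n_qpcr_lines = 5, paralog_fraction = 1,
                           n_knockout_genes = 20, compensation_factor = 3,
                           expression_cv = 0.02, seed = 31)
  b <- simulate_dataset(cfg)
  ko <- b$knockout
  for (g in unique(ko$mutant_gene)) {
    sim <- b$truth_genes$similarity[b$truth_genes$gene_id == g]
    par <- ko[ko$mutant_gene == g & ko$gene_role == "paralog", ]
    fold <- mean(par$expression[par$condition == "mutant"]) /
      mean(par$expression[par$condition == "wt"])
    if (sim >= cfg$compensation_similarity) {
      expect_gt(fold, 2)
    } else {
      expect_lt(abs(fold - 1), 0.25)
    }
  }
})
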