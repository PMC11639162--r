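test_that("the composition generator honors its constraints", {
  cfg <- simulation_config(n_samples = 200, n_taxa = 12,
                           sequencing_depth = 5000, seed = 21)
  g <- simulate_composition(cfg)
  expect_equal(unname(rowSums(g$counts$counts)), rep(5000, 200))
  expect_true(all(g$composition$X > 0))
  expect_equal(rowSums(g$composition$X), setNames(rep(1, 200),
               g$composition$sample_ids), tolerance = 1e-12)
  # same seed, same output
  g2 <- simulate_composition(cfg)
  expect_identical(g$counts$counts, g2$counts$counts)
})

test_that("a concentrated Dirichlet gives near-uniform mean abundances", {
  K <- 10
  cfg <- simulation_config(n_samples = 400, n_taxa = K,
                           dirichlet_alpha = 1000, seed = 22)
  g <- simulate_composition(cfg)
  mra <- colMeans(g$composition$X)
  # var of one coordinate ~ (1/K)(1-1/K)/(K*1000+1); 3 MC SEs
  se <- sqrt((1 / K) * (1 - 1 / K) / (K * 1000 + 1) / 400)
  expect_true(all(abs(mra - 1 / K) < 3 * se + 1e-4))
})

test_that("survival generation hits the target censoring rate", {
  for (cr in c(0.2, 0.5)) {
    cfg <- simulation_config(n_samples = 500, censoring_rate = cr,
                             seed = 23)
    sim <- simulate_dataset(cfg)
    expect_lt(abs(mean(1 - sim$outcome$event) - cr), 0.05)
    expect_true(all(sim$outcome$time > 0))
  }
  cfg0 <- simulation_config(n_samples = 100, censoring_rate = 0, seed = 24)
  expect_true(all(simulate_dataset(cfg0)$outcome$event == 1))
})

test_that("datasets reproduce exactly from (config, seed)", {
  cfg <- simulation_config(seed = 25)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$outcome$time, s2$outcome$time)
  expect_identical(s1$true_balance, s2$true_balance)
})

test_that("null data shows no balance-time association", {
  set.seed(26)
  hits <- replicate(50, {
    cfg <- simulation_config(n_samples = 100, gamma_true = 0,
                             censoring_rate = 0, seed = sample.int(1e6, 1))
    sim <- simulate_dataset(cfg)
    cor.test(sim$true_balance, sim$outcome$time,
             method = "kendall")$p.value < 0.01
  })
  expect_gte(mean(!hits), 0.9)
})

test_that("a strong effect separates the survival of balance halves", {
  set.seed(27)
  ok <- replicate(20, {
    cfg <- simulation_config(n_samples = 300, gamma_true = 1.5,
                             seed = sample.int(1e6, 1))
    sim <- simulate_dataset(cfg)
    hi <- sim$true_balance > median(sim$true_balance)
    sd <- survival::survdiff(
      survival::Surv(sim$outcome$time, sim$outcome$event) ~ hi)
    pchisq(sd$chisq, 1, lower.tail = FALSE) < 0.05
  })
  expect_gte(mean(ok), 0.9)
})

test_that("precision and recall follow the set arithmetic", {
  truth <- balance_spec(c(1, 2), c(3, 4))
  expect_equal(evaluate_selection(balance_spec(c(1, 2), c(3, 4)), truth),
               c(precision = 1, recall = 1))
  # orientation-agnostic
  expect_equal(evaluate_selection(balance_spec(c(3, 4), c(1, 2)), truth),
               c(precision = 1, recall = 1))
  expect_equal(evaluate_selection(balance_spec(c(1, 2), c(3, 4, 5)), truth),
               c(precision = 0.8, recall = 1))
  expect_equal(evaluate_selection(balance_spec(7, 8), truth),
               c(precision = 0, recall = 0))
})

test_that("simulated datasets round-trip through the TSV pair", {
  cfg <- simulation_config(n_samples = 30, n_taxa = 6, seed = 28)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulated_dataset(sim, dir)
  got <- read_tables(paths["counts"], paths["metadata"], "time", "event")
  expect_equal(got$counts$counts, sim$counts$counts)
  expect_equal(got$outcome$time, sim$outcome$time)
  truth <- jsonlite::fromJSON(paths[["truth"]])
  expect_equal(truth$plus, sim$counts$taxon_ids[sim$truth$plus])
})

test_that("configs validate their fields", {
  expect_error(simulation_config(planted_plus = 1, planted_minus = 1),
               "disjoint")
  expect_error(simulation_config(censoring_rate = 1), "censoring_rate")
  expect_error(simulation_config(n_taxa = 5, planted_minus = 9), "exceed")
  expect_error(simulation_config(dirichlet_alpha = -1), "positive")
})
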