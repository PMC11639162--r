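test_that("Bray-Curtis distances match direct arithmetic", {
  X <- composition(rbind(c(0.5, 0.5), c(0.25, 0.75), c(0.5, 0.5)))
  D <- bray_curtis(X)
  expect_equal(D$metric_name, "bray_curtis")
  expect_equal(unname(D$D[1, 3]), 0)              # identical rows
  expect_equal(unname(D$D[1, 2]), 0.25)           # |.25|+|.25| over 2
  expect_true(isSymmetric(D$D))
  expect_equal(unname(diag(D$D)), rep(0, 3))
  # disjoint support: distance 1
  m <- rbind(c(1, 0), c(0, 1), c(1, 0))
  D2 <- bray_curtis(m)
  expect_equal(unname(D2$D[1, 2]), 1)
  expect_true(all(D$D >= 0 & D$D <= 1))
})

test_that("Jaccard presence/absence distances match set arithmetic", {
  m <- rbind(a = c(1, 5, 0, 0),   # {1,2}
             b = c(0, 2, 3, 0),   # {2,3}
             c = c(0, 0, 0, 7),   # {4}
             d = c(2, 8, 0, 0))   # {1,2}
  tab <- count_table(m, taxon_ids = paste0("T", 1:4))
  D <- jaccard(tab)
  expect_equal(unname(D$D[1, 2]), 1 - 1 / 3)
  expect_equal(unname(D$D[1, 3]), 1)     # disjoint nonempty
  expect_equal(unname(D$D[1, 4]), 0)     # identical presence sets
  expect_true(isSymmetric(D$D))
  # empty union pair is defined as 0 with a message
  m0 <- rbind(c(0, 0, 1), c(0, 0, 0), c(0, 0, 0))
  expect_message(D0 <- jaccard(m0), "empty")
  expect_equal(unname(D0$D[2, 3]), 0)
})

test_that("Gower centering produces a centered PSD kernel", {
  # Euclidean-embeddable distances: no eigenvalue clipping needed,
  # so the centering identity (zero row sums) survives exactly
  pts <- c(0, 1, 3, 7)
  D <- abs(outer(pts, pts, "-"))
  K <- kernel_from_distance(D)   # squared line distances are Euclidean
  expect_equal(unname(rowSums(K)), rep(0, 4), tolerance = 1e-10)
  expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-10)

  expect_equal(kernel_from_distance(matrix(0, 3, 3)), matrix(0, 3, 3))

  set.seed(2)
  X <- random_composition(20, 6)
  Kb <- kernel_from_distance(bray_curtis(X))
  expect_gte(min(eigen(Kb, symmetric = TRUE)$values), -1e-10)
  expect_true(isSymmetric(Kb))
})

test_that("ACAT combination has the documented fixed points", {
  expect_equal(acat(c(0.2, 0.2)), 0.2, tolerance = 1e-12)
  expect_equal(acat(0.731), 0.731, tolerance = 1e-12)
  p <- c(0.01, 0.4, 0.9)
  expect_equal(acat(p), acat(rev(p)))   # order invariance
  expect_lt(acat(c(0.001, 0.5)), 0.05)  # driven by the strong signal
  expect_error(acat(c(0, 0.5)), "0, 1")
})

test_that("mirkat_s detects a maximally associated kernel", {
  set.seed(11)
  n <- 60
  out <- survival_outcome(rexp(n), rbinom(n, 1, 0.8))
  # the documented construction: a kernel built from the null-model
  # residuals' own outer product must be detected
  df <- data.frame(time = out$time, event = out$event)
  r <- residuals(survival::coxph(survival::Surv(time, event) ~ 1,
                                 data = df), type = "martingale")
  res <- mirkat_s(list(self = outer(r, r)), out, n_permutations = 999,
                  seed = 1)
  expect_lte(res$per_kernel_p[["self"]], 0.01)
  expect_equal(res$omnibus_p, unname(res$per_kernel_p["self"]))
})

test_that("omnibus p-value is invariant to kernel ordering", {
  set.seed(12)
  cfg <- simulation_config(n_samples = 50, n_taxa = 8, gamma_true = 0,
                           seed = 12)
  sim <- simulate_dataset(cfg)
  k1 <- kernel_from_distance(bray_curtis(
    sim$counts$counts / rowSums(sim$counts$counts)))
  k2 <- kernel_from_distance(jaccard(sim$counts))
  r12 <- mirkat_s(list(a = k1, b = k2), sim$outcome,
                  n_permutations = 499, seed = 5)
  r21 <- mirkat_s(list(b = k2, a = k1), sim$outcome,
                  n_permutations = 499, seed = 5)
  expect_equal(r12$omnibus_p, r21$omnibus_p)
  expect_equal(r12$per_kernel_p[["a"]], r21$per_kernel_p[["a"]])
})

test_that("null permutation p-values look uniform", {
  set.seed(13)
  ps <- replicate(40, {
    cfg <- simulation_config(n_samples = 40, n_taxa = 10, gamma_true = 0,
                             seed = sample.int(1e6, 1))
    sim <- simulate_dataset(cfg)
    community_test(sim$counts, sim$outcome, n_permutations = 199)$omnibus_p
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_lte(mean(ps <= 0.05), 0.2)
})

test_that("the caution gate follows the omnibus p-value", {
  mk <- function(p) structure(list(per_kernel_p = c(k = p), omnibus_p = p,
                                   statistic = c(k = 1),
                                   n_permutations = 999),
                              class = "kernel_test_result")
  expect_false(gate_warning(mk(0.03), 0.05))
  expect_true(gate_warning(mk(0.82), 0.05))
  expect_true(gate_warning(mk(0.05), 0.05))  # boundary: >= means caution
})

test_that("mirkat_s validates inputs", {
  out <- survival_outcome(1:5, rep(0, 5))
  expect_error(mirkat_s(list(diag(5)), out), "event")
  out2 <- survival_outcome(1:5, c(1, 0, 1, 0, 1))
  expect_warning(mirkat_s(list(diag(5)), out2, n_permutations = 20),
                 "permutations")
  expect_error(mirkat_s(list(diag(4)), out2, n_permutations = 199),
               "dimension")
})
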