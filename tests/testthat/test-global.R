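test_that("the V statistic is the size-weighted squared distance", {
  expect_equal(global_statistic(c(.5, .5), c(.5, .5), 10, 20), 0)
  expect_equal(global_statistic(c(0.5, 0.5, 0.5), c(0.25, 0.5, 0.75),
                                100, 100), 6.25)
  # doubling both sizes doubles V at fixed distance
  v1 <- global_statistic(c(.3, .1), c(.2, .4), 50, 80)
  v2 <- global_statistic(c(.3, .1), c(.2, .4), 100, 160)
  expect_equal(v2, 2 * v1)
})

test_that("identical lists give V = 0, p = 1 and no rejection", {
  ann <- toy_annotation()
  fit <- compare_lists(paste0("g", 1:4), paste0("g", 1:4), ann,
                       warn_small = FALSE)
  expect_equal(fit$V, 0)
  expect_equal(fit$p_value, 1)
  expect_false(fit$reject)
  expect_equal(fit$d, 0)
  expect_equal(c(fit$ci_lower, fit$ci_upper), c(0, 0))
})

test_that("the test is symmetric in its two lists", {
  set.seed(61)
  ann <- random_annotation(60, 4)
  genes <- names(ann$mapping)
  A <- sample(genes, 35); B <- sample(genes, 30)
  f1 <- compare_lists(A, B, ann, warn_small = FALSE)
  f2 <- compare_lists(B, A, ann, warn_small = FALSE)
  expect_equal(f1$d, f2$d)
  expect_equal(f1$V, f2$V)
  expect_equal(f1$beta, f2$beta)
  expect_equal(f1$p_value, f2$p_value)
})

test_that("V / beta equals the unpooled two-proportion z^2 when s = 1", {
  # disjoint lists over one class (annotated or not): the mixture null has a
  # single weight and the test collapses to the squared z statistic
  set.seed(62)
  for (rep in 1:100) {
    n <- sample(30:200, 1); m <- sample(30:200, 1)
    a <- sample(seq(5, n - 5), 1); b <- sample(seq(5, m - 5), 1)
    mapping <- c(
      stats::setNames(rep(list("A1"), a), paste0("ga", seq_len(a))),
      stats::setNames(rep(list(character()), n - a),
                      paste0("gu", seq_len(n - a))),
      stats::setNames(rep(list("A1"), b), paste0("hb", seq_len(b))),
      stats::setNames(rep(list(character()), m - b),
                      paste0("hu", seq_len(m - b))))
    ann <- annotation_index(mapping, "A1")
    A <- grep("^g", names(mapping), value = TRUE)
    B <- grep("^h", names(mapping), value = TRUE)
    fit <- compare_lists(A, B, ann, include_unannotated = TRUE,
                         warn_small = FALSE)
    ph <- a / n; qh <- b / m
    z2 <- (ph - qh)^2 / (ph * (1 - ph) / n + qh * (1 - qh) / m)
    expect_equal(fit$V / fit$beta, z2, tolerance = 1e-10)
    expect_equal(fit$p_value, pchisq(z2, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("pooled covariance estimation is available behind a flag", {
  set.seed(68)
  ann <- random_annotation(100, 4, p_unannotated = 0)
  genes <- names(ann$mapping)
  A <- genes[1:55]; B <- genes[46:100]
  plug <- compare_lists(A, B, ann, warn_small = FALSE)
  pool <- compare_lists(A, B, ann, warn_small = FALSE, pooled = TRUE)
  # same statistic, different null spectrum estimate
  expect_equal(pool$V, plug$V)
  expect_equal(pool$d, plug$d)
  expect_false(isTRUE(all.equal(pool$beta, plug$beta)))
  # full-overlap degeneracy is preserved under pooling
  same <- compare_lists(A, A, ann, warn_small = FALSE, pooled = TRUE)
  expect_equal(same$p_value, 1)
})

test_that("under the null the p-value is approximately uniform", {
  set.seed(63)
  pop <- synthetic_population(8, unannotated = 0.1)
  cfg <- scenario_config(pop, pop, 120, 100, k = 30)
  B <- 2000L
  ps <- vapply(seq_len(B), function(b) {
    compare_profiles(simulate_pair(cfg), warn_small = FALSE)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("confidence interval recomputes at other levels and degenerates safely", {
  set.seed(64)
  ann <- random_annotation(80, 4)
  genes <- names(ann$mapping)
  fit <- compare_lists(sample(genes, 50), sample(genes, 45), ann,
                       warn_small = FALSE)
  ci90 <- distance_ci(fit, alpha = 0.05)
  ci99 <- distance_ci(fit, alpha = 0.005)
  expect_equal(unname(ci90["upper"] - ci90["lower"]),
               2 * qnorm(0.95) * fit$sigma_hat * sqrt(1 / fit$n + 1 / fit$m))
  expect_true(ci99["lower"] <= ci90["lower"] && ci99["upper"] >= ci90["upper"])
  expect_true(ci90["lower"] <= fit$d && fit$d <= ci90["upper"])

  # quadrupling both sizes halves the half-width at fixed profiles
  w1 <- qnorm(0.95) * fit$sigma_hat * sqrt(1 / 100 + 1 / 100)
  w2 <- qnorm(0.95) * fit$sigma_hat * sqrt(1 / 400 + 1 / 400)
  expect_equal(w1, 2 * w2)
})

test_that("approximate power behaves like a power function", {
  pop <- synthetic_population(6, unannotated = 0.1)
  alt <- perturb_population(pop, 1.0)
  cfg <- function(n) scenario_config(pop, alt, n, n, k = 0)
  # monotone in alpha
  p_a <- vapply(c(0.001, 0.01, 0.05, 0.2), function(a)
    approx_power(cfg(150), alpha = a), numeric(1))
  expect_true(all(diff(p_a) > 0))
  # monotone in sample size, and -> 1 for well-separated large samples
  p_n <- vapply(c(50, 200, 800, 5000), function(n)
    approx_power(cfg(n)), numeric(1))
  expect_true(all(diff(p_n) >= 0))
  expect_gt(p_n[4], 0.999)
  # equal populations are rejected as input
  expect_error(approx_power(scenario_config(pop, pop, 50, 50)), "d = 0")
  # overlapping lists: the shared component dilutes the profile difference
  p_k0 <- approx_power(cfg(200))
  p_k <- approx_power(scenario_config(pop, alt, 200, 200, k = 80,
                                      pop_shared = pop))
  expect_gte(p_k, 0)
  expect_lte(p_k, p_k0)
})

test_that("approximate power tracks the simulated rejection rate", {
  # empirical reference: 5000 seeded replicates of the global test at
  # s = 10, n = m = 200, population distance 0.060 gave rejection rate
  # 0.9964 (frozen from the simulation oracle, seed 1101):
  #   pop <- synthetic_population(10); alt <- perturb_population(pop, 1.0)
  #   cfg <- scenario_config(pop, alt, 200, 200, k = 0); set.seed(1101)
  #   mean(replicate(5000, compare_profiles(simulate_pair(cfg))$reject))
  pop <- synthetic_population(10)
  alt <- perturb_population(pop, 1.0)
  cfg <- scenario_config(pop, alt, 200, 200, k = 0)
  expect_equal(squared_distance(contract(pop), contract(alt)), 0.05999852,
               tolerance = 1e-6)
  expect_lt(abs(approx_power(cfg) - 0.9964), 0.05)
})

test_that("empirical power is monotone along nested alternatives", {
  set.seed(66)
  pop <- synthetic_population(6, unannotated = 0.1)
  rates <- vapply(c(0.3, 0.8, 1.4), function(delta) {
    alt <- perturb_population(pop, delta)
    cfg <- scenario_config(pop, alt, 150, 150, k = 0)
    mean(vapply(1:120, function(b)
      compare_profiles(simulate_pair(cfg), warn_small = FALSE)$reject,
      logical(1)))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("results serialize to JSON and TSV", {
  set.seed(67)
  ann <- random_annotation(60, 3, p_unannotated = 0)
  genes <- names(ann$mapping)
  fit <- compare_lists(genes[1:35], genes[26:60], ann, warn_small = FALSE)
  js <- jsonlite::fromJSON(result_json(fit))
  expect_equal(js$d, fit$d)
  expect_equal(js$p_value, fit$p_value)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_result_tsv(fit, path)
  tab <- utils::read.delim(path)
  expect_equal(tab$V, fit$V)
  expect_equal(tab$n, fit$n)
})
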