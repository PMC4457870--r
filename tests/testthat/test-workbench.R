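test_that("capacity sweep accounts for every condition, trial and method", {
  sw <- run_sweep("capacity", N = 80, trials = 2, seed = 1,
                  alpha_grid = c(0.2, 0.4), max_epochs = 5000)
  expect_s3_class(sw, "data.frame")
  expect_equal(nrow(sw), 2 * 2 * 5)   # alpha x trial x method
  expect_setequal(unique(sw$method),
                  c("balanced", "max_imbalance", "minL2", "prune_smallest",
                    "prune_random"))
  expect_false(any(is.na(sw$C)))
  cfgattr <- attr(sw, "config")
  expect_equal(cfgattr$N, 80)
})

test_that("sweeps reproduce bit-identically under one master seed", {
  a <- run_sweep("capacity", N = 60, trials = 2, seed = 7, alpha_grid = 0.2)
  b <- run_sweep("capacity", N = 60, trials = 2, seed = 7, alpha_grid = 0.2)
  expect_identical(a, b)
  c2 <- run_sweep("capacity", N = 60, trials = 2, seed = 8, alpha_grid = 0.2)
  expect_false(identical(a$C, c2$C))
})

test_that("imbalance sweep curves terminate at the detected lambda_max", {
  sw <- run_sweep("imbalance", N = 100, trials = 2, seed = 3,
                  alpha_grid = 0.1, lambda_grid = seq(0, 0.6, by = 0.1),
                  max_epochs = 2000)
  for (tr in unique(sw$trial)) {
    cur <- sw[sw$trial == tr, ]
    expect_true(all(cur$converged[cur$lambda <= cur$lambda_max[1]]))
    # at most one non-convergent row (the terminating lambda)
    expect_lte(sum(!cur$converged), 1)
    expect_equal(max(cur$lambda[cur$converged]), cur$lambda_max[1])
  }
})

test_that("coding and correlation sweeps carry their grids through", {
  sw <- run_sweep("coding", N = 60, trials = 1, seed = 4, f_grid = c(0.25, 0.5),
                  alpha_grid = 0.2, max_epochs = 3000)
  expect_setequal(unique(sw$f), c(0.25, 0.5))
  expect_setequal(unique(sw$method), c("adaptive_gamma", "fixed_threshold"))

  sc <- run_sweep("correlation", N = 60, trials = 1, seed = 5, g_grid = c(0, 0.4),
                  alpha_grid = 0.2, max_epochs = 5000)
  expect_setequal(unique(sc$mode), c("homogeneous", "heterogeneous"))
  expect_equal(nrow(sc), 2 * 2 * 3)
})

test_that("noise sweep re-optimises the threshold per level", {
  sw <- run_sweep("noise", N = 60, trials = 1, seed = 6,
                  alpha_grid = 0.2, delta_grid = c(0, 0.2),
                  sigma_grid = 0.5, max_epochs = 5000)
  expect_true(all(c("delta", "sigma", "theta_star") %in% names(sw)))
  # information decreases with presynaptic distortion, per method
  for (m in unique(sw$method)) {
    rows <- sw[sw$method == m & sw$sigma == 0, ]
    expect_gte(rows$C[rows$delta == 0], rows$C[rows$delta == 0.2])
  }
})

test_that("weight histograms pool counts and zero mass conservatively", {
  expect_error(make_weight_histogram(list()), "no solutions")
  h1 <- make_weight_histogram(list(c(0, 0, 1)), bins = 4)
  expect_equal(h1$zero_mass, 2)
  expect_equal(sum(h1$counts), 1)

  set.seed(8)
  sols <- lapply(1:5, function(i) c(numeric(3), runif(7)))
  h <- make_weight_histogram(sols, bins = 10)
  expect_equal(sum(h$counts), 5 * 7)
  expect_equal(h$zero_mass, 5 * 3)
  hrev <- make_weight_histogram(rev(sols), bins = 10)
  expect_identical(h$counts, hrev$counts)    # pooling is order-invariant

  sw <- run_sweep("weight_hist", N = 60, trials = 2, seed = 9, alpha_grid = 0.2)
  sols2 <- attr(sw, "solutions")
  expect_named(sols2, c("balanced", "minL2", "max_imbalance"))
  expect_length(sols2$balanced, 2)
})

test_that("pattern sets and configurations round-trip through plain text", {
  dir <- withr::local_tempdir()
  p <- gen_correlated(20, 6, g = 0.4, mode = "heterogeneous", seed = 10)
  f <- file.path(dir, "patterns.csv")
  write_pattern_set(p, f)
  q <- read_pattern_set(f)
  expect_equal(q$x, p$x)
  expect_identical(q$coding, p$coding)
  expect_equal(q$g, p$g)
  expect_equal(q$templates[[1]], p$templates[[1]])

  cfg <- plasticity_config(epsilon = 0.01, lambda = 0.3, theta = 2, f = 0.25,
                           rule = "decay", max_epochs = 500, seed = 11)
  cf <- file.path(dir, "config.json")
  write_config(cfg, cf)
  cfg2 <- read_config(cf)
  expect_equal(cfg2[c("epsilon", "lambda", "theta", "f", "rule", "max_epochs")],
               cfg[c("epsilon", "lambda", "theta", "f", "rule", "max_epochs")])
})

test_that("fitted-model methods expose the standard interface", {
  p <- gen_patterns(100, 10, seed = 12)
  fit <- perceptron(p, lambda = 0.1, seed = 13)
  expect_identical(coef(fit), fit$w)
  expect_true(all(predict(fit, p) == 1))
  lu <- gen_lures(p, M = 50, seed = 14)
  h <- predict(fit, lu, type = "current")
  expect_length(h, 50)
  sims <- simulate(fit, nsim = 2, seed = 15)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "pattern_set")
  sm <- summary(fit, seed = 16)
  expect_s3_class(sm, "summary.perceptron")
  expect_equal(sm$metrics$p10, 0)
  expect_output(print(sm), "efficiency")
})
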