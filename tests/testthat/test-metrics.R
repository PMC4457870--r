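test_that("information per synapse matches its closed forms", {
  expect_equal(information(0, 0, K = 100, N = 1000), 0.2)   # perfect discrimination
  expect_equal(information(1, 0, K = 100, N = 1000), 0)     # uninformative output
  expect_equal(information(0.5, 0, K = 500, N = 1000), 0.311278, tolerance = 1e-6)

  # closed form at p10 = 0 equals the general binary mutual information
  for (p01 in seq(0.01, 0.99, by = 0.07)) {
    closed <- information(p01, 0, 10, 100)
    general <- sparseperceptron:::trial_information(p01, 1e-300) * 2 * 10 / 100
    expect_equal(closed, general, tolerance = 1e-8)
  }

  # strictly decreasing in p01
  grid <- seq(0, 1, by = 0.05)
  vals <- vapply(grid, information, numeric(1), p10 = 0, K = 10, N = 100)
  expect_true(all(diff(vals) < 0))
})

test_that("efficiency is information per functional synapse", {
  expect_equal(efficiency(0.3, 0.5), 0.6)
  expect_equal(efficiency(0.2, 1.0), 0.2)
  expect_gte(efficiency(0.15, 0.7), 0.15)   # S >= C since F <= 1
  expect_equal(efficiency(0, 0), 0)
  expect_error(efficiency(0.1, 0), "undefined")
})

test_that("error rates count decision failures with and without noise", {
  p <- gen_patterns(100, 20, seed = 1)
  lu <- gen_lures(p, M = 500, seed = 2)
  er0 <- error_rates(rep(0, 100), p, lu)
  expect_equal(er0$p10, 1)      # never fires
  expect_equal(er0$p01, 0)

  fit <- perceptron(p, lambda = 0.1, seed = 3)
  er <- error_rates(fit$w, p, lu)
  expect_equal(er$p10, 0)       # perfect recognition after convergence

  # overwhelming symmetric noise at theta = 0: coin-flip limit
  p2 <- gen_patterns(50, 2000, seed = 5)
  lu2 <- gen_lures(p2, M = 2000, seed = 6)
  big <- error_rates(runif(50), p2, lu2, theta = 0, sigma = 1e7, seed = 4)
  expect_lt(abs(big$p10 - 0.5), 0.05)
  expect_lt(abs(big$p01 - 0.5), 0.05)
  expect_error(error_rates(fit$w, p, gen_lures(p, M = 0)), "empty|K >= 1")
})

test_that("analytic false-positive rate matches the Gaussian tail and Monte Carlo", {
  # theta*sqrt(N)/||w||_2 = 1: half the complementary error function at 1/sqrt(2)
  w <- rep(1, 100)                          # ||w||_2 = sqrt(N) = theta*sqrt(N)
  expect_equal(fp_rate_analytic(w, theta = 1), 0.158655, tolerance = 1e-5)
  expect_equal(fp_rate_analytic(runif(50), theta = 0), 0.5)
  expect_equal(fp_rate_analytic(rep(0, 50), theta = 1), 0)
  expect_equal(fp_rate_analytic(rep(0, 50), theta = 0), 1)

  # Monte-Carlo validation across a range of weight scales
  p <- gen_patterns(500, 150, seed = 20)    # alpha = 0.3
  l2 <- solve_min_l2(p)
  lu <- gen_lures(p, M = 40000, seed = 21)
  for (scale in c(0.6, 1, 3)) {
    wsc <- l2$w * scale
    pa <- fp_rate_analytic(wsc, theta = 1)
    pe <- mean(drop(lu$x %*% wsc) - sqrt(500) >= 0)
    se <- sqrt(max(pa * (1 - pa), 1 / 40000) / 40000)
    expect_lt(abs(pa - pe), 3 * se + 0.002)
  }
})

test_that("functional-synapse counting separates true zeros from small weights", {
  w <- c(0, 0, 0.4, 0.9, 0)
  cf <- count_functional(w, mode = "threshold")
  expect_equal(cf$n_zero, 3)
  expect_equal(cf$F, 1 - 3 / 5)

  p <- gen_patterns(200, 20, seed = 30)
  l1 <- solve_min_l1(p)
  lu <- gen_lures(p, M = 5000, seed = 31)
  # threshold count is insensitive across three orders of magnitude ...
  counts <- vapply(c(1e-5, 1e-7, 1e-9), function(tol)
    count_functional(l1$w, mode = "threshold", tol = tol)$n_zero, numeric(1))
  expect_true(all(counts == counts[1]))
  # ... and agrees with the information-drop procedure
  cfd <- count_functional(l1$w, p, lu)
  expect_equal(cfd$n_zero, counts[1])

  # pruning d synapses raises the exact-zero count by exactly d
  bal <- perceptron(p, seed = 32)
  d <- 25
  pruned <- prune_smallest(bal$w, d)
  expect_equal(count_functional(pruned, mode = "threshold")$n_zero,
               count_functional(bal$w, mode = "threshold")$n_zero + d)
})

test_that("unit-threshold normalisation fixes the weakest response at one", {
  expect_equal(normalize_to_unit_threshold(c(2, 2), matrix(c(1, 1), 1)), c(0.5, 0.5))
  p <- gen_patterns(100, 10, seed = 40)
  l1 <- solve_min_l1(p)
  wn <- normalize_to_unit_threshold(l1$w, p)
  expect_equal(min(drop(p$x %*% wn)), 1)
  expect_equal(which(wn == 0), which(l1$w == 0))   # support unchanged
  expect_error(normalize_to_unit_threshold(rep(0, 100), p), "not positive")
})

test_that("compressed-exponential MLE recovers known parameters", {
  for (tc in list(c(2, 1), c(2, 1.4), c(2, 2))) {
    sm <- rcompexp(1e5, c = tc[1], beta = tc[2], seed = 1)
    fit <- fit_compressed_exponential(sm)
    expect_lt(abs(fit$beta - tc[2]), 0.04)
    expect_lt(abs(fit$c - tc[1]), 0.1)
    # binned least-squares cross-check lands nearby
    fb <- fit_compressed_exponential(sm, method = "bins")
    expect_lt(abs(fb$beta - tc[2]), 0.25)
  }
  expect_error(fit_compressed_exponential(c(-1, 1)), "positive")
  expect_error(fit_compressed_exponential(runif(10)), "100 samples")
})

test_that("threshold optimisation maximises empirical information", {
  p <- gen_patterns(200, 20, seed = 50)
  lu <- gen_lures(p, M = 2000, seed = 51)
  fit <- perceptron(p, seed = 52)
  wn <- fit$w / mean(drop(p$x %*% fit$w))
  one <- optimize_threshold(wn, p, lu, grid = 0.7)
  expect_equal(one$theta, 0.7)

  grid <- seq(0.2, 3, by = 0.2)
  er <- error_rates(wn, p, lu, theta = 1)
  C_train <- information(er$p01, er$p10, 20, 200)
  opt <- optimize_threshold(wn, p, lu, grid = c(grid, 1))
  expect_gte(opt$C, C_train)

  # complete distortion at f = 1/2: patterns become lures, no information
  ns <- noise_spec(delta01 = 0.5, delta10 = 0.5)
  lun <- gen_lures(p, M = 2000, noise = ns, seed = 53)
  opt2 <- optimize_threshold(wn, p, lun, noise = ns, grid = grid, seed = 54)
  expect_lt(opt2$C, 0.02)
})

test_that("smallest-value pruning dominates random pruning on average", {
  set.seed(60)
  gain <- replicate(8, {
    p <- gen_patterns(200, 20)
    lu <- gen_lures(p, M = 1000)
    bal <- perceptron(p)
    d <- round(0.4 * sum(bal$w > 0))
    ws <- prune_smallest(bal$w, d)
    wr <- prune_random(bal$w, d)
    ers <- error_rates(ws, p, lu); err <- error_rates(wr, p, lu)
    information(ers$p01, ers$p10, 20, 200) - information(err$p01, err$p10, 20, 200)
  })
  expect_gt(mean(gain), 0)
})
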