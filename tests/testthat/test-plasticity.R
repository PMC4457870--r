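test_that("config reparameterisation (a, b) <-> (epsilon, lambda) is consistent", {
  cfg <- plasticity_config(a = 0.05, b = 0.15)
  expect_equal(cfg$epsilon, 0.1)
  expect_equal(cfg$lambda, 0.5)
  cfg2 <- plasticity_config(epsilon = 0.1, lambda = 0.5)
  expect_equal(cfg2$a, 0.05)
  expect_equal(cfg2$b, 0.15)
  expect_equal(plasticity_config(a = 0.1, b = 0.1)$lambda, 0)  # a = b <=> balanced
  expect_error(plasticity_config(epsilon = 0.1, lambda = 1.5), "lambda")
  expect_error(plasticity_config(epsilon = -1), "positive")
})

test_that("postsynaptic current matches its closed forms", {
  expect_equal(postsynaptic_current(rep(0, 4), c(1, 1, -1, -1), theta = 1), -2)
  expect_equal(postsynaptic_current(c(1, 1), c(1, -1), theta = 1), -sqrt(2))
  expect_error(postsynaptic_current(c(1, 1), c(1, -1, 1)), "length")
  expect_error(postsynaptic_current(c(-1, 1), c(1, -1)), "non-negative")
})

test_that("adaptive-threshold 0/1 current equals the zero-mean current", {
  # h = sum w x - f sum w - theta_f sqrt(N) is the zero-mean current in
  # disguise (x = z + f); algebraic identity for any w
  set.seed(10)
  for (f in c(0.25, 0.5, 0.8)) {
    w <- runif(40)
    x01 <- rbinom(40, 1, f)
    h_bin <- postsynaptic_current(w, x01, theta = 1.3, coding = "binary01", f = f)
    h_zm <- postsynaptic_current(w, x01 - f, theta = 1.3, coding = "zeromean", f = f)
    expect_equal(h_bin, h_zm, tolerance = 1e-12)
  }
})

test_that("single plasticity events follow the update rule", {
  cfg0 <- plasticity_config(epsilon = 0.1, lambda = 0, theta = 1)
  w1 <- plasticity_step(c(0, 0, 0), c(1, -1, 1), cfg0)
  expect_equal(w1, c(0.1, 0, 0.1))  # depression rectified at the zero bound

  cfg5 <- plasticity_config(epsilon = 0.1, lambda = 0.5, theta = 1)
  w2 <- plasticity_step(c(0, 0, 0), c(1, -1, 1), cfg5)
  expect_equal(w2, c(0.05, 0, 0.05))  # delta = eps*(x - lambda)

  # decay variant, fired case: uniform decay -eps*lambda, clamped
  cfgd <- plasticity_config(epsilon = 0.1, lambda = 0.5, theta = 0, rule = "decay")
  w3 <- plasticity_step(c(0.2, 0.05), c(1, 1), cfgd)
  expect_equal(w3, c(0.15, 0))

  # stop variant leaves fired patterns untouched
  cfgs <- plasticity_config(epsilon = 0.1, lambda = 0.5, theta = 0)
  expect_equal(plasticity_step(c(0.2, 0.05), c(1, 1), cfgs), c(0.2, 0.05))
})

test_that("weights stay non-negative under any update sequence", {
  set.seed(4)
  w <- runif(30, 0, 0.05)
  cfg <- plasticity_config(epsilon = 0.07, lambda = 0.8, theta = 2, rule = "decay")
  for (i in 1:200) {
    x <- sample(c(-1, 1), 30, replace = TRUE)
    w <- plasticity_step(w, x, cfg)
    expect_true(all(w >= 0))
  }
})

test_that("a single all-high pattern is learned in exactly theta*sqrt(N)/(eps*N) updates", {
  # dyadic eps = 1/N keeps the arithmetic exact: each update adds eps*N = 1
  # to h, so the pattern fires at m = theta*sqrt(N) = 8 with w_i = 8/64
  p <- pattern_set(matrix(1, 1, 64), coding = "bipolar", f = 0.5)
  cfg <- plasticity_config(epsilon = 1 / 64, lambda = 0, theta = 1, seed = 1)
  fit <- train_online(p, cfg)
  expect_true(fit$converged)
  expect_equal(fit$updates, 8)
  expect_identical(fit$w, rep(8 / 64, 64))
  expect_identical(unname(residuals(fit)), 0)
})

test_that("balanced learning converges below capacity and stalls above lambda_max", {
  p <- gen_patterns(500, 400, seed = 15)   # alpha = 0.8
  fit <- perceptron(p, lambda = 0, seed = 16)
  expect_true(fit$converged)
  expect_true(all(residuals(fit) >= 0))

  bad <- perceptron(p, lambda = 0.99, max_epochs = 300, seed = 17)
  expect_false(bad$converged)
  expect_identical(bad$status, "not_converged")
})

test_that("zeromean model at f = 1/2 reproduces the bipolar trajectory exactly", {
  # eps*(z - lam) with z = x/2 equals (eps/2)*(x - 2*lam) in floating point,
  # and the zeromean threshold is theta*sqrt(f(1-f)) = theta/2, so the two
  # parameterisations generate bitwise-identical runs under one seed
  pb <- gen_patterns(60, 8, "bipolar", seed = 21)
  pz <- pattern_set(pb$x / 2, coding = "zeromean", f = 0.5)
  for (rule in c("stop", "decay")) {
    fz <- train_online(pz, plasticity_config(epsilon = 0.02, lambda = 0.3,
                                             theta = 1, rule = rule,
                                             max_epochs = 2000, seed = 5))
    fb <- train_online(pb, plasticity_config(epsilon = 0.01, lambda = 0.6,
                                             theta = 1, rule = rule,
                                             max_epochs = 2000, seed = 5))
    expect_identical(fz$w, fb$w)
    expect_identical(fz$epochs, fb$epochs)
    expect_identical(fz$updates, fb$updates)
  }
})

test_that("0/1 model with adaptive threshold matches the zero-mean model run for run", {
  p01 <- gen_patterns(60, 8, "binary01", f = 0.25, seed = 22)
  pz <- pattern_set(p01$x - 0.25, coding = "zeromean", f = 0.25)
  cfg <- plasticity_config(epsilon = 0.02, lambda = 0.2, theta = 1, f = 0.25,
                           max_epochs = 4000, seed = 6)
  f1 <- train_online(p01, cfg)
  f2 <- train_online(pz, cfg)
  expect_true(f1$converged)
  expect_identical(f1$w, f2$w)
  expect_identical(f1$epochs, f2$epochs)
})

test_that("energy matches its closed forms and decreases under the decay rule", {
  p <- one_pattern_set(c(1, -1))
  expect_equal(energy(c(0, 0), p, lambda = 0.5), sqrt(2))        # w = 0: K*theta*sqrt(N)
  expect_equal(energy(c(1, 0), p, lambda = 0.5), sqrt(2) - 1 + 0.5)
  p3 <- gen_patterns(100, 5, seed = 30)
  w0 <- rep(0, 100)
  fit <- perceptron(p3, lambda = 0.2, rule = "decay", seed = 31)
  expect_true(fit$converged)
  # feasible endpoint: first energy term vanishes
  expect_equal(energy(fit$w, p3, lambda = 0.2), 0.2 * sum(fit$w))
  expect_lte(energy(fit$w, p3, lambda = 0.2), energy(w0, p3, lambda = 0.2))
})
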