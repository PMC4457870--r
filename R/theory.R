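# Convergence theory for imbalanced one-class perceptron learning, and the
# empirical estimation of the critical imbalance lambda_max.

#' Convergence bound for imbalanced perceptron learning
#'
#' Evaluates the lower bound on the cosine
#' `a(m) = w* . w(m) / (||w*||_2 ||w(m)||_2)` between the learned weights
#' after `m` plasticity events and a reference solution `w*` that stores all
#' patterns with margin `kappa` at threshold `(theta + kappa) * sqrt(N)`.
#' The bound has the form `a(m) > sqrt(eps * m * N) * U / (l2_star *
#' sqrt(V))` with
#' `U = kappa/sqrt(N) - lambda*|w*|/N - eps*(1 + 2*lambda*q + lambda^2*q)/2 -
#' q*eps*(1 + lambda)^2` and
#' `V = 2*theta/sqrt(N) + eps*(1 + 2*lambda*q + lambda^2*q) +
#' 2*q*eps*(1 + lambda)^2`, where `q` is the maximal fraction of low inputs
#' across the patterns.  Learning is guaranteed to converge iff `U > 0`
#' (since `a(m) <= 1` by Cauchy-Schwarz, the bound exceeding 1 forces the
#' dynamics to stop); the smallest such `m` is
#' `m_star = l2_star^2 * V / (eps * N * U^2)`.  At `lambda = 0`, `U > 0`
#' reduces to the balanced small-learning-rate condition
#' `eps < 2*kappa / (sqrt(N) * (1 + 2*q))`.
#'
#' @param epsilon learning rate.
#' @param theta threshold parameter of the learning dynamics.
#' @param lambda imbalance.
#' @param kappa margin of the reference solution (>= 0).
#' @param l1_star,l2_star linear and Euclidean norms of the reference
#'   solution `w*`.
#' @param q maximal fraction of low inputs across patterns, in \[0, 1\].
#' @param N number of synapses.
#' @param m optional update count(s) at which to evaluate the bound.
#' @return A list of class `convergence_bound`: `guaranteed` (U > 0), `U`,
#'   `V`, `m_star` (NA when not guaranteed), `bound` (a function of m), and
#'   `a_lower_bound` (the bound evaluated at `m`, if supplied).
#' @export
convergence_bound <- function(epsilon, theta, lambda, kappa, l1_star, l2_star,
                              q, N, m = NULL) {
  if (kappa < 0 || q < 0 || q > 1 || l1_star <= 0 || l2_star <= 0 || N < 1 ||
      epsilon <= 0 || lambda < 0 || lambda > 1)
    stop("invalid convergence parameters")
  poly <- 1 + 2 * lambda * q + lambda^2 * q
  U <- kappa / sqrt(N) - lambda * l1_star / N - epsilon * poly / 2 -
    q * epsilon * (1 + lambda)^2
  V <- 2 * theta / sqrt(N) + epsilon * poly + 2 * q * epsilon * (1 + lambda)^2
  guaranteed <- U > 0
  m_star <- if (guaranteed) ceiling(l2_star^2 * V / (epsilon * N * U^2)) else NA_real_
  bound <- function(m) sqrt(epsilon * m * N) * U / (l2_star * sqrt(V))
  out <- list(guaranteed = guaranteed, U = U, V = V, m_star = m_star,
              bound = bound,
              a_lower_bound = if (!is.null(m)) bound(m) else NULL)
  class(out) <- "convergence_bound"
  out
}

#' @export
print.convergence_bound <- function(x, ...) {
  cat(sprintf("convergence bound: %s (U = %.4g)\n",
              if (x$guaranteed) sprintf("guaranteed, m* = %g updates", x$m_star)
              else "not guaranteed (numerator factor non-positive)", x$U))
  invisible(x)
}

#' Empirical critical imbalance lambda_max
#'
#' Estimates the largest imbalance for which online learning still converges
#' on a given pattern set, by training with the stop-learning rule at
#' increasing `lambda`.  With `lambda_grid` supplied, trains at each value in
#' ascending order and stops at the first non-convergent one; otherwise runs
#' a bisection to the requested resolution.  The epoch budget is part of the
#' definition of "no longer converges" and is recorded in the result.
#'
#' @param patterns a [pattern_set].
#' @param epsilon learning rate (default `1/N`).
#' @param theta threshold parameter.
#' @param lambda_grid optional increasing grid in \[0, 1\].
#' @param resolution bisection resolution when no grid is given.
#' @param max_epochs per-lambda epoch budget.
#' @param with_metrics also compute efficiency `S` at each convergent lambda
#'   (fresh `M = K` lures; threshold zero count for speed).
#' @param seed optional integer seed (presentation order and lures).
#' @return A list of class `lambda_max`: `lambda_max` (NA if even
#'   `lambda = 0` fails), `curve` (data frame: lambda, converged, epochs,
#'   updates, l1, and optionally S), `max_epochs`.
#' @export
lambda_max_empirical <- function(patterns, epsilon = NULL, theta = 1,
                                 lambda_grid = NULL, resolution = 0.01,
                                 max_epochs = 5000, with_metrics = FALSE,
                                 seed = NULL) {
  stopifnot(inherits(patterns, "pattern_set"))
  N <- ncol(patterns$x)
  epsilon <- epsilon %||% (1 / N)
  rows <- list()
  with_seed(seed, {
    lures <- if (with_metrics) gen_lures(patterns) else NULL
    try_lambda <- function(lam) {
      cfg <- plasticity_config(epsilon = epsilon, lambda = lam, theta = theta,
                               f = patterns$f, rule = "stop",
                               max_epochs = max_epochs)
      fit <- train_online(patterns, cfg)
      row <- data.frame(lambda = lam, converged = fit$converged,
                        epochs = fit$epochs, updates = fit$updates,
                        l1 = sum(fit$w))
      if (with_metrics && fit$converged) {
        mm <- memory_metrics(fit, lures = lures, count = "threshold")
        row$S <- mm$S
      } else if (with_metrics) row$S <- NA_real_
      rows[[length(rows) + 1L]] <<- row
      fit$converged
    }
    if (!is.null(lambda_grid)) {
      stopifnot(all(lambda_grid >= 0), all(lambda_grid <= 1),
                !is.unsorted(lambda_grid))
      lmax <- NA_real_
      for (lam in lambda_grid) {
        if (try_lambda(lam)) lmax <- lam else break
      }
    } else {
      if (!try_lambda(0)) {
        lmax <- NA_real_
      } else {
        lo <- 0; hi <- 1
        if (try_lambda(1)) {
          lmax <- 1
        } else {
          while (hi - lo > resolution) {
            mid <- (lo + hi) / 2
            if (try_lambda(mid)) lo <- mid else hi <- mid
          }
          lmax <- lo
        }
      }
    }
    structure(list(lambda_max = lmax, curve = do.call(rbind, rows),
                   max_epochs = max_epochs),
              class = "lambda_max")
  })
}

#' @export
print.lambda_max <- function(x, ...) {
  cat(sprintf("empirical lambda_max = %s (epoch budget %d; %d training runs)\n",
              format(x$lambda_max), x$max_epochs, nrow(x$curve)))
  invisible(x)
}
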