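#' Fit a sign-constrained one-class perceptron
#'
#' Learns (or solves for) a non-negative synaptic weight vector `w` such that
#' every stored pattern drives the neuron above its firing threshold,
#' `sum_i w_i x_i^k >= theta' * sqrt(N)` for all k.  Four routes are
#' available:
#'
#' * `"online"` — cyclic presentation with the perceptron rule under a
#'   potentiation/depression imbalance `lambda`; plasticity only acts on
#'   patterns that do not yet fire (optionally with a uniform decay when they
#'   do, `rule = "decay"`).  Imbalance biases the dynamics towards the hard
#'   bound at zero and is equivalent to stochastic subgradient descent on an
#'   L1-penalised energy, so larger `lambda` yields sparser connectivity.
#' * `"minL1"` — the offline minimum-linear-norm solution, the limit of
#'   maximal imbalance.  Solved as a linear programme via exact Tikhonov
#'   regularisation on a quadratic-programming backend.
#' * `"minL2"` — the offline minimum-Euclidean-norm solution, which maximises
#'   the pattern stability `Delta = theta*sqrt(N)/||w||_2` and hence the
#'   recognition information.
#' * `"minover"` — the min-over batch rule (always reinforce the pattern with
#'   the smallest postsynaptic sum, then rectify), which converges to the
#'   `"minL2"` stabilities.
#'
#' @param patterns a [pattern_set] of the K patterns to store.
#' @param method fitting route, see Details.
#' @param lambda imbalance in \[0, 1\] (online method).
#' @param epsilon learning rate; default `1/N`.
#' @param theta firing threshold parameter (working threshold
#'   `theta' * sqrt(N)`, see [postsynaptic_current()]).
#' @param rule `"stop"` or `"decay"` (online method).
#' @param adaptive for 0/1 coding, use the adaptive threshold `gamma`.
#' @param max_epochs epoch budget for the online method.
#' @param max_iter iteration budget for `"minover"`.
#' @param w0 optional initial weights (default tabula rasa, all zero).
#' @param seed optional integer seed (presentation order).
#' @param ridge Tikhonov parameter for the `"minL1"` solver.
#' @param ... unused.
#' @return An object of class `perceptron` with elements `w` (weights; `NULL`
#'   if the offline problem is infeasible), `method`, `theta`, `lambda`,
#'   `epsilon`, `rule`, `converged`, `status` (`"optimal"`, `"converged"`,
#'   `"not_converged"` or `"infeasible"`), `epochs`, `updates`, `objective`
#'   (solver objective value), `stabilities` (per-pattern
#'   `w.x^k / ||w||_2`), and the training `patterns`.
#' @examples
#' p <- gen_patterns(200, 20, seed = 1)
#' fit <- perceptron(p, lambda = 0.1, seed = 2)
#' fit
#' all(residuals(fit) >= 0)
#' @export
perceptron <- function(patterns,
                       method = c("online", "minL1", "minL2", "minover"),
                       lambda = 0, epsilon = NULL, theta = 1,
                       rule = c("stop", "decay"), adaptive = TRUE,
                       max_epochs = 10000, max_iter = 1e5, w0 = NULL,
                       seed = NULL, ridge = 1e-4, ...) {
  method <- match.arg(method)
  rule <- match.arg(rule)
  stopifnot(inherits(patterns, "pattern_set"))
  N <- ncol(patterns$x)
  cl <- match.call()

  fit <- switch(method,
    online = {
      cfg <- plasticity_config(epsilon = epsilon %||% (1 / N), lambda = lambda,
                               theta = theta, f = patterns$f, rule = rule,
                               max_epochs = max_epochs, seed = seed)
      train_online(patterns, cfg, adaptive = adaptive, w0 = w0)
    },
    minL1 = solve_min_l1(patterns, theta = theta, ridge = ridge),
    minL2 = solve_min_l2(patterns, theta = theta),
    minover = train_minover(patterns, theta = theta,
                            epsilon = epsilon %||% 1, max_iter = max_iter)
  )
  fit$call <- cl
  fit
}

# assemble the common fitted object
new_perceptron <- function(w, patterns, method, theta, lambda = NA_real_,
                           epsilon = NA_real_, rule = NA_character_,
                           adaptive = TRUE, converged = NA, status,
                           epochs = NA_real_, updates = NA_real_,
                           objective = NA_real_, diagnostics = NULL) {
  stab <- if (!is.null(w) && any(w > 0))
    drop(patterns$x %*% w) / sqrt(sum(w^2)) else NULL
  structure(list(w = w, method = method, theta = theta, lambda = lambda,
                 epsilon = epsilon, rule = rule, adaptive = adaptive,
                 coding = patterns$coding, f = patterns$f,
                 converged = converged, status = status, epochs = epochs,
                 updates = updates, objective = objective,
                 stabilities = stab, diagnostics = diagnostics,
                 patterns = patterns, call = NULL),
            class = "perceptron")
}

#' Online training (the perceptron plasticity rule)
#'
#' Lower-level interface behind `perceptron(method = "online")`.  Starts from
#' `w0` (default all-zero), presents the patterns in a freshly drawn random
#' order each epoch, applies the rule of `cfg`, and stops as soon as a
#' no-plasticity probe pass fires for every pattern, or at the epoch budget.
#'
#' @param patterns a [pattern_set].
#' @param cfg a [plasticity_config()]; `cfg$f` must match the pattern set.
#' @param adaptive adaptive threshold for 0/1 coding.
#' @param w0 initial weights.
#' @return A `perceptron` object (`status` `"converged"`/`"not_converged"`;
#'   `updates` counts only presentations with `h < 0`).
#' @export
train_online <- function(patterns, cfg, adaptive = TRUE, w0 = NULL) {
  stopifnot(inherits(patterns, "pattern_set"), inherits(cfg, "plasticity_config"))
  if (!isTRUE(all.equal(cfg$f, patterns$f)))
    stop("coding level mismatch between config (f = ", cfg$f,
         ") and patterns (f = ", patterns$f, ")")
  N <- ncol(patterns$x)
  eps <- cfg$epsilon %||% (1 / N)
  tp <- threshold_parts(patterns$coding, patterns$f, cfg$theta, N, adaptive)
  shift <- if (patterns$coding == "binary01") patterns$f else 0
  w0 <- w0 %||% numeric(N)
  if (length(w0) != N || any(w0 < 0)) stop("w0 must be a non-negative vector of length N")
  res <- with_seed(cfg$seed,
    .ocp_train_cpp(patterns$x, tp$thr, tp$fsum, shift, eps, cfg$lambda,
                   if (cfg$rule == "decay") 1L else 0L, cfg$max_epochs, w0))
  new_perceptron(res$w, patterns, "online", cfg$theta, lambda = cfg$lambda,
                 epsilon = eps, rule = cfg$rule, adaptive = adaptive,
                 converged = res$converged,
                 status = if (res$converged) "converged" else "not_converged",
                 epochs = res$epochs, updates = res$updates)
}

#' @export
print.perceptron <- function(x, ...) {
  N <- length(x$w %||% numeric(0))
  K <- nrow(x$patterns$x)
  cat(sprintf("one-class perceptron (%s), N = %d synapses, K = %d patterns (alpha = %.3g)\n",
              x$method, ncol(x$patterns$x), K, K / ncol(x$patterns$x)))
  if (x$status == "infeasible") {
    cat("  infeasible: no non-negative weight vector satisfies the firing constraints\n")
    return(invisible(x))
  }
  if (x$method == "online")
    cat(sprintf("  lambda = %g (%s rule), epsilon = %g, %s after %d epochs (%g updates)\n",
                x$lambda, x$rule, x$epsilon,
                if (x$converged) "converged" else "NOT converged", x$epochs, x$updates))
  nz <- sum(x$w > 0)
  cat(sprintf("  |w|_1 = %.4g, ||w||_2 = %.4g, non-zero synapses: %d/%d (F = %.3f)\n",
              sum(x$w), sqrt(sum(x$w^2)), nz, N, nz / N))
  if (!is.null(x$stabilities))
    cat(sprintf("  minimal stability Delta_min = %.4g\n", min(x$stabilities)))
  invisible(x)
}

#' @export
coef.perceptron <- function(object, ...) object$w

#' Pattern margins of a fitted perceptron
#'
#' Returns the postsynaptic currents `h_k` of the stored patterns under the
#' fitted weights (no noise): the margin of each pattern above the firing
#' threshold.  All margins are non-negative iff the memory task is solved.
#' @param object a `perceptron` fit.
#' @param ... unused.
#' @export
residuals.perceptron <- function(object, ...) {
  if (is.null(object$w)) stop("no weights: the fit is infeasible")
  postsynaptic_current(object$w, object$patterns, theta = object$theta,
                       adaptive = object$adaptive)
}

#' Predict firing responses for new patterns
#'
#' @param object a `perceptron` fit.
#' @param newdata a [pattern_set] or pattern matrix in the training coding.
#' @param type `"response"` for the 0/1 firing decision, `"current"` for the
#'   postsynaptic current `h`.
#' @param sigma postsynaptic Gaussian noise s.d. added to `h`.
#' @param seed optional seed for the noise draw.
#' @param ... unused.
#' @export
predict.perceptron <- function(object, newdata, type = c("response", "current"),
                               sigma = 0, seed = NULL, ...) {
  type <- match.arg(type)
  if (is.null(object$w)) stop("no weights: the fit is infeasible")
  h <- postsynaptic_current(object$w, newdata, theta = object$theta,
                            coding = object$coding, f = object$f,
                            adaptive = object$adaptive)
  if (sigma > 0) h <- h + with_seed(seed, rnorm(length(h), 0, sigma))
  if (type == "current") h else as.integer(h >= 0)
}

#' Simulate lure pattern sets from the fitted reference
#'
#' Draws `nsim` independent lure sets from the generative law of the training
#' patterns (same coding, coding level, templates).
#' @param object a `perceptron` fit.
#' @param nsim number of lure sets.
#' @param seed optional integer seed.
#' @param M lures per set (default K).
#' @param ... unused.
#' @return A list of [pattern_set] objects.
#' @export
simulate.perceptron <- function(object, nsim = 1, seed = NULL, M = NULL, ...) {
  with_seed(seed, lapply(seq_len(nsim), function(i)
    gen_lures(object$patterns, M = M, seed = NULL)))
}

#' Summarise a fitted perceptron
#'
#' Computes the recognition metrics of the fit against a lure set: error
#' rates, information per synapse `C`, fraction of functional synapses `F`,
#' and memory efficiency `S = C/F`.  See [memory_metrics()] for the knobs.
#'
#' @param object a `perceptron` fit.
#' @param lures optional [pattern_set] of lures; drawn fresh (M = K) if
#'   missing.
#' @param seed seed for the lure draw.
#' @param ... passed to [memory_metrics()].
#' @export
summary.perceptron <- function(object, lures = NULL, seed = NULL, ...) {
  m <- memory_metrics(object, lures = lures, seed = seed, ...)
  out <- list(fit = object, metrics = m)
  class(out) <- "summary.perceptron"
  out
}

#' @export
print.summary.perceptron <- function(x, ...) {
  print(x$fit)
  m <- x$metrics
  cat(sprintf("  p10 = %.4g, p01 = %.4g\n", m$p10, m$p01))
  cat(sprintf("  information C = %.4g bits/synapse, F = %.3f, efficiency S = %.4g bits/functional synapse\n",
              m$C, m$F, m$S))
  invisible(x)
}

#' Histogram of the fitted synaptic weights
#'
#' Plots the distribution of the non-zero weights after normalisation to unit
#' minimal pattern response, with the zero-weight (silent synapse) mass
#' reported separately in the title.
#' @param x a `perceptron` fit.
#' @param breaks passed to [graphics::hist()].
#' @param ... further plot arguments.
#' @export
plot.perceptron <- function(x, breaks = 30, ...) {
  if (is.null(x$w)) stop("no weights: the fit is infeasible")
  wn <- normalize_to_unit_threshold(x$w, x$patterns)
  nz <- wn[wn > 0]
  graphics::hist(nz, breaks = breaks, freq = FALSE,
                 main = sprintf("%s weights (silent fraction %.2f)",
                                x$method, mean(wn == 0)),
                 xlab = "normalised synaptic weight", ...)
  invisible(x)
}
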