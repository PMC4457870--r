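#' Plasticity rule configuration
#'
#' The rule is parameterised either by the potentiation/depression increments
#' `(a, b)` or by the learning rate and imbalance, `epsilon = (a + b)/2` and
#' `lambda = (b - a)/(a + b)`.  `lambda = 0` is balanced plasticity;
#' `0 < lambda <= 1` biases the rule towards depression, which acts as an L1
#' penalty on the weight vector and silences synapses.
#'
#' @param epsilon learning rate (> 0); if `NULL` it defaults to `1/N` at fit
#'   time.
#' @param lambda imbalance in \[0, 1\].
#' @param a,b alternative parameterisation (potentiation and depression
#'   increments); supply either both or neither.
#' @param theta firing threshold parameter (the working threshold is
#'   `theta * sqrt(N)` for bipolar inputs, scaled by the input standard
#'   deviation `sqrt(f(1-f))/0.5` for the other codings).
#' @param f coding level.
#' @param rule `"stop"`: no plasticity once the pattern fires; `"decay"`:
#'   uniform depression `-epsilon*lambda` also when it fires.
#' @param max_epochs presentation-cycle budget before learning is declared
#'   non-convergent.
#' @param seed optional integer seed controlling presentation order.
#' @return An object of class `plasticity_config`.
#' @export
plasticity_config <- function(epsilon = NULL, lambda = 0, a = NULL, b = NULL,
                              theta = 1, f = 0.5, rule = c("stop", "decay"),
                              max_epochs = 10000, seed = NULL) {
  rule <- match.arg(rule)
  if (!is.null(a) || !is.null(b)) {
    if (is.null(a) || is.null(b)) stop("supply both a and b, or neither")
    if (a < 0 || b < 0 || a + b <= 0) stop("a, b must be non-negative with a + b > 0")
    epsilon <- (a + b) / 2
    lambda <- (b - a) / (a + b)
  }
  if (!is.null(epsilon) && epsilon <= 0) stop("epsilon must be positive")
  if (lambda < 0 || lambda > 1) stop("imbalance lambda must lie in [0, 1]")
  if (theta < 0) stop("theta must be non-negative")
  if (f <= 0 || f >= 1) stop("coding level f must lie strictly inside (0, 1)")
  structure(list(epsilon = epsilon, lambda = lambda,
                 a = if (is.null(epsilon)) NULL else epsilon * (1 - lambda),
                 b = if (is.null(epsilon)) NULL else epsilon * (1 + lambda),
                 theta = theta, f = f, rule = rule,
                 max_epochs = as.integer(max_epochs), seed = seed),
            class = "plasticity_config")
}

#' @export
print.plasticity_config <- function(x, ...) {
  eps <- if (is.null(x$epsilon)) "1/N (set at fit time)" else format(x$epsilon)
  cat(sprintf("plasticity_config: epsilon = %s, lambda = %g (%s rule), theta = %g, f = %g\n",
              eps, x$lambda, x$rule, x$theta, x$f))
  invisible(x)
}

# Threshold bookkeeping.  The working threshold subtracted from the weighted
# sum is theta' * sqrt(N), with theta' scaled by the input standard deviation:
#   bipolar:  theta              (sd = 1)
#   zeromean: theta*sqrt(f(1-f)) (sd = sqrt(f(1-f)); equals theta/2 at f=1/2,
#             which makes the f = 1/2 model bit-identical to the bipolar one)
#   binary01: same theta' inside the adaptive threshold
#             gamma = f*sum(w) + theta'*sqrt(N); with a fixed (non-adaptive)
#             threshold the working value is theta*f*sqrt(N).
theta_eff <- function(theta, coding, f) {
  switch(coding,
         bipolar  = theta,
         zeromean = theta * sqrt(f * (1 - f)),
         binary01 = theta * sqrt(f * (1 - f)))
}

# fixed part of the threshold and the sum(w) multiplier, per coding
threshold_parts <- function(coding, f, theta, N, adaptive = TRUE) {
  if (coding == "binary01") {
    if (adaptive)
      list(thr = theta_eff(theta, coding, f) * sqrt(N), fsum = f)
    else
      list(thr = theta * f * sqrt(N), fsum = 0)
  } else {
    list(thr = theta_eff(theta, coding, f) * sqrt(N), fsum = 0)
  }
}

#' Postsynaptic current
#'
#' The net input of the neuron for one or more patterns:
#' `h = sum_i w_i x_i - theta' * sqrt(N)` for bipolar or zero-mean inputs, and
#' `h = sum_i w_i x_i - gamma` with the adaptive threshold
#' `gamma = f * sum(w) + theta' * sqrt(N)` for 0/1 inputs.  The neuron fires
#' whenever `h >= 0`.  The adaptive threshold grows with the total synaptic
#' weight, a homeostatic adjustment that makes the 0/1 model decision-for-
#' decision equivalent to the zero-mean model.
#'
#' @param w non-negative weight vector of length N.
#' @param patterns a [pattern_set], or a numeric vector/matrix of patterns
#'   (rows) in the coding given by `coding`.
#' @param theta threshold parameter.
#' @param coding,f coding and coding level when `patterns` is a bare matrix.
#' @param adaptive for 0/1 coding: use the adaptive threshold `gamma`
#'   (default) or a fixed threshold `theta * f * sqrt(N)`.
#' @return Numeric vector of currents, one per pattern.
#' @export
postsynaptic_current <- function(w, patterns, theta = 1,
                                 coding = c("bipolar", "binary01", "zeromean"),
                                 f = 0.5, adaptive = TRUE) {
  if (inherits(patterns, "pattern_set")) {
    coding <- patterns$coding
    f <- patterns$f
    X <- patterns$x
  } else {
    coding <- match.arg(coding)
    X <- if (is.matrix(patterns)) patterns else matrix(patterns, nrow = 1L)
  }
  if (ncol(X) != length(w)) stop("pattern length does not match the number of synapses")
  if (any(w < 0)) stop("weights must be non-negative")
  tp <- threshold_parts(coding, f, theta, length(w), adaptive)
  drop(X %*% w) - tp$fsum * sum(w) - tp$thr
}

#' One plasticity event
#'
#' Applies the learning rule to a single pattern presentation and returns the
#' new weight vector.  When the neuron fails to fire (`h < 0`) every synapse
#' moves by `epsilon * (s_i - lambda)` where `s_i` is the zero-mean input
#' signal (`x_i` for bipolar/zero-mean coding, `x_i - f` for 0/1 coding);
#' potentiation for high inputs, depression for low ones.  When it fires, the
#' `"stop"` rule leaves the weights untouched while the `"decay"` rule applies
#' a uniform depression `-epsilon * lambda`.  Every update is followed by
#' rectification at zero, so synapses stay excitatory.
#'
#' @param w current weight vector (non-negative).
#' @param x a single pattern (vector) in the coding of `cfg`.
#' @param cfg a [plasticity_config()].
#' @param coding input coding of `x`.
#' @param adaptive use the adaptive threshold for 0/1 coding.
#' @return The updated weight vector.
#' @export
plasticity_step <- function(w, x, cfg, coding = c("bipolar", "binary01", "zeromean"),
                            adaptive = TRUE) {
  coding <- match.arg(coding)
  stopifnot(inherits(cfg, "plasticity_config"))
  eps <- cfg$epsilon %||% (1 / length(w))
  h <- postsynaptic_current(w, x, theta = cfg$theta, coding = coding,
                            f = cfg$f, adaptive = adaptive)
  s <- if (coding == "binary01") x - cfg$f else x
  if (h < 0) {
    pmax(0, w + eps * (s - cfg$lambda))
  } else if (cfg$rule == "decay" && cfg$lambda > 0) {
    pmax(0, w - eps * cfg$lambda)
  } else {
    w
  }
}

#' Energy of a weight configuration
#'
#' The objective that the decay-variant imbalanced rule descends:
#' `E = sum_k [theta' * sqrt(N) - sum_i w_i x_i^k]_+ + lambda * sum_i w_i`.
#' The first term penalises patterns that do not yet fire in proportion to
#' their distance to threshold; the second is the L1 regulariser induced by
#' the potentiation/depression imbalance.
#'
#' @param w non-negative weight vector.
#' @param patterns a [pattern_set] (bipolar or zero-mean coding).
#' @param lambda imbalance parameter.
#' @param theta threshold parameter.
#' @return The scalar energy.
#' @export
energy <- function(w, patterns, lambda, theta = 1) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (patterns$coding == "binary01")
    stop("energy is defined for bipolar/zeromean coding; use the zeromean form")
  thr <- theta_eff(theta, patterns$coding, patterns$f) * sqrt(ncol(patterns$x))
  sum(pmax(0, thr - drop(patterns$x %*% w))) + lambda * sum(w)
}
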