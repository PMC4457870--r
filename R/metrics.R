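# Performance measures: error rates, mutual information per synapse C,
# fraction of functional synapses F, memory efficiency S = C/F, the Gaussian
# false-positive approximation, weight normalisation, and the
# compressed-exponential fit to weight distributions.

log2z <- function(p) ifelse(p > 0, log2(p), 0)  # 0*log2(0) = 0 convention

#' Empirical error rates of a weight configuration
#'
#' Presents the stored patterns and a lure set and counts decision errors:
#' `p10` is the false-negative rate (patterns that fail to fire) and `p01`
#' the false-positive rate (lures that fire).  Optional additive Gaussian
#' noise of s.d. `sigma` perturbs the postsynaptic current of every
#' presentation independently.
#'
#' @param w non-negative weight vector.
#' @param patterns stored patterns ([pattern_set]).
#' @param lures lure patterns ([pattern_set]).
#' @param theta threshold parameter.
#' @param sigma postsynaptic noise s.d. (0 = noise-free).
#' @param seed optional seed for the noise draw.
#' @param adaptive adaptive threshold for 0/1 coding.
#' @return `list(p10 = , p01 = )`.
#' @export
error_rates <- function(w, patterns, lures, theta = 1, sigma = 0, seed = NULL,
                        adaptive = TRUE) {
  stopifnot(inherits(patterns, "pattern_set"), inherits(lures, "pattern_set"))
  if (nrow(patterns$x) == 0L || nrow(lures$x) == 0L)
    stop("empty test sets")
  hp <- postsynaptic_current(w, patterns, theta = theta, adaptive = adaptive)
  hl <- postsynaptic_current(w, lures, theta = theta, adaptive = adaptive)
  if (sigma > 0) {
    noise <- with_seed(seed, rnorm(length(hp) + length(hl), 0, sigma))
    hp <- hp + noise[seq_along(hp)]
    hl <- hl + noise[length(hp) + seq_along(hl)]
  }
  list(p10 = mean(hp < 0), p01 = mean(hl >= 0))
}

#' Mutual information per synapse
#'
#' The recognition information between pattern class (stored vs lure,
#' presented with equal probability) and the firing response, accumulated
#' over `2K` test trials and normalised per synapse: `C = (2K/N) * I`.  When
#' all patterns are recognised (`p10 = 0`) the closed form
#' `C = (2K/N) * (1 - [(1 + p01) log2(1 + p01) - p01 log2 p01]/2)` applies;
#' otherwise the full binary mutual information is used.
#'
#' @param p01 false-positive rate.
#' @param p10 false-negative rate.
#' @param K number of stored patterns.
#' @param N number of synapses.
#' @return `C` in bits per synapse.
#' @export
information <- function(p01, p10 = 0, K, N) {
  stopifnot(p01 >= 0, p01 <= 1, p10 >= 0, p10 <= 1)
  (2 * K / N) * trial_information(p01, p10)
}

# per-trial mutual information between class and response (Bernoulli 1/2 prior)
trial_information <- function(p01, p10 = 0) {
  if (p10 == 0)
    return(1 - 0.5 * ((1 + p01) * log2z(1 + p01) - p01 * log2z(p01)))
  pfire <- 0.5 * (1 - p10) + 0.5 * p01
  term <- function(pr_given, pr) ifelse(pr_given > 0, pr_given * (log2z(pr_given) - log2z(pr)), 0)
  0.5 * (term(1 - p10, pfire) + term(p10, 1 - pfire)) +
    0.5 * (term(p01, pfire) + term(1 - p01, 1 - pfire))
}

#' Memory efficiency
#'
#' Information per functional (non-zero) synapse, `S = C/F`.  Under the
#' assumption that a silent synapse costs nothing and a functional one has a
#' fixed cost, `S` is the energy-aware capacity measure.
#'
#' @param C information in bits per synapse.
#' @param F_frac fraction of non-zero synapses, in (0, 1\].
#' @return `S` in bits per functional synapse.
#' @export
efficiency <- function(C, F_frac) {
  if (F_frac == 0) {
    if (C > 0) stop("efficiency undefined: C > 0 with no functional synapses")
    return(0)
  }
  if (F_frac < 0 || F_frac > 1) stop("F must lie in [0, 1]")
  C / F_frac
}

#' Analytic false-positive rate (Gaussian lure current)
#'
#' For lures uncorrelated with the weights the lure current is asymptotically
#' Gaussian; the false-positive rate follows from its mean and variance.  For
#' bipolar coding `p01 = erfc(theta*sqrt(N) / (sqrt(2)*||w||_2)) / 2`.  For
#' 0/1 coding the mean is `f|w| - gamma` and the variance
#' `f*||w||_2^2 - f^2*|w|^2/N` (the weight-distribution form); with the
#' adaptive threshold the mean reduces to `-theta'*sqrt(N)`.
#'
#' @param w non-negative weight vector.
#' @param theta threshold parameter.
#' @param coding input coding.
#' @param f coding level.
#' @param adaptive adaptive threshold for 0/1 coding.
#' @return The approximate `p01`.
#' @export
fp_rate_analytic <- function(w, theta = 1, coding = c("bipolar", "binary01", "zeromean"),
                             f = 0.5, adaptive = TRUE) {
  coding <- match.arg(coding)
  N <- length(w)
  l2sq <- sum(w^2)
  tp <- threshold_parts(coding, f, theta, N, adaptive)
  if (l2sq == 0) return(if (tp$thr > 0) 0 else 1)
  if (coding == "bipolar") {
    mu <- -tp$thr
    v <- l2sq
  } else if (coding == "zeromean") {
    mu <- -tp$thr
    v <- f * (1 - f) * l2sq
  } else {
    mu <- f * sum(w) - tp$fsum * sum(w) - tp$thr
    v <- f * l2sq - f^2 * sum(w)^2 / N
  }
  # P(h >= 0) for h ~ N(mu, v); erfc form of the Gaussian tail
  stats::pnorm(mu / sqrt(v))
}

#' Count functional synapses by the information-drop procedure
#'
#' Distinguishes truly silent synapses from small but functional ones without
#' an arbitrary cut-off: the weakest synapses are removed one by one while the
#' neuron is probed with a large lure set, until the empirical information
#' drops (beyond the binomial standard error of the probe, or any pattern
#' stops firing).  The count of removable synapses is the zero count.  A fast
#' fallback (`mode = "threshold"`) counts weights below
#' `tol * max(w)` instead.
#'
#' @param w non-negative weight vector.
#' @param patterns stored patterns.
#' @param lures lure probe set (large; the default protocol uses 100K).
#' @param theta threshold parameter.
#' @param mode `"info_drop"` (authoritative) or `"threshold"` (fallback).
#' @param tol relative tolerance of the fallback count.
#' @return `list(F = fraction of functional synapses, n_zero = count)`.
#' @export
count_functional <- function(w, patterns, lures = NULL, theta = 1,
                             mode = c("info_drop", "threshold"), tol = 1e-8) {
  mode <- match.arg(mode)
  N <- length(w)
  if (mode == "threshold" || all(w == 0)) {
    mx <- max(w)
    n_zero <- if (mx == 0) N else sum(w < tol * mx)
    return(list(F = 1 - n_zero / N, n_zero = n_zero))
  }
  stopifnot(inherits(patterns, "pattern_set"), inherits(lures, "pattern_set"))
  K <- nrow(patterns$x); M <- nrow(lures$x)
  tp <- threshold_parts(patterns$coding, patterns$f, theta, N, adaptive = TRUE)
  up <- drop(patterns$x %*% w); ul <- drop(lures$x %*% w)
  sw <- sum(w)
  ord <- order(w)                       # ascending removal
  # Decision with an absolute current guard: solver outputs place the weakest
  # pattern exactly on the margin, so cumulative rounding drift (~1e-13) from
  # removing numerically-zero weights must not register as a decision change,
  # while removing a genuine support synapse shifts currents by O(w_i).
  ntol <- 1e-7 * max(1, tp$thr)
  dec <- function(u, sw) u - tp$fsum * sw - tp$thr >= -ntol
  C0 <- information(mean(dec(ul, sw)), mean(!dec(up, sw)), K, N)
  p01_0 <- mean(dec(ul, sw))
  se <- sqrt(max(p01_0 * (1 - p01_0), 1 / M) / M)
  Cse <- abs(information(min(p01_0 + se, 1), 0, K, N) -
             information(max(p01_0 - se, 0), 0, K, N)) / 2
  n_zero <- 0L
  for (j in seq_len(N)) {
    i <- ord[j]
    if (w[i] > 0) {
      up <- up - w[i] * patterns$x[, i]
      ul <- ul - w[i] * lures$x[, i]
      sw <- sw - w[i]
    }
    p10j <- mean(!dec(up, sw)); p01j <- mean(dec(ul, sw))
    Cj <- information(p01j, p10j, K, N)
    if (p10j > 0 || Cj < C0 - max(Cse, 1e-12)) break
    n_zero <- j
  }
  list(F = 1 - n_zero / N, n_zero = n_zero)
}

#' Normalise weights to unit minimal pattern response
#'
#' Rescales `w` by `1 / min_k sum_i x_i^k w_i`, so the weakest stored pattern
#' elicits a raw response of exactly 1.  This sets a common weight scale
#' across learning rules before pooling histograms; the support, error rates
#' (against a rescaled threshold) and histogram shape are unchanged.
#'
#' @param w non-negative weight vector.
#' @param patterns the stored patterns.
#' @return The rescaled weight vector.
#' @export
normalize_to_unit_threshold <- function(w, patterns) {
  X <- if (inherits(patterns, "pattern_set")) patterns$x else as.matrix(patterns)
  s <- min(drop(X %*% w))
  if (s <= 0) stop("minimal pattern response is not positive; cannot normalise")
  w / s
}

#' Fit a compressed exponential to positive weight samples
#'
#' Maximum-likelihood fit of the density `P(w)` proportional to
#' `exp(-c * w^beta)` on `w > 0` (normalising constant
#' `c^(-1/beta) * Gamma(1 + 1/beta)`).  `beta = 1` is the exponential law,
#' `beta = 2` the hemi-Gaussian; `beta > 1` compresses the tail.  The profile
#' likelihood over `beta` is maximised with the scale solved in closed form,
#' `c_hat = n / (beta * sum(w^beta))`.  A binned least-squares fit on the log
#' histogram is available as a cross-check.
#'
#' @param samples positive weight samples (>= 100 for a stable fit).
#' @param method `"mle"` (default) or `"bins"`.
#' @param beta_range profile search interval for `beta`.
#' @param bins bin count for `method = "bins"`.
#' @return An object of class `compexp_fit` with elements `c`, `beta`,
#'   `logLik`, `n`, `method`.
#' @export
fit_compressed_exponential <- function(samples, method = c("mle", "bins"),
                                       beta_range = c(0.2, 6), bins = 60) {
  method <- match.arg(method)
  samples <- as.numeric(samples)
  if (any(samples <= 0) || any(!is.finite(samples)))
    stop("samples must be strictly positive and finite")
  n <- length(samples)
  if (n < 100) stop("at least 100 samples are required")
  s <- mean(samples)
  ws <- samples / s                     # scale-stabilised; beta is invariant
  if (method == "mle") {
    prof <- function(b) {
      chat <- n / (b * sum(ws^b))
      -n / b + (n / b) * log(chat) - n * lgamma(1 + 1 / b)
    }
    o <- optimize(prof, beta_range, maximum = TRUE, tol = 1e-8)
    beta <- o$maximum
    c_scaled <- n / (beta * sum(ws^beta))
    ll <- o$objective - n * log(s)      # back-transform the density scale
    cc <- c_scaled / s^beta
  } else {
    h <- graphics::hist(ws, breaks = bins, plot = FALSE)
    keep <- h$counts > 0
    mids <- h$mids[keep]; y <- log(h$density[keep])
    fitb <- function(b) {
      X <- cbind(1, -mids^b)
      cf <- stats::lm.fit(X, y)$coefficients
      list(rss = sum((y - X %*% cf)^2), c = cf[2L])
    }
    o <- optimize(function(b) fitb(b)$rss, beta_range, tol = 1e-8)
    beta <- o$minimum
    c_scaled <- fitb(beta)$c
    cc <- c_scaled / s^beta
    ll <- NA_real_
  }
  structure(list(c = unname(cc), beta = unname(beta), logLik = ll, n = n,
                 method = method),
            class = "compexp_fit")
}

#' @export
print.compexp_fit <- function(x, ...) {
  cat(sprintf("compressed-exponential fit (%s, n = %d): P(w) ~ exp(-c w^beta), c = %.4g, beta = %.3f\n",
              x$method, x$n, x$c, x$beta))
  invisible(x)
}

#' Draw samples from a compressed exponential
#'
#' Random deviates with density proportional to `exp(-c * w^beta)` on
#' `w > 0`, via the Gamma representation `w = (G/c)^(1/beta)` with
#' `G ~ Gamma(1/beta, 1)`.
#'
#' @param n sample count.
#' @param c,beta distribution parameters (> 0).
#' @param seed optional integer seed.
#' @export
rcompexp <- function(n, c = 1, beta = 1, seed = NULL) {
  stopifnot(c > 0, beta > 0)
  with_seed(seed, (rgamma(n, shape = 1 / beta, rate = 1) / c)^(1 / beta))
}

#' Optimise the firing threshold for information under noise
#'
#' Scans a threshold grid and returns the value maximising the empirical
#' recognition information when the stored patterns are distorted by
#' presynaptic flips and the current carries additive Gaussian noise.  The
#' currents are computed once; only the threshold moves, so one noise draw is
#' shared across the grid.
#'
#' @param w non-negative weight vector.
#' @param patterns stored patterns (distorted copies are generated here when
#'   `noise` has non-zero flip probabilities).
#' @param lures lure probe set (should be drawn with matched mean activity).
#' @param noise a [noise_spec()].
#' @param grid numeric vector of candidate `theta` values.
#' @param seed optional seed (pattern distortion and current noise).
#' @return `list(theta = , C = , grid = , C_grid = )`.
#' @export
optimize_threshold <- function(w, patterns, lures, noise = noise_spec(),
                               grid, seed = NULL) {
  stopifnot(length(grid) >= 1)
  K <- nrow(patterns$x); N <- length(w)
  with_seed(seed, {
    test_p <- if (noise$delta01 > 0 || noise$delta10 > 0)
      corrupt_patterns(patterns, noise) else patterns
    up <- drop(test_p$x %*% w)
    ul <- drop(lures$x %*% w)
    if (noise$sigma > 0) {
      up <- up + rnorm(length(up), 0, noise$sigma)
      ul <- ul + rnorm(length(ul), 0, noise$sigma)
    }
    Cs <- vapply(grid, function(th) {
      tp <- threshold_parts(patterns$coding, patterns$f, th, N, adaptive = TRUE)
      gam <- tp$fsum * sum(w) + tp$thr
      information(mean(ul >= gam), mean(up < gam), K, N)
    }, numeric(1))
    best <- which.max(Cs)
    list(theta = grid[best], C = Cs[best], grid = grid, C_grid = Cs)
  })
}

#' Full metrics report for a fitted perceptron
#'
#' Error rates against a lure set, information `C`, functional-synapse
#' fraction `F` (information-drop count by default), efficiency `S`, and the
#' weight norms.
#'
#' @param object a `perceptron` fit.
#' @param lures optional lure [pattern_set]; drawn fresh with `M` lures
#'   otherwise.
#' @param M lure count when drawing (default K).
#' @param sigma postsynaptic noise s.d. for the error rates.
#' @param count `"info_drop"` or `"threshold"` zero counting.
#' @param seed optional integer seed.
#' @return A list of class `memory_metrics`: `p01`, `p10`, `C`, `F`, `S`,
#'   `l1`, `l2`, `theta_used`, `n_zero`.
#' @export
memory_metrics <- function(object, lures = NULL, M = NULL, sigma = 0,
                           count = c("info_drop", "threshold"), seed = NULL) {
  stopifnot(inherits(object, "perceptron"))
  count <- match.arg(count)
  if (is.null(object$w)) stop("no weights: the fit is infeasible")
  p <- object$patterns
  lures <- lures %||% gen_lures(p, M = M, seed = seed)
  er <- error_rates(object$w, p, lures, theta = object$theta, sigma = sigma,
                    seed = seed, adaptive = object$adaptive)
  K <- nrow(p$x); N <- ncol(p$x)
  C <- information(er$p01, er$p10, K, N)
  cf <- count_functional(object$w, p, lures, theta = object$theta, mode = count)
  structure(list(p01 = er$p01, p10 = er$p10, C = C, F = cf$F,
                 S = efficiency(C, cf$F), l1 = sum(object$w),
                 l2 = sqrt(sum(object$w^2)), theta_used = object$theta,
                 n_zero = cf$n_zero),
            class = "memory_metrics")
}

#' @export
print.memory_metrics <- function(x, ...) {
  cat(sprintf("p10 = %.4g, p01 = %.4g | C = %.4g bps, F = %.3f, S = %.4g bpfs | |w|1 = %.4g, ||w||2 = %.4g\n",
              x$p10, x$p01, x$C, x$F, x$S, x$l1, x$l2))
  invisible(x)
}
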