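#' Input pattern sets
#'
#' A `pattern_set` holds `K` input patterns over `N` presynaptic inputs
#' together with the generative metadata needed to draw further patterns from
#' the same law (coding, coding level, correlation structure, templates).
#' Three codings are supported: `"bipolar"` inputs in \{-1, +1\} (coding level
#' fixed at f = 1/2), `"binary01"` inputs in \{0, 1\} with P(x = 1) = f, and
#' `"zeromean"` inputs in \{-f, 1 - f\} with P(x = 1 - f) = f (the zero-mean
#' form of 0/1 coding).
#'
#' @param data K x N numeric matrix, one pattern per row.
#' @param coding one of `"bipolar"`, `"binary01"`, `"zeromean"`.
#' @param f coding level (probability of the high state), in (0, 1).
#' @param g correlation parameter in \[0, 1\] (0 = independent entries).
#' @param mode correlation mode: `"none"`, `"homogeneous"` (template and its
#'   negative), or `"heterogeneous"` (a single template).
#' @param templates list of template vectors (`NULL`, one, or two vectors).
#' @param seed integer seed recorded for provenance.
#' @return An object of class `pattern_set`: a list with elements `x` (the
#'   matrix), `coding`, `f`, `g`, `mode`, `templates`, `seed`.
#' @seealso [gen_patterns()], [gen_correlated()], [corrupt_patterns()],
#'   [gen_lures()]
#' @export
pattern_set <- function(data, coding = c("bipolar", "binary01", "zeromean"),
                        f = 0.5, g = 0, mode = c("none", "homogeneous", "heterogeneous"),
                        templates = NULL, seed = NULL) {
  coding <- match.arg(coding)
  mode <- match.arg(mode)
  data <- as.matrix(data)
  if (nrow(data) < 1L || ncol(data) < 1L)
    stop("pattern matrix must have K >= 1 rows and N >= 1 columns")
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 1)
    stop("coding level f must lie strictly inside (0, 1)")
  if (coding == "bipolar" && f != 0.5)
    stop("bipolar coding fixes the coding level at f = 1/2")
  if (g < 0 || g > 1) stop("correlation parameter g must lie in [0, 1]")
  dom <- coding_states(coding, f)
  if (!all(data %in% dom))
    stop("pattern entries do not respect the '", coding, "' coding domain")
  if (mode == "homogeneous") {
    if (length(templates) != 2L || !isTRUE(all.equal(templates[[1L]], -templates[[2L]])))
      stop("homogeneous mode requires exactly two templates that are negatives of each other")
  } else if (mode == "heterogeneous") {
    if (length(templates) != 1L) stop("heterogeneous mode requires exactly one template")
  }
  structure(list(x = unname(data), coding = coding, f = f, g = g, mode = mode,
                 templates = templates, seed = seed),
            class = "pattern_set")
}

# the two attainable states (low, high) for each coding
coding_states <- function(coding, f) {
  switch(coding,
         bipolar  = c(-1, 1),
         binary01 = c(0, 1),
         zeromean = c(-f, 1 - f))
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("pattern_set: K = %d patterns, N = %d inputs, coding = %s (f = %g)\n",
              nrow(x$x), ncol(x$x), x$coding, x$f))
  if (x$mode != "none")
    cat(sprintf("  correlated (%s template model, g = %g)\n", x$mode, x$g))
  invisible(x)
}

#' @export
as.matrix.pattern_set <- function(x, ...) x$x

#' @export
dim.pattern_set <- function(x) dim(x$x)

#' Generate independent random patterns
#'
#' Draws `K` patterns of `N` independent inputs. The high state is drawn with
#' probability `f` (fixed at 1/2 for bipolar coding), each entry independently
#' of all others.
#'
#' @param N number of presynaptic inputs (>= 1).
#' @param K number of patterns (>= 1).
#' @inheritParams pattern_set
#' @param seed optional integer; a fixed seed makes the draw reproducible
#'   without touching the caller's RNG state.
#' @return A [pattern_set].
#' @examples
#' p <- gen_patterns(100, 10, seed = 1)
#' range(p$x)
#' @export
gen_patterns <- function(N, K, coding = c("bipolar", "binary01", "zeromean"),
                         f = 0.5, seed = NULL) {
  coding <- match.arg(coding)
  if (!is.numeric(N) || !is.numeric(K) || N < 1 || K < 1)
    stop("N and K must be positive integers")
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 1)
    stop("coding level f must lie strictly inside (0, 1)")
  st <- coding_states(coding, f)
  x <- with_seed(seed, matrix(ifelse(runif(K * N) < f, st[2L], st[1L]), K, N))
  pattern_set(x, coding = coding, f = f, seed = seed)
}

#' Generate correlated bipolar patterns from a template model
#'
#' Patterns are drawn conditioned on a random bipolar template `xhat`: each
#' entry copies the template with probability (1 + g)/2 and flips otherwise.
#' In `"homogeneous"` mode both `xhat` and `-xhat` serve as templates (chosen
#' by a fair coin per pattern), which keeps the mean activity of every input
#' at 1/2.  In `"heterogeneous"` mode only `xhat` is used, so inputs that are
#' high in the template fire more often than the rest, giving heterogeneous
#' per-input activity.  `g = 0` reduces to [gen_patterns()]; at `g = 1` every
#' pattern is an exact copy (or reversal) of the template.
#'
#' @inheritParams gen_patterns
#' @param g correlation parameter in \[0, 1\].
#' @param mode `"homogeneous"` or `"heterogeneous"`.
#' @return A [pattern_set] carrying the template(s) for lure generation.
#' @export
gen_correlated <- function(N, K, g, mode = c("homogeneous", "heterogeneous"),
                           seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(g) || length(g) != 1L || g < 0 || g > 1)
    stop("correlation parameter g must lie in [0, 1]")
  if (N < 1 || K < 1) stop("N and K must be positive integers")
  with_seed(seed, {
    xhat <- sample(c(-1, 1), N, replace = TRUE)
    templates <- if (mode == "homogeneous") list(xhat, -xhat) else list(xhat)
    x <- draw_from_templates(K, N, g, mode, templates)
    pattern_set(x, coding = "bipolar", f = 0.5, g = g, mode = mode,
                templates = templates, seed = seed)
  })
}

# K draws of the template-copy process: P(x_i = template_i) = (1+g)/2
draw_from_templates <- function(K, N, g, mode, templates) {
  x <- matrix(0, K, N)
  for (k in seq_len(K)) {
    tpl <- if (mode == "homogeneous") templates[[sample.int(2L, 1L)]] else templates[[1L]]
    keep <- runif(N) < (1 + g) / 2
    x[k, ] <- ifelse(keep, tpl, -tpl)
  }
  x
}

#' Presynaptic and postsynaptic noise specification
#'
#' `delta01` is the probability that a silent input fires spuriously,
#' `delta10` the probability that an active input fails (is switched off);
#' `sigma` is the standard deviation of additive zero-mean Gaussian noise on
#' the postsynaptic current.
#'
#' @param delta01,delta10 flip probabilities in \[0, 1\].
#' @param sigma non-negative standard deviation of postsynaptic current noise.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(delta01 = 0, delta10 = 0, sigma = 0) {
  if (delta01 < 0 || delta01 > 1 || delta10 < 0 || delta10 > 1)
    stop("flip probabilities must lie in [0, 1]")
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(delta01 = delta01, delta10 = delta10, sigma = sigma),
            class = "noise_spec")
}

#' Corrupt patterns with state-conditional flips
#'
#' Each high entry is switched to the low state with probability `delta10`
#' and each low entry to the high state with probability `delta01`,
#' independently.  Bipolar and zero-mean codings are handled by mapping the
#' high/low states onto active/silent.  The input set is left untouched.
#'
#' @param p a [pattern_set].
#' @param noise a [noise_spec()] (only the flip probabilities are used).
#' @param seed optional integer seed.
#' @return A new [pattern_set] with flipped entries.
#' @export
corrupt_patterns <- function(p, noise, seed = NULL) {
  stopifnot(inherits(p, "pattern_set"), inherits(noise, "noise_spec"))
  st <- coding_states(p$coding, p$f)
  x <- p$x
  with_seed(seed, {
    hi <- x == st[2L]
    u <- matrix(runif(length(x)), nrow(x), ncol(x))
    flip <- (hi & u < noise$delta10) | (!hi & u < noise$delta01)
    x[flip & hi] <- st[1L]
    x[flip & !hi] <- st[2L]
  })
  out <- p
  out$x <- x
  out
}

#' Generate lure patterns from a stored reference
#'
#' Lures are fresh patterns drawn from the same generative law as the
#' reference set but statistically independent of it: same coding and coding
#' level, same templates and `g` for correlated references.  When presynaptic
#' noise is non-trivial the lure mean activity is matched to the
#' corrupted-pattern statistics, `<x> = (1 - f) * delta01 + f * (1 - delta10)`,
#' so that lures cannot be told apart from distorted learned patterns by their
#' activity level alone.
#'
#' @param reference a [pattern_set] carrying the generative metadata.
#' @param M number of lures; defaults to `K` of the reference (the pairing
#'   used for information estimates).
#' @param noise a [noise_spec()]; flip probabilities shift the lure activity.
#' @param seed optional integer seed.
#' @return A [pattern_set] of `M` lures.
#' @export
gen_lures <- function(reference, M = NULL, noise = noise_spec(), seed = NULL) {
  stopifnot(inherits(reference, "pattern_set"))
  M <- M %||% nrow(reference$x)
  N <- ncol(reference$x)
  f <- reference$f
  if (reference$mode != "none") {
    if (is.null(reference$templates))
      stop("correlated reference carries no templates; cannot generate lures")
    x <- with_seed(seed,
      draw_from_templates(M, N, reference$g, reference$mode, reference$templates))
    out <- reference
    out$x <- x
    out$seed <- seed
    return(out)
  }
  fhigh <- (1 - f) * noise$delta01 + f * (1 - noise$delta10)
  st <- coding_states(reference$coding, f)
  x <- with_seed(seed, matrix(ifelse(runif(M * N) < fhigh, st[2L], st[1L]), M, N))
  out <- reference
  out$x <- x
  out$seed <- seed
  out
}
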