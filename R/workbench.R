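# Experiment drivers reproducing the figure-level sweeps at desk scale, plus
# histogram pooling and plain-text serialisation.

#' Run a figure-level experiment sweep
#'
#' Executes one of the standard experiment protocols (generation, learning or
#' solving, metrics) over a grid of conditions with repeated trials, and
#' returns a tidy table with one row per condition, trial and method.
#' Available experiments:
#'
#' * `"capacity"`: balanced online, maximal-imbalance (min-L1), min-L2 (QP),
#'   thresholded pruning and random pruning (both matched to the min-L1 zero
#'   count) across a memory-load grid `alpha_grid`.
#' * `"weight_hist"`: collects normalised weight vectors for the balanced,
#'   min-L2 and min-L1 rules at one load (see [make_weight_histogram()]).
#' * `"coding"`: 0/1 patterns across `f_grid`, balanced coding-adjusted rule
#'   with the adaptive threshold vs the fixed threshold.
#' * `"correlation"`: template-correlated patterns across `g_grid` for both
#'   correlation modes; balanced, min-L1 and min-L2.
#' * `"noise"`: solutions trained once per trial on clean patterns, then
#'   tested under presynaptic flip noise `delta_grid` and postsynaptic
#'   Gaussian noise `sigma_grid` with a threshold re-optimised per level.
#' * `"imbalance"`: efficiency vs `lambda` up to the empirical critical
#'   imbalance, per instance, across `alpha_grid`.
#'
#' @param experiment experiment name.
#' @param N number of synapses (desk-scale default 500).
#' @param trials trials per condition (default 20).
#' @param seed master seed; every run derives its streams from it, so
#'   identical configurations reproduce identical tables.
#' @param alpha_grid,f_grid,g_grid,delta_grid,sigma_grid,lambda_grid
#'   condition grids (defaults per experiment).
#' @param lure_factor lures per stored pattern for metric estimation.
#' @param theta threshold parameter.
#' @param max_epochs online epoch budget.
#' @return A data frame; the full configuration is attached as
#'   `attr(, "config")`.  For `"weight_hist"` the normalised weight vectors
#'   are attached as `attr(, "solutions")` (a list per method).
#' @export
run_sweep <- function(experiment = c("capacity", "weight_hist", "coding",
                                     "correlation", "noise", "imbalance"),
                      N = 500, trials = 20, seed = 1,
                      alpha_grid = NULL, f_grid = NULL, g_grid = NULL,
                      delta_grid = NULL, sigma_grid = NULL, lambda_grid = NULL,
                      lure_factor = 1, theta = 1, max_epochs = 10000) {
  experiment <- match.arg(experiment)
  stopifnot(trials >= 1, N >= 2)
  cfg <- list(experiment = experiment, N = N, trials = trials, seed = seed,
              alpha_grid = alpha_grid, f_grid = f_grid, g_grid = g_grid,
              delta_grid = delta_grid, sigma_grid = sigma_grid,
              lambda_grid = lambda_grid, lure_factor = lure_factor,
              theta = theta, max_epochs = max_epochs)
  out <- with_seed(seed, switch(experiment,
    capacity    = sweep_capacity(cfg),
    weight_hist = sweep_weight_hist(cfg),
    coding      = sweep_coding(cfg),
    correlation = sweep_correlation(cfg),
    noise       = sweep_noise(cfg),
    imbalance   = sweep_imbalance(cfg)))
  attr(out, "config") <- cfg
  out
}

# metrics row for one solution (threshold zero counting for sweep speed)
sweep_metrics_row <- function(fit, lures, label, extra = list()) {
  base <- data.frame(method = label, stringsAsFactors = FALSE)
  if (is.null(fit$w)) {
    row <- cbind(base, data.frame(C = NA_real_, S = NA_real_, F = NA_real_,
                                  p01 = NA_real_, p10 = NA_real_,
                                  status = fit$status))
  } else {
    mm <- memory_metrics(fit, lures = lures, count = "threshold")
    row <- cbind(base, data.frame(C = mm$C, S = mm$S, F = mm$F, p01 = mm$p01,
                                  p10 = mm$p10, status = fit$status))
  }
  if (length(extra)) row <- cbind(row, as.data.frame(extra))
  row
}

sweep_capacity <- function(cfg) {
  alphas <- cfg$alpha_grid %||% c(0.1, 0.2, 0.4, 0.6, 0.8)
  rows <- list()
  for (a in alphas) {
    K <- max(1L, round(a * cfg$N))
    for (tr in seq_len(cfg$trials)) {
      p <- gen_patterns(cfg$N, K)
      lures <- gen_lures(p, M = max(1L, round(cfg$lure_factor * K)))
      bal <- perceptron(p, "online", lambda = 0, theta = cfg$theta,
                        max_epochs = cfg$max_epochs)
      l1 <- perceptron(p, "minL1", theta = cfg$theta)
      l2 <- perceptron(p, "minL2", theta = cfg$theta)
      fits <- list(balanced = bal, max_imbalance = l1, minL2 = l2)
      if (!is.null(l1$w) && !is.null(bal$w)) {
        ndel <- max(0L, sum(l1$w == 0) - sum(bal$w == 0))
        ndel <- min(ndel, sum(bal$w > 0))
        fits$prune_smallest <- prune_smallest(bal, ndel)
        fits$prune_random <- prune_random(bal, ndel)
      }
      for (lab in names(fits))
        rows[[length(rows) + 1L]] <-
          sweep_metrics_row(fits[[lab]], lures, lab,
                            list(alpha = a, trial = tr))
    }
  }
  do.call(rbind, rows)
}

sweep_weight_hist <- function(cfg) {
  a <- (cfg$alpha_grid %||% 0.1)[1L]
  K <- max(1L, round(a * cfg$N))
  sols <- list(balanced = list(), minL2 = list(), max_imbalance = list())
  rows <- list()
  for (tr in seq_len(cfg$trials)) {
    p <- gen_patterns(cfg$N, K)
    lures <- gen_lures(p, M = max(1L, round(cfg$lure_factor * K)))
    fits <- list(balanced = perceptron(p, "online", lambda = 0,
                                       theta = cfg$theta,
                                       max_epochs = cfg$max_epochs),
                 minL2 = perceptron(p, "minL2", theta = cfg$theta),
                 max_imbalance = perceptron(p, "minL1", theta = cfg$theta))
    for (lab in names(fits)) {
      f <- fits[[lab]]
      if (!is.null(f$w)) {
        wn <- normalize_to_unit_threshold(f$w, p)
        wn[f$w < 1e-8 * max(f$w)] <- 0   # solver zeros are tiny, not exact
        sols[[lab]][[length(sols[[lab]]) + 1L]] <- wn
      }
      rows[[length(rows) + 1L]] <-
        sweep_metrics_row(f, lures, lab, list(alpha = a, trial = tr))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "solutions") <- sols
  out
}

sweep_coding <- function(cfg) {
  fs <- cfg$f_grid %||% c(0.05, 0.1, 0.2, 0.35, 0.5)
  a <- (cfg$alpha_grid %||% 0.5)[1L]
  K <- max(1L, round(a * cfg$N))
  rows <- list()
  for (f in fs) {
    for (tr in seq_len(cfg$trials)) {
      p <- gen_patterns(cfg$N, K, coding = "binary01", f = f)
      lures <- gen_lures(p, M = max(1L, round(cfg$lure_factor * K)))
      cfg_f <- plasticity_config(epsilon = 1 / cfg$N, lambda = 0,
                                 theta = cfg$theta, f = f,
                                 max_epochs = cfg$max_epochs)
      for (adap in c(TRUE, FALSE)) {
        fit <- train_online(p, cfg_f, adaptive = adap)
        er <- error_rates(fit$w, p, lures, theta = cfg$theta, adaptive = adap)
        C <- information(er$p01, er$p10, K, cfg$N)
        rows[[length(rows) + 1L]] <- data.frame(
          method = if (adap) "adaptive_gamma" else "fixed_threshold",
          C = C, S = NA_real_,
          F = count_functional(fit$w, mode = "threshold")$F,
          p01 = er$p01, p10 = er$p10, status = fit$status,
          f = f, alpha = a, trial = tr, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

sweep_correlation <- function(cfg) {
  gs <- cfg$g_grid %||% c(0, 0.2, 0.4, 0.6)
  a <- (cfg$alpha_grid %||% 0.1)[1L]
  K <- max(1L, round(a * cfg$N))
  rows <- list()
  for (mode in c("homogeneous", "heterogeneous")) {
    for (g in gs) {
      for (tr in seq_len(cfg$trials)) {
        p <- gen_correlated(cfg$N, K, g = g, mode = mode)
        lures <- gen_lures(p, M = max(1L, round(cfg$lure_factor * K)))
        fits <- list(balanced = perceptron(p, "online", lambda = 0,
                                           theta = cfg$theta,
                                           max_epochs = cfg$max_epochs),
                     max_imbalance = perceptron(p, "minL1", theta = cfg$theta),
                     minL2 = perceptron(p, "minL2", theta = cfg$theta))
        for (lab in names(fits))
          rows[[length(rows) + 1L]] <-
            sweep_metrics_row(fits[[lab]], lures, lab,
                              list(g = g, mode = mode, alpha = a, trial = tr))
      }
    }
  }
  do.call(rbind, rows)
}

sweep_noise <- function(cfg) {
  deltas <- cfg$delta_grid %||% c(0, 0.05, 0.1, 0.2, 0.3)
  sigmas <- cfg$sigma_grid %||% numeric(0)
  a <- (cfg$alpha_grid %||% 0.1)[1L]
  K <- max(1L, round(a * cfg$N))
  th_grid <- seq(0.1, 3, by = 0.1)
  rows <- list()
  for (tr in seq_len(cfg$trials)) {
    p <- gen_patterns(cfg$N, K, coding = "zeromean", f = 0.5)
    bal <- perceptron(p, "online", lambda = 0, theta = cfg$theta,
                      max_epochs = cfg$max_epochs)
    l1 <- perceptron(p, "minL1", theta = cfg$theta)
    fits <- list(balanced = bal, max_imbalance = l1)
    if (!is.null(l1$w) && !is.null(bal$w)) {
      ndel <- min(max(0L, sum(l1$w == 0) - sum(bal$w == 0)), sum(bal$w > 0))
      fits$prune_smallest <- prune_smallest(bal, ndel)
    }
    M <- max(1L, round(cfg$lure_factor * K))
    for (d in deltas) {
      ns <- noise_spec(delta01 = d, delta10 = d)
      lures <- gen_lures(p, M = M, noise = ns)
      for (lab in names(fits)) {
        f <- fits[[lab]]
        if (is.null(f$w)) next
        # unit mean response scale, threshold re-optimised per noise level
        wn <- f$w / mean(drop(p$x %*% f$w))
        opt <- optimize_threshold(wn, p, lures, noise = ns, grid = th_grid)
        Ffrac <- count_functional(f$w, mode = "threshold")$F
        rows[[length(rows) + 1L]] <- data.frame(
          method = lab, C = opt$C, S = efficiency(opt$C, Ffrac), F = Ffrac,
          p01 = NA_real_, p10 = NA_real_, status = f$status,
          delta = d, sigma = 0, theta_star = opt$theta, alpha = a, trial = tr,
          stringsAsFactors = FALSE)
      }
    }
    for (s in sigmas) {
      ns <- noise_spec(sigma = s)
      lures <- gen_lures(p, M = M)
      for (lab in names(fits)) {
        f <- fits[[lab]]
        if (is.null(f$w)) next
        wn <- f$w / mean(drop(p$x %*% f$w))
        opt <- optimize_threshold(wn, p, lures, noise = ns, grid = th_grid)
        Ffrac <- count_functional(f$w, mode = "threshold")$F
        rows[[length(rows) + 1L]] <- data.frame(
          method = lab, C = opt$C, S = efficiency(opt$C, Ffrac), F = Ffrac,
          p01 = NA_real_, p10 = NA_real_, status = f$status,
          delta = 0, sigma = s, theta_star = opt$theta, alpha = a, trial = tr,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

sweep_imbalance <- function(cfg) {
  alphas <- cfg$alpha_grid %||% c(0.1, 0.3, 0.5)
  lam_grid <- cfg$lambda_grid %||% seq(0, 1, by = 0.05)
  rows <- list()
  for (a in alphas) {
    K <- max(1L, round(a * cfg$N))
    for (tr in seq_len(cfg$trials)) {
      p <- gen_patterns(cfg$N, K)
      lm <- lambda_max_empirical(p, theta = cfg$theta,
                                 lambda_grid = lam_grid,
                                 max_epochs = cfg$max_epochs,
                                 with_metrics = TRUE)
      cur <- lm$curve
      cur$alpha <- a
      cur$trial <- tr
      cur$lambda_max <- lm$lambda_max
      rows[[length(rows) + 1L]] <- cur
    }
  }
  do.call(rbind, rows)
}

#' Pool weight vectors into a histogram
#'
#' Pools the positive weights of a list of solutions (normalised to unit
#' minimal pattern response beforehand) into one histogram, keeping the mass
#' of exactly-zero (silent) synapses separate.
#'
#' @param solutions list of non-negative weight vectors.
#' @param bins number of bins over the positive range.
#' @return A list of class `weight_histogram`: `bin_edges`, `counts`,
#'   `zero_mass`, `n_vectors`.
#' @export
make_weight_histogram <- function(solutions, bins = 50) {
  if (!length(solutions)) stop("no solutions supplied")
  all_w <- unlist(solutions, use.names = FALSE)
  if (any(all_w < 0)) stop("weights must be non-negative")
  pos <- all_w[all_w > 0]
  zero_mass <- sum(all_w == 0)
  if (!length(pos)) stop("no positive weights to bin")
  edges <- seq(0, max(pos), length.out = bins + 1L)
  counts <- graphics::hist(pos, breaks = edges, plot = FALSE)$counts
  structure(list(bin_edges = edges, counts = counts, zero_mass = zero_mass,
                 n_vectors = length(solutions)),
            class = "weight_histogram")
}

#' @export
print.weight_histogram <- function(x, ...) {
  cat(sprintf("weight_histogram: %d vectors pooled, %d positive weights in %d bins, %d silent\n",
              x$n_vectors, sum(x$counts), length(x$counts), x$zero_mass))
  invisible(x)
}

#' @export
plot.weight_histogram <- function(x, ...) {
  mids <- (head(x$bin_edges, -1) + x$bin_edges[-1L]) / 2
  graphics::plot(mids, x$counts / sum(x$counts), type = "h",
                 xlab = "normalised weight", ylab = "relative frequency", ...)
  invisible(x)
}

#' Write / read a pattern set as plain text
#'
#' The matrix goes to CSV; the generative metadata (coding, f, g, mode,
#' templates, seed) goes to a JSON sidecar `<file>.json` so that a round trip
#' restores the full object.
#'
#' @param p a [pattern_set].
#' @param file CSV path.
#' @return `read_pattern_set` returns the restored [pattern_set];
#'   `write_pattern_set` returns `file` invisibly.
#' @export
write_pattern_set <- function(p, file) {
  stopifnot(inherits(p, "pattern_set"))
  write.csv(p$x, file, row.names = FALSE)
  meta <- list(coding = p$coding, f = p$f, g = p$g, mode = p$mode,
               templates = p$templates, seed = p$seed)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_pattern_set
#' @export
read_pattern_set <- function(file) {
  x <- as.matrix(read.csv(file))
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  tpl <- if (is.null(meta$templates) || !length(meta$templates)) NULL
         else lapply(seq_len(nrow(as.matrix(meta$templates))), function(i)
           as.numeric(as.matrix(meta$templates)[i, ]))
  pattern_set(x, coding = meta$coding, f = meta$f, g = meta$g %||% 0,
              mode = meta$mode %||% "none", templates = tpl,
              seed = meta$seed)
}

#' Serialise a plasticity configuration to JSON and back
#'
#' @param cfg a [plasticity_config()].
#' @param file JSON path.
#' @export
write_config <- function(cfg, file) {
  stopifnot(inherits(cfg, "plasticity_config"))
  jsonlite::write_json(unclass(cfg), file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  plasticity_config(epsilon = x$epsilon, lambda = x$lambda, theta = x$theta,
                    f = x$f, rule = x$rule, max_epochs = x$max_epochs,
                    seed = x$seed)
}
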