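# Offline reference solutions and post-hoc pruning.
#
# Both offline problems share the feasible cone
#   { w : X w >= theta' * sqrt(N) * 1,  w >= 0 }.
# minL2 is the quadratic programme itself.  minL1 is a linear programme; it
# is solved through exact Tikhonov regularisation, min ridge/2*||w||^2+|w|_1,
# on the same quadratic backend: for a ridge below a problem-dependent
# threshold the minimiser is exactly the minimum-L2 point of the LP's optimal
# face (the unique LP vertex for generic random patterns).  The reported
# duality-gap bound ridge*||w||_2^2 certifies proximity to the true LP value.

# The interior-point iterate satisfies the firing constraints only to solver
# tolerance; active patterns can sit ~1e-9 below threshold.  The feasible set
# is a cone, so a multiplicative rescale putting the weakest response exactly
# on the margin restores strict feasibility without moving the solution.
rescale_to_margin <- function(w, X, margin) {
  s <- min(drop(X %*% w))
  # the 1e-12 overshoot keeps the weakest response strictly above the margin
  # after the rescaled responses are themselves rounded
  if (s > 0) w * (margin / s) * (1 + 1e-12) else w
}

qp_feasible_solve <- function(X, margin, Dmat, dvec) {
  N <- ncol(X)
  Amat <- cbind(t(X), diag(N))
  bvec <- c(rep(margin, nrow(X)), rep(0, N))
  tryCatch(
    list(sol = quadprog::solve.QP(Dmat, dvec, Amat, bvec), status = "optimal"),
    error = function(e) {
      if (grepl("constraints are inconsistent", conditionMessage(e)))
        list(sol = NULL, status = "infeasible")
      else list(sol = NULL, status = "numerical_failure", message = conditionMessage(e))
    })
}

#' Minimum-L1 (maximal-imbalance) solution
#'
#' The feasible non-negative weight vector with the smallest linear norm
#' `|w| = sum_i w_i`, subject to every stored pattern firing.  This offline
#' solution is the endpoint of imbalanced online learning as
#' `lambda -> lambda_max` and is typically highly sparse.
#'
#' @param patterns a [pattern_set] in bipolar or zero-mean coding.
#' @param theta threshold parameter.
#' @param ridge Tikhonov regularisation strength; exact for any sufficiently
#'   small value, the default is conservative (diagnostics report the
#'   duality-gap bound `ridge * ||w||_2^2`).
#' @return A `perceptron` object with `objective = |w|_1` and `status`
#'   `"optimal"`, `"infeasible"` or `"numerical_failure"`.
#' @export
solve_min_l1 <- function(patterns, theta = 1, ridge = 1e-4) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (patterns$coding == "binary01")
    stop("offline solvers operate on bipolar/zeromean coding")
  X <- patterns$x
  N <- ncol(X)
  margin <- theta_eff(theta, patterns$coding, patterns$f) * sqrt(N)
  r <- qp_feasible_solve(X, margin, diag(ridge, N), rep(-1, N))
  if (r$status != "optimal")
    return(new_perceptron(NULL, patterns, "minL1", theta, converged = FALSE,
                          status = r$status))
  w <- rescale_to_margin(pmax(r$sol$solution, 0), X, margin)
  new_perceptron(w, patterns, "minL1", theta, converged = TRUE,
                 status = "optimal", objective = sum(w),
                 diagnostics = list(ridge = ridge,
                                    gap_bound = ridge * sum(w^2)))
}

#' Minimum-L2 (maximal-information) solution
#'
#' The feasible non-negative weight vector with the smallest Euclidean norm.
#' At fixed threshold this maximises the stability
#' `Delta = theta * sqrt(N) / ||w||_2` and therefore minimises the Gaussian
#' false-positive rate: it is the maximal-information solution.
#'
#' @inheritParams solve_min_l1
#' @return A `perceptron` object with `objective = ||w||_2^2`.
#' @export
solve_min_l2 <- function(patterns, theta = 1) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (patterns$coding == "binary01")
    stop("offline solvers operate on bipolar/zeromean coding")
  X <- patterns$x
  N <- ncol(X)
  margin <- theta_eff(theta, patterns$coding, patterns$f) * sqrt(N)
  r <- qp_feasible_solve(X, margin, diag(1, N), rep(0, N))
  if (r$status != "optimal")
    return(new_perceptron(NULL, patterns, "minL2", theta, converged = FALSE,
                          status = r$status))
  w <- rescale_to_margin(pmax(r$sol$solution, 0), X, margin)
  new_perceptron(w, patterns, "minL2", theta, converged = TRUE,
                 status = "optimal", objective = sum(w^2))
}

#' Min-over learning with rectification
#'
#' The Krauth-Mezard batch rule under the non-negativity constraint: at each
#' step the pattern with the smallest postsynaptic sum is reinforced with the
#' balanced update (`w <- w + epsilon * x`, rectified at zero).  As iterations
#' grow the normalised stabilities converge to those of the minimum-L2
#' solution.  Iteration stops when all patterns fire and the minimal
#' stability has stalled, or at the budget.
#'
#' @inheritParams solve_min_l1
#' @param epsilon step size (the final direction is scale-free; 1 is fine).
#' @param max_iter iteration budget.
#' @param stall_window steps without stability improvement that end the run
#'   once feasible (0 = stop at first feasibility).
#' @param stall_tol minimal improvement counted as progress.
#' @return A `perceptron` object; `converged` reports whether the stopping
#'   criterion (not the budget) ended the run.
#' @export
train_minover <- function(patterns, theta = 1, epsilon = 1, max_iter = 1e5,
                          stall_window = 1000, stall_tol = 1e-12) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (patterns$coding == "binary01")
    stop("min-over operates on bipolar/zeromean coding")
  X <- patterns$x
  N <- ncol(X)
  margin <- theta_eff(theta, patterns$coding, patterns$f) * sqrt(N)
  res <- .minover_cpp(X, margin, epsilon, max_iter, stall_window, stall_tol)
  new_perceptron(res$w, patterns, "minover", theta, epsilon = epsilon,
                 converged = res$converged,
                 status = if (res$converged) "converged" else "not_converged",
                 epochs = res$iterations, updates = res$iterations)
}

#' Prune the smallest synapses
#'
#' Sets the `n_delete` smallest strictly positive weights to zero, the
#' offline minimal-value deletion rule.  In the comparison protocol
#' `n_delete` is matched to the zero count of the minimum-L1 solution on the
#' same patterns.
#'
#' @param w numeric weight vector, or a `perceptron` fit.
#' @param n_delete how many non-zero weights to remove (0 <= n_delete <=
#'   number of non-zeros).
#' @return Same type as `w`, with the pruned weights.
#' @export
prune_smallest <- function(w, n_delete) {
  if (inherits(w, "perceptron")) {
    out <- w
    out$w <- prune_smallest(w$w, n_delete)
    out$method <- paste0(w$method, "+prune_smallest")
    out$stabilities <- if (any(out$w > 0))
      drop(out$patterns$x %*% out$w) / sqrt(sum(out$w^2)) else NULL
    return(out)
  }
  pos <- which(w > 0)
  if (n_delete < 0 || n_delete > length(pos))
    stop("n_delete must lie between 0 and the number of non-zero weights (",
         length(pos), ")")
  if (n_delete == 0) return(w)
  drop_idx <- pos[order(w[pos])[seq_len(n_delete)]]
  w[drop_idx] <- 0
  w
}

#' Prune a random subset of synapses
#'
#' As [prune_smallest()], but the deleted non-zero weights are chosen
#' uniformly at random.
#'
#' @inheritParams prune_smallest
#' @param seed optional integer seed.
#' @export
prune_random <- function(w, n_delete, seed = NULL) {
  if (inherits(w, "perceptron")) {
    out <- w
    out$w <- prune_random(w$w, n_delete, seed = seed)
    out$method <- paste0(w$method, "+prune_random")
    out$stabilities <- if (any(out$w > 0))
      drop(out$patterns$x %*% out$w) / sqrt(sum(out$w^2)) else NULL
    return(out)
  }
  pos <- which(w > 0)
  if (n_delete < 0 || n_delete > length(pos))
    stop("n_delete must lie between 0 and the number of non-zero weights (",
         length(pos), ")")
  if (n_delete == 0) return(w)
  drop_idx <- with_seed(seed, sample(pos, n_delete))
  w[drop_idx] <- 0
  w
}
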