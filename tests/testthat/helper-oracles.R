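# Brute-force oracles for the offline solvers, independent of quadprog.
# Feasible set: { w : X w >= margin * 1, w >= 0 }.

# Minimum-L1 by vertex enumeration: every vertex of the polyhedron activates
# N of the K + N constraints; solve each square subsystem, keep feasible
# solutions, return the smallest linear norm.
oracle_min_l1 <- function(X, margin) {
  K <- nrow(X); N <- ncol(X)
  A <- rbind(X, diag(N))
  b <- c(rep(margin, K), rep(0, N))
  best <- Inf; best_w <- NULL
  for (rows in combn(K + N, N, simplify = FALSE)) {
    As <- A[rows, , drop = FALSE]
    if (abs(det(As)) < 1e-10) next
    w <- solve(As, b[rows])
    if (all(w >= -1e-9) && all(A %*% w >= b - 1e-9)) {
      obj <- sum(pmax(w, 0))
      if (obj < best) { best <- obj; best_w <- pmax(w, 0) }
    }
  }
  list(objective = best, w = best_w)
}

# Minimum-L2 by active-set enumeration: the projection of the origin onto the
# polyhedron makes some subset of constraints tight; solve the equality-
# constrained projection for every subset, keep feasible candidates.
oracle_min_l2 <- function(X, margin) {
  K <- nrow(X); N <- ncol(X)
  A <- rbind(X, diag(N))
  b <- c(rep(margin, K), rep(0, N))
  best <- Inf; best_w <- NULL
  nc <- K + N
  for (bits in 0:(2^nc - 1)) {
    act <- which(bitwAnd(bits, 2^(seq_len(nc) - 1)) > 0)
    if (length(act) > N) next
    if (length(act) == 0) {
      w <- rep(0, N)
    } else {
      As <- A[act, , drop = FALSE]
      G <- As %*% t(As)
      if (abs(det(G)) < 1e-12) next
      w <- drop(t(As) %*% solve(G, b[act]))
    }
    if (all(A %*% w >= b - 1e-9)) {
      obj <- sum(w^2)
      if (obj < best - 1e-12) { best <- obj; best_w <- w }
    }
  }
  list(objective = best, w = best_w)
}

# single-pattern bipolar set built by hand
one_pattern_set <- function(x) {
  pattern_set(matrix(x, nrow = 1), coding = "bipolar", f = 0.5)
}
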