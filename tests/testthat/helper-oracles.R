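# Independent oracles used to cross-check the solvers. Both are deliberately
# naive: the LP oracle enumerates candidate vertices from all n-subsets of
# active hyperplanes; the QP oracle is projected gradient descent with a
# Dykstra projection onto the constraint intersection. Neither shares any
# code with the package's solver path.

# Minimize c'x over {lower <= A x <= upper, xl <= x <= xu} by brute-force
# vertex enumeration. Assumes the feasible set is bounded.
lp_vertex_oracle <- function(objective, A, lower, upper, xl, xu,
                             tol = 1e-8) {
  n <- length(objective)
  planes <- list()
  for (k in seq_len(nrow(A))) {
    if (is.finite(lower[k])) planes[[length(planes) + 1]] <-
        list(a = A[k, ], b = lower[k])
    if (is.finite(upper[k]) && upper[k] != lower[k]) {
      planes[[length(planes) + 1]] <- list(a = A[k, ], b = upper[k])
    }
  }
  ei <- diag(n)
  for (i in seq_len(n)) {
    if (is.finite(xl[i])) planes[[length(planes) + 1]] <-
        list(a = ei[i, ], b = xl[i])
    if (is.finite(xu[i])) planes[[length(planes) + 1]] <-
        list(a = ei[i, ], b = xu[i])
  }
  feasible <- function(x) {
    v <- as.numeric(A %*% x)
    all(v >= lower - tol * pmax(1, abs(lower)),
        v <= upper + tol * pmax(1, abs(upper)),
        x >= xl - tol, x <= xu + tol)
  }
  best <- Inf
  arg <- NULL
  for (idx in utils::combn(length(planes), n, simplify = FALSE)) {
    M <- do.call(rbind, lapply(planes[idx], `[[`, "a"))
    b <- vapply(planes[idx], `[[`, numeric(1), "b")
    if (abs(det(M)) < 1e-10) next
    x <- tryCatch(solve(M, b), error = function(e) NULL)
    if (is.null(x) || !feasible(x)) next
    val <- sum(objective * x)
    if (val < best - 1e-12) {
      best <- val
      arg <- x
    }
  }
  list(objective = best, x = arg)
}

# Euclidean projection onto {x : lo <= a'x <= up} (a slab).
project_slab <- function(x, a, lo, up) {
  v <- sum(a * x)
  nrm2 <- sum(a^2)
  if (v < lo) x + (lo - v) / nrm2 * a
  else if (v > up) x + (up - v) / nrm2 * a
  else x
}

# Dykstra's algorithm for the intersection of slabs and a box.
dykstra_project <- function(x, A, lower, upper, xl, xu, sweeps = 60) {
  m <- nrow(A)
  sets <- m + 1
  p <- matrix(0, sets, length(x))
  for (s in seq_len(sweeps)) {
    for (k in seq_len(sets)) {
      y <- x + p[k, ]
      z <- if (k <= m) project_slab(y, A[k, ], lower[k], upper[k])
           else pmin(pmax(y, xl), xu)
      p[k, ] <- y - z
      x <- z
    }
  }
  x
}

# Projected gradient descent for min sum(((x - x0)/x0)^2) s.t. the system.
qp_pg_oracle <- function(A, lower, upper, xl, xu, x0, iters = 4000) {
  L <- max(2 / x0^2)
  x <- dykstra_project(x0, A, lower, upper, xl, xu)
  for (i in seq_len(iters)) {
    grad <- 2 * (x - x0) / x0^2
    x_new <- dykstra_project(x - grad / L, A, lower, upper, xl, xu)
    if (max(abs(x_new - x)) < 1e-10) {
      x <- x_new
      break
    }
    x <- x_new
  }
  list(objective = sum(((x - x0) / x0)^2), x = x)
}

# Small shared fixtures --------------------------------------------------

tiny_config <- function(seed = 1, ...) {
  generator_config(seed = seed, n_foods = 20, n_main = 8, n_persons = 120,
                   ...)
}

random_lp_system <- function(n, m, rng_scale = 1) {
  A <- matrix(stats::runif(m * n, 0.1, 1) * rng_scale, m, n)
  x_feas <- stats::runif(n, 0.5, 2)
  v <- as.numeric(A %*% x_feas)
  constraint_system(A, lower = 0.7 * v, upper = 1.3 * v,
                    x_lower = rep(0, n), x_upper = rep(4, n) * max(x_feas))
}
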