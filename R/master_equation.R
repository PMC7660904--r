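#' Build the reset-augmented birth-death chain of a focal type
#'
#' The marginal within-host frequency of a focal type moves on the grid
#' `{0, 1/N, ..., 1}` as a tridiagonal birth-death chain whose up/down
#' probabilities come from [marginal_step_probabilities()]; host death adds
#' a resetting flow of probability `tau` from every state into the
#' microbe-free state (grid index 0 for a taxon; `x_0 = 1`, the last grid
#' index, for the empty-space target).
#'
#' @inheritParams marginal_step_probabilities
#' @return A `reset_chain` object: list with `grid` (frequencies), `up`,
#'   `down`, `stay` (per-state probabilities, already carrying the
#'   `1 - tau` survival factor), `tau`, `reset_index` (1-based grid index of
#'   the reset state), `target`, `params`.
#' @examples
#' pars <- model_params(N = 50, m = 0.01, tau = 1e-3, p = 0.5)
#' chain <- build_reset_chain(focal_taxon(1), pars)
#' chain
#' @export
build_reset_chain <- function(target, params) {
  assert_closure(target, params)
  N <- params$N
  grid <- (0:N) / N
  pr <- marginal_step_probabilities(grid, target, params)
  structure(
    list(grid = grid, up = pr$p_up, down = pr$p_down, stay = pr$p_stay,
         tau = params$tau,
         reset_index = if (target$kind == "taxon") 1L else N + 1L,
         target = target, params = params),
    class = "reset_chain"
  )
}

#' @export
print.reset_chain <- function(x, ...) {
  cat("<reset_chain>\n")
  cat(sprintf("  %d states on {0, 1/%d, ..., 1}; tau = %g; reset into x = %g\n",
              length(x$grid), x$params$N, x$tau, x$grid[x$reset_index]))
  cat(sprintf("  target: %s\n",
              if (x$target$kind == "taxon")
                sprintf("taxon %d (p = %g)", x$target$taxon_index,
                        p_focal(x$target, x$params))
              else "empty space"))
  invisible(x)
}

#' One-step transition matrix of a reset chain
#'
#' Returns the column-stochastic sparse matrix `R`: entry `R[k, j]` is the
#' probability of moving from grid state `j` to state `k` in one step.  The
#' sub/super diagonals hold the birth-death probabilities, the diagonal the
#' stay probabilities, and the reset row receives `tau` from every column
#' (including itself, so columns sum to exactly 1).
#'
#' @param chain A [build_reset_chain()] object.
#' @return A `dgCMatrix` of dimension `(N+1) x (N+1)` with unit column sums.
#' @export
transition_matrix <- function(chain) {
  stopifnot(inherits(chain, "reset_chain"))
  n <- length(chain$grid)
  i <- c(seq_len(n), seq_len(n - 1) + 1L, seq_len(n - 1), rep(chain$reset_index, n))
  j <- c(seq_len(n), seq_len(n - 1), seq_len(n - 1) + 1L, seq_len(n))
  v <- c(chain$stay, chain$up[-n], chain$down[-1], rep(chain$tau, n))
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n))
}

new_marginal_distribution <- function(mass, chain = NULL, params = NULL,
                                      target = NULL, method = "unknown") {
  if (!is.null(chain)) {
    params <- chain$params
    target <- chain$target
  }
  n <- length(mass)
  out <- tibble(
    state_index = 0:(n - 1L),
    frequency = (0:(n - 1L)) / (n - 1L),
    mass = as.numeric(mass)
  )
  class(out) <- c("marginal_distribution", class(out))
  attr(out, "params") <- params
  attr(out, "target") <- target
  attr(out, "method") <- method
  out
}

is_marginal_distribution <- function(x) inherits(x, "marginal_distribution")

assert_distribution <- function(dist) {
  if (!is_marginal_distribution(dist))
    abort("expected a `marginal_distribution` (see stationary_distribution()).")
  if (any(dist$mass < 0))
    abort("distribution has negative mass.")
  if (abs(sum(dist$mass) - 1) > 1e-10)
    abort("distribution mass must sum to 1 within 1e-10.")
  invisible(dist)
}

#' Stationary distribution of a reset chain
#'
#' Solves `R phi = phi` for the column-stochastic one-step matrix of the
#' chain: the long-run population-level distribution of the focal type's
#' within-host frequency.  Writing `R = S + tau * e_r 1'` with `S` the
#' tridiagonal survival part and `e_r` the reset state, stationarity under
#' the normalization `sum(phi) = 1` is the banded linear system
#' `(S - I) phi = -tau e_r`, which the default method solves directly: for
#' `tau > 0` the matrix `S - I` is strictly column diagonally dominant (by
#' exactly `tau`) and the solution sums to 1 by construction; for `tau = 0`
#' the tridiagonal null-space is pinned at a reference state and
#' renormalized.  This stays fast and well-conditioned for `tau` spanning
#' `1e-9` to 1; the solution is verified against the full one-step matrix
#' and the solver falls back to power iteration on `R` if the residual
#' exceeds `tol`.
#'
#' Uniqueness requires `tau > 0`, or `tau = 0` with `m > 0` (otherwise both
#' boundaries are absorbing and the stationary distribution is not unique).
#'
#' Tiny negative entries from the floating-point solve are clipped to zero
#' and the vector renormalized; a clip larger than `1e-10` raises a warning.
#'
#' @param chain A [build_reset_chain()] object.
#' @param method `"linear"` (sparse direct solve, default) or `"power"`.
#' @param tol Maximum acceptable residual `max |R phi - phi|`.
#' @return A `marginal_distribution`: tibble with columns `state_index`,
#'   `frequency`, `mass`, carrying the target/params as attributes.
#' @examples
#' pars <- model_params(N = 100, m = 0.01, tau = 1e-3, p = 0.5)
#' phi <- stationary_distribution(build_reset_chain(focal_taxon(1), pars))
#' glance(phi)
#' @export
stationary_distribution <- function(chain, method = c("linear", "power"),
                                    tol = 1e-12) {
  stopifnot(inherits(chain, "reset_chain"))
  method <- match.arg(method)
  if (chain$tau == 0 && chain$params$m == 0)
    abort("non-unique stationary distribution: tau = 0 and m = 0 leaves absorbing boundaries.")
  R <- transition_matrix(chain)
  n <- nrow(R)

  phi <- NULL
  if (method == "linear") {
    A <- survival_generator(chain)
    phi <- if (chain$tau > 0) {
      b <- numeric(n)
      b[chain$reset_index] <- -chain$tau
      tryCatch(as.numeric(Matrix::solve(A, b)), error = function(e) NULL)
    } else if (chain$up[1] == 0) {
      # tau = 0 with zero pool frequency: x = 0 is absorbing and reachable
      v <- numeric(n); v[1] <- 1; v
    } else if (chain$down[n] == 0) {
      # tau = 0 with a single colonizing taxon (p = 1): x = 1 absorbs
      v <- numeric(n); v[n] <- 1; v
    } else {
      solve_nullspace_tridiag(A)
    }
    if (!is.null(phi)) phi <- clip_and_normalize(phi)
    if (!is.null(phi)) {
      res <- max(abs(as.numeric(R %*% phi) - phi))
      if (!is.finite(res) || res > tol) phi <- NULL
    }
  }
  if (is.null(phi)) {
    phi <- power_iterate(R, start = {
      v <- numeric(n); v[chain$reset_index] <- 1; v
    }, tol = tol)
    phi <- clip_and_normalize(phi)
  }
  new_marginal_distribution(phi, chain = chain, method = "master_equation")
}

# (S - I): the tridiagonal generator of the chain without the resetting
# inflow (the survival factor 1 - tau is already inside up/down/stay)
survival_generator <- function(chain) {
  n <- length(chain$grid)
  i <- c(seq_len(n), seq_len(n - 1) + 1L, seq_len(n - 1))
  j <- c(seq_len(n), seq_len(n - 1), seq_len(n - 1) + 1L)
  v <- c(chain$stay - 1, chain$up[-n], chain$down[-1])
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n))
}

# Null vector of a singular tridiagonal generator (tau = 0): pin one state
# to 1, solve, renormalize.  The pinned state must carry non-negligible
# stationary mass for good conditioning, so re-solve once anchored at the
# mode of the first attempt.
solve_nullspace_tridiag <- function(A) {
  n <- nrow(A)
  k <- (n + 1L) %/% 2L
  phi <- NULL
  for (attempt in 1:3) {
    Ak <- A
    Ak[k, ] <- 0
    Ak[k, k] <- 1
    b <- numeric(n); b[k] <- 1
    phi <- tryCatch(as.numeric(Matrix::solve(Ak, b)), error = function(e) NULL)
    if (is.null(phi) || !all(is.finite(phi))) return(NULL)
    k_new <- which.max(phi)
    if (k_new == k) break
    k <- k_new
  }
  phi
}

clip_and_normalize <- function(phi, clip_warn = 1e-10) {
  neg <- phi < 0
  if (any(neg)) {
    worst <- max(-phi[neg])
    if (worst > clip_warn)
      warn(sprintf("clipped negative stationary mass of magnitude %.3g", worst))
    phi[neg] <- 0
  }
  s <- sum(phi)
  if (!is.finite(s) || s <= 0) return(NULL)
  phi / s
}

power_iterate <- function(R, start, tol = 1e-12, max_iter = 5e6) {
  phi <- start / sum(start)
  check_every <- 100L
  for (it in seq_len(max_iter)) {
    phi <- as.numeric(R %*% phi)
    if (it %% check_every == 0L) {
      nxt <- as.numeric(R %*% phi)
      if (max(abs(nxt - phi)) < tol) return(nxt)
      phi <- nxt
    }
  }
  abort("power iteration did not converge to the stationary distribution.")
}

#' Propagate a distribution through the chain
#'
#' Applies the one-step transition matrix `steps` times:
#' `phi(t + steps) = R^steps phi(t)`.  Mass is conserved to floating
#' precision at each application; for `tau > 0` repeated application from
#' any start converges geometrically to [stationary_distribution()].
#'
#' @param dist A `marginal_distribution` on the chain's grid.
#' @param chain A [build_reset_chain()] object.
#' @param steps Non-negative integer number of steps.
#' @return The propagated `marginal_distribution`.
#' @export
propagate <- function(dist, chain, steps) {
  stopifnot(inherits(chain, "reset_chain"))
  assert_distribution(dist)
  if (length(dist$mass) != length(chain$grid))
    abort("grid mismatch between distribution and chain.")
  if (steps < 0 || steps != round(steps))
    abort("`steps` must be a non-negative integer.")
  R <- transition_matrix(chain)
  phi <- dist$mass
  for (k in seq_len(steps)) phi <- as.numeric(R %*% phi)
  # guard against floating drift over many applications
  phi <- phi / sum(phi)
  new_marginal_distribution(phi, chain = chain, method = "propagate")
}

#' Uniform and point-mass distributions on a chain's grid
#'
#' Convenience constructors for initial conditions of [propagate()].
#'
#' @param chain A [build_reset_chain()] object.
#' @param state_index Grid index (0-based) of the point mass.
#' @return A `marginal_distribution`.
#' @export
uniform_distribution <- function(chain) {
  n <- length(chain$grid)
  new_marginal_distribution(rep(1 / n, n), chain = chain, method = "uniform")
}

#' @rdname uniform_distribution
#' @export
point_mass <- function(chain, state_index = 0L) {
  n <- length(chain$grid)
  if (state_index < 0 || state_index > n - 1)
    abort("`state_index` outside the grid.")
  mass <- numeric(n)
  mass[state_index + 1L] <- 1
  new_marginal_distribution(mass, chain = chain, method = "point_mass")
}

#' Distribution import and export as TSV
#'
#' Full-double-precision TSV with columns `state_index`, `frequency`,
#' `mass`.
#'
#' @param dist A `marginal_distribution`.
#' @param path File path.
#' @return `read_distribution()` returns a `marginal_distribution`.
#' @export
write_distribution <- function(dist, path) {
  assert_distribution(dist)
  df <- as.data.frame(dist[c("state_index", "frequency", "mass")])
  utils::write.table(format(df, digits = 17, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("state_index", "frequency", "mass") %in% names(tab)))
    abort("distribution TSV must have columns state_index, frequency, mass.")
  tab <- tab[order(tab$state_index), ]
  new_marginal_distribution(tab$mass, method = "file")
}
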