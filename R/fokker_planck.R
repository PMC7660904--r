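#' Drift and diffusion coefficients of the diffusion approximation
#'
#' In the large-`N` limit the marginal chain is approximated by a
#' Fokker-Planck equation with resetting.  `drift()` is the first moment of
#' the per-step frequency change (units: frequency per time step) and
#' `diffusion_sq()` the second moment (frequency squared per time step).
#' For a focal taxon under strict neutrality they reduce to
#' \deqn{a(x) = (1-\tau)\, m (p - x) / N}
#' \deqn{b^2(x) = (1-\tau)\,[\,m (p + x - 2 p x) + 2 (1-m) x (1-x)\,] / N^2}
#' and for the empty-space target, with
#' \eqn{D = (1+\alpha_0) x_0 + (1 - x_0)},
#' \deqn{a_0(x_0) = (1-\tau)\,x_0 \left[-m - (1-m)\left(1 -
#'   \tfrac{1+\alpha_0}{D}\right)\right] / N}
#' \deqn{b_0^2(x_0) = (1-\tau)\,x_0 \left[m + (1-m)\left(1 +
#'   \tfrac{(1+\alpha_0)(1-2 x_0)}{D}\right)\right] / N^2.}
#' Both are exactly `(p_up - p_down) / N` and `(p_up + p_down) / N^2` of the
#' discrete kernel — the identity the package's tests assert.
#'
#' @inheritParams marginal_step_probabilities
#' @param x Numeric vector of frequencies in `[0, 1]` (need not be on the
#'   grid; the coefficients are continuous functions).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' pars <- model_params(N = 1e4, m = 0.01, tau = 0, p = 0.5)
#' drift(0.25, focal_taxon(1), pars)          # 2.5e-7
#' diffusion_sq(0.5, focal_taxon(1), pars)
#' @export
drift <- function(x, target, params) {
  assert_closure(target, params)
  if (anyNA(x) || any(x < 0) || any(x > 1)) abort("`x` must lie in [0, 1].")
  m <- params$m; tau <- params$tau; N <- params$N
  if (target$kind == "taxon") {
    p <- params$p[target$taxon_index]
    (1 - tau) * m * (p - x) / N
  } else {
    a0 <- params$alpha0
    d <- (1 + a0) * x + (1 - x)
    (1 - tau) * x * (-m - (1 - m) * (1 - (1 + a0) / d)) / N
  }
}

#' @rdname drift
#' @export
diffusion_sq <- function(x, target, params) {
  assert_closure(target, params)
  if (anyNA(x) || any(x < 0) || any(x > 1)) abort("`x` must lie in [0, 1].")
  m <- params$m; tau <- params$tau; N <- params$N
  if (target$kind == "taxon") {
    p <- params$p[target$taxon_index]
    (1 - tau) * (m * (p + x - 2 * p * x) + 2 * (1 - m) * x * (1 - x)) / N^2
  } else {
    a0 <- params$alpha0
    d <- (1 + a0) * x + (1 - x)
    (1 - tau) * x * (m + (1 - m) * (1 + (1 + a0) * (1 - 2 * x) / d)) / N^2
  }
}

#' Stationary solution of the Fokker-Planck equation with resetting
#'
#' Discretizes the stationary Fokker-Planck equation
#' \deqn{0 = \frac{d}{dx}\left[-a(x)\Phi + \tfrac12 \frac{d}{dx}
#'   b^2(x)\Phi\right] + \tau(\delta_{reset} - \Phi)}
#' with a conservative (flux-form) central scheme and no-flux boundaries,
#' and solves the resulting sparse linear system under the normalization
#' constraint.
#'
#' This solver is second-class by design: the continuum approximation
#' degrades as `tau` shrinks (the stationary distribution develops mass
#' spikes at the boundaries that the diffusion limit represents poorly), so
#' a fragility warning is emitted for `tau < 1e-6`.  The master-equation
#' solver ([stationary_distribution()]) is the source of truth; accuracy of
#' this one is documented only by comparison against it.
#'
#' @inheritParams marginal_step_probabilities
#' @param grid_size Number of grid points on `[0, 1]` (default `N + 1`).
#' @param scheme Discretization; only `"flux"` (conservative central
#'   differencing) is implemented.
#' @return A `marginal_distribution` on the chosen grid.
#' @export
stationary_fp <- function(target, params, grid_size = params$N + 1L,
                          scheme = c("flux")) {
  assert_closure(target, params)
  scheme <- match.arg(scheme)
  if (grid_size < 3) abort("`grid_size` must be at least 3.")
  tau <- params$tau
  if (tau == 0 && params$m == 0)
    abort("non-unique stationary solution: tau = 0 and m = 0.")
  if (tau > 0 && tau < 1e-6)
    warn("stationary_fp is numerically fragile for tau < 1e-6; prefer stationary_distribution().")

  n <- as.integer(grid_size)
  h <- 1 / (n - 1)
  xg <- (0:(n - 1)) * h
  xm <- (xg[-n] + xg[-1]) / 2                   # midpoints, length n - 1
  a_mid <- drift(xm, target, params)
  b2 <- diffusion_sq(xg, target, params)

  # flux F_{k+1/2} = -a_mid * (phi_k + phi_{k+1})/2 + (b2_{k+1} phi_{k+1} -
  # b2_k phi_k) / (2h); working in cell masses M = phi * h:
  # dM_k/dt = F_{k+1/2} - F_{k-1/2} (+ resetting), no-flux at both ends.
  cK  <- (-a_mid / 2 - b2[-n] / (2 * h)) / h    # coefficient of M_k in F_{k+1/2}
  cK1 <- (-a_mid / 2 + b2[-1] / (2 * h)) / h    # coefficient of M_{k+1}
  idx <- seq_len(n - 1)
  i <- c(idx,     idx,      idx + 1L,  idx + 1L)
  j <- c(idx,     idx + 1L, idx,       idx + 1L)
  v <- c(cK,      cK1,      -cK,       -cK1)
  L <- Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n))

  reset_index <- if (target$kind == "taxon") 1L else n
  A <- L - tau * Matrix::Diagonal(n)
  # the resetting source tau enters only the reset-state balance row, which
  # is redundant (columns sum to zero) and is replaced by normalization
  A[reset_index, ] <- 1
  b <- numeric(n); b[reset_index] <- 1
  phi <- tryCatch(as.numeric(Matrix::solve(A, b)), error = function(e) NULL)
  if (is.null(phi) || !all(is.finite(phi)))
    abort("Fokker-Planck discretization failed to produce a solution.")
  negmass <- sum(pmax(-phi, 0))
  if (negmass > 0.05)
    abort(sprintf(
      "Fokker-Planck discretization non-convergent: %.2g negative mass; refine the grid or use stationary_distribution().",
      negmass))
  phi <- pmax(phi, 0)
  phi <- phi / sum(phi)
  new_marginal_distribution(phi, params = params, target = target,
                            method = "fokker_planck")
}
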