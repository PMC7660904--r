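#' Replacement distribution for a vacated slot
#'
#' When a slot inside a host is vacated, its new content is drawn from the
#' environment with probability `m` (proportionally to the pool frequencies
#' `p_j`, with empty space never immigrating, `p_0 = 0`) and from the host
#' itself with probability `1 - m` (proportionally to the fitness-weighted
#' local frequencies `(1 + alpha_j) * x_j`, including empty space as type 0).
#'
#' @param n Integer vector of occupancy counts `(n_0, n_1, ..., n_M)`, where
#'   `n_0` is the number of empty slots; must sum to `params$N`.
#' @param params A [model_params()] object.
#' @return A numeric probability vector of length `M + 1` over types
#'   `0..M`; sums to 1.
#' @examples
#' pars <- model_params(N = 10, m = 0.3, tau = 0, p = 1)
#' replacement_distribution(c(10, 0), pars)  # sterile host: (0.7, 0.3)
#' @export
replacement_distribution <- function(n, params) {
  assert_params(params)
  n <- check_counts(n, params)
  w <- (1 + c(params$alpha0, params$alpha)) * (n / params$N)
  local <- w / sum(w)                      # sum(w) > 0 since sum(n) = N > 0
  pool <- c(0, params$p)
  params$m * pool + (1 - params$m) * local
}

check_counts <- function(n, params) {
  if (length(n) != params$M + 1L)
    abort(sprintf("`n` must have length M + 1 = %d (empty space first).",
                  params$M + 1L))
  if (anyNA(n) || any(n < 0) || any(n != round(n)))
    abort("`n` must be non-negative integer counts.")
  if (sum(n) != params$N)
    abort(sprintf("counts must sum to N = %d (got %s).", params$N, sum(n)))
  as.integer(n)
}

#' One-step transition probabilities of the marginal chain
#'
#' For a focal type at frequency `x` on the grid `{0, 1/N, ..., 1}`, the
#' process either resets to the microbe-free state (host death, probability
#' `tau`), moves up or down by `1/N`, or stays.  For a focal taxon `i` under
#' strict neutrality (`alpha0 = 0`, all `alpha = 0`):
#' \deqn{P[x \to x + 1/N] = (1-\tau)(1-x)\,[m p + (1-m) x]}
#' \deqn{P[x \to x - 1/N] = (1-\tau)\,x\,[m (1-p) + (1-m)(1-x)]}
#' For the empty-space marginal the local reproduction weight of empty space
#' is \eqn{(1+\alpha_0) x_0 / D} with \eqn{D = (1+\alpha_0) x_0 + (1-x_0)},
#' and empty space never immigrates.  Taxon marginals with non-neutral
#' fitness are refused (no autonomous closure exists); see [focal_taxon()].
#'
#' @param x Numeric vector of focal frequencies in `[0, 1]` (grid values
#'   `k / N` for the exact chain).
#' @param target A [focal_taxon()] or [focal_empty()] target.
#' @param params A [model_params()] object.
#' @return A tibble with columns `x`, `p_reset`, `p_up`, `p_down`, `p_stay`;
#'   each row sums to 1.
#' @examples
#' pars <- model_params(N = 10, m = 0, tau = 0.5, p = 0.5)
#' marginal_step_probabilities(0.5, focal_taxon(1), pars)
#' @export
marginal_step_probabilities <- function(x, target, params) {
  assert_closure(target, params)
  if (anyNA(x) || any(x < 0) || any(x > 1))
    abort("`x` must lie in [0, 1].")
  m <- params$m; tau <- params$tau
  if (target$kind == "taxon") {
    p <- params$p[target$taxon_index]
    up <- (1 - tau) * (1 - x) * (m * p + (1 - m) * x)
    down <- (1 - tau) * x * (m * (1 - p) + (1 - m) * (1 - x))
  } else {
    a0 <- params$alpha0
    d <- (1 + a0) * x + (1 - x)
    up <- (1 - tau) * (1 - x) * (1 - m) * (1 + a0) * x / d
    down <- (1 - tau) * x * (m + (1 - m) * (1 - (1 + a0) * x / d))
  }
  tibble(
    x = x,
    p_reset = rep_len(tau, length(x)),
    p_up = up,
    p_down = down,
    p_stay = 1 - tau - up - down
  )
}
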