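# Independent oracles, written straight from the model definitions rather
# than through the package's solver code paths.

# Detailed-balance product form for the tau = 0 neutral taxon chain:
# pi_k proportional to prod_{j=1..k} up_{j-1} / down_j, computed in log
# space.  up/down are written out directly from the one-step event
# probabilities of the neutral single-taxon process.
oracle_product_form_tau0 <- function(N, m, p) {
  x <- (0:N) / N
  up <- (1 - x) * (m * p + (1 - m) * x)
  down <- x * (m * (1 - p) + (1 - m) * (1 - x))
  if (p == 1) {                       # x = 1 absorbs: all mass there
    pi <- numeric(N + 1); pi[N + 1] <- 1
    return(pi)
  }
  if (p == 0) {                       # x = 0 absorbs
    pi <- numeric(N + 1); pi[1] <- 1
    return(pi)
  }
  logpi <- c(0, cumsum(log(up[1:N]) - log(down[2:(N + 1)])))
  logpi <- logpi - max(logpi)
  pi <- exp(logpi)
  pi / sum(pi)
}

# Exact one-step moments of the frequency change of a focal type for a
# fixed host state, by enumerating every (dying slot, replacement) outcome.
# The host-death branch contributes the survival factor (1 - tau) only:
# the resetting jump is accounted separately in the model, not in the
# drift/diffusion moments.
oracle_step_moments <- function(n, m, tau, p_pool, alpha0, alpha, focal) {
  N <- sum(n)
  K <- length(n)                      # M + 1 types, empty space first
  x <- n / N
  w <- (1 + c(alpha0, alpha)) * x
  repl <- m * c(0, p_pool) + (1 - m) * w / sum(w)
  e1 <- 0; e2 <- 0
  for (j in seq_len(K)) {             # dying slot of type j, prob x_j
    for (k in seq_len(K)) {           # replacement of type k
      dx <- ((k == focal) - (j == focal)) / N
      pr <- x[j] * repl[k]
      e1 <- e1 + pr * dx
      e2 <- e2 + pr * dx^2
    }
  }
  c(mean = (1 - tau) * e1, second = (1 - tau) * e2)
}

# Total variation between two plain mass vectors.
tv_vec <- function(a, b) 0.5 * sum(abs(a - b))
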