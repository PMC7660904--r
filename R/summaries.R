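#' Total-variation difference between two distributions
#'
#' One half the summed absolute difference of the two mass vectors,
#' \eqn{\tfrac12 \sum_x |\Phi_a(x) - \Phi_b(x)|}: ranges from 0 to 1 and
#' equals zero only if the distributions are identical.  Used to quantify
#' how far the finite-lifespan (`tau > 0`) stationary distribution is from
#' the infinite-lifespan (`tau = 0`) prediction.
#'
#' @param a,b `marginal_distribution` objects on the same grid.
#' @return A number in `[0, 1]`.
#' @examples
#' pars <- model_params(N = 50, m = 0.01, tau = 1e-3, p = 0.5)
#' phi <- stationary_distribution(build_reset_chain(focal_taxon(1), pars))
#' total_variation(phi, phi)  # 0
#' @export
total_variation <- function(a, b) {
  assert_distribution(a)
  assert_distribution(b)
  if (length(a$mass) != length(b$mass))
    abort("grid mismatch: distributions have different numbers of states.")
  0.5 * sum(abs(a$mass - b$mass))
}

#' Colonization probabilities from a stationary distribution
#'
#' For a focal taxon: `p_absent` is the probability a host carries none of
#' it (`P[x < 1/N]`, the mass at frequency 0), `p_present = 1 - p_absent`
#' the colonization probability, and `p_full` the probability the taxon
#' occupies the host entirely (`P[x > (N-1)/N]`, the mass at frequency 1).
#' For the empty-space target the boundary roles swap: the mass at
#' `x_0 = 0` is the probability of hosts full of microbes (`p_full`), and
#' the mass at `x_0 = 1` the probability of microbe-free hosts
#' (`p_absent`, with `p_present` the probability a host carries any
#' microbes at all).
#'
#' @param dist A normalized `marginal_distribution`.
#' @param target The focal target the distribution describes; defaults to
#'   the target attached to `dist`.
#' @return A one-row tibble with columns `p_absent`, `p_present`, `p_full`.
#' @export
colonization_probabilities <- function(dist, target = NULL) {
  assert_distribution(dist)
  target <- target %||% attr(dist, "target")
  if (is.null(target))
    abort("`dist` carries no focal target; supply `target` explicitly.")
  n <- length(dist$mass)
  at0 <- dist$mass[1]
  at1 <- dist$mass[n]
  if (target$kind == "taxon") {
    tibble(p_absent = at0, p_present = 1 - at0, p_full = at1)
  } else {
    tibble(p_absent = at1, p_present = 1 - at1, p_full = at0)
  }
}

#' Classify the modality of a stationary distribution
#'
#' Identifies the local maxima of the mass vector after zeroing entries
#' below `zero_threshold` (default `1e-9`), and classifies the distribution
#' as unimodal or bimodal with maxima at the boundaries (`x = 0`, `x = 1`)
#' or at an internal frequency.  Coexistence of a maximum at 0 with another
#' maximum signals alternative microbiome states: host subpopulations
#' dominated by different taxa, or colonized and microbe-free hosts
#' coexisting.
#'
#' A grid point is a maximum if it is strictly greater than both
#' neighbours; at the boundaries, strictly greater than the single
#' neighbour.  A plateau of equal values counts as one maximum located at
#' its first index.  If more than two maxima survive thresholding the two
#' largest are retained and the result is flagged `truncated` (the model's
#' taxonomy is at most bimodal).
#'
#' @param dist A normalized `marginal_distribution`.
#' @param zero_threshold Mass below this value is treated as exactly zero
#'   before maxima detection.
#' @return A `modality_label`: list with `category` (one of
#'   `unimodal_at_0`, `unimodal_at_1`, `unimodal_internal`,
#'   `bimodal_0_and_1`, `bimodal_0_and_internal`,
#'   `bimodal_internal_and_1`, `bimodal_internal_pair`), `maxima` (tibble
#'   of `state_index`, `frequency`, `mass`), and `truncated`.
#' @examples
#' pars <- model_params(N = 100, m = 0.01, tau = 1e-3, p = 0.5)
#' phi <- stationary_distribution(build_reset_chain(focal_taxon(1), pars))
#' classify_modality(phi)
#' @export
classify_modality <- function(dist, zero_threshold = 1e-9) {
  assert_distribution(dist)
  v <- dist$mass
  v[v < zero_threshold] <- 0
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_max <- vapply(seq_len(k), function(q) {
    if (r$values[q] <= 0) return(FALSE)
    left_ok <- q == 1L || r$values[q - 1L] < r$values[q]
    right_ok <- q == k || r$values[q + 1L] < r$values[q]
    left_ok && right_ok
  }, logical(1))
  maxima <- tibble(
    state_index = starts[is_max] - 1L,
    frequency = dist$frequency[starts[is_max]],
    mass = r$values[is_max]
  )
  if (nrow(maxima) == 0)
    abort("no maxima above `zero_threshold`; the distribution is numerically zero.")
  truncated <- nrow(maxima) > 2
  if (truncated) {
    keep <- order(maxima$mass, decreasing = TRUE)[1:2]
    maxima <- maxima[sort(keep), ]
  }
  n_last <- length(v) - 1L
  pos <- vapply(maxima$state_index, function(s) {
    if (s == 0L) "0" else if (s == n_last) "1" else "internal"
  }, character(1))
  category <- if (nrow(maxima) == 1L) {
    switch(pos, "0" = "unimodal_at_0", "1" = "unimodal_at_1",
           "internal" = "unimodal_internal")
  } else {
    key <- paste(pos, collapse = "+")
    switch(key,
           "0+1" = "bimodal_0_and_1",
           "0+internal" = "bimodal_0_and_internal",
           "internal+1" = "bimodal_internal_and_1",
           "internal+internal" = "bimodal_internal_pair",
           abort(sprintf("unexpected maxima arrangement: %s", key)))
  }
  structure(list(category = category, maxima = maxima, truncated = truncated),
            class = "modality_label")
}

#' @export
print.modality_label <- function(x, ...) {
  cat("<modality_label>", x$category,
      if (x$truncated) "(multimodal_truncated)" else "", "\n")
  print(x$maxima)
  invisible(x)
}

#' Sample host states at geometrically distributed host deaths
#'
#' The stationary population-level distribution of a finite-lifespan host
#' population is the lifespan-weighted mixture of the reset-free
#' colonization transients: each host is observed at the moment of its
#' death, and lifespans are geometrically distributed,
#' `P[t] = tau * (1 - tau)^t` for `t = 0, 1, 2, ...` (the discrete
#' counterpart of an exponential lifespan density).  This function draws
#' one lifespan per host and extracts the recorded state nearest that time
#' from a trajectory simulated *without* host death (`tau = 0` in the
#' simulator).
#'
#' @param trajectory A [simulate_population()] result.
#' @param tau Host death-birth probability used for the lifespan draws
#'   (`0 < tau <= 1`).
#' @param seed Integer seed for the lifespan draws.
#' @return A tibble of sampled host states in long form: columns
#'   `host_id`, `lifespan`, `time` (nearest recorded time), `type_index`,
#'   `count`; carries the trajectory's `params` as an attribute.
#' @export
sample_at_host_death <- function(trajectory, tau, seed = 1L) {
  stopifnot(inherits(trajectory, "population_trajectory"))
  if (length(tau) != 1L || is.na(tau) || tau <= 0 || tau > 1)
    abort("`tau` must be a single probability in (0, 1].")
  horizon <- max(trajectory$sample_times)
  trunc_mass <- (1 - tau)^(horizon + 1)
  if (trunc_mass > 0.01)
    warn(sprintf(
      "trajectory horizon %d truncates %.1f%% of the lifespan distribution; simulate longer.",
      horizon, 100 * trunc_mass))
  n_hosts <- trajectory$n_hosts
  lifespans <- withr::with_seed(as.integer(seed),
                                stats::rgeom(n_hosts, tau))
  lifespans <- pmin(lifespans, horizon)
  nearest <- vapply(lifespans, function(t)
    which.min(abs(trajectory$sample_times - t)), integer(1))
  K <- dim(trajectory$counts)[2]
  out <- tibble(
    host_id = rep(seq_len(n_hosts), each = K),
    lifespan = rep(lifespans, each = K),
    time = rep(trajectory$sample_times[nearest], each = K),
    type_index = rep(0:(K - 1L), times = n_hosts),
    count = as.integer(vapply(seq_len(n_hosts), function(h)
      trajectory$counts[nearest[h], , h], integer(K)))
  )
  attr(out, "params") <- trajectory$params
  out
}

#' Empirical marginal distribution of a focal type
#'
#' Normalized histogram of per-host focal-type counts on the frequency grid
#' `{0, 1/N, ..., 1}`, comparable to solver output via
#' [total_variation()].
#'
#' @param states A tibble of host states in long form (columns `host_id`,
#'   `type_index`, `count`), e.g. from [sample_at_host_death()], or an
#'   integer vector of focal-type counts.
#' @param target The focal target whose counts to histogram.
#' @param params A [model_params()] object; defaults to the `params`
#'   attribute of `states`.
#' @return A `marginal_distribution`.
#' @export
empirical_distribution <- function(states, target, params = NULL) {
  params <- params %||% attr(states, "params")
  assert_params(params)
  assert_target(target, params)
  if (is.data.frame(states)) {
    want <- if (target$kind == "taxon") target$taxon_index else 0L
    counts <- states$count[states$type_index == want]
  } else {
    counts <- states
  }
  if (length(counts) == 0) abort("no states supplied.")
  if (anyNA(counts) || any(counts < 0) || any(counts > params$N))
    abort("counts must lie in 0..N.")
  mass <- tabulate(counts + 1L, nbins = params$N + 1L)
  new_marginal_distribution(mass / sum(mass), params = params,
                            target = target, method = "empirical")
}
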