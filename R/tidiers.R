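#' Tidy and summarize model objects
#'
#' broom-style methods: `tidy()` returns one row per grid state (or per
#' maximum, for modality labels) and `glance()` a one-row summary.
#'
#' @param x A `marginal_distribution`, `reset_chain`, `modality_label` or
#'   `population_trajectory`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy marginal_distribution
#' @export
tidy.marginal_distribution <- function(x, ...) {
  tibble(state_index = x$state_index, frequency = x$frequency, mass = x$mass)
}

#' @rdname tidiers
#' @method glance marginal_distribution
#' @export
glance.marginal_distribution <- function(x, ...) {
  target <- attr(x, "target")
  tibble(
    n_states = length(x$mass),
    method = attr(x, "method") %||% "unknown",
    mean_frequency = sum(x$frequency * x$mass),
    mass_at_0 = x$mass[1],
    mass_at_1 = x$mass[length(x$mass)],
    target_kind = if (is.null(target)) NA_character_ else target$kind
  )
}

#' @rdname tidiers
#' @method tidy reset_chain
#' @export
tidy.reset_chain <- function(x, ...) {
  tibble(
    state_index = seq_along(x$grid) - 1L,
    frequency = x$grid,
    p_up = x$up,
    p_down = x$down,
    p_stay = x$stay,
    p_reset = rep(x$tau, length(x$grid))
  )
}

#' @rdname tidiers
#' @method glance reset_chain
#' @export
glance.reset_chain <- function(x, ...) {
  tibble(
    n_states = length(x$grid),
    N = x$params$N,
    m = x$params$m,
    tau = x$tau,
    target_kind = x$target$kind,
    reset_frequency = x$grid[x$reset_index]
  )
}

#' @rdname tidiers
#' @method tidy modality_label
#' @export
tidy.modality_label <- function(x, ...) {
  dplyr::mutate(x$maxima, category = x$category, truncated = x$truncated)
}

#' @rdname tidiers
#' @method glance population_trajectory
#' @export
glance.population_trajectory <- function(x, ...) {
  tibble(
    n_hosts = x$n_hosts,
    n_recorded_times = length(x$sample_times),
    horizon = max(x$sample_times),
    N = x$params$N,
    M = x$params$M,
    m = x$params$m,
    tau = x$params$tau,
    seed = x$seed
  )
}
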