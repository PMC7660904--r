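#' Advance one host by a single time step
#'
#' Applies the one-step kernel to a single host: with probability `tau` the
#' host dies and is replaced by a microbe-free newborn (`n_0 = N`); otherwise
#' one of the `N` slots is selected uniformly, its content dies, and it is
#' refilled by a draw from [replacement_distribution()].
#'
#' Uses R's global random number stream; call `set.seed()` for
#' reproducibility.
#'
#' @inheritParams replacement_distribution
#' @return The updated integer count vector (length `M + 1`).
#' @export
step_host <- function(n, params) {
  assert_params(params)
  n <- check_counts(n, params)
  out <- sim_host_counts(n, 1L, 1L, params$m, params$tau,
                         c(0, params$p), c(params$alpha0, params$alpha))
  as.integer(out[1L, ])
}

#' Simulate a population of hosts
#'
#' Runs `n_hosts` independent replicate hosts of the full multi-taxon
#' within-host process (arbitrary fitness offsets allowed), each for
#' `n_steps` events, recording occupancy counts every `sample_every` steps.
#' Hosts do not interact except through the shared constant pool of
#' colonizers, so each host is driven by its own RNG substream (derived from
#' `seed` with L'Ecuyer-CMRG streams): adding hosts never perturbs the
#' trajectories of existing ones, and the same seed reproduces the
#' trajectory exactly.
#'
#' Time is measured in within-host microbial death-birth events; each host
#' carries its own event clock.
#'
#' @param params A [model_params()] object.  A full-community simulation
#'   requires the pool frequencies to sum to 1 (`sum(p) == 1` within 1e-12).
#' @param n_hosts Number of replicate hosts (positive integer).
#' @param n_steps Number of time steps per host (`>= 1`).
#' @param sample_every Recording cadence in steps (default 10); the initial
#'   state at time 0 is always recorded.
#' @param seed Integer master seed.
#' @param initial Integer count vector `(n_0, ..., n_M)` used as the initial
#'   state of every host; default is the microbe-free state `n_0 = N`.
#' @param max_bytes Memory budget for the recorded array; configurations
#'   exceeding it are refused with an explicit error.
#' @return A `population_trajectory` object: list with `counts` (integer
#'   array `time x type x host`), `sample_times`, `params`, `n_hosts`,
#'   `seed`.  Convert to a tidy table with [as_tibble()][tibble::as_tibble].
#' @examples
#' pars <- model_params(N = 50, m = 0.1, tau = 0, p = c(0.5, 0.5))
#' traj <- simulate_population(pars, n_hosts = 4, n_steps = 200, seed = 1)
#' traj
#' @export
simulate_population <- function(params, n_hosts, n_steps, sample_every = 10L,
                                seed = 1L, initial = NULL,
                                max_bytes = 2e9) {
  assert_params(params)
  if (params$M < 1)
    abort("simulation needs at least one taxon (length(p) >= 1).")
  if (abs(sum(params$p) - 1) > 1e-12)
    abort("a full-community simulation requires sum(p) = 1 (p0 = 0 always).")
  if (n_hosts < 1 || n_steps < 1 || sample_every < 1)
    abort("`n_hosts`, `n_steps` and `sample_every` must be positive.")
  n_hosts <- as.integer(n_hosts)
  n_steps <- as.integer(n_steps)
  if (is.null(initial)) initial <- c(params$N, integer(params$M))
  initial <- check_counts(initial, params)

  sample_times <- seq.int(0L, n_steps, by = as.integer(sample_every))
  need <- as.double(length(sample_times)) * (params$M + 1) * n_hosts * 4
  if (need > max_bytes)
    abort(sprintf(
      "recorded array would need %.2g bytes (> max_bytes = %.2g); increase sample_every or raise max_bytes.",
      need, max_bytes))

  counts <- array(NA_integer_,
                  dim = c(length(sample_times), params$M + 1L, n_hosts))
  pool <- c(0, params$p)
  alpha <- c(params$alpha0, params$alpha)

  withr::with_seed(as.integer(seed), {
    stream <- .Random.seed
    for (h in seq_len(n_hosts)) {
      stream <- parallel::nextRNGStream(stream)
      assign(".Random.seed", stream, envir = globalenv())
      counts[, , h] <- sim_host_counts(initial, n_steps, sample_times,
                                       params$m, params$tau, pool, alpha)
    }
  }, .rng_kind = "L'Ecuyer-CMRG")

  structure(
    list(counts = counts, sample_times = sample_times, params = params,
         n_hosts = n_hosts, seed = as.integer(seed)),
    class = "population_trajectory"
  )
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat("<population_trajectory>\n")
  cat(sprintf("  %d hosts, %d recorded times (0..%d every %d steps)\n",
              x$n_hosts, length(x$sample_times),
              max(x$sample_times),
              if (length(x$sample_times) > 1)
                diff(x$sample_times[1:2]) else 0L))
  cat(sprintf("  N = %d, M = %d, m = %g, tau = %g, seed = %d\n",
              x$params$N, x$params$M, x$params$m, x$params$tau, x$seed))
  invisible(x)
}

#' @method as_tibble population_trajectory
#' @export
as_tibble.population_trajectory <- function(x, ...) {
  d <- dim(x$counts)
  tibble(
    host_id = rep(seq_len(d[3]), each = d[1] * d[2]),
    time = rep(rep(x$sample_times, times = d[2]), times = d[3]),
    type_index = rep(rep(0:(d[2] - 1L), each = d[1]), times = d[3]),
    count = as.integer(x$counts)
  )
}

#' Trajectory import and export as tidy TSV
#'
#' `write_trajectory()` writes the tidy long form (columns `host_id`,
#' `time`, `type_index`, `count`) to a tab-separated file;
#' `read_trajectory()` reconstructs the `population_trajectory` object
#' given the generating parameters.
#'
#' @param x A `population_trajectory`.
#' @param path File path.
#' @param params,seed Parameters and seed to attach on read (the TSV holds
#'   only the recorded counts).
#' @return `read_trajectory()` returns a `population_trajectory`.
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "population_trajectory"))
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, params, seed = NA_integer_) {
  assert_params(params)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("host_id", "time", "type_index", "count")
  if (!all(needed %in% names(tab)))
    abort("trajectory TSV must have columns host_id, time, type_index, count.")
  sample_times <- sort(unique(tab$time))
  hosts <- sort(unique(tab$host_id))
  types <- as.integer(sort(unique(tab$type_index)))
  if (!identical(types, 0:(params$M)))
    abort("type indices in file do not match params (expected 0..M).")
  tab <- dplyr::arrange(tab, .data$host_id, .data$type_index, .data$time)
  counts <- array(as.integer(tab$count),
                  dim = c(length(sample_times), length(types), length(hosts)))
  structure(
    list(counts = counts, sample_times = as.integer(sample_times),
         params = params, n_hosts = length(hosts), seed = as.integer(seed)),
    class = "population_trajectory"
  )
}
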