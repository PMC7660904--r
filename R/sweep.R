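#' Configuration of an (m, tau) parameter sweep
#'
#' Describes a rectangular scan over migration probabilities and host
#' death-birth probabilities for one or more focal targets, the engine
#' behind the model's phase maps: per grid cell the stationary distribution
#' is solved and summarized (colonization probabilities, modality, and the
#' total-variation difference to the infinite-lifespan `tau = 0`
#' reference).
#'
#' @param m_grid,tau_grid Strictly increasing, non-empty numeric grids
#'   (typically log-spaced, e.g. via [log_grid()]).  `tau_grid` may include
#'   0 (the infinite-lifespan reference column).
#' @param N Host capacity.
#' @param targets List of target descriptors; each is a list with elements
#'   `target` (a [focal_taxon()] or [focal_empty()]), `p_focal` (pool
#'   frequency, ignored for empty space) and optionally `alpha0`
#'   (default 0).
#' @param zero_threshold Modality-classification threshold, see
#'   [classify_modality()].
#' @param seed Integer recorded in the manifest (the sweep itself is
#'   deterministic).
#' @return A `sweep_config` object.
#' @examples
#' cfg <- sweep_config(
#'   m_grid = log_grid(1e-3, 1e-1, 3), tau_grid = log_grid(1e-4, 1e-2, 3),
#'   N = 100, targets = list(list(target = focal_taxon(1), p_focal = 0.5)))
#' @export
sweep_config <- function(m_grid, tau_grid, N,
                         targets = list(list(target = focal_empty(),
                                             p_focal = 0, alpha0 = 0)),
                         zero_threshold = 1e-9, seed = 1L) {
  m_grid <- as.numeric(m_grid); tau_grid <- as.numeric(tau_grid)
  if (length(m_grid) == 0 || length(tau_grid) == 0)
    abort("`m_grid` and `tau_grid` must be non-empty.")
  if (is.unsorted(m_grid, strictly = TRUE) ||
      is.unsorted(tau_grid, strictly = TRUE))
    abort("grids must be strictly increasing.")
  if (any(m_grid < 0 | m_grid > 1) || any(tau_grid < 0 | tau_grid > 1))
    abort("grid values must lie in [0, 1].")
  if (!is.list(targets) || length(targets) == 0)
    abort("`targets` must be a non-empty list.")
  targets <- lapply(targets, function(tg) {
    if (!is.list(tg) || !is_focal_target(tg$target))
      abort("each target entry must be list(target = focal_*(), p_focal = ..., alpha0 = ...).")
    tg$alpha0 <- tg$alpha0 %||% 0
    tg$p_focal <- tg$p_focal %||% 0
    if (tg$target$kind == "taxon" &&
        (tg$p_focal < 0 || tg$p_focal > 1))
      abort("`p_focal` must lie in [0, 1].")
    tg
  })
  structure(
    list(m_grid = m_grid, tau_grid = tau_grid, N = as.integer(N),
         targets = targets, zero_threshold = zero_threshold,
         seed = as.integer(seed)),
    class = "sweep_config"
  )
}

#' Log-spaced grid with fixed per-decade density
#'
#' @param from,to Positive range endpoints.
#' @param points_per_decade Grid density (default 5).
#' @return Strictly increasing numeric vector including both endpoints.
#' @export
log_grid <- function(from, to, points_per_decade = 5) {
  if (from <= 0 || to <= from) abort("need 0 < from < to.")
  n <- max(2L, ceiling(log10(to / from) * points_per_decade) + 1L)
  10^seq(log10(from), log10(to), length.out = n)
}

#' Read a sweep configuration from a YAML file
#'
#' Flat key-value schema: `N`, `m_grid`, `tau_grid` (explicit lists, or
#' maps with `from`/`to`/`points_per_decade` expanded via [log_grid()]),
#' `zero_threshold`, `seed`, and `targets`, a list of maps with `kind`
#' (`"taxon"` or `"empty"`), `p_focal` and `alpha0`.
#'
#' @param path YAML file path.
#' @return A `sweep_config`.
#' @export
read_sweep_config <- function(path) {
  # keep YAML-1.1 boolean-like scalars (notably the key "N") as strings
  raw <- yaml::read_yaml(path, handlers = list("bool#yes" = function(x) x,
                                               "bool#no" = function(x) x))
  need <- c("N", "m_grid", "tau_grid")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0)
    abort(sprintf("sweep config is missing required keys: %s",
                  paste(missing, collapse = ", ")))
  expand_grid_key <- function(g, key) {
    if (is.list(g) && all(c("from", "to") %in% names(g)))
      return(log_grid(g$from, g$to, g$points_per_decade %||% 5))
    g <- suppressWarnings(as.numeric(unlist(g)))
    if (anyNA(g))
      abort(sprintf("`%s` must be numeric or a from/to/points_per_decade map.", key))
    g
  }
  targets <- lapply(raw$targets %||% list(list(kind = "empty")), function(tg) {
    kind <- tg$kind %||% "taxon"
    if (!kind %in% c("taxon", "empty", "empty_space"))
      abort("target `kind` must be 'taxon' or 'empty'.")
    list(
      target = if (kind == "taxon") focal_taxon(1) else focal_empty(),
      p_focal = tg$p_focal %||% 0,
      alpha0 = tg$alpha0 %||% 0
    )
  })
  sweep_config(
    m_grid = expand_grid_key(raw$m_grid, "m_grid"),
    tau_grid = expand_grid_key(raw$tau_grid, "tau_grid"),
    N = raw$N,
    targets = targets,
    zero_threshold = raw$zero_threshold %||% 1e-9,
    seed = raw$seed %||% 1L
  )
}

cell_params <- function(cfg, tg, m, tau) {
  if (tg$target$kind == "taxon") {
    model_params(N = cfg$N, m = m, tau = tau, p = tg$p_focal, alpha0 = 0)
  } else {
    model_params(N = cfg$N, m = m, tau = tau, p = numeric(),
                 alpha0 = tg$alpha0)
  }
}

#' Run an (m, tau) sweep of stationary summaries
#'
#' For every cell of the configured grid the reset-chain stationary
#' distribution is solved and summarized.  Solver failures in individual
#' cells are recorded in the `status` column and the sweep continues.  The
#' result carries a manifest (configuration, package version, seed, hash)
#' as an attribute; re-running the same configuration yields an identical
#' table.
#'
#' @param config A [sweep_config()].
#' @return A tibble of class `sweep_result`, one row per
#'   `(target, m, tau)` cell with columns `target_kind`, `p_focal`,
#'   `alpha0`, `m`, `tau`, `p_absent`, `p_present`, `p_full`, `modality`,
#'   `internal_max_frequency`, `tv_to_tau0`, `status`.
#' @export
run_sweep <- function(config) {
  if (!inherits(config, "sweep_config"))
    abort("`config` must be a sweep_config().")
  rows <- list()
  for (tg in config$targets) {
    # tau = 0 reference per m column (infinite host lifespan)
    refs <- lapply(config$m_grid, function(m) {
      tryCatch(
        stationary_distribution(
          build_reset_chain(tg$target, cell_params(config, tg, m, 0))),
        error = function(e) NULL)
    })
    for (im in seq_along(config$m_grid)) {
      m <- config$m_grid[im]
      for (tau in config$tau_grid) {
        row <- tibble(
          target_kind = tg$target$kind,
          p_focal = if (tg$target$kind == "taxon") tg$p_focal else 0,
          alpha0 = tg$alpha0,
          m = m, tau = tau,
          p_absent = NA_real_, p_present = NA_real_, p_full = NA_real_,
          modality = NA_character_, internal_max_frequency = NA_real_,
          tv_to_tau0 = NA_real_, status = "ok"
        )
        res <- tryCatch({
          pars <- cell_params(config, tg, m, tau)
          phi <- stationary_distribution(build_reset_chain(tg$target, pars))
          cp <- colonization_probabilities(phi, tg$target)
          mod <- classify_modality(phi, config$zero_threshold)
          internal <- mod$maxima$frequency[
            mod$maxima$state_index > 0 &
            mod$maxima$state_index < config$N]
          list(phi = phi, cp = cp, mod = mod,
               internal = if (length(internal) > 0) internal[1] else NA_real_)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          row$status <- conditionMessage(res)
        } else {
          row$p_absent <- res$cp$p_absent
          row$p_present <- res$cp$p_present
          row$p_full <- res$cp$p_full
          row$modality <- res$mod$category
          row$internal_max_frequency <- res$internal
          row$tv_to_tau0 <- if (is.null(refs[[im]])) NA_real_ else
            total_variation(res$phi, refs[[im]])
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  manifest <- list(
    config = config,
    package_version = as.character(utils::packageVersion("finitehost")),
    seed = config$seed
  )
  manifest$hash <- rlang::hash(manifest)
  attr(out, "manifest") <- manifest
  out
}

#' Write a sweep result with its manifest
#'
#' The CSV carries the manifest hash as a `#`-prefixed header comment; the
#' full manifest is written alongside as plain text.
#'
#' @param x A [run_sweep()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the CSV path.
#' @export
write_sweep_result <- function(x, dir) {
  stopifnot(inherits(x, "sweep_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- attr(x, "manifest")
  csv <- file.path(dir, "sweep.csv")
  con <- file(csv, open = "wt")
  writeLines(sprintf("# finitehost sweep manifest_hash: %s", manifest$hash), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  close(con)
  writeLines(c(
    sprintf("manifest_hash: %s", manifest$hash),
    sprintf("package_version: %s", manifest$package_version),
    sprintf("seed: %d", manifest$seed),
    utils::capture.output(utils::str(manifest$config))
  ), file.path(dir, "manifest.txt"))
  invisible(csv)
}

#' Locate the bimodality window along the tau axis
#'
#' Scans a log-spaced tau grid at fixed migration `m`, classifies the
#' stationary distribution of each cell, and returns the smallest and
#' largest tau whose distribution is bimodal, with each edge refined by
#' bisection (in log tau) against its nearest non-bimodal neighbour to a
#' stated relative tolerance.  An empty window (no bimodal cell) is an
#' explicit result, not an error.
#'
#' @param target A [focal_taxon()] or [focal_empty()] target.
#' @param params A [model_params()] object; its `tau` is ignored (scanned).
#' @param tau_range Length-2 positive range to scan.
#' @param points_per_decade Scan density (at least 5 recommended).
#' @param zero_threshold Passed to [classify_modality()].
#' @param rel_tol Relative tolerance of the refined edges (default 5%).
#' @return A list with `found` (logical), `tau_low`, `tau_high` (NA when
#'   not found), and `scan`, the tibble of classified grid cells.
#' @export
find_bimodality_boundaries <- function(target, params,
                                       tau_range = c(1e-9, 1e-3),
                                       points_per_decade = 5,
                                       zero_threshold = 1e-9,
                                       rel_tol = 0.05) {
  assert_closure(target, params)
  if (length(tau_range) != 2 || any(tau_range <= 0) ||
      tau_range[2] <= tau_range[1])
    abort("`tau_range` must be an increasing positive pair.")
  taus <- log_grid(tau_range[1], tau_range[2], points_per_decade)
  is_bimodal <- function(tau) {
    pars <- model_params(N = params$N, m = params$m, tau = tau,
                         p = params$p, alpha0 = params$alpha0,
                         alpha = params$alpha)
    phi <- stationary_distribution(build_reset_chain(target, pars))
    startsWith(classify_modality(phi, zero_threshold)$category, "bimodal")
  }
  flags <- vapply(taus, is_bimodal, logical(1))
  scan <- tibble(tau = taus, bimodal = flags)
  if (!any(flags))
    return(list(found = FALSE, tau_low = NA_real_, tau_high = NA_real_,
                scan = scan))
  bisect <- function(lo, hi) {
    # invariant: classification differs between lo and hi
    while (hi / lo > 1 + rel_tol) {
      mid <- sqrt(lo * hi)
      if (is_bimodal(mid) == is_bimodal(lo)) lo <- mid else hi <- mid
    }
    c(lo, hi)
  }
  first <- which(flags)[1]
  last <- which(flags)[sum(flags)]
  tau_low <- if (first == 1L) taus[1] else {
    br <- bisect(taus[first - 1L], taus[first])
    br[2]
  }
  tau_high <- if (last == length(taus)) taus[length(taus)] else {
    br <- bisect(taus[last], taus[last + 1L])
    br[1]
  }
  list(found = TRUE, tau_low = tau_low, tau_high = tau_high, scan = scan)
}
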