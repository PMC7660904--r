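#' Parameters of the host-microbiome colonization model
#'
#' Bundles and validates all parameters of the within-host death-birth
#' stochastic process: hosts hold `N` microbe-sized slots; at every time step
#' one slot is vacated and refilled either by a migrant from an external pool
#' of colonizers (probability `m`, pool frequencies `p`) or by local
#' reproduction weighted by fitness `(1 + alpha_j) * x_j`; in addition, with
#' probability `tau` per step the host dies and is replaced by a microbe-free
#' newborn.  Index 0 is reserved for unoccupied space, a pseudo-type with
#' reproduction weight `(1 + alpha0) * x_0` and pool frequency zero, so
#' `alpha0` tunes the host's resistance to being filled.
#'
#' A marginal (single focal type) analysis allows an arbitrary `p` for the
#' focal taxon; a full-community simulation additionally requires
#' `sum(p) == 1`, which [simulate_population()] enforces.
#'
#' @param N Host capacity: number of microbe-sized slots (integer, `>= 2`).
#' @param m Migration probability per replacement event, in `[0, 1]`.
#' @param tau Host death-birth probability per time step, in `[0, 1]`.
#'   `tau = 0` corresponds to infinitely-lived hosts; `tau = 1` to hosts as
#'   short-lived as a single microbe generation.
#' @param p Numeric vector of pool-of-colonizer frequencies, one per taxon,
#'   each in `[0, 1]`.  May be empty when only the unoccupied-space marginal
#'   is of interest.
#' @param alpha0 Occupation-resistance fitness offset of empty space
#'   (`> -1`).  Negative values make empty space fill faster.
#' @param alpha Numeric vector of fitness offsets of the taxa (each `> -1`),
#'   recycled to `length(p)`; the neutral case is all zeros.
#'
#' @return An object of class `model_params`: a named list with fields
#'   `N`, `M` (number of taxa), `m`, `tau`, `p`, `alpha0`, `alpha`.
#' @examples
#' model_params(N = 100, m = 0.01, tau = 1e-3, p = c(0.5, 0.5))
#' @export
model_params <- function(N, m, tau, p = numeric(), alpha0 = 0,
                         alpha = rep(0, length(p))) {
  if (length(N) != 1L || !is.numeric(N) || is.na(N) || N < 2 || N != round(N))
    abort("`N` must be a single integer >= 2.")
  if (length(m) != 1L || !is.numeric(m) || is.na(m) || m < 0 || m > 1)
    abort("`m` must be a single probability in [0, 1].")
  if (length(tau) != 1L || !is.numeric(tau) || is.na(tau) || tau < 0 || tau > 1)
    abort("`tau` must be a single probability in [0, 1].")
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    abort("`p` entries must be probabilities in [0, 1].")
  if (length(alpha0) != 1L || !is.numeric(alpha0) || is.na(alpha0) || alpha0 <= -1)
    abort("`alpha0` must be a single number > -1.")
  alpha <- rep_len(as.numeric(alpha), length(p))
  if (anyNA(alpha) || any(alpha <= -1))
    abort("`alpha` entries must all be > -1.")
  structure(
    list(N = as.integer(N), M = length(p), m = m, tau = tau,
         p = p, alpha0 = alpha0, alpha = alpha),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  N = %d slots, M = %d taxa\n", x$N, x$M))
  cat(sprintf("  m = %g (migration), tau = %g (host death-birth)\n", x$m, x$tau))
  if (x$M > 0) {
    cat("  p =", paste(signif(x$p, 4), collapse = ", "), "\n")
    cat("  alpha =", paste(signif(x$alpha, 4), collapse = ", "), "\n")
  }
  cat(sprintf("  alpha0 = %g (empty-space occupation resistance)\n", x$alpha0))
  invisible(x)
}

is_model_params <- function(x) inherits(x, "model_params")

assert_params <- function(params) {
  if (!is_model_params(params))
    abort("`params` must be created with model_params().")
  invisible(params)
}

#' Focal targets for marginal analyses
#'
#' The marginal (single-type) solvers track either one microbial taxon or the
#' unoccupied space inside hosts.  `focal_taxon(i)` selects taxon `i` (its
#' pool frequency is `params$p[i]`); `focal_empty()` selects unoccupied
#' space, whose pool frequency is identically zero and whose resetting state
#' at host death is full vacancy (`x_0 = 1`).
#'
#' @param taxon_index Positive integer index of the focal taxon.
#' @return An object of class `focal_target`.
#' @examples
#' focal_taxon(1)
#' focal_empty()
#' @export
focal_taxon <- function(taxon_index = 1L) {
  if (length(taxon_index) != 1L || is.na(taxon_index) ||
      taxon_index < 1 || taxon_index != round(taxon_index))
    abort("`taxon_index` must be a single positive integer.")
  structure(list(kind = "taxon", taxon_index = as.integer(taxon_index)),
            class = "focal_target")
}

#' @rdname focal_taxon
#' @export
focal_empty <- function() {
  structure(list(kind = "empty_space", taxon_index = NA_integer_),
            class = "focal_target")
}

#' @export
print.focal_target <- function(x, ...) {
  if (x$kind == "taxon") {
    cat(sprintf("<focal_target> taxon %d\n", x$taxon_index))
  } else {
    cat("<focal_target> empty space (x0)\n")
  }
  invisible(x)
}

is_focal_target <- function(x) inherits(x, "focal_target")

assert_target <- function(target, params) {
  if (!is_focal_target(target))
    abort("`target` must be created with focal_taxon() or focal_empty().")
  if (target$kind == "taxon" && target$taxon_index > params$M)
    abort(sprintf("focal taxon %d does not exist: params has M = %d taxa.",
                  target$taxon_index, params$M))
  invisible(target)
}

#' Pool frequency of a focal target
#'
#' @param target A [focal_taxon()] or [focal_empty()] target.
#' @param params A [model_params()] object.
#' @return The pool-of-colonizers frequency of the target (0 for empty space).
#' @export
p_focal <- function(target, params) {
  assert_params(params)
  assert_target(target, params)
  if (target$kind == "empty_space") 0 else params$p[target$taxon_index]
}

# The single-type marginal dynamics is autonomous only when the local
# reproduction weights reduce to a function of the focal frequency alone:
# always true for the empty-space marginal (the taxa are interchangeable
# given x0 when all alpha_i = 0), and true for a taxon marginal only in the
# strictly neutral case alpha0 = 0, alpha_i = 0 (total weight sums to 1).
closure_holds <- function(target, params) {
  if (target$kind == "empty_space") {
    all(params$alpha == 0)
  } else {
    params$alpha0 == 0 && all(params$alpha == 0)
  }
}

assert_closure <- function(target, params) {
  assert_params(params)
  assert_target(target, params)
  if (!closure_holds(target, params)) {
    abort(paste0(
      "marginal closure unavailable: the single-type marginal dynamics is ",
      "autonomous only for the empty-space target with all alpha_i = 0, or ",
      "for a taxon target with alpha0 = 0 and all alpha_i = 0. ",
      "Use the individual-based simulator for other fitness configurations."
    ))
  }
  invisible(target)
}
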