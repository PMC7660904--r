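test_that("the one-step matrix matches hand-computed event probabilities", {
  # N = 3, tau = 0.1, m = 0.5, p = 0.5, neutral: all 16 entries by hand
  pars <- model_params(N = 3, m = 0.5, tau = 0.1, p = 0.5)
  R <- as.matrix(transition_matrix(build_reset_chain(focal_taxon(1), pars)))
  x <- (0:3) / 3
  up <- 0.9 * (1 - x) * (0.5 * 0.5 + 0.5 * x)
  down <- 0.9 * x * (0.5 * 0.5 + 0.5 * (1 - x))
  expected <- matrix(0, 4, 4)
  for (j in 1:4) {
    if (j < 4) expected[j + 1, j] <- up[j]
    if (j > 1) expected[j - 1, j] <- down[j]
    expected[j, j] <- expected[j, j] + 1 - 0.1 - up[j] - down[j]
    expected[1, j] <- expected[1, j] + 0.1       # resetting into x = 0
  }
  expect_equal(R, expected, tolerance = 1e-15)
})

test_that("reset flow goes to the full-vacancy boundary for empty space", {
  pars <- model_params(N = 10, m = 0.3, tau = 0.2, alpha0 = 0)
  ch <- build_reset_chain(focal_empty(), pars)
  expect_equal(ch$reset_index, 11L)
  R <- transition_matrix(ch)
  # every column feeds tau into the x0 = 1 state
  expect_true(all(as.matrix(R)[11, ] >= 0.2))
})

test_that("columns of the reset-augmented matrix sum to one exactly", {
  for (m in c(0, 0.001, 0.3, 1)) {
    for (tau in c(0, 1e-6, 0.5, 1)) {
      pars <- model_params(N = 60, m = m, tau = tau, p = 0.25)
      R <- transition_matrix(build_reset_chain(focal_taxon(1), pars))
      expect_lt(max(abs(Matrix::colSums(R) - 1)), 1e-12)
      parse <- model_params(N = 60, m = m, tau = tau, alpha0 = -0.6)
      Re <- transition_matrix(build_reset_chain(focal_empty(), parse))
      expect_lt(max(abs(Matrix::colSums(Re) - 1)), 1e-12)
    }
  }
})

test_that("tau = 1 gives a point mass at the reset state", {
  pars <- model_params(N = 20, m = 0.5, tau = 1, p = 0.5)
  phi <- stationary_distribution(build_reset_chain(focal_taxon(1), pars))
  expect_equal(phi$mass[1], 1)
  parse <- model_params(N = 20, m = 0.5, tau = 1, alpha0 = 0)
  phie <- stationary_distribution(build_reset_chain(focal_empty(), parse))
  expect_equal(phie$mass[21], 1)
})

test_that("tau = 0 stationary equals the detailed-balance product form", {
  for (N in c(20, 100, 200)) {
    for (m in c(0.005, 0.1, 0.9)) {
      for (p in c(0.2, 0.5, 1)) {
        pars <- model_params(N = N, m = m, tau = 0, p = p)
        phi <- stationary_distribution(build_reset_chain(focal_taxon(1), pars))
        expect_lt(max(abs(phi$mass - oracle_product_form_tau0(N, m, p))),
                  1e-10)
      }
    }
  }
})

test_that("the tau = 0 stationary mean equals the pool frequency", {
  pars <- model_params(N = 200, m = 0.01, tau = 0, p = 0.5)
  phi <- stationary_distribution(build_reset_chain(focal_taxon(1), pars))
  expect_lt(abs(sum(phi$frequency * phi$mass) - 0.5), 1e-8)
})

test_that("degenerate chains are refused", {
  pars <- model_params(N = 10, m = 0, tau = 0, p = 0.5)
  expect_error(stationary_distribution(build_reset_chain(focal_taxon(1), pars)),
               "non-unique")
})

test_that("propagation conserves mass and fixes the stationary point", {
  pars <- model_params(N = 50, m = 0.05, tau = 1e-2, p = 0.5)
  ch <- build_reset_chain(focal_taxon(1), pars)
  u <- uniform_distribution(ch)
  expect_equal(propagate(u, ch, 0)$mass, u$mass)
  one <- propagate(u, ch, 1)
  expect_lt(abs(sum(one$mass) - 1), 1e-12)
  st <- stationary_distribution(ch)
  expect_lt(total_variation(propagate(st, ch, 25), st), 1e-12)
})

test_that("an absorbing point mass is invariant without migration or death", {
  pars <- model_params(N = 10, m = 0, tau = 0, p = 0.5)
  ch <- build_reset_chain(focal_taxon(1), pars)
  pm <- point_mass(ch, 0L)
  expect_equal(propagate(pm, ch, 50)$mass, pm$mass)
})

test_that("propagation converges to the solved stationary distribution", {
  pars <- model_params(N = 50, m = 0.05, tau = 1e-3, p = 0.5)
  ch <- build_reset_chain(focal_taxon(1), pars)
  st <- stationary_distribution(ch)
  prop <- propagate(uniform_distribution(ch), ch, 1e5)
  expect_lt(total_variation(prop, st), 1e-6)
})

test_that("the stationary law is the lifespan-weighted mixture of transients", {
  # renewal representation: geometric lifespan weights applied to the
  # reset-free colonization transients reproduce the resetting stationary
  for (tau in c(1e-2, 5e-2)) {
    pars <- model_params(N = 40, m = 0.05, tau = tau, p = 0.5)
    ch <- build_reset_chain(focal_taxon(1), pars)
    st <- stationary_distribution(ch)
    pars0 <- model_params(N = 40, m = 0.05, tau = 0, p = 0.5)
    ch0 <- build_reset_chain(focal_taxon(1), pars0)
    R0 <- transition_matrix(ch0)
    horizon <- ceiling(20 / tau)
    v <- numeric(41); v[ch$reset_index] <- 1
    mix <- tau * v
    for (t in seq_len(horizon)) {
      v <- as.numeric(R0 %*% v)
      mix <- mix + tau * (1 - tau)^t * v
    }
    expect_lt(tv_vec(mix / sum(mix), st$mass), 1e-3)
  }
})

test_that("vanishing host death recovers the infinite-lifespan solution", {
  pars_eps <- model_params(N = 100, m = 0.1, tau = 1e-9, p = 0.5)
  phi_eps <- stationary_distribution(build_reset_chain(focal_taxon(1), pars_eps))
  expect_lt(tv_vec(phi_eps$mass, oracle_product_form_tau0(100, 0.1, 0.5)),
            1e-5)
})

test_that("solver and long propagation agree across a parameter lattice", {
  for (N in c(30, 120)) {
    for (m in c(0.01, 0.4)) {
      for (tau in c(1e-3, 0.1)) {
        pars <- model_params(N = N, m = m, tau = tau, p = 0.3)
        ch <- build_reset_chain(focal_taxon(1), pars)
        st <- stationary_distribution(ch)
        steps <- min(ceiling(30 / tau), 2e5)
        prop <- propagate(uniform_distribution(ch), ch, steps)
        expect_lt(total_variation(prop, st), 1e-8)
      }
    }
  }
})

test_that("distributions round-trip through TSV at full precision", {
  pars <- model_params(N = 30, m = 0.05, tau = 1e-3, p = 0.5)
  phi <- stationary_distribution(build_reset_chain(focal_taxon(1), pars))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distribution(phi, path)
  back <- read_distribution(path)
  expect_equal(back$mass, phi$mass, tolerance = 1e-15)
})
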