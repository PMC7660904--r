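make_dist <- function(mass) {
  finitehost:::new_marginal_distribution(mass / sum(mass), method = "test")
}

test_that("total variation behaves as a metric on the grid simplex", {
  a <- make_dist(c(0.5, 0.5, 0))
  b <- make_dist(c(0, 0.5, 0.5))
  expect_equal(total_variation(a, b), 0.5)
  expect_equal(total_variation(a, a), 0)
  p0 <- make_dist(c(1, 0, 0))
  p2 <- make_dist(c(0, 0, 1))
  expect_equal(total_variation(p0, p2), 1)   # disjoint support
  set.seed(4)
  for (rep in 1:25) {
    x <- make_dist(stats::runif(7)); y <- make_dist(stats::runif(7))
    z <- make_dist(stats::runif(7))
    expect_equal(total_variation(x, y), total_variation(y, x))
    expect_gte(total_variation(x, y) + 1e-15,
               0); expect_lte(total_variation(x, y), 1)
    expect_lte(total_variation(x, z),
               total_variation(x, y) + total_variation(y, z) + 1e-15)
  }
  expect_error(total_variation(a, make_dist(rep(1, 5))), "grid mismatch")
})

test_that("colonization probabilities read the boundary masses", {
  pm <- make_dist(c(1, rep(0, 10)))
  cp <- colonization_probabilities(pm, focal_taxon(1))
  expect_equal(cp$p_absent, 1)
  expect_equal(cp$p_present, 0)
  expect_equal(cp$p_full, 0)
  u <- make_dist(rep(1, 11))
  cpu <- colonization_probabilities(u, focal_taxon(1))
  expect_equal(cpu$p_absent, 1 / 11)
  expect_equal(cpu$p_full, 1 / 11)
  # every host resets instantly: the taxon is always absent
  pars <- model_params(N = 20, m = 0.5, tau = 1, p = 0.5)
  st <- stationary_distribution(build_reset_chain(focal_taxon(1), pars))
  expect_equal(colonization_probabilities(st)$p_absent, 1)
  # empty-space target: boundary roles swap (x0 = 0 means a full host)
  d <- make_dist(c(0.7, rep(0, 9), 0.3))
  cpe <- colonization_probabilities(d, focal_empty())
  expect_equal(cpe$p_full, 0.7)
  expect_equal(cpe$p_absent, 0.3)
  expect_equal(cpe$p_present, 0.7)
})

test_that("modality classification finds and labels thresholded maxima", {
  expect_equal(classify_modality(make_dist(c(1, rep(0, 8))))$category,
               "unimodal_at_0")
  expect_equal(classify_modality(make_dist(c(rep(0, 8), 1)))$category,
               "unimodal_at_1")
  expect_equal(classify_modality(make_dist(c(0, 1, 5, 1, 0)))$category,
               "unimodal_internal")
  expect_equal(classify_modality(make_dist(c(5, 1, 1, 1, 4)))$category,
               "bimodal_0_and_1")
  expect_equal(classify_modality(make_dist(c(5, 1, 3, 1, 0)))$category,
               "bimodal_0_and_internal")
  expect_equal(classify_modality(make_dist(c(0, 1, 3, 1, 5)))$category,
               "bimodal_internal_and_1")
  # plateaus count once, located at their first grid index
  lab <- classify_modality(make_dist(c(1, 4, 4, 4, 1, 0)))
  expect_equal(lab$category, "unimodal_internal")
  expect_equal(lab$maxima$state_index, 1L)
  # sub-threshold wiggles are erased before maxima detection
  tiny <- c(1, 0, 1e-12, 0, 2)
  expect_equal(classify_modality(make_dist(tiny))$category, "bimodal_0_and_1")
  # more than two maxima: two largest kept, flagged truncated
  multi <- classify_modality(make_dist(c(5, 1, 4, 1, 3, 1, 0)))
  expect_true(multi$truncated)
  expect_equal(nrow(multi$maxima), 2L)
  expect_equal(multi$category, "bimodal_0_and_internal")
})

test_that("modality is invariant to positive rescaling before normalization", {
  set.seed(12)
  for (rep in 1:10) {
    raw <- stats::runif(31)^3
    a <- classify_modality(make_dist(raw))
    b <- classify_modality(make_dist(raw * 7.3))
    expect_equal(a$category, b$category)
    expect_equal(a$maxima$state_index, b$maxima$state_index)
  }
})

test_that("lifespan sampling is geometric and anchored at birth for tau = 1", {
  pars <- model_params(N = 20, m = 0.2, tau = 0, p = 1)
  traj <- simulate_population(pars, n_hosts = 300, n_steps = 400,
                              sample_every = 1, seed = 2)
  smp1 <- sample_at_host_death(traj, tau = 1, seed = 5)
  expect_true(all(smp1$time == 0))
  expect_true(all(smp1$count[smp1$type_index == 0] == 20))
  smp <- sample_at_host_death(traj, tau = 0.05, seed = 5)
  t_bar <- mean(smp$lifespan[smp$type_index == 0])
  se <- sqrt((1 - 0.05) / 0.05^2 / 300)
  expect_lt(abs(t_bar - (1 - 0.05) / 0.05), 3 * se)
  expect_error(sample_at_host_death(traj, tau = 0), "tau")
  # too-short trajectories are flagged
  expect_warning(sample_at_host_death(traj, tau = 1e-4, seed = 5),
                 "truncates")
})

test_that("empirical distributions are normalized histograms on the grid", {
  pars <- model_params(N = 9, m = 0.1, tau = 0, p = 1)
  counts <- 0:9
  emp <- empirical_distribution(counts, focal_taxon(1), pars)
  expect_equal(emp$mass, rep(0.1, 10))
  one <- empirical_distribution(4L, focal_taxon(1), pars)
  expect_equal(one$mass[5], 1)
  dup <- empirical_distribution(c(counts, counts), focal_taxon(1), pars)
  expect_equal(dup$mass, emp$mass)
  expect_error(empirical_distribution(integer(0), focal_taxon(1), pars),
               "no states")
  expect_error(empirical_distribution(10L, focal_taxon(1), pars), "0..N")
})

test_that("sampled simulations recover the solver stationary distribution", {
  pars <- model_params(N = 100, m = 0.01, tau = 0, p = c(0.5, 0.5))
  traj <- simulate_population(pars, n_hosts = 1500, n_steps = 6000,
                              sample_every = 10, seed = 77)
  smp <- sample_at_host_death(traj, tau = 1e-3, seed = 78)
  emp <- empirical_distribution(smp, focal_taxon(1))
  pars_m <- model_params(N = 100, m = 0.01, tau = 1e-3, p = 0.5)
  st <- stationary_distribution(build_reset_chain(focal_taxon(1), pars_m))
  expect_lt(total_variation(emp, st), 0.1)
})
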