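test_that("BAOAB at zero temperature relaxes into the minimum", {
  h <- make_potential("harmonic_1d", list(k = 2, x0 = 1.5))
  tr <- run_baoab(h, langevin_config(temperature = 0, n_steps = 5000L,
                                     stride = 100L, seed = 1), x0 = 1.4)
  expect_lt(abs(tail(tr$x, 1) - 1.5), 1e-8)
})

test_that("BAOAB samples the harmonic equipartition variance", {
  k <- 4
  h <- make_potential("harmonic_1d", list(k = k))
  tr <- run_baoab(h, langevin_config(n_steps = 400000L, stride = 5L,
                                     dt = 0.05, seed = 1), x0 = 0)
  expect_equal(var(tr$x), 1 / k, tolerance = 0.03)
})

test_that("unbiased double-well occupancies match the quadrature ratio", {
  pot <- make_potential("tilted_double_well_1d", list(barrier = 2,
                                                      target_dg = 0.6))
  tr <- run_baoab(pot, langevin_config(n_steps = 500000L, stride = 10L,
                                       seed = 7), x0 = -1)
  p_a <- mean(tr$x < 0)
  # Boltzmann ratio from quadrature within ~3 sd (correlated samples, so
  # use a conservative effective sample size from transitions)
  truth <- pot$fe$p_states["A"]
  n_trans <- sum(diff(tr$x < 0) != 0)
  se <- sqrt(truth * (1 - truth) / max(n_trans, 1))
  expect_lt(abs(p_a - truth), 3 * se + 0.02)
})

test_that("time-step halving leaves long-run observables within error bars", {
  k <- 4
  h <- make_potential("harmonic_1d", list(k = k))
  v1 <- var(run_baoab(h, langevin_config(n_steps = 200000L, stride = 5L,
                                         dt = 0.05, seed = 3), 0)$x)
  v2 <- var(run_baoab(h, langevin_config(n_steps = 400000L, stride = 10L,
                                         dt = 0.025, seed = 4), 0)$x)
  expect_lt(abs(v1 - v2), 0.02)
})

test_that("divergence raises an error naming the step", {
  h <- make_potential("harmonic_1d", list(k = 1e6))
  expect_error(run_baoab(h, langevin_config(dt = 1, n_steps = 100L, seed = 1,
                                            guard = 100), x0 = 1),
               "diverged at step")
})

test_that("biased walker crosses a barrier the unbiased walker cannot", {
  dw <- make_potential("double_well_1d", list(barrier = 8))
  un <- run_baoab(dw, langevin_config(n_steps = 30000L, stride = 10L,
                                      seed = 13), x0 = -1)
  expect_true(all(un$x < 0))  # desk-length unbiased run never transitions
  run <- run_metad(dw, x0 = matrix(-1), cfg = metad_config(
    n_walkers = 1L, sigma = 0.08, pace = 200L, max_steps = 200000L,
    window = 2000L, stride = 10L), seed = 13)
  expect_true(run$converged[1])
  expect_true(any(run$walkers[[1]]$x > 0))
})

test_that("shared-bias mode with one walker equals single-walker mode", {
  dw <- make_potential("double_well_1d", list(barrier = 4))
  cfg <- metad_config(n_walkers = 1L, sigma = 0.1, pace = 100L,
                      max_steps = 20000L, window = 1000L, stride = 10L)
  r1 <- run_metad(dw, x0 = matrix(-1), cfg = cfg, seed = 5)
  r2 <- run_metad(dw, x0 = matrix(-1), cfg = cfg, seed = 5)
  expect_identical(r1$walkers[[1]], r2$walkers[[1]])
  expect_identical(r1$bias$heights, r2$bias$heights)
})

test_that("two walkers sharing bias escape the start well with fewer deposits", {
  dw <- make_potential("double_well_1d", list(barrier = 6))
  first_escape_deposits <- function(n_walkers, seed) {
    cfg <- metad_config(n_walkers = n_walkers, sigma = 0.08, pace = 200L,
                        max_steps = 300000L, window = 500L, stride = 10L)
    run <- run_metad(dw, x0 = matrix(rep(-1, n_walkers), ncol = 1),
                     cfg = cfg, seed = seed)
    # deposits accumulated when any walker first crosses the barrier
    cross <- min(vapply(run$walkers, function(w) {
      i <- which(w$x > 0)[1]
      if (is.na(i)) Inf else w$step[i]
    }, numeric(1)))
    sum(run$bias$times <= cross)
  }
  seeds <- 1:10
  d1 <- vapply(seeds, function(s) first_escape_deposits(1L, s), numeric(1))
  d2 <- vapply(seeds + 100, function(s) first_escape_deposits(2L, s),
               numeric(1))
  expect_lte(median(d2), median(d1))
})

test_that("static transfer under a learned bias yields two-way transitions", {
  dw <- make_potential("double_well_1d", list(barrier = 8))
  learn <- run_metad(dw, cfg = metad_config(n_walkers = 2L, sigma = 0.08,
    pace = 200L, max_steps = 300000L, window = 3000L, stride = 10L),
    seed = 3)
  sb <- freeze(learn$bias)
  succ <- 0L
  for (s in 1:10) {
    tr <- static_bias_transfer(sb, dw, cfg = metad_config(
      max_steps = 150000L, window = 2000L, stride = 10L),
      n_per_basin = 1L, seed = 100 + s)
    if (all(tr$converged)) succ <- succ + 1L
  }
  expect_gte(succ, 8L)
  # a zero static bias cannot cross the 8 kBT barrier at desk length
  zb <- freeze(bias_potential(ds = 1))
  tr0 <- static_bias_transfer(zb, dw, cfg = metad_config(
    max_steps = 50000L, window = 2000L, stride = 10L), n_per_basin = 1L,
    seed = 5)
  expect_false(any(tr0$converged))
  # and no deposits ever occur under a frozen bias
  expect_equal(tr0$n_deposits, 0L)
})
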