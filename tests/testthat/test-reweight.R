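test_that("weights are unit for zero bias and shift-invariant", {
  s <- matrix(rnorm(100), ncol = 1)
  zb <- freeze(bias_potential(ds = 1))
  w0 <- compute_weights(s, zb)
  expect_equal(w0$weights, rep(1, 100))
  expect_equal(w0$ess, 100)

  # a constant bias (wide kernel far away approximates it poorly; instead
  # compare two biases differing by adding the same kernel list twice)
  b1 <- freeze(bias_potential(centers = matrix(0), sigmas = matrix(1e6),
                              heights = 2.5))  # effectively constant ~2.5
  w1 <- compute_weights(s, b1)
  expect_equal(w1$weights, rep(1, 100), tolerance = 1e-6)
})

test_that("reweighting requires a frozen bias", {
  b <- bias_potential(ds = 1)
  expect_error(compute_weights(matrix(0), b), "frozen")
})

test_that("a bias equal to -F restores the Boltzmann density", {
  pot <- make_potential("double_well_1d", list(barrier = 4))
  # build V(s) = -F(s) from dense narrow kernels fitted on a grid
  xs <- seq(-1.6, 1.6, by = 0.02)
  f <- potential_energy(pot, xs)
  v <- max(f) - f  # -F + const, nonnegative
  sb <- freeze(bias_potential(centers = matrix(xs),
                              sigmas = matrix(rep(0.02, length(xs))),
                              heights = v * 0.02 / sqrt(2 * pi) / 0.02))
  # kernel-sum approximates the continuous profile: check it first
  prof <- evaluate_bias(sb, xs)
  scale <- mean(prof / pmax(v, 0.1))
  sb$heights <- sb$heights / scale
  tr <- run_metad(pot, x0 = matrix(-1), cfg = metad_config(
    n_walkers = 1L, max_steps = 400000L, window = 1L, stride = 5L),
    bias = sb, targets = -1L, seed = 31)
  expect_error(compute_weights(tr$walkers[[1]], sb), NA)
  wt <- compute_weights(tr$walkers[[1]], sb)
  # weighted histogram vs quadrature density, total variation < 0.05
  br <- seq(-1.8, 1.8, by = 0.1)
  h <- numeric(length(br) - 1)
  ix <- findInterval(wt$frames[, 1], br)
  ok <- ix >= 1 & ix <= length(h)
  for (i in which(ok)) h[ix[i]] <- h[ix[i]] + wt$weights[i]
  h <- h / sum(h)
  mid <- (head(br, -1) + tail(br, -1)) / 2
  q <- exp(-potential_energy(pot, mid))
  q <- q / sum(q)
  expect_lt(sum(abs(h - q)) / 2, 0.05)
})

test_that("PMF arithmetic: flat case, exact two-bin ratio, minima placement", {
  set.seed(8)
  # uniform samples with uniform weights -> flat PMF up to noise
  fr <- cbind(runif(20000, 8, 12), runif(20000, 8, 12))
  wt <- structure(list(frames = fr, s = fr, weights = rep(1, 20000),
                       ess = 20000, kBT = 1), class = "weighted_traj")
  pmf <- pmf_2d(wt, xbreaks = seq(8, 12, 1), ybreaks = seq(8, 12, 1))
  expect_lt(max(abs(pmf$F), na.rm = TRUE), 0.15)

  # two bins with weight ratio e:1 differ by exactly 1 kBT
  fr2 <- rbind(c(8.5, 8.5), c(9.5, 8.5))
  wt2 <- structure(list(frames = fr2, s = fr2, weights = c(exp(1), 1),
                        ess = 2, kBT = 1), class = "weighted_traj")
  pmf2 <- pmf_2d(wt2, xbreaks = seq(8, 10, 1), ybreaks = seq(8, 9, 1))
  expect_equal(pmf2$F[2, 1] - pmf2$F[1, 1], 1)

  # unsampled bins are NA, not zero
  pmf3 <- pmf_2d(wt2, xbreaks = seq(6, 10, 1), ybreaks = seq(6, 9, 1))
  expect_true(any(is.na(pmf3$F)))
})

test_that("toy kinase PMF minima land on the generator's basin centers", {
  km <- make_potential("kinase_mimic_2d")
  sb <- freeze(bias_potential(ds = 2))
  # direct unbiased sampling from each basin (no bias: weights all 1)
  runs <- lapply(list(km$basins["IN", ], km$basins["OUT", ]), function(x0)
    run_metad(km, x0 = matrix(x0, 1), cfg = metad_config(n_walkers = 1L,
      max_steps = 400000L, window = 1L, stride = 10L), bias = sb,
      targets = -1L, seed = 19))
  wts <- lapply(runs, function(r) compute_weights(r$walkers[[1]], sb))
  pmf <- pmf_2d(wts, xbreaks = seq(6, 20, 0.5), ybreaks = seq(6, 20, 0.5))
  idx <- which(pmf$F == 0, arr.ind = TRUE)
  m <- c(pmf$xmid[idx[1]], pmf$ymid[idx[2]])
  on_in <- all(abs(m - km$basins["IN", ]) <= 0.5)
  on_out <- all(abs(m - km$basins["OUT", ]) <= 0.5)
  expect_true(on_in || on_out)
})

test_that("state_thermo follows the closed form and excludes one-sided runs", {
  mkwt <- function(labels, weights) {
    fr <- cbind(ifelse(labels == "IN", 10, 12),
                ifelse(labels == "IN", 15, 13))
    structure(list(frames = fr, s = fr, weights = weights,
                   ess = length(weights), kBT = 1), class = "weighted_traj")
  }
  # P_in = P_out -> dG = 0
  th0 <- state_thermo(list(mkwt(rep(c("IN", "OUT"), 50), rep(1, 100))))
  expect_equal(th0$delta_g_mean, 0)
  # P_in = 0.62, P_out = 0.38
  th1 <- state_thermo(list(mkwt(c(rep("IN", 62), rep("OUT", 38)),
                                rep(1, 100))))
  expect_equal(th1$delta_g_mean, -log(0.62 / 0.38), tolerance = 1e-12)
  expect_equal(round(th1$delta_g_mean, 3), -0.49)
  # one-sided trajectory excluded with a warning
  expect_warning(th2 <- state_thermo(list(
    mkwt(rep(c("IN", "OUT"), 50), rep(1, 100)),
    mkwt(rep("IN", 40), rep(1, 40)))), "one-sided")
  expect_equal(th2$n_traj, 1L)
})

test_that("GAP mass is reported separately, not in the state normalization", {
  fr <- rbind(c(10, 15), c(12, 13), c(10, 12.5), c(10, 12.5))
  wt <- structure(list(frames = fr, s = fr, weights = rep(1, 4), ess = 4,
                       kBT = 1), class = "weighted_traj")
  th <- state_thermo(list(wt))
  expect_equal(th$gap_mass, 0.5)
  expect_equal(unname(th$p[1, c("IN", "OUT")]), c(0.5, 0.5))
  expect_lte(sum(th$p[1, ]), 1)
})

test_that("adding a constant to the bias changes no reweighted result", {
  set.seed(5)
  s <- matrix(rnorm(500, sd = 0.5), ncol = 1)
  b <- freeze(bias_potential(centers = matrix(c(0, 1), 2),
                             sigmas = matrix(c(0.5, 0.7), 2),
                             heights = c(1, 2)))
  # same kernels plus a near-constant offset kernel
  b2 <- freeze(bias_potential(centers = matrix(c(0, 1, 0), 3),
                              sigmas = matrix(c(0.5, 0.7, 1e7), 3),
                              heights = c(1, 2, 3.7)))
  w1 <- compute_weights(s, b)$weights
  w2 <- compute_weights(s, b2)$weights
  expect_equal(w1, w2, tolerance = 1e-8)
})

test_that("state_thermo agrees with PMF-region integration", {
  km <- make_potential("kinase_mimic_2d")
  sb <- freeze(bias_potential(ds = 2))
  runs <- lapply(c(101, 102), function(s)
    run_metad(km, x0 = matrix(km$basins["IN", ] + c(0.1, -0.1), 1),
              cfg = metad_config(n_walkers = 1L, max_steps = 200000L,
                                 window = 1L, stride = 10L),
              bias = sb, targets = -1L, seed = s))
  wts <- lapply(runs, function(r) compute_weights(r$walkers[[1]], sb))
  th <- state_thermo(wts)
  pmf <- pmf_2d(wts, xbreaks = seq(6, 20, 0.1), ybreaks = seq(6, 20, 0.1))
  expect_true(all(!is.na(th$delta_g)))
  expect_equal(delta_g_from_pmf(pmf),
               -log(sum(vapply(wts, function(w)
                 sum(w$weights[classify_dfg(w$frames[,1], w$frames[,2]) == "IN"]),
                 numeric(1))) /
                 sum(vapply(wts, function(w)
                 sum(w$weights[classify_dfg(w$frames[,1], w$frames[,2]) == "OUT"]),
                 numeric(1)))),
               tolerance = 0.05)
})
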