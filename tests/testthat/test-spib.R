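test_that("spib_fit recovers the true states of a two-well trajectory", {
  d <- two_state_cv_traj(seed = 5)
  init <- factor(ifelse(d$cv[, "inf1"] < 0, "A", "B"))
  cfg <- spib_config(lag = 5L, epochs = 150L, seed = 11)
  model <- spib_fit(d$cv, init, cfg)
  expect_gte(label_accuracy(model$state_labels, d$truth), 0.9)
  # the informative CVs dominate the encoder
  imp <- feature_importance(model)
  expect_true(names(which.max(imp)) %in% paste0("inf", 1:3))
})

test_that("white-noise CVs give no time-lagged predictability", {
  set.seed(77)
  n <- 2000L
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("cv", 1:6)))
  labels <- factor(sample(c("A", "B"), n, replace = TRUE, prob = c(0.5, 0.5)))
  cfg <- spib_config(lag = 4L, epochs = 80L, relabel_max = 1L, seed = 3)
  model <- spib_fit(x, labels, cfg)
  # predicted future label vs actual future label on the training pairs
  z <- project(model, x)
  p <- exp(z %*% t(model$U) + matrix(model$c, n, 2, byrow = TRUE))
  pred <- model$classes[max.col(p)]
  tt <- seq_len(n - 4L)
  acc <- mean(pred[tt] == as.character(labels[tt + 4L]))
  marg <- max(table(labels) / n)
  se <- sqrt(marg * (1 - marg) / length(tt))
  expect_lt(acc, marg + 2 * se + 0.02)
})

test_that("an exclusively informative CV receives the top weight", {
  set.seed(42)
  dw <- make_potential("double_well_1d", list(barrier = 3))
  tr <- run_baoab(dw, langevin_config(n_steps = 20000L, stride = 10L,
                                      seed = 15), x0 = -1)
  n <- nrow(tr)
  cv <- cbind(sig = tr$x, matrix(rnorm(n * 9), n))
  colnames(cv) <- c("sig", paste0("nz", 1:9))
  cvs <- standardize(cv)$values
  init <- factor(ifelse(tr$x < 0, "A", "B"))
  model <- spib_fit(cvs, init, spib_config(lag = 5L, epochs = 120L, seed = 2))
  imp <- feature_importance(model)
  expect_equal(names(which.max(imp)), "sig")
})

test_that("prune_features applies the quarter-of-maximum rule exactly", {
  model <- structure(list(W = rbind(c(1.0, 0.3, 0.2), c(0.1, 0.1, 0.1)),
                          b = c(0, 0), cv_names = c("a", "b", "c"),
                          cfg = spib_config()), class = "ib_model")
  expect_equal(unname(prune_features(model)), c(1L, 2L))
  # all equal importances -> everything retained
  model$W <- rbind(c(0.5, 0.5, 0.5), c(0.2, 0.2, 0.2))
  expect_equal(unname(prune_features(model)), 1:3)
  # a single feature always survives
  m1 <- structure(list(W = matrix(c(0.7, 0.1), 2, 1), b = c(0, 0),
                       cv_names = "only", cfg = spib_config()),
                  class = "ib_model")
  expect_equal(unname(prune_features(m1)), 1L)
})

test_that("the refinement loop keeps informative CVs and shrinks the basis", {
  d <- two_state_cv_traj(seed = 9, n_steps = 30000L)
  init <- factor(ifelse(d$cv[, "inf2"] < 0, "A", "B"))
  cfg <- spib_config(lag = 5L, epochs = 120L, seed = 4)
  loop <- spib_refine_loop(d$cv, init, cfg)
  expect_true(all(paste0("inf", 1:3) %in%
                  colnames(d$cv)[loop$retained]))
  expect_true(all(diff(loop$rounds) <= 0))  # never grows
  imp <- feature_importance(loop$model)
  expect_true(all(imp[prune_features(loop$model)] >= 0.25 * max(imp)))
  # prune_rounds = 1 degenerates to one fit + prune
  cfg1 <- spib_config(lag = 5L, epochs = 120L, seed = 4, prune_rounds = 1L)
  l1 <- spib_refine_loop(d$cv, init, cfg1)
  m1 <- spib_fit(d$cv, init, cfg1)
  expect_equal(l1$retained, unname(prune_features(m1)))
})

test_that("projection is the deterministic linear map", {
  model <- structure(list(W = rbind(c(0.5, -1, 2), c(1, 0, -0.5)),
                          b = c(0.1, -0.2), cv_names = c("a", "b", "c")),
                    class = "ib_model")
  x <- matrix(rnorm(15), 5, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(project(model, x),
               sweep(x %*% t(model$W), 2, model$b, "+"), tolerance = 1e-10)
  # zero-weight encoder maps everything to the bias
  model0 <- model
  model0$W[] <- 0
  z <- project(model0, x)
  expect_true(all(abs(sweep(z, 2, model$b)) < 1e-12))
  expect_error(project(model, x[, 1:2]), "CV-set mismatch")
})

test_that("the learned latent separates states at least as well as raw CVs", {
  d <- two_state_cv_traj(seed = 21)
  init <- factor(ifelse(d$cv[, "inf1"] < 0, "A", "B"))
  model <- spib_fit(d$cv, init, spib_config(lag = 5L, epochs = 150L, seed = 8))
  z <- project(model, d$cv)
  f_lat <- max(apply(z, 2, fisher_ratio, labels = d$truth))
  f_raw <- max(apply(d$cv, 2, fisher_ratio, labels = d$truth))
  expect_gte(f_lat, f_raw)
})

test_that("training is bit-reproducible with a fixed seed", {
  d <- two_state_cv_traj(seed = 2, n_steps = 8000L)
  init <- factor(ifelse(d$cv[, "inf1"] < 0, "A", "B"))
  cfg <- spib_config(lag = 5L, epochs = 60L, seed = 10)
  m1 <- spib_fit(d$cv, init, cfg)
  m2 <- spib_fit(d$cv, init, cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$state_labels, m2$state_labels)
})

test_that("occupied-state count never increases across relabeling", {
  d <- two_state_cv_traj(seed = 6, n_steps = 20000L)
  # deliberately over-split initial labels into 4 states
  q <- cut(d$cv[, "inf1"], breaks = c(-Inf, -1, 0, 1, Inf),
           labels = c("s1", "s2", "s3", "s4"))
  model <- spib_fit(d$cv, q, spib_config(lag = 5L, epochs = 100L, seed = 5,
                                         relabel_max = 6L))
  expect_true(all(diff(model$history$occupied) <= 0))
  expect_lte(length(unique(model$state_labels)), 4L)
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(100), 50)
  expect_error(spib_fit(x, factor(rep("A", 50)), spib_config(lag = 2L)),
               "degenerate-labels")
  expect_error(spib_fit(x[1:3, ], factor(c("A", "B", "A")),
                        spib_config(lag = 10L)), "shorter than")
})

test_that("model JSON serialization round-trips with the scaler", {
  d <- two_state_cv_traj(seed = 3, n_steps = 6000L)
  init <- factor(ifelse(d$cv[, "inf1"] < 0, "A", "B"))
  model <- spib_fit(d$cv, init, spib_config(lag = 5L, epochs = 40L, seed = 1))
  sc <- standardize(matrix(rnorm(40), 10,
                           dimnames = list(NULL, colnames(d$cv)[1:4])))
  f <- withr::local_tempfile(fileext = ".json")
  write_ib_model(model, f, scaler = sc)
  back <- read_ib_model(f)
  expect_equal(back$model$W, model$W, ignore_attr = TRUE)
  expect_equal(back$model$cv_names, model$cv_names)
  expect_equal(back$scaler$center, sc$center)
  expect_equal(project(back$model, d$cv), project(model, d$cv))
})
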