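# Loss closed forms, class weighting, GEM projection, episodic memory,
# and the curriculum training loop.

ns <- asNamespace("cryosse")

test_that("compute_class_weights is inverse-frequency, normalized", {
  mk <- function(counts) {
    v <- rep(0:2, times = counts)
    label_grid(array(v, c(length(v), 1, 1)))
  }
  w <- compute_class_weights(mk(c(80, 10, 10)))
  expect_equal(as.numeric(w), c(0.0588, 0.4706, 0.4706), tolerance = 1e-3)
  expect_equal(sum(w), 1)

  w_uni <- compute_class_weights(mk(c(10, 10, 10)))
  expect_equal(as.numeric(w_uni), rep(1 / 3, 3))

  w_skew <- compute_class_weights(mk(c(98, 1, 1)))
  expect_lt(w_skew[["background"]], w_skew[["helix"]])
  expect_lt(w_skew[["background"]], w_skew[["sheet"]])

  expect_error(compute_class_weights(mk(c(5, 5, 0))), "sheet")
})

test_that("combined loss reproduces closed forms", {
  # perfect one-hot prediction: zero loss
  truth <- label_grid(array(c(1L, 2L, 0L, 1L), c(4, 1, 1)))
  onehot <- array(0, c(4, 1, 1, 3))
  for (i in 1:4) onehot[i, 1, 1, truth$labels[i, 1, 1] + 1L] <- 1
  pg <- probability_grid(onehot)
  l0 <- combined_loss(pg, truth, dice_weight = 0.5)
  expect_equal(l0$loss, 0, tolerance = 1e-6)

  # uniform prediction, equal weights, no dice: cross-entropy = ln 3
  unif <- probability_grid(array(1 / 3, c(4, 1, 1, 3)))
  lu <- combined_loss(unif, truth, weights = rep(1 / 3, 3), dice_weight = 0)
  expect_equal(lu$loss, log(3), tolerance = 1e-6)

  # two-voxel Dice instance evaluated by hand from the soft-Dice formula:
  # truth (helix, sheet), probabilities (.25,.5,.25) and (.25,.25,.5).
  # background: inter 0, denom .5        -> term 1
  # helix:      inter .5, denom .75 + 1  -> term 1 - 1/1.75
  # sheet:      symmetric                -> term 1 - 1/1.75
  t2 <- label_grid(array(c(1L, 2L), c(2, 1, 1)))
  p2 <- probability_grid(array(c(.25, .25, .5, .25, .25, .5), c(2, 1, 1, 3)))
  ld <- combined_loss(p2, t2, dice_weight = 1)
  expect_equal(ld$loss, (1 + 2 * (1 - 1 / 1.75)) / 3, tolerance = 1e-12)

  expect_error(combined_loss(unif, label_grid(array(0L, c(3, 1, 1)))),
               "lattice")
})

test_that("upweighting a class increases the loss of errors on that class", {
  # voxel 1 is a bad error on a helix voxel (p_true = .05); voxels 2-4 are
  # mild errors on background voxels (p_true = .5)
  truth <- label_grid(array(c(1L, 0L, 0L, 0L), c(4, 1, 1)))
  probs <- probability_grid(array(c(
    .90, .50, .50, .50,    # background probs
    .05, .40, .40, .40,    # helix probs
    .05, .10, .10, .10), c(4, 1, 1, 3)))
  lo <- combined_loss(probs, truth, weights = c(.4, .2, .4),
                      dice_weight = 0)$loss
  hi <- combined_loss(probs, truth, weights = c(.2, .6, .2),
                      dice_weight = 0)$loss
  expect_gt(hi, lo)
})

test_that("gem_project returns the minimal-norm constrained correction", {
  expect_equal(gem_project(c(1, -3), c(0, 1)), c(1, 0))
  expect_equal(gem_project(c(2, -1), -c(2, -1)), c(0, 0))
  g <- c(1, 2, 3); m <- c(0.5, 1, 0)
  expect_identical(gem_project(g, m), g)  # no violation: unchanged
  expect_error(gem_project(c(1, 2), c(0, 0)), "zero")
  expect_error(gem_project(c(1, 2), c(1, 2, 3)), "length")
})

test_that("gem_project satisfies the constraint and matches a numeric minimizer", {
  set.seed(77)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(2:6, 1)
    g <- rnorm(n); m <- rnorm(n)
    z <- gem_project(g, m)
    expect_gte(sum(z * m), -1e-6)
    if (sum(g * m) >= 0) expect_identical(z, g)
  }
  # independent numeric minimizer: when the constraint is violated the
  # optimum is on the boundary m.z = 0, so solve the KKT stationarity
  # system  2(z - g) = lambda m,  m.z = 0  numerically by LU factorization
  kkt_min <- function(g, m) {
    n <- length(g)
    A <- rbind(cbind(2 * diag(n), -m), c(m, 0))
    sol <- solve(A, c(2 * g, 0))
    list(z = sol[1:n], lambda = sol[n + 1])
  }
  for (i in 1:20) {
    n <- sample(2:5, 1)
    g <- rnorm(n); m <- rnorm(n)
    if (sum(g * m) >= 0) next
    num <- kkt_min(g, m)
    expect_gte(num$lambda, 0)  # multiplier sign confirms the active constraint
    expect_equal(num$z, gem_project(g, m), tolerance = 1e-6)
  }
})

test_that("episodic memory sampling is seeded, clamped, and empty for phase 1", {
  ex <- as.list(letters[1:10])
  s1 <- sample_episodic_memory(ex, 5, seed = 42)
  s2 <- sample_episodic_memory(ex, 5, seed = 42)
  expect_identical(s1, s2)
  expect_length(s1, 5)
  expect_length(sample_episodic_memory(as.list(1:3), 5), 3)
  expect_length(sample_episodic_memory(list(), 5), 0)
})

test_that("curriculum phases include the right bins", {
  expect_equal(curriculum_phase(1)$bins_included, 1L)
  expect_equal(curriculum_phase(2)$bins_included, 1:2)
  expect_equal(curriculum_phase(3)$bins_included, 1:3)
  expect_error(curriculum_phase(4), "1, 2 or 3")
})

test_that("training runs, learns, projects only when memory exists, and is reproducible", {
  cases <- tiny_cases(4, seed = 300)
  by_bin <- list(cases[1:2], cases[3], cases[4])
  cfg <- train_config(epochs_per_phase = c(2L, 1L, 1L), seed = 9,
                      learning_rate = 2e-3)
  model <- build_unet(unet_config(base_channels = 2, seed = 4))

  fit1 <- train_curriculum(model, by_bin, cfg)
  fit2 <- train_curriculum(model, by_bin, cfg)
  expect_identical(fit1$history, fit2$history)          # seed-reproducible
  expect_identical(fit1$model$params, fit2$model$params)
  expect_gt(fit1$gem_calls, 0)                          # phases 2-3 project
  expect_true(all(is.finite(fit1$history$train_loss)))
  expect_lt(fit1$history$train_loss[2], fit1$history$train_loss[1])

  # phase 1 only: the projection is never invoked
  cfg1 <- train_config(epochs_per_phase = c(2L, 0L, 0L), seed = 9)
  fit_p1 <- train_curriculum(model, list(cases, list(), list()), cfg1)
  expect_equal(fit_p1$gem_calls, 0L)
  expect_equal(unique(fit_p1$history$phase), 1L)

  expect_error(train_curriculum(model, list(list(), cases, list()), cfg),
               "bin 1")
})

test_that("validation loss is tracked and early stopping respects patience", {
  cases <- tiny_cases(3, seed = 41)
  cfg <- train_config(epochs_per_phase = c(3L, 0L, 0L), seed = 2,
                      patience = 1L)
  model <- build_unet(unet_config(base_channels = 2, seed = 8))
  fit <- train_curriculum(model, list(cases[1:2], list(), list()), cfg,
                          validation = cases[3])
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_lte(nrow(fit$history), 3)
})
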