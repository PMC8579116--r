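test_that("constructors enforce stability, sign, and stochasticity invariants", {
  expect_error(ec_matrix(matrix(c(1, 0, 0, -1), 2, 2)), "strictly negative")
  expect_error(ec_matrix(matrix(c(0.2, 0.6, 0.6, -0.1), 2, 2) - diag(0.3, 2)),
               "unstable")
  expect_error(transition_matrix(matrix(c(0.5, 0.4, 0.5, 0.6), 2, 2)),
               "column\\(s\\): 1")
  tm <- preset_transition_matrix()
  expect_equal(colSums(tm), rep(1, 3), tolerance = 1e-14)
  for (A in preset_A_matrices()) {
    expect_lt(max(Re(eigen(A, only.values = TRUE)$values)), 0)
  }
})

test_that("state paths are piecewise constant with the requested epoch structure", {
  # absorbing states: identity transition matrix keeps the initial state
  p <- sample_state_path(diag(3), 20, 300, 0.8, seed = 5)
  expect_equal(length(unique(p$labels)), 1L)

  # bundled preset: 25-sample epochs, 375 samples, 15 epochs
  p <- sample_state_path(preset_transition_matrix(), 20, 300, 0.8, seed = 2)
  expect_equal(p$dwell_samples, 25L)
  expect_length(p$labels, 375L)
  epochs <- p$labels[seq(1, 375, by = 25)]
  expect_equal(rep(epochs, each = 25), p$labels)

  # deterministic swap alternates
  p <- sample_state_path(matrix(c(0, 1, 1, 0), 2, 2), 10, 100, 1, seed = 3)
  epochs <- p$labels[seq(1, 100, by = 10)]
  expect_true(all(diff(epochs) != 0))
})

test_that("epoch-transition frequencies match the transition matrix", {
  tm <- preset_transition_matrix()
  p <- sample_state_path(tm, 1, 10000, 1, seed = 11)
  lab <- p$labels
  for (j in 1:3) {
    from_j <- which(head(lab, -1) == j)
    n_j <- length(from_j)
    emp <- tabulate(lab[from_j + 1], 3) / n_j
    se <- sqrt(tm[, j] * (1 - tm[, j]) / n_j)
    expect_true(all(abs(emp - tm[, j]) <= 3 * se + 1e-12),
                info = sprintf("column %d", j))
  }
})

test_that("neural integration matches closed-form oracles", {
  # zero noise from the origin stays at equilibrium
  p <- sample_state_path(diag(2), 10, 50, 1, seed = 1)
  x <- integrate_neural(p, list(ec_matrix(diag(-1, 2)), ec_matrix(diag(-2, 2))),
                        neural_noise(sigma = 0, dt = 1), seed = 1)
  expect_equal(max(abs(x)), 0)

  # noiseless decay from x0 follows expm(A t) x0
  A <- rand_stable_A(3, seed = 4)
  p <- sample_state_path(diag(1), 5, 20, 0.5, seed = 1)
  x0 <- c(1, -2, 0.5)
  x <- integrate_neural(p, list(ec_matrix(A)), neural_noise(sigma = 0, dt = 0.5),
                        seed = 1, x0 = x0)
  for (t in c(1, 5, 20)) {
    oracle <- drop(statedcm:::expm_dense(A * t * 0.5) %*% x0)
    expect_equal(x[t, ], oracle, tolerance = 1e-8)
  }
  nrm <- sqrt(rowSums(x^2))
  expect_true(all(diff(nrm) < 0))

  # Ornstein-Uhlenbeck stationary variance sigma^2 / (2|a|)
  p <- sample_state_path(diag(1), 4000, 4000, 0.5, seed = 1)
  x <- integrate_neural(p, list(ec_matrix(matrix(-1, 1, 1))),
                        neural_noise(sigma = 1, dt = 0.5), seed = 9)
  expect_equal(var(x[, 1]), 0.5, tolerance = 0.05)
})

test_that("neural integration rejects invalid inputs", {
  p <- sample_state_path(diag(1), 5, 20, 1, seed = 1)
  unstable <- matrix(c(0.1, 0, 0, -1), 2, 2)
  expect_error(integrate_neural(p, list(unstable), neural_noise()), "negative")
  expect_error(integrate_neural(p, list(ec_matrix(diag(-1, 2))),
                                neural_noise(sigma = 1, dt = 2), seed = 1),
               "dt")
})

test_that("hemodynamic forward model reproduces balloon phenomenology", {
  # resting equilibrium: zero input gives exactly baseline output
  y <- hemodynamic_forward(matrix(0, 20, 3), tr = 0.8)
  expect_equal(max(abs(y)), 0)

  # a brief unit impulse peaks 3-7 s later (canonical hemodynamic lag)
  x <- matrix(0, 40, 1)
  x[5, 1] <- 1
  y <- hemodynamic_forward(x, tr = 1)
  peak <- which.max(y[, 1]) - 5
  expect_gte(peak, 3)
  expect_lte(peak, 7)

  # local linearity: doubling a small impulse doubles the peak
  x1 <- matrix(0, 40, 1); x1[5, 1] <- 0.05
  x2 <- matrix(0, 40, 1); x2[5, 1] <- 0.10
  r <- max(hemodynamic_forward(x2, tr = 1)) / max(hemodynamic_forward(x1, tr = 1))
  expect_equal(r, 2, tolerance = 0.1)

  # agreement with a fine-step integration of the same equations
  set.seed(2)
  xs <- matrix(rnorm(60, sd = 0.05), 60, 1)
  y8 <- hemodynamic_forward(xs, tr = 0.8, dt = 0.1)
  y64 <- hemodynamic_forward(xs, tr = 0.8, dt = 0.0125)
  expect_lt(max(abs(y8 - y64)) / max(abs(y64)), 0.01)
})

test_that("simulated datasets have the advertised size and are reproducible", {
  cfg <- sim_config()
  ds <- simulate_dataset(cfg, seed = 3)
  expect_length(ds$bold, 5L)
  for (j in 1:5) {
    expect_equal(dim(ds$bold[[j]]), c(375L, 4L))
    expect_length(ds$truth_path[[j]]$labels, 375L)
    expect_gt(stats::sd(ds$bold[[j]]), 0)
    expect_equal(colMeans(ds$bold[[j]]), rep(0, 4), tolerance = 1e-10)
  }
  ds2 <- simulate_dataset(cfg, seed = 3)
  expect_identical(ds$bold, ds2$bold)
  expect_identical(ds$truth_path, ds2$truth_path)
  # different seed, different data
  ds3 <- simulate_dataset(cfg, seed = 4)
  expect_false(identical(ds$bold[[1]], ds3$bold[[1]]))
})

test_that("dataset round-trips through delimited text with sidecar truth", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(tiny_sim_config(seed = 8))
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "subject01.csv")))
  back <- read_dataset(dir)
  expect_equal(back$tr, ds$tr)
  expect_equal(back$bold[[1]], ds$bold[[1]], ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$truth_path[[2]]$labels, ds$truth_path[[2]]$labels)
  expect_equal(unclass(back$truth_A[[1]]), unclass(ds$truth_A[[1]]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(back$tm), unclass(ds$tm), tolerance = 1e-12,
               ignore_attr = TRUE)
})
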