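test_that("degenerate one-state HMM reduces to the global least-squares MAR", {
  set.seed(1)
  W <- list(matrix(c(0.5, 0.1, -0.2, 0.4), 2, 2))
  y <- simulate_mar(W, diag(2), T_len = 400, seed = 2)
  fit <- hmm_fit(y, K = 1, order = 1, n_init = 1, seed = 1, w_prior = 0, sigma_nu = 0)
  s <- fit$probs[[1]]
  expect_true(all(abs(s[attr(s, "valid"), 1] - 1) < 1e-12))
  ref <- fit_mar(y, order = 1)
  expect_equal(fit$states[[1]]$W[[1]], ref$W[[1]], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a single-regime process collapses onto one state under pruning", {
  # a strong fixed coefficient prior prunes states that carry no distinctive
  # evidence; data from one MAR regime end up in a single state
  W <- list(matrix(c(0.6, 0.2, -0.1, 0.5), 2, 2))
  y <- simulate_mar(W, diag(2), T_len = 500, seed = 5)
  fit <- hmm_fit(y, K = 3, order = 1, n_init = 5, seed = 2, w_prior = 50, sigma_nu = 4)
  occ <- colMeans(fit$probs[[1]][attr(fit$probs[[1]], "valid"), ])
  expect_gte(max(occ), 0.95)
  # the same prior leaves genuinely distinct planted regimes intact
  pr <- planted_regime_series(T_len = 500, block = 50, seed = 6)
  fit2 <- hmm_fit(pr$y, K = 2, order = 1, n_init = 5, seed = 2, w_prior = 50, sigma_nu = 4)
  occ2 <- colMeans(fit2$probs[[1]][attr(fit2$probs[[1]], "valid"), ])
  expect_gt(min(occ2), 0.3)
})

test_that("planted two-regime switching is segmented accurately", {
  pr <- planted_regime_series(T_len = 600, block = 50, seed = 3)
  fit <- hmm_fit(pr$y, K = 2, order = 1, n_init = 10, seed = 4)
  s <- fit$probs[[1]]
  est <- max.col(s)
  valid <- attr(s, "valid")
  acc <- function(map) mean(map[pr$labels[valid]] == est[valid])
  expect_gte(max(acc(c(1, 2)), acc(c(2, 1))), 0.95)
})

test_that("EM objective is non-decreasing and posteriors are normalised", {
  pr <- planted_regime_series(T_len = 400, block = 40, seed = 9)
  fit <- hmm_fit(pr$y, K = 2, order = 2, n_init = 3, seed = 6)
  expect_true(all(diff(fit$trace) >= -1e-6 * pmax(1, abs(fit$trace[-1]))))
  s <- fit$probs[[1]]
  expect_true(all(abs(rowSums(s) - 1) < 1e-8))
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(abs(rowSums(fit$transition) - 1) < 1e-10))
  expect_equal(sum(fit$initial), 1, tolerance = 1e-10)
})

test_that("occupation indices are exact window means of state probabilities", {
  # pure state and symmetric cases are forced by the arithmetic mean
  s <- matrix(0, 40, 5)
  s[, 2] <- 1
  attr(s, "valid") <- rep(TRUE, 40)
  w <- make_windows(40, 10, 5)
  u <- occupation_index(s, w)
  expect_equal(u[, 2], rep(1, w$n))
  expect_equal(u[, 1], rep(0, w$n))

  s_unif <- matrix(1 / 5, 40, 5)
  attr(s_unif, "valid") <- rep(TRUE, 40)
  expect_equal(occupation_index(s_unif, w), matrix(1 / 5, w$n, 5))

  s4 <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2)
  attr(s4, "valid") <- rep(TRUE, 4)
  u4 <- occupation_index(s4, make_windows(4, 4, 0))
  expect_equal(drop(u4), c(0.5, 0.5))

  # whole-series single window equals fractional occupancy
  set.seed(2)
  s <- matrix(rexp(60), 20, 3)
  s <- s / rowSums(s)
  attr(s, "valid") <- rep(TRUE, 20)
  u <- occupation_index(s, make_windows(20, 20, 0))
  expect_equal(drop(u), colMeans(s))

  expect_error(occupation_index(s, make_windows(30, 30, 0)), "beyond")
})

test_that("state spectra follow the closed-form AR spectrum and are Hermitian", {
  # build a deterministic fit object around a univariate AR(1)
  y <- simulate_mar(list(matrix(0.9, 1, 1)), diag(1), T_len = 3000, seed = 7)
  fit <- hmm_fit(y, K = 1, order = 1, n_init = 1, seed = 1, tr = 1, w_prior = 0, sigma_nu = 0)
  freqs <- seq(0.05, 0.45, by = 0.1)
  S <- state_spectra(fit, 1, freqs)
  a <- fit$states[[1]]$W[[1]][1, 1]
  s2 <- fit$states[[1]]$Sigma[1, 1]
  oracle <- s2 / Mod(1 - a * exp(-2i * pi * freqs))^2
  expect_equal(Re(S$values[1, 1, ]), oracle, tolerance = 1e-10)
})

test_that("summary statistics capture occupancy, transitions, and entropy", {
  s <- matrix(0, 30, 3)
  s[, 2] <- 1
  attr(s, "valid") <- rep(TRUE, 30)
  st <- summary_stats(s)
  expect_equal(st$entropy, 0)
  expect_equal(st$transition, diag(3)[, ], ignore_attr = TRUE)
  expect_equal(st$occupancy, c(0, 1, 0))

  # strict alternation gives unit off-diagonal transition estimates
  s2 <- matrix(0, 20, 2)
  s2[cbind(1:20, rep(c(1, 2), 10))] <- 1
  attr(s2, "valid") <- rep(TRUE, 20)
  st2 <- summary_stats(s2)
  expect_equal(st2$transition[1, 2], 1)
  expect_equal(st2$transition[2, 1], 1)
  expect_equal(st2$entropy, log(2), tolerance = 1e-12)
})

test_that("state matching recovers identity and planted permutations", {
  pr <- planted_regime_series(T_len = 500, block = 50, seed = 11)
  fit <- hmm_fit(pr$y, K = 2, order = 1, n_init = 5, seed = 12)
  expect_equal(match_states(fit, fit), 1:2)

  # permute the labels by hand; matching must invert the permutation
  perm <- c(2L, 1L)
  fit_p <- fit
  fit_p$states <- fit$states[perm]
  inv <- match_states(fit, fit_p)
  expect_equal(inv, order(perm))

  # independent refit of the same data matches closer than the mismatch
  fit2 <- hmm_fit(pr$y, K = 2, order = 1, n_init = 5, seed = 99)
  p <- match_states(fit, fit2)
  freqs <- seq(0.01, 0.4, length.out = 16)
  d <- function(i, j) sum(Mod(state_spectra(fit, i, freqs)$values -
                              state_spectra(fit2, j, freqs)$values)^2)
  matched <- d(1, p[1]) + d(2, p[2])
  swapped <- d(1, p[2]) + d(2, p[1])
  expect_lt(matched, swapped)
})

test_that("retention keeps only states dominant in every subject", {
  pr1 <- planted_regime_series(T_len = 400, block = 50, seed = 21)
  pr2 <- planted_regime_series(T_len = 400, block = 50, seed = 22)
  fit <- hmm_fit(list(pr1$y, pr2$y), K = 3, order = 1, n_init = 5, seed = 23)
  ret <- retain_states(fit, threshold = 0.05)
  occ <- vapply(fit$probs, function(s)
    colMeans(s[attr(s, "valid"), , drop = FALSE]), numeric(3))
  for (k in ret) expect_true(all(occ[k, ] > 0.05))
  for (k in setdiff(1:3, ret)) expect_false(all(occ[k, ] > 0.05))
})
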