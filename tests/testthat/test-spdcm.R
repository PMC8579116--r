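test_that("self-connection transform is forced by its formula", {
  expect_equal(self_connection_value(0), -0.5)
  expect_equal(self_connection_value(log(2)), -1.0)
  th <- seq(-10, 2, by = 0.5)
  v <- self_connection_value(th)
  expect_true(all(v < 0))
  expect_true(all(diff(v) < 0))          # monotone decreasing in theta
  expect_gt(self_connection_value(-30), -1e-12)  # -> 0- in the limit
})

test_that("predicted CSD is Hermitian with positive auto-spectra", {
  pri <- dcm_priors(3)
  th <- pri$mean
  th["a_1_2"] <- 0.4; th["a_3_1"] <- -0.3
  freqs <- csd_freq_grid(60, 0.8)
  G <- predict_csd(th, 3, freqs)
  for (fi in c(1, 16, 32)) {
    Gf <- G$values[, , fi]
    expect_lt(max(Mod(Gf - Conj(t(Gf)))), 1e-12)
    expect_true(all(Re(diag(Gf)) > 0))
  }
  expect_error(predict_csd(th, 3, c(0, 0.1)), "exclude 0")
  th_bad <- pri$mean
  th_bad["a_1_2"] <- 2; th_bad["a_2_1"] <- 2
  expect_error(predict_csd(th_bad, 3, freqs), "unstable")
})

test_that("uncoupled nodes predict zero cross-spectra", {
  pri <- dcm_priors(2)
  G <- predict_csd(pri$mean, 2, csd_freq_grid(60, 0.8))
  expect_equal(max(Mod(G$values[1, 2, ])), 0)
})

test_that("predicted auto-spectra match a forward simulation of the same system", {
  # one node, known self-connection: simulate neural + balloon BOLD at length,
  # Welch-estimate the spectrum, and compare band-averaged magnitude
  pri <- dcm_priors(1)
  th <- pri$mean
  th[c("v_exp", "e_exp")] <- 0           # white fluctuations to match simulator
  sigma_v <- 0.02
  th["v_amp"] <- log(sigma_v^2)          # two-sided spectral density sigma^2
  th["e_amp"] <- -30                     # negligible observation noise
  tr <- 0.8
  T_len <- 30000
  p <- sample_state_path(diag(1), T_len * tr, T_len * tr, tr, seed = 1)
  x <- integrate_neural(p, list(ec_matrix(matrix(-0.5, 1, 1))),
                        neural_noise(sigma = sigma_v, dt = tr), seed = 2)
  y <- hemodynamic_forward(x, tr = tr)
  seg <- 512
  w <- 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / (seg - 1)))
  U <- sum(w^2)
  starts <- seq(1, T_len - seg + 1, by = seg %/% 2)
  acc <- 0
  for (s in starts) {
    z <- fft((y[s:(s + seg - 1), 1] - mean(y[s:(s + seg - 1), 1])) * w)
    acc <- acc + Mod(z)^2 / U
  }
  pxx <- acc / length(starts) * tr       # density per Hz
  fgrid <- (0:(seg - 1)) / (seg * tr)
  band <- fgrid >= 0.02 & fgrid <= 0.2
  G <- predict_csd(th, 1, fgrid[band])
  expect_equal(mean(Re(G$values[1, 1, ])), mean(pxx[band]), tolerance = 0.15)
})

test_that("inversion of prior-mean data returns the prior", {
  pri <- dcm_priors(2)
  G <- predict_csd(pri$mean, 2, csd_freq_grid(60, 0.8))
  post <- dcm_invert(G, pri)
  expect_lt(max(abs(post$mean - pri$mean)), 0.05)
  expect_true(all(diff(post$trace) >= -1e-8))
})

test_that("noiseless two-node inversion covers the truth at 95 percent", {
  pri <- dcm_priors(2)
  th <- pri$mean
  th["a_1_2"] <- 0.3; th["a_2_1"] <- -0.2; th["self_1"] <- 0.1
  G <- predict_csd(th, 2, csd_freq_grid(60, 0.8))
  post <- dcm_invert(G, pri)
  a_par <- c("a_1_2", "a_2_1", "self_1", "self_2")
  sd_p <- sqrt(diag(post$cov)[match(a_par, names(post$mean))])
  m <- post$mean[a_par]
  expect_true(all(th[a_par] >= m - 1.96 * sd_p & th[a_par] <= m + 1.96 * sd_p))
  expect_true(all(diff(post$trace) >= -1e-8))
  # posterior variance does not exceed prior variance beyond tolerance
  expect_true(all(diag(post$cov) <= diag(pri$cov) + 1e-6))
})

test_that("4-node parameter recovery exceeds r = 0.7 at low noise", {
  rs <- numeric(10)
  pri <- dcm_priors(4)
  freqs <- csd_freq_grid(60, 0.8)
  for (i in seq_len(10)) {
    set.seed(300 + i)
    th <- pri$mean
    od <- statedcm:::dcm_offdiag_names(4)
    th[od] <- rnorm(length(od), sd = 0.25)
    th[paste0("self_", 1:4)] <- rnorm(4, sd = 0.25)
    A <- statedcm:::dcm_build_A(th, 4)
    if (max(Re(eigen(A, only.values = TRUE)$values)) >= -0.01) {
      rs[i] <- NA
      next
    }
    G <- predict_csd(th, 4, freqs)
    post <- dcm_invert(G, pri)
    idx <- statedcm:::dcm_A_param_index(4)
    rs[i] <- cor(post$mean[as.vector(idx)], th[as.vector(idx)])
  }
  expect_gte(median(rs, na.rm = TRUE), 0.7)
})

test_that("windowed inversion yields one posterior per subject-window", {
  ds <- simulate_dataset(tiny_sim_config(seed = 31))
  wn <- make_windows(nrow(ds$bold[[1]]), 100, 50)
  dcms <- invert_windows(lapply(ds$bold, scale), wn, tr = ds$tr,
                         opts = list(order = 3, max_iter = 32))
  expect_length(dcms$fits, wn$n * length(ds$bold))
  expect_equal(dcms$subject, rep(seq_along(ds$bold), each = wn$n))
  ok <- !vapply(dcms$fits, is.null, logical(1))
  expect_true(all(ok))
  for (f in dcms$fits) expect_true(all(diff(f$trace) >= -1e-8))

  # determinism: the same window inverted twice gives identical posteriors
  seg <- hann_taper(ds$bold[[1]][1:100, ])
  mar <- fit_mar(seg, 3, delta = ds$tr, ridge = 1e-6)
  csd <- mar_to_csd(mar, csd_freq_grid(100 * ds$tr, ds$tr))
  p1 <- dcm_invert(csd, dcm_priors(2), opts = list(max_iter = 32))
  p2 <- dcm_invert(csd, dcm_priors(2), opts = list(max_iter = 32))
  expect_identical(p1$mean, p2$mean)
  expect_identical(p1$F, p2$F)
})
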