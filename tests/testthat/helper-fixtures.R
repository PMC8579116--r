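# shared fixture builders; everything is generated in code at test time

# simulate a (possibly vector) AR process y_t = sum_l W_l y_{t-l} + e_t
simulate_mar <- function(W, Sigma, T_len, seed = 1, burn = 200) {
  set.seed(seed)
  n <- nrow(Sigma)
  p <- length(W)
  R <- chol(Sigma)
  y <- matrix(0, T_len + burn, n)
  for (t in (p + 1):(T_len + burn)) {
    m <- rep(0, n)
    for (l in seq_len(p)) m <- m + W[[l]] %*% y[t - l, ]
    y[t, ] <- m + drop(rnorm(n) %*% R)
  }
  y[(burn + 1):(burn + T_len), , drop = FALSE]
}

# random stable coupling matrix with negative diagonal
rand_stable_A <- function(n, seed = 1, scale = 0.3) {
  set.seed(seed)
  repeat {
    A <- matrix(rnorm(n * n, sd = scale), n, n)
    diag(A) <- -abs(rnorm(n, 0.5, 0.1))
    if (max(Re(eigen(A, only.values = TRUE)$values)) < -0.01) return(A)
  }
}

# two-regime MAR(1) series switching every `block` samples
planted_regime_series <- function(T_len = 600, block = 50, seed = 1) {
  set.seed(seed)
  W1 <- list(matrix(c(0.9, 0, 0, 0.2), 2, 2))
  W2 <- list(matrix(c(-0.6, 0.3, 0.3, 0.7), 2, 2))
  R <- diag(2)
  y <- matrix(0, T_len, 2)
  lab <- integer(T_len)
  prev <- c(0, 0)
  regime <- 1L
  for (t in seq_len(T_len)) {
    if (t > 1 && (t - 1) %% block == 0) regime <- 3L - regime
    W <- if (regime == 1L) W1[[1]] else W2[[1]]
    y[t, ] <- drop(W %*% prev) + rnorm(2)
    prev <- y[t, ]
    lab[t] <- regime
  }
  list(y = y, labels = lab)
}

# tiny two-state simulation configuration (cheap end-to-end runs)
tiny_sim_config <- function(seed = 1, n_subjects = 2, duration_s = 160,
                            obs_sd = 0.02) {
  A1 <- matrix(c(-0.4, 0.35, -0.3, -0.5), 2, 2)
  A2 <- matrix(c(-0.6, -0.3, 0.4, -0.3), 2, 2)
  sim_config(n_subjects = n_subjects, duration_s = duration_s, tr = 0.8,
             dwell_s = 16,
             A_by_state = list(ec_matrix(A1), ec_matrix(A2)),
             tm = transition_matrix(matrix(c(0.2, 0.8, 0.8, 0.2), 2, 2)),
             noise = neural_noise(obs_sd = obs_sd),
             seed = seed)
}
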