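#' Effective-connectivity matrix constructor
#'
#' Validates a square coupling matrix A (Hz). Off-diagonal entry (i, j) is the
#' directed influence of node j on node i; diagonal entries are self
#' connections and must be strictly negative. For use in the simulator the
#' matrix must be dynamically stable (all eigenvalues with negative real
#' part), so that dx/dt = A x + v(t) has a stationary solution.
#'
#' @param values square numeric matrix
#' @param check_stable require all eigenvalues to have negative real part
#' @return the validated matrix with class `statedcm_ec`
#' @export
ec_matrix <- function(values, check_stable = TRUE) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("effective-connectivity matrix must be square")
  if (any(!is.finite(values))) stop("effective-connectivity matrix must be finite")
  if (any(diag(values) >= 0)) {
    stop("diagonal (self-connection) entries must be strictly negative; offending node(s): ",
         paste(which(diag(values) >= 0), collapse = ", "))
  }
  if (check_stable) {
    mre <- max(Re(eigen(values, only.values = TRUE)$values))
    if (mre >= 0) stop(sprintf("unstable A matrix: max real eigenvalue = %.4g >= 0", mre))
  }
  structure(values, class = c("statedcm_ec", "matrix", "array"))
}

#' State-transition probability matrix constructor
#'
#' Column-stochastic convention: entry (i, j) is the probability that the next
#' state is i given that the current state is j, so every column sums to one.
#'
#' @param values K x K numeric matrix of probabilities
#' @return the validated matrix with class `statedcm_tm`
#' @export
transition_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("transition matrix must be square")
  if (any(values < 0 | values > 1)) stop("transition probabilities must lie in [0, 1]")
  cs <- colSums(values)
  bad <- which(abs(cs - 1) > 1e-12)
  if (length(bad)) {
    stop("transition matrix columns must sum to 1; offending column(s): ",
         paste(sprintf("%d (sum %.6f)", bad, cs[bad]), collapse = ", "))
  }
  structure(values, class = c("statedcm_tm", "matrix", "array"))
}

#' Ground-truth connectivity states of the bundled simulation preset
#'
#' Three stable 4-node effective-connectivity matrices (Hz) derived from
#' default-mode-network estimates, used as the switching regimes of the
#' bundled simulation configuration.
#'
#' @return list of three `statedcm_ec` matrices
#' @export
preset_A_matrices <- function() {
  A1 <- matrix(c(-0.561, -0.359,  0.539,  0.582,
                 -0.131, -0.201,  0.398,  0.367,
                  0.153, -0.121, -0.431,  0.578,
                  0.075, -0.071,  0.216, -0.549), 4, 4, byrow = TRUE)
  A2 <- matrix(c(-0.153, -0.568,  0.164, -0.032,
                  0.031, -0.549,  0.349, -0.055,
                  0.380,  0.170, -0.326,  0.350,
                  0.257,  0.593, -0.245, -0.510), 4, 4, byrow = TRUE)
  A3 <- matrix(c(-0.161,  0.130,  0.247, -0.299,
                 -0.314, -0.133, -0.466, -0.184,
                  0.522,  0.294, -0.354,  0.323,
                  0.070,  0.058,  0.151, -1.199), 4, 4, byrow = TRUE)
  lapply(list(A1, A2, A3), ec_matrix)
}

#' Ground-truth transition matrix of the bundled simulation preset
#'
#' Column-stochastic 3 x 3 matrix of epoch-to-epoch transition probabilities
#' between the three connectivity states.
#'
#' @return a `statedcm_tm` matrix
#' @export
preset_transition_matrix <- function() {
  transition_matrix(matrix(c(0.3, 0.5, 0.1,
                             0.2, 0.2, 0.8,
                             0.5, 0.3, 0.1), 3, 3, byrow = TRUE))
}

#' Hemodynamic (balloon model) parameter set
#'
#' Standard balloon/Windkessel constants: signal decay rate kappa (1/s),
#' flow feedback rate gamma (1/s), venous transit time tau (s), vessel
#' stiffness alpha, resting oxygen extraction E0, echo time TE (s), plus the
#' BOLD readout constants (resting venous volume fraction V0 in percent,
#' frequency offset theta0, sensitivity r0, ratio epsilon).
#'
#' @param kappa,gamma,tau,alpha,E0,TE,V0,theta0,r0,epsilon balloon-model constants
#' @return list of validated constants with class `statedcm_hrf`
#' @export
hemodynamic_params <- function(kappa = 0.64, gamma = 0.32, tau = 2.0,
                               alpha = 0.32, E0 = 0.4, TE = 0.04,
                               V0 = 4, theta0 = 40.3, r0 = 25, epsilon = 1) {
  stopifnot(kappa > 0, gamma > 0, tau > 0, TE > 0, V0 > 0)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (E0 <= 0 || E0 >= 1) stop("E0 must lie in (0, 1)")
  structure(list(kappa = kappa, gamma = gamma, tau = tau, alpha = alpha,
                 E0 = E0, TE = TE, V0 = V0, theta0 = theta0, r0 = r0,
                 epsilon = epsilon),
            class = "statedcm_hrf")
}

#' Neural / observation noise specification
#'
#' @param sigma standard deviation (spectral density scale) of the endogenous
#'   neural fluctuation v(t), per node (scalar or per-node vector)
#' @param ar_smooth AR(1) smoothing coefficient in [0, 1) applied to the
#'   discrete innovations (0 = white noise)
#' @param obs_sd standard deviation of additive BOLD observation noise e(t)
#' @param dt integration step in seconds
#' @return list with class `statedcm_noise`
#' @export
neural_noise <- function(sigma = 0.02, ar_smooth = 0, obs_sd = 0.05, dt = 0.1) {
  stopifnot(all(sigma >= 0), obs_sd >= 0, dt > 0, ar_smooth >= 0, ar_smooth < 1)
  structure(list(sigma = sigma, ar_smooth = ar_smooth, obs_sd = obs_sd, dt = dt),
            class = "statedcm_noise")
}

#' Sample a piecewise-constant hidden state path
#'
#' The path is constant over epochs of `dwell_s` seconds; at each epoch
#' boundary the next state is drawn from the current state's column of the
#' transition matrix. The initial state is uniform over states.
#'
#' @param tm `statedcm_tm` (or coercible matrix), column-stochastic
#' @param dwell_s epoch (dwell) duration in seconds; must be a whole number of
#'   samples at `tr`
#' @param duration_s total duration in seconds
#' @param tr sampling interval in seconds
#' @param seed integer seed
#' @return object of class `statedcm_path`: integer labels per sample with
#'   fields `dwell_samples` and `tr`
#' @export
sample_state_path <- function(tm, dwell_s, duration_s, tr, seed = 1) {
  tm <- transition_matrix(tm)
  stopifnot(dwell_s > 0, duration_s > 0, tr > 0)
  dwell <- dwell_s / tr
  if (abs(dwell - round(dwell)) > 1e-8)
    stop("dwell_s must be a whole number of samples at the given tr")
  dwell <- as.integer(round(dwell))
  n_samp <- as.integer(round(duration_s / tr))
  n_epochs <- ceiling(n_samp / dwell)
  K <- nrow(tm)
  set.seed(seed)
  states <- integer(n_epochs)
  states[1] <- sample.int(K, 1)
  if (n_epochs > 1) {
    for (e in 2:n_epochs) {
      states[e] <- sample.int(K, 1, prob = tm[, states[e - 1]])
    }
  }
  labels <- rep(states, each = dwell)[seq_len(n_samp)]
  structure(list(labels = labels, dwell_samples = dwell, tr = tr, K = K),
            class = "statedcm_path")
}

#' Integrate state-switching linear neural dynamics
#'
#' Solves dx = A_z(t) x dt + dW over the state path, where A_z is the
#' effective-connectivity matrix of the active state and dW is white noise
#' with spectral density sigma^2 per node. Uses exact discretisation (matrix
#' exponential transition and Lyapunov-integral innovation covariance, Van
#' Loan method) at step `noise$dt`; the active state is the state of the
#' enclosing TR sample. Returns the neural state sampled on the TR grid.
#'
#' @param path `statedcm_path`
#' @param A_by_state list of stable `statedcm_ec` matrices, indexed by state
#' @param noise `statedcm_noise`
#' @param seed integer seed
#' @param x0 initial neural state (default zero)
#' @param return_fine also return the full fine-step series (attribute
#'   `fine`, with attribute `dt`), for driving the hemodynamic model at the
#'   integration resolution
#' @return T x n matrix of neural states at the TR grid
#' @export
integrate_neural <- function(path, A_by_state, noise = neural_noise(), seed = 1,
                             x0 = NULL, return_fine = FALSE) {
  stopifnot(inherits(path, "statedcm_path"))
  A_by_state <- lapply(A_by_state, function(A) ec_matrix(A, check_stable = TRUE))
  n <- nrow(A_by_state[[1]])
  if (max(path$labels) > length(A_by_state))
    stop("path contains state labels beyond the supplied A matrices")
  tr <- path$tr
  dt <- noise$dt
  if (dt > tr) stop("integration step dt must not exceed the sampling interval tr")
  n_sub <- round(tr / dt)
  if (abs(tr / dt - n_sub) > 1e-8)
    stop("tr must be a whole multiple of the integration step dt")
  n_sub <- as.integer(n_sub)
  dt <- tr / n_sub
  sigma <- rep(noise$sigma, length.out = n)
  Qc <- diag(sigma^2, n)
  disc <- lapply(A_by_state, function(A) {
    d <- discretize_lti(unclass(A), Qc, dt)
    d$R <- if (all(sigma == 0)) NULL else chol(d$Qd + diag(1e-14, n))
    d
  })
  T_len <- length(path$labels)
  set.seed(seed)
  x <- if (is.null(x0)) rep(0, n) else as.numeric(x0)
  out <- matrix(0, T_len, n)
  fine <- if (return_fine) matrix(0, T_len * n_sub, n) else NULL
  phi <- noise$ar_smooth
  w_prev <- rep(0, n)
  for (t in seq_len(T_len)) {
    d <- disc[[path$labels[t]]]
    for (s in seq_len(n_sub)) {
      w <- if (is.null(d$R)) rep(0, n) else drop(rnorm(n) %*% d$R)
      if (phi > 0) {
        w <- phi * w_prev + sqrt(1 - phi^2) * w
        w_prev <- w
      }
      x <- drop(d$Ad %*% x) + w
      if (return_fine) fine[(t - 1L) * n_sub + s, ] <- x
    }
    out[t, ] <- x
  }
  if (return_fine) {
    attr(fine, "dt") <- dt
    attr(out, "fine") <- fine
  }
  out
}

# balloon-model ODE right-hand side in log space for (f, v, q);
# state columns: s, log f, log v, log q; u is the neural drive per node
balloon_rhs <- function(S, u, h) {
  s <- S[, 1]; f <- exp(S[, 2]); v <- exp(S[, 3]); q <- exp(S[, 4])
  E_f <- 1 - (1 - h$E0)^(1 / f)
  fv <- v^(1 / h$alpha)
  cbind(u - h$kappa * s - h$gamma * (f - 1),
        s / f,
        (f - fv) / (h$tau * v),
        (f * E_f / h$E0 / q - fv / v) / h$tau)
}

# analytic Jacobian of balloon_rhs for one node (states s, log f, log v,
# log q); needed by the linearly-implicit integrator
balloon_jac <- function(Sj, u, h) {
  s <- Sj[1]; lf <- Sj[2]; lv <- Sj[3]; lq <- Sj[4]
  f <- exp(lf)
  ia <- 1 / h$alpha
  E_f <- 1 - (1 - h$E0)^(1 / f)
  Ep <- (1 - h$E0)^(1 / f) * log(1 - h$E0) / f^2
  phi <- f * E_f / h$E0            # flow-weighted extraction
  dphi <- (f * E_f + f^2 * Ep) / h$E0
  J <- matrix(0, 4, 4)
  J[1, 1] <- -h$kappa
  J[1, 2] <- -h$gamma * f
  J[2, 1] <- exp(-lf)
  J[2, 2] <- -s * exp(-lf)
  J[3, 2] <- exp(lf - lv) / h$tau
  J[3, 3] <- (-exp(lf - lv) - (ia - 1) * exp((ia - 1) * lv)) / h$tau
  J[4, 2] <- dphi * exp(-lq) / h$tau
  J[4, 3] <- -(ia - 1) * exp((ia - 1) * lv) / h$tau
  J[4, 4] <- -phi * exp(-lq) / h$tau
  J
}

# static BOLD readout from log-volume / log-deoxyhemoglobin
balloon_bold <- function(S, h) {
  v <- exp(S[, 3]); q <- exp(S[, 4])
  k1 <- 4.3 * h$theta0 * h$E0 * h$TE
  k2 <- h$epsilon * h$r0 * h$E0 * h$TE
  k3 <- 1 - h$epsilon
  h$V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

#' Hemodynamic (balloon model) forward BOLD response
#'
#' Integrates the four hemodynamic states per node (vasodilatory signal,
#' inflow, venous volume, deoxyhemoglobin content; the latter three in log
#' space for positivity) driven by the neural series, with a linearly
#' implicit matrix-exponential (Rosenbrock) step of size `dt` and zero-order
#' hold of the neural input within each TR, then applies the static BOLD
#' readout. The implicit step is required because the log-flow equation is
#' stiff whenever sustained negative drive pushes inflow toward zero.
#' Optional i.i.d. Gaussian observation noise is added.
#'
#' @param x neural series: T x n at the TR grid (held constant within each
#'   TR), or `T * round(tr/input_dt)` rows sampled at `input_dt`
#' @param theta `statedcm_hrf` parameter set
#' @param tr sampling interval (s) of the returned BOLD series
#' @param obs_sd observation noise standard deviation (0 = noiseless)
#' @param dt integration step (default tr/8)
#' @param seed seed for the observation noise
#' @param input_dt sampling interval of `x` (default `tr`); when finer than
#'   `tr` the integration step follows the input resolution
#' @return T x n BOLD series (baseline-relative, approximately zero mean)
#' @export
hemodynamic_forward <- function(x, theta = hemodynamic_params(), tr,
                                obs_sd = 0, dt = tr / 8, seed = 1,
                                input_dt = tr) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("neural input must be finite")
  n <- ncol(x)
  in_sub <- as.integer(round(tr / input_dt))
  if (in_sub > 1L) dt <- input_dt
  T_len <- nrow(x) %/% in_sub
  n_sub <- as.integer(round(tr / dt))
  dt <- tr / n_sub
  sub_per_in <- max(1L, n_sub %/% in_sub)
  S <- cbind(rep(0, n), rep(0, n), rep(0, n), rep(0, n))  # equilibrium
  y <- matrix(0, T_len, n)
  M <- matrix(0, 5, 5)
  for (t in seq_len(T_len)) {
    for (s in seq_len(n_sub)) {
      # input held over the finest available resolution
      u <- x[(t - 1L) * in_sub + min(in_sub, 1L + (s - 1L) %/% sub_per_in), ]
      g <- balloon_rhs(S, u, theta)
      for (j in seq_len(n)) {
        # S_j <- S_j + (expm(J dt) - I) J^-1 g via the augmented exponential
        M[1:4, 1:4] <- balloon_jac(S[j, ], u[j], theta)
        M[1:4, 5] <- g[j, ]
        E <- expm_dense(M * dt)
        S[j, ] <- S[j, ] + E[1:4, 5]
      }
      # physiological guard: log states bounded (flow/volume cannot vanish
      # or grow without limit); prevents the finite-time log-flow escape
      S[, 2:4][S[, 2:4] < -5] <- -5
      S[, 2:4][S[, 2:4] > 5] <- 5
    }
    if (any(!is.finite(S)))
      stop(sprintf("hemodynamic states diverged at sample %d; reduce dt or input amplitude", t))
    y[t, ] <- balloon_bold(S, theta)
  }
  if (obs_sd > 0) {
    set.seed(seed)
    y <- y + matrix(rnorm(T_len * n, sd = obs_sd), T_len, n)
  }
  y
}

#' Simulation configuration
#'
#' Defaults reproduce the bundled validation study: five subjects, 300 s at
#' TR 0.8 s (375 samples), three 4-node connectivity states with 20-s dwell
#' epochs switching per the preset transition matrix.
#'
#' @param n_subjects number of subjects
#' @param duration_s scan duration per subject (s)
#' @param tr sampling interval (s)
#' @param dwell_s state dwell time (s)
#' @param A_by_state list of `statedcm_ec` matrices (one per state)
#' @param tm `statedcm_tm` transition matrix
#' @param noise `statedcm_noise`
#' @param hrf `statedcm_hrf`
#' @param seed integer seed
#' @return list with class `statedcm_simconfig`
#' @export
sim_config <- function(n_subjects = 5, duration_s = 300, tr = 0.8, dwell_s = 20,
                       A_by_state = preset_A_matrices(),
                       tm = preset_transition_matrix(),
                       noise = neural_noise(), hrf = hemodynamic_params(),
                       seed = 1) {
  tm <- transition_matrix(tm)
  A_by_state <- lapply(A_by_state, ec_matrix)
  if (nrow(tm) != length(A_by_state))
    stop("transition matrix dimension must equal the number of A matrices")
  structure(list(n_subjects = n_subjects, duration_s = duration_s, tr = tr,
                 dwell_s = dwell_s, A_by_state = A_by_state, tm = tm,
                 noise = noise, hrf = hrf, seed = seed),
            class = "statedcm_simconfig")
}

#' Simulate a multi-subject state-switching BOLD dataset
#'
#' For each subject, independently samples a state path, integrates the
#' state-switching neural dynamics, passes them through the balloon-model
#' observation function, adds observation noise, and mean-centres each node.
#'
#' @param config `statedcm_simconfig`
#' @param seed overrides `config$seed` when given
#' @return object of class `statedcm_dataset`: `bold` (list of T x n
#'   matrices), `truth_path` (list of `statedcm_path`), `truth_A`, `tm`,
#'   `tr`, `seed`, `config`
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "statedcm_simconfig"))
  seed <- seed %||% config$seed
  bold <- vector("list", config$n_subjects)
  paths <- vector("list", config$n_subjects)
  for (j in seq_len(config$n_subjects)) {
    paths[[j]] <- sample_state_path(config$tm, config$dwell_s, config$duration_s,
                                    config$tr, seed = derive_seed(seed, 3L * j))
    x <- integrate_neural(paths[[j]], config$A_by_state, config$noise,
                          seed = derive_seed(seed, 3L * j + 1L),
                          return_fine = TRUE)
    xf <- attr(x, "fine")
    y <- hemodynamic_forward(xf, config$hrf, tr = config$tr,
                             obs_sd = config$noise$obs_sd,
                             seed = derive_seed(seed, 3L * j + 2L),
                             input_dt = attr(xf, "dt"))
    bold[[j]] <- scale(y, center = TRUE, scale = FALSE)
    attr(bold[[j]], "scaled:center") <- NULL
  }
  structure(list(bold = bold, truth_path = paths, truth_A = config$A_by_state,
                 tm = config$tm, tr = config$tr, seed = seed, config = config),
            class = "statedcm_dataset")
}

#' @export
print.statedcm_dataset <- function(x, ...) {
  cat(sprintf("statedcm dataset: %d subjects, %d samples x %d nodes, TR %.3g s, %d states\n",
              length(x$bold), nrow(x$bold[[1]]), ncol(x$bold[[1]]), x$tr,
              length(x$truth_A)))
  invisible(x)
}
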