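#' Spectral-DCM parameter template and priors
#'
#' The parameter vector holds, in order: the n(n-1) off-diagonal couplings of
#' A (Hz, unconstrained, column-major), the n self-connection log-scalings
#' (effective rate -0.5 exp(theta)), per-node log-scalings of the
#' hemodynamic decay rate and transit time, per-node signal log-gains
#' (diagonal output scalings that absorb arbitrary per-node units, e.g.
#' z-scored components), and log-amplitude/exponent pairs for the power-law
#' spectra of the endogenous fluctuations and observation noise,
#' g(f) = exp(amp) * f^(-exp). Prior means are zero except the two spectral
#' exponents (mean 1, pink); prior variances are 1/16 for the couplings and
#' self log-scalings, 1/64 for the gains and noise parameters, and 1/256 for
#' the hemodynamic log-scalings.
#'
#' @param n number of nodes
#' @return list with `mean` (named vector), `cov` (diagonal matrix), `n`
#' @export
dcm_priors <- function(n) {
  od <- dcm_offdiag_names(n)
  nm <- c(od,
          paste0("self_", seq_len(n)),
          paste0("kappa_", seq_len(n)),
          paste0("tau_", seq_len(n)),
          paste0("gain_", seq_len(n)),
          "v_amp", "v_exp", "e_amp", "e_exp")
  mu <- stats::setNames(numeric(length(nm)), nm)
  mu["v_exp"] <- 1
  mu["e_exp"] <- 1
  v <- stats::setNames(rep(1 / 64, length(nm)), nm)
  v[od] <- 1 / 16
  v[paste0("self_", seq_len(n))] <- 1 / 16
  v[paste0("kappa_", seq_len(n))] <- 1 / 256
  v[paste0("tau_", seq_len(n))] <- 1 / 256
  list(mean = mu, cov = diag(v), n = n)
}

dcm_offdiag_names <- function(n) {
  idx <- which(row(diag(n)) != col(diag(n)))
  sprintf("a_%d_%d", row(diag(n))[idx], col(diag(n))[idx])
}

# n x n matrix of positions into the parameter vector for the A matrix
# (off-diagonals are raw couplings; diagonal entries index the self
# log-scalings, to be interpreted through -0.5 exp())
dcm_A_param_index <- function(n) {
  nm <- names(dcm_priors(n)$mean)
  M <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    M[i, j] <- if (i == j) match(sprintf("self_%d", i), nm)
               else match(sprintf("a_%d_%d", i, j), nm)
  }
  M
}

# assemble A from the parameter vector
dcm_build_A <- function(theta, n) {
  A <- matrix(0, n, n)
  idx <- dcm_A_param_index(n)
  A[] <- theta[idx]
  diag(A) <- -0.5 * exp(theta[idx[cbind(seq_len(n), seq_len(n))]])
  A
}

#' Self-connection transformation
#'
#' Maps the unconstrained self-connection log-scaling to the effective
#' (always inhibitory) rate -0.5 exp(theta) in Hz.
#'
#' @param theta_ii numeric log-scaling(s)
#' @return effective self-connection rate(s), strictly negative
#' @export
self_connection_value <- function(theta_ii) {
  stopifnot(all(is.finite(theta_ii)))
  -0.5 * exp(theta_ii)
}

# first-order (linearised balloon) hemodynamic frequency response for one
# node; returns a complex vector over freqs
hemo_response <- function(freqs, kappa, tau, hrf) {
  cf <- (hrf$E0 + (1 - hrf$E0) * log(1 - hrf$E0)) / hrf$E0
  cv <- 1 / hrf$alpha - 1
  J <- rbind(c(-kappa, -hrf$gamma, 0, 0),
             c(1, 0, 0, 0),
             c(0, 1 / tau, -1 / (hrf$alpha * tau), 0),
             c(0, cf / tau, -cv / tau, -1 / tau))
  k1 <- 4.3 * hrf$theta0 * hrf$E0 * hrf$TE
  k2 <- hrf$epsilon * hrf$r0 * hrf$E0 * hrf$TE
  k3 <- 1 - hrf$epsilon
  c_out <- c(0, 0, hrf$V0 * (k2 - k3), -hrf$V0 * (k1 + k2))
  e <- eigen(J)
  iw <- 2i * pi * freqs
  w_in <- tryCatch(solve(e$vectors, c(1, 0, 0, 0)), error = function(err) NULL)
  if (is.null(w_in)) {
    return(sapply(seq_along(freqs), function(fi)
      sum(c_out * solve(diag(iw[fi], 4) - J, c(1, 0, 0, 0)))))
  }
  w_out <- drop(c_out %*% e$vectors)
  sapply(seq_along(freqs), function(fi) sum(w_out * w_in / (iw[fi] - e$values)))
}

#' Predicted cross-spectral density of the spectral DCM
#'
#' The linearised neural + hemodynamic cascade has transfer function
#' S(f) = diag(B(f)) (i 2 pi f I - A)^-1 per frequency, where B is the
#' per-node first-order hemodynamic frequency response; the predicted CSD is
#' S gv(f) S* + ge(f) I with power-law spectra gv, ge for the endogenous
#' fluctuations and observation noise.
#'
#' @param theta named parameter vector (layout of [dcm_priors()])
#' @param n number of nodes
#' @param freqs frequency grid in Hz (must exclude 0)
#' @param hrf `statedcm_hrf` constants shared with the simulator
#' @return `statedcm_csd`
#' @export
predict_csd <- function(theta, n, freqs, hrf = hemodynamic_params()) {
  if (any(freqs <= 0)) stop("frequency grid must exclude 0 (power-law noise)")
  A <- dcm_build_A(theta, n)
  mre <- max(Re(eigen(A, only.values = TRUE)$values))
  if (mre >= 0)
    stop(sprintf("implied A is unstable: max real eigenvalue %.4g >= 0", mre))
  structure(list(freqs = freqs,
                 values = predict_csd_values(theta, n, freqs, hrf, A)),
            class = "statedcm_csd")
}

# core forward pass; assumes A stable, returns n x n x nf complex array
predict_csd_values <- function(theta, n, freqs, hrf, A = NULL) {
  if (is.null(A)) A <- dcm_build_A(theta, n)
  nf <- length(freqs)
  # eigen-decomposition accelerates the per-frequency resolvent, but a
  # defective A (repeated eigenvalues) needs the direct solve fallback
  eA <- eigen(A)
  Vi <- tryCatch(solve(eA$vectors), error = function(e) NULL)
  B <- matrix(0i, n, nf)
  for (j in seq_len(n)) {
    B[j, ] <- hemo_response(freqs,
                            kappa = hrf$kappa * exp(theta[[paste0("kappa_", j)]]),
                            tau = hrf$tau * exp(theta[[paste0("tau_", j)]]),
                            hrf)
  }
  gains <- exp(vapply(seq_len(n), function(j) theta[[paste0("gain_", j)]],
                      numeric(1)))
  gv <- exp(theta[["v_amp"]]) * freqs^(-theta[["v_exp"]])
  ge <- exp(theta[["e_amp"]]) * freqs^(-theta[["e_exp"]])
  vals <- array(0i, c(n, n, nf))
  iw <- 2i * pi * freqs
  I_n <- diag(n)
  for (fi in seq_len(nf)) {
    Tf <- if (is.null(Vi)) solve(diag(iw[fi], n) - A)
          else eA$vectors %*% (Vi / (iw[fi] - eA$values))
    S <- (gains * B[, fi]) * Tf
    G <- gv[fi] * S %*% Conj(t(S)) + ge[fi] * I_n
    vals[, , fi] <- (G + Conj(t(G))) / 2
  }
  vals
}

# internal: forward pass returning NULL instead of erroring on instability
predict_csd_try <- function(theta, n, freqs, hrf) {
  A <- dcm_build_A(theta, n)
  ev <- eigen(A, only.values = TRUE)$values
  if (max(Re(ev)) >= -1e-6) return(NULL)
  predict_csd_values(theta, n, freqs, hrf, A)
}

# vectorise a CSD array: per frequency, real upper triangle (incl. diagonal)
# then imaginary strict upper triangle
vec_csd <- function(vals) {
  n <- dim(vals)[1]
  ur <- upper.tri(diag(n), diag = TRUE)
  ui <- upper.tri(diag(n), diag = FALSE)
  nf <- dim(vals)[3]
  out <- numeric(nf * (sum(ur) + sum(ui)))
  m <- sum(ur) + sum(ui)
  for (fi in seq_len(nf)) {
    G <- vals[, , fi]
    out[((fi - 1) * m + 1):(fi * m)] <- c(Re(G[ur]), Im(G[ui]))
  }
  out
}

#' Invert a spectral DCM against an observed CSD (variational Laplace)
#'
#' Gauss-Newton ascent on the variational free energy over the stacked
#' real/imaginary CSD residuals, with Levenberg-Marquardt regularisation and
#' an EM update of a single log-precision hyperparameter. Residuals are
#' normalised per frequency by the observed mean auto-spectral power
#' (multiplicative-error weighting in the spirit of Whittle likelihoods), so
#' the strongly coloured low-frequency bins do not dominate the fit. Steps
#' are accepted only when they increase the free energy, so the accepted-step
#' trace is monotone. The observed CSD is rescaled once so its mean
#' auto-spectral power matches the prior-mean prediction (the scale is
#' returned); this makes the amplitude parameters commensurate with their
#' priors without affecting the connectivity estimates.
#'
#' @param observed `statedcm_csd` (Hermitian, grid excluding 0)
#' @param priors list as from [dcm_priors()]; defaults to `dcm_priors(n)`
#' @param opts list: `hrf` (balloon constants), `max_iter` (128), `tol`
#'   (1e-4), `normalize` (TRUE), `diff_step` (1e-3 finite-difference step),
#'   `lambda_var` (16, hyperprior variance on the log precision),
#'   `weight_floor` (0.1, the fraction of the peak auto-spectral power at
#'   which the per-frequency residual weights saturate)
#' @return object of class `statedcm_dcm`: posterior `mean` and `cov`, free
#'   energy `F`, accepted-step `trace`, `converged`, log-precision `lambda`,
#'   data `scale`, `n`, `freqs`
#' @export
dcm_invert <- function(observed, priors = NULL, opts = list()) {
  stopifnot(inherits(observed, "statedcm_csd"))
  n <- dim(observed$values)[1]
  freqs <- observed$freqs
  if (any(freqs <= 0)) stop("observed CSD grid must exclude 0")
  herm_err <- max(vapply(seq_along(freqs), function(fi) {
    G <- observed$values[, , fi]
    max(Mod(G - Conj(t(G))))
  }, numeric(1)))
  if (herm_err > 1e-8) stop("observed CSD is not Hermitian")
  priors <- priors %||% dcm_priors(n)
  hrf <- opts$hrf %||% hemodynamic_params()
  max_iter <- opts$max_iter %||% 128
  tol <- opts$tol %||% 1e-4
  diff_step <- opts$diff_step %||% 1e-3
  lambda_var <- opts$lambda_var %||% 16
  normalize <- opts$normalize %||% TRUE

  mu0 <- priors$mean
  P0 <- solve(priors$cov)
  p <- length(mu0)
  g0 <- predict_csd_values(mu0, n, freqs, hrf)
  obs_vals <- observed$values
  scale <- rep(1, n)
  if (normalize) {
    # per-node scaling so each observed mean auto-power matches the
    # prior-mean prediction; residual unit mismatch is absorbed by the gain
    # parameters, which therefore stay near their prior
    pow_obs <- vapply(seq_len(n), function(j) mean(Re(obs_vals[j, j, ])),
                      numeric(1))
    pow_prd <- vapply(seq_len(n), function(j) mean(Re(g0[j, j, ])), numeric(1))
    scale <- sqrt(pow_prd / pmax(pow_obs, 1e-300))
    obs_vals <- obs_vals * array(outer(scale, scale), dim(obs_vals))
  }
  # per-frequency weights: inverse mean auto-spectral power of the observed
  # CSD (replicated over the vectorised elements of that frequency), with the
  # power floored at a fraction of its maximum so that bins far below the
  # hemodynamic passband - which carry mostly spectral-estimation noise - are
  # not amplified to parity with the informative bins
  nf <- length(freqs)
  m_el <- n * (n + 1) / 2 + n * (n - 1) / 2
  pow_f <- vapply(seq_len(nf), function(fi)
    mean(Re(diag(obs_vals[, , fi, drop = FALSE][, , 1]))), numeric(1))
  w_floor <- opts$weight_floor %||% 0.1
  pow_f <- pmax(pow_f, w_floor * max(pow_f))
  wvec <- rep(1 / pow_f, each = m_el)

  y <- vec_csd(obs_vals) * wvec
  N <- length(y)

  theta <- mu0
  gth <- vec_csd(g0) * wvec
  e <- y - gth
  # floor the initial residual at a small fraction of the data power so a
  # perfect prior-mean fit cannot drive the precision to infinity
  sse0 <- max(sum(e^2), 1e-8 * max(sum(y^2), 1e-8))
  lambda <- log(N / sse0)
  lambda_h <- lambda  # hyperprior centred on the initial residual estimate
  ld0 <- determinant(P0, logarithm = TRUE)$modulus

  f_energy <- function(e, theta, lambda, logdet_Sq) {
    dth <- theta - mu0
    -0.5 * exp(lambda) * sum(e^2) + 0.5 * N * lambda - 0.5 * N * log(2 * pi) -
      0.5 * drop(dth %*% P0 %*% dth) + 0.5 * ld0 + 0.5 * logdet_Sq +
      -0.5 * (lambda - lambda_h)^2 / lambda_var
  }

  lm <- 1 / 64
  trace <- numeric(0)
  n_small <- 0L
  converged <- FALSE
  best <- NULL   # best accepted iterate: theta, lambda, e, gth, F
  for (it in seq_len(max_iter)) {
    # numerical Jacobian (forward differences) at the current iterate
    J <- matrix(0, N, p)
    for (i in seq_len(p)) {
      th <- theta
      th[i] <- th[i] + diff_step
      gi <- predict_csd_try(th, n, freqs, hrf)
      if (is.null(gi)) {
        th[i] <- theta[i] - diff_step
        gi <- predict_csd_try(th, n, freqs, hrf)
        if (is.null(gi)) next
        J[, i] <- (gth - vec_csd(gi) * wvec) / diff_step
      } else {
        J[, i] <- (vec_csd(gi) * wvec - gth) / diff_step
      }
    }
    JtJ <- crossprod(J)
    f_at <- function(e_, theta_, lambda_) {
      Sq_ <- solve_jit(exp(lambda_) * JtJ + P0)
      list(F = f_energy(e_, theta_, lambda_,
                        determinant(Sq_, logarithm = TRUE)$modulus),
           Sq = Sq_)
    }
    cur <- f_at(e, theta, lambda)
    # EM: Newton updates of the log precision, accepted only on improvement
    for (em in 1:8) {
      r2 <- sum(e^2) + sum((J %*% cur$Sq) * J)
      d1 <- -0.5 * exp(lambda) * r2 + 0.5 * N - (lambda - lambda_h) / lambda_var
      d2 <- -0.5 * exp(lambda) * r2 - 1 / lambda_var
      lam_new <- min(max(lambda - d1 / d2, lambda_h - 8), lambda_h + 8)
      cand <- f_at(e, theta, lam_new)
      if (cand$F > cur$F) {
        lambda <- lam_new
        cur <- cand
      } else break
    }
    F_cur <- cur$F
    logdet_Sq <- determinant(cur$Sq, logarithm = TRUE)$modulus

    # Gauss-Newton step with Levenberg-Marquardt regularisation
    grad <- exp(lambda) * drop(crossprod(J, e)) - drop(P0 %*% (theta - mu0))
    P <- exp(lambda) * JtJ + P0
    accepted <- FALSE
    for (try_i in 1:8) {
      dth <- tryCatch(
        solve_jit(P + lm * mean(diag(P)) * diag(p), grad),
        error = function(err) NULL)
      if (!is.null(dth)) {
        th_new <- theta + dth
        g_new <- predict_csd_try(th_new, n, freqs, hrf)
        if (!is.null(g_new)) {
          gv_new <- vec_csd(g_new) * wvec
          e_new <- y - gv_new
          F_new <- f_energy(e_new, th_new, lambda, logdet_Sq)
          if (is.finite(F_new) && F_new > F_cur) {
            theta <- th_new; gth <- gv_new; e <- e_new
            F_cur <- F_new
            lm <- max(lm / 2, 1e-6)
            accepted <- TRUE
            break
          }
        }
      }
      lm <- lm * 8
    }
    # record only accepted improvements so the trace is monotone; keep the
    # best iterate seen so far
    if (is.null(best) || F_cur > best$F) {
      dF <- if (is.null(best)) Inf else F_cur - best$F
      best <- list(theta = theta, lambda = lambda, F = F_cur)
      trace <- c(trace, F_cur)
    } else {
      # the refreshed linearisation lowered F: revert to the best iterate
      dF <- 0
      theta <- best$theta
      lambda <- best$lambda
      g_best <- predict_csd_try(theta, n, freqs, hrf)
      gth <- vec_csd(g_best) * wvec
      e <- y - gth
      lm <- lm * 4
    }
    n_small <- if (abs(dF) < tol) n_small + 1L else 0L
    if (n_small >= 4L) {
      converged <- TRUE
      break
    }
  }
  theta <- best$theta
  lambda <- best$lambda
  F_cur <- best$F
  g_best <- predict_csd_try(theta, n, freqs, hrf)
  gth <- vec_csd(g_best) * wvec
  Jf <- jac_final(theta, gth, n, freqs, hrf, diff_step, wvec)
  Sq <- solve_jit(exp(lambda) * crossprod(Jf) + P0)
  Sq <- (Sq + t(Sq)) / 2
  structure(list(mean = theta, cov = Sq, F = F_cur, trace = trace,
                 converged = converged, lambda = lambda, scale = scale,
                 n = n, freqs = freqs),
            class = "statedcm_dcm")
}

# final-iterate Jacobian for the posterior covariance
jac_final <- function(theta, gth, n, freqs, hrf, h, wvec = 1) {
  p <- length(theta)
  N <- length(gth)
  J <- matrix(0, N, p)
  for (i in seq_len(p)) {
    th <- theta
    th[i] <- th[i] + h
    gi <- predict_csd_try(th, n, freqs, hrf)
    if (is.null(gi)) {
      th[i] <- theta[i] - h
      gi <- predict_csd_try(th, n, freqs, hrf)
      if (is.null(gi)) next
      J[, i] <- (gth - vec_csd(gi) * wvec) / h
    } else {
      J[, i] <- (vec_csd(gi) * wvec - gth) / h
    }
  }
  J
}

#' @export
print.statedcm_dcm <- function(x, ...) {
  cat(sprintf("spDCM posterior: %d nodes, %d parameters, F = %.2f (%s)\n",
              x$n, length(x$mean), x$F,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Invert spectral DCMs for all sliding windows of all subjects
#'
#' Per window: extract the segment, mean-remove and Hann-taper, fit a MAR of
#' the requested order, evaluate its parametric CSD on the default grid, and
#' invert. Windows are processed independently; failures are collected
#' rather than aborting the batch.
#'
#' @param series_set T x n matrix or list of such (one per subject)
#' @param windows `statedcm_windows`
#' @param tr sampling interval (s)
#' @param priors DCM priors (default `dcm_priors(n)`)
#' @param opts list: `order` (MAR order, 5), `nf` (frequency bins, 32),
#'   `ridge` (MAR ridge, 1e-6), plus options passed to [dcm_invert()]
#' @return object of class `statedcm_dcm_set`: `fits` (list, one per
#'   subject-window in subject-major order; NULL where inversion failed),
#'   `subject`, `window` index vectors, `windows`, `failures`
#' @export
invert_windows <- function(series_set, windows, tr, priors = NULL, opts = list()) {
  if (is.matrix(series_set)) series_set <- list(series_set)
  stopifnot(inherits(windows, "statedcm_windows"))
  order <- opts$order %||% 5
  nf <- opts$nf %||% 32
  ridge <- opts$ridge %||% 1e-6
  n <- ncol(series_set[[1]])
  priors <- priors %||% dcm_priors(n)
  freqs <- csd_freq_grid(windows$window_size * tr, tr, nf)
  fits <- list()
  subj <- integer(0)
  wins <- integer(0)
  failures <- character(0)
  for (j in seq_along(series_set)) {
    y <- as.matrix(series_set[[j]])
    if (nrow(y) < windows$T_len)
      stop(sprintf("series %d shorter than the window specification", j))
    for (i in seq_len(windows$n)) {
      rows <- (windows$starts[i] + 1):(windows$starts[i] + windows$window_size)
      seg <- hann_taper(y[rows, , drop = FALSE])
      fit <- tryCatch({
        mar <- fit_mar(seg, order, delta = tr, ridge = ridge)
        csd <- mar_to_csd(mar, freqs)
        dcm_invert(csd, priors, opts)
      }, error = function(err) {
        failures <<- c(failures, sprintf("subject %d window %d: %s", j, i,
                                         conditionMessage(err)))
        NULL
      })
      fits[[length(fits) + 1L]] <- fit
      subj <- c(subj, j)
      wins <- c(wins, i)
    }
  }
  if (length(failures))
    warning(sprintf("%d window inversion(s) failed; see $failures", length(failures)))
  structure(list(fits = fits, subject = subj, window = wins, windows = windows,
                 failures = failures, tr = tr, n = n),
            class = "statedcm_dcm_set")
}
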