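#' Fit a hidden Markov model with MAR observations
#'
#' EM (Baum-Welch): the E-step is scaled forward-backward; the M-step refits
#' each state's multivariate autoregression by responsibility-weighted
#' regression under a fixed Gaussian prior on the coefficients (maximum a
#' posteriori), with a shared row-stochastic transition matrix. Data from all
#' subjects are concatenated so the states are shared across subjects
#' (forward-backward runs per subject). The best of `n_init` random restarts
#' by final penalised objective is returned. Redundant states empty out
#' during EM (see `w_prior`); low-occupancy states are kept in the model but
#' can be dropped downstream with [retain_states()].
#'
#' @param series_set a T x n matrix or list of such matrices (one per subject),
#'   expected demeaned (z-scoring upstream is typical)
#' @param K maximum number of states
#' @param order MAR order p
#' @param n_init number of random restarts
#' @param seed integer seed
#' @param tr sampling interval in seconds (stored for spectral conversion)
#' @param tol relative log-likelihood convergence tolerance
#' @param max_iter maximum EM iterations per restart
#' @param stage1_iter EM iterations given to every restart before only the
#'   `n_final` most promising runs are continued to convergence
#' @param n_final number of short-listed restarts run to convergence
#' @param select how the returned run is chosen among the converged
#'   restarts: `"objective"` (highest penalised log-likelihood), `"shared"`
#'   (prefer runs by their number of states dominant in every subject,
#'   mirroring the practice of picking the restart whose state sequence is
#'   shared by all subjects; ties broken by the objective), or
#'   `"consensus"` (the run whose argmax state path agrees best, after
#'   optimal label matching, with the other converged runs - a stability
#'   criterion that tracks segmentation quality more reliably than the
#'   objective alone)
#' @param share_threshold per-subject fractional-occupancy threshold used by
#'   `select = "shared"`
#' @param target_shared with `select = "shared"`, prefer runs whose shared
#'   dominant-state count is closest to this number (e.g. the known number of
#'   generative states in a simulation study); `NULL` prefers the largest
#'   count
#' @param init_block length (samples) of the random contiguous blocks used to
#'   initialise the state responsibilities. Block initialisation gives each
#'   state temporally coherent data from the first M-step, which avoids the
#'   symmetric saddle that i.i.d. random responsibilities start from; the
#'   default scales with the series length (about 15 initial segments)
#' @param w_prior precision of a zero-mean Gaussian (MAP) prior on every MAR
#'   coefficient; 0 is plain maximum likelihood. The default mild shrinkage
#'   (10, i.e. prior sd ~0.3 on coefficients of z-scored data) regularises
#'   the ~p n^2 coefficients each state must estimate from a few hundred
#'   samples, which substantially cleans the EM landscape (restarts reach
#'   far better segmentations). Because the prior is fixed and
#'   occupancy-independent, much larger values make states without
#'   distinctive evidence collapse, mirroring the state pruning of
#'   variational treatments
#' @param sigma_nu pseudo-count of an inverse-Wishart-style floor anchoring
#'   each state's innovation covariance to the global signal covariance.
#'   Default 0 (a tiny numerical jitter only): the anchor flattens the
#'   between-state covariance differences that carry much of the state
#'   evidence, so it should be used (together with a large `w_prior`) only
#'   when deliberate state pruning is wanted
#' @return object of class `statedcm_hmm`: `states` (list of per-state MAR
#'   models), `transition` (row-stochastic: entry (i, j) = P(next = j |
#'   current = i)), `initial`, `probs` (per-subject T x K posterior state
#'   probabilities, first `order` rows set to the stationary distribution and
#'   flagged invalid via attribute `valid`), `loglik`, `trace`, `n_init`,
#'   `best_run`, `seed`, `order`, `tr`
#' @export
hmm_fit <- function(series_set, K, order, n_init = 30, seed = 1, tr = 1,
                    tol = 1e-6, max_iter = 500, w_prior = 10, sigma_nu = NULL,
                    stage1_iter = 30, n_final = 3,
                    select = c("objective", "shared", "consensus"),
                    share_threshold = 0.05,
                    target_shared = NULL, init_block = NULL) {
  select <- match.arg(select)
  if (is.matrix(series_set)) series_set <- list(series_set)
  series_set <- lapply(series_set, as.matrix)
  n <- ncol(series_set[[1]])
  stopifnot(K >= 1, order >= 0)
  min_len <- n * order + order + 2
  for (j in seq_along(series_set)) {
    if (nrow(series_set[[j]]) <= min_len)
      stop(sprintf("series %d too short for MAR(%d): need more than %d samples",
                   j, order, min_len))
  }
  dat <- lapply(series_set, function(y) {
    T_len <- nrow(y)
    idx <- (order + 1):T_len
    X <- if (order > 0)
      do.call(cbind, lapply(seq_len(order), function(l) y[idx - l, , drop = FALSE]))
    else matrix(0, length(idx), 0)
    list(Y = y[idx, , drop = FALSE], X = X, T_len = T_len)
  })

  # stage 1: short EM from every random start; stage 2: continue the most
  # promising runs to convergence
  sigma_nu <- sigma_nu %||% 0
  init_block <- init_block %||%
    max(5L, min(100L, as.integer(round(mean(vapply(dat, function(d)
      nrow(d$Y), integer(1))) / 15))))
  stage1 <- vector("list", n_init)
  for (r in seq_len(n_init)) {
    stage1[[r]] <- hmm_em_once(dat, K, n, order, seed = derive_seed(seed, 100L + r),
                               tol = tol, max_iter = min(stage1_iter, max_iter),
                               w_prior = w_prior, sigma_nu = sigma_nu,
                               init_block = init_block)
  }
  lls <- vapply(stage1, `[[`, numeric(1), "loglik")
  shortlist <- order(lls, decreasing = TRUE)[seq_len(min(n_final, n_init))]
  cand <- vector("list", length(shortlist))
  for (ci in seq_along(shortlist)) {
    r <- shortlist[ci]
    fit_r <- hmm_em_once(dat, K, n, order, seed = derive_seed(seed, 100L + r),
                         tol = tol, max_iter = max_iter, w_prior = w_prior,
                         sigma_nu = sigma_nu, warm = stage1[[r]])
    fit_r$trace <- c(stage1[[r]]$trace, fit_r$trace)
    fit_r$best_run <- r
    # states dominant in every subject, from the final responsibilities
    occ <- vapply(fit_r$gamma, colMeans, numeric(K))
    fit_r$n_shared <- sum(apply(matrix(occ, K) > share_threshold, 1, all))
    cand[[ci]] <- fit_r
  }
  score_ll <- vapply(cand, `[[`, numeric(1), "loglik")
  if (select == "shared") {
    ns <- vapply(cand, `[[`, numeric(1), "n_shared")
    key <- if (is.null(target_shared)) -ns else abs(ns - target_shared)
    best <- cand[[order(key, -score_ll)[1]]]
  } else if (select == "consensus" && length(cand) > 2) {
    paths <- lapply(cand, function(f)
      do.call(c, lapply(f$gamma, function(g) max.col(g, ties.method = "first"))))
    nc <- length(paths)
    agree <- matrix(1, nc, nc)
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        agree[i, j] <- agree[j, i] <- path_agreement(paths[[i]], paths[[j]], K)
      }
    }
    cons <- (rowSums(agree) - 1) / (nc - 1)
    best <- cand[[order(-cons, -score_ll)[1]]]
  } else {
    best <- cand[[which.max(score_ll)]]
  }

  pi_stat <- hmm_stationary(best$transition)
  probs <- vector("list", length(dat))
  for (j in seq_along(dat)) {
    T_len <- dat[[j]]$T_len
    s <- matrix(rep(pi_stat, each = T_len), T_len, K)
    s[(order + 1):T_len, ] <- best$gamma[[j]]
    valid <- rep(TRUE, T_len)
    if (order > 0) valid[seq_len(order)] <- FALSE
    attr(s, "valid") <- valid
    probs[[j]] <- s
  }
  states <- lapply(seq_len(K), function(k) {
    W <- if (order > 0) lapply(seq_len(order), function(l) {
      t(best$coef[[k]][((l - 1) * n + 1):(l * n), , drop = FALSE])
    }) else list()
    structure(list(W = W, Sigma = best$Sigma[[k]], order = as.integer(order),
                   delta = tr), class = "statedcm_mar")
  })
  structure(list(states = states, transition = best$transition,
                 initial = best$initial, probs = probs, loglik = best$loglik,
                 trace = best$trace, n_init = n_init, best_run = best$best_run,
                 seed = seed, order = as.integer(order), K = as.integer(K),
                 n = n, tr = tr, n_subjects = length(dat)),
            class = "statedcm_hmm")
}

# single EM run initialised from random contiguous state blocks (or a warm
# start)
hmm_em_once <- function(dat, K, n, order, seed, tol, max_iter, w_prior,
                        sigma_nu, warm = NULL, init_block = 25L) {
  set.seed(seed)
  nS <- length(dat)
  if (is.null(warm)) {
    gamma <- lapply(dat, function(d) {
      Tn <- nrow(d$Y)
      nb <- ceiling(Tn / init_block)
      lab <- rep(sample.int(K, nb, replace = TRUE), each = init_block)[seq_len(Tn)]
      g <- matrix(if (K > 1) 0.1 / (K - 1) else 0, Tn, K)
      g[cbind(seq_len(Tn), lab)] <- if (K > 1) 0.9 else 1
      g
    })
    Theta <- matrix(1 / K, K, K)
    eta <- rep(1 / K, K)
  } else {
    gamma <- warm$gamma
    Theta <- warm$transition
    eta <- warm$initial
  }
  pars <- hmm_mstep_obs(dat, gamma, K, n, w_prior, sigma_nu,
                        if (is.null(warm)) NULL else warm$Sigma)
  obj_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    e <- hmm_estep(dat, pars, Theta, eta, K)
    gamma <- e$gamma
    obj <- e$loglik + hmm_log_prior(pars, w_prior, sigma_nu)
    trace <- c(trace, obj)
    if (obj < obj_old - 1e-6 * max(1, abs(obj_old)))
      warning(sprintf("EM objective decreased at iteration %d", it))
    # transition / initial updates
    Xi <- Reduce(`+`, e$xi)
    rs <- rowSums(Xi)
    Theta <- sweep(Xi + 1e-12, 1, rs + K * 1e-12, "/")
    eta <- Reduce(`+`, lapply(gamma, function(g) g[1, ])) / nS
    eta <- eta / sum(eta)
    pars <- hmm_mstep_obs(dat, gamma, K, n, w_prior, sigma_nu, pars$Sigma)
    if (is.finite(obj_old) && abs(obj - obj_old) < tol * max(1, abs(obj))) {
      obj_old <- obj
      break
    }
    obj_old <- obj
  }
  list(coef = pars$coef, Sigma = pars$Sigma, transition = Theta, initial = eta,
       gamma = gamma, loglik = obj_old, trace = trace)
}

# log prior of the MAP-EM observation parameters (up to a constant)
hmm_log_prior <- function(pars, w_prior, sigma_nu) {
  lp <- 0
  for (k in seq_along(pars$coef)) {
    if (w_prior > 0) lp <- lp - 0.5 * w_prior * sum(pars$coef[[k]]^2)
    if (sigma_nu > 0) {
      S0 <- attr(pars, "S0")
      lp <- lp - 0.5 * sigma_nu *
        (determinant(pars$Sigma[[k]], logarithm = TRUE)$modulus +
           sum(diag(solve(pars$Sigma[[k]], S0))))
    }
  }
  as.numeric(lp)
}

# responsibility-weighted MAP refit of each state MAR (fixed Gaussian prior
# on coefficients; inverse-Wishart-style floor on the innovation covariance).
# With a coefficient prior the exact update couples the target dimensions
# through Sigma, giving a Kronecker-structured normal equation; coordinate
# updates (W given the previous Sigma, then Sigma given the new W) keep the
# penalised EM objective monotone.
hmm_mstep_obs <- function(dat, gamma, K, n, w_prior, sigma_nu,
                          Sigma_prev = NULL) {
  X_all <- do.call(rbind, lapply(dat, `[[`, "X"))
  Y_all <- do.call(rbind, lapply(dat, `[[`, "Y"))
  G_all <- do.call(rbind, gamma)
  S0 <- crossprod(Y_all) / nrow(Y_all)
  p_cols <- ncol(X_all)
  coef <- vector("list", K)
  Sigma <- vector("list", K)
  for (k in seq_len(K)) {
    w <- G_all[, k]
    sw <- sum(w)
    if (p_cols > 0) {
      Xw <- X_all * w
      G <- crossprod(Xw, X_all)
      XtY <- crossprod(Xw, Y_all)
      if (w_prior > 0) {
        Sk <- if (is.null(Sigma_prev)) S0 else Sigma_prev[[k]]
        Si <- solve(Sk)
        A_big <- kronecker(Si, G) + diag(w_prior, p_cols * n)
        coef[[k]] <- matrix(solve(A_big, as.vector(XtY %*% Si)), p_cols, n)
      } else {
        coef[[k]] <- tryCatch(solve(G, XtY), error = function(e) {
          warning("singular weighted MAR regression; falling back to a ridge")
          solve(G + diag(1e-6 * max(mean(diag(G)), 1e-12), p_cols), XtY)
        })
      }
      E <- Y_all - X_all %*% coef[[k]]
    } else {
      coef[[k]] <- matrix(0, 0, n)
      E <- Y_all
    }
    Sk <- (crossprod(E * w, E) + sigma_nu * S0) / (max(sw, n + 1) + sigma_nu)
    Sigma[[k]] <- Sk + diag(1e-8 * mean(diag(S0)), n)
  }
  structure(list(coef = coef, Sigma = Sigma), S0 = S0)
}

# log emission densities, forward-backward with scaling, per subject
hmm_estep <- function(dat, pars, Theta, eta, K) {
  loglik <- 0
  gamma <- vector("list", length(dat))
  xi <- vector("list", length(dat))
  for (j in seq_along(dat)) {
    Y <- dat[[j]]$Y; X <- dat[[j]]$X
    Tn <- nrow(Y); n <- ncol(Y)
    logB <- matrix(0, Tn, K)
    for (k in seq_len(K)) {
      E <- if (ncol(X) > 0) Y - X %*% pars$coef[[k]] else Y
      R <- chol(pars$Sigma[[k]])
      z <- E %*% backsolve(R, diag(n))
      logB[, k] <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + rowSums(z^2))
    }
    mx <- apply(logB, 1, max)
    B <- exp(logB - mx)
    a <- matrix(0, Tn, K); b <- matrix(0, Tn, K); cs <- numeric(Tn)
    a1 <- eta * B[1, ]
    cs[1] <- sum(a1)
    a[1, ] <- a1 / cs[1]
    for (t in 2:Tn) {
      at <- drop(crossprod(Theta, a[t - 1, ])) * B[t, ]
      cs[t] <- sum(at)
      if (cs[t] <= 0 || !is.finite(cs[t])) {
        at <- rep(1 / K, K); cs[t] <- .Machine$double.xmin
      }
      a[t, ] <- at / cs[t]
    }
    b[Tn, ] <- 1
    for (t in (Tn - 1):1) {
      b[t, ] <- drop(Theta %*% (B[t + 1, ] * b[t + 1, ])) / cs[t + 1]
    }
    g <- a * b
    g <- g / rowSums(g)
    # sum_t xi_t in one product: xi_t = (a_t o (B_{t+1} b_{t+1} / c_{t+1})) * Theta
    # (each term already sums to one under the scaled recursions)
    Bb <- (B * b) / cs
    Xi <- crossprod(a[-Tn, , drop = FALSE], Bb[-1, , drop = FALSE]) * Theta
    gamma[[j]] <- g
    xi[[j]] <- Xi
    loglik <- loglik + sum(log(cs)) + sum(mx)
  }
  list(gamma = gamma, xi = xi, loglik = loglik)
}

# stationary distribution of a row-stochastic transition matrix
hmm_stationary <- function(Theta) {
  e <- eigen(t(Theta))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- abs(v)
  v / sum(v)
}

#' @export
print.statedcm_hmm <- function(x, ...) {
  occ <- colMeans(do.call(rbind, lapply(x$probs, function(s)
    colMeans(s[attr(s, "valid"), , drop = FALSE]))))
  cat(sprintf("HMM-MAR fit: K=%d, order=%d, %d subjects, loglik %.2f (best of %d runs)\n",
              x$K, x$order, x$n_subjects, x$loglik, x$n_init))
  cat("group fractional occupancy:", paste(sprintf("%.3f", occ), collapse = " "), "\n")
  invisible(x)
}

#' Per-window state occupation indices
#'
#' The occupation index of state k in window i is the arithmetic mean of the
#' posterior state probability s_k(t) over the samples of the window. Samples
#' flagged invalid (the first `order` samples of a series, which carry no
#' lagged evidence) are excluded from the mean.
#'
#' @param probs a single subject's T x K state-probability matrix (an element
#'   of `fit$probs`) carrying a logical `valid` attribute
#' @param windows `statedcm_windows`
#' @return W x K occupation matrix (rows sum to 1)
#' @export
occupation_index <- function(probs, windows) {
  stopifnot(inherits(windows, "statedcm_windows"))
  probs <- as.matrix(probs)
  valid <- attr(probs, "valid") %||% rep(TRUE, nrow(probs))
  u <- matrix(0, windows$n, ncol(probs))
  for (i in seq_len(windows$n)) {
    rows <- (windows$starts[i] + 1):(windows$starts[i] + windows$window_size)
    if (max(rows) > nrow(probs))
      stop(sprintf("window %d extends beyond the series (%d > %d samples)",
                   i, max(rows), nrow(probs)))
    rows <- rows[valid[rows]]
    if (!length(rows)) stop(sprintf("window %d contains no valid samples", i))
    u[i, ] <- colMeans(probs[rows, , drop = FALSE])
  }
  u
}

#' Parametric cross-spectral density of one HMM state
#'
#' @param fit `statedcm_hmm`
#' @param k state index
#' @param freqs frequency grid in Hz
#' @return `statedcm_csd` of state k's MAR model
#' @export
state_spectra <- function(fit, k, freqs) {
  stopifnot(inherits(fit, "statedcm_hmm"), k >= 1, k <= fit$K)
  mar_to_csd(fit$states[[k]], freqs)
}

#' Summary statistics of a state-probability series
#'
#' Fractional occupancy (column means of the valid rows), the empirical
#' transition-probability matrix of the argmax state path, occupancy entropy
#' in nats, and the set of dominant states.
#'
#' @param probs T x K state-probability matrix with a `valid` attribute
#' @param dominant_threshold fractional-occupancy threshold for the dominant set
#' @return list with class `statedcm_state_stats`
#' @export
summary_stats <- function(probs, dominant_threshold = 0.05) {
  probs <- as.matrix(probs)
  valid <- attr(probs, "valid") %||% rep(TRUE, nrow(probs))
  s <- probs[valid, , drop = FALSE]
  K <- ncol(s)
  occ <- colMeans(s)
  path <- max.col(s, ties.method = "first")
  counts <- matrix(0, K, K)
  if (length(path) > 1) {
    for (t in seq_len(length(path) - 1)) {
      counts[path[t], path[t + 1]] <- counts[path[t], path[t + 1]] + 1
    }
  }
  rs <- rowSums(counts)
  trans <- counts
  nz <- rs > 0
  trans[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  trans[!nz, ] <- diag(K)[!nz, , drop = FALSE]
  pos <- occ[occ > 0]
  entropy <- -sum(pos * log(pos))
  structure(list(occupancy = occ, transition_counts = counts,
                 transition = trans, entropy = entropy,
                 dominant = which(occ > dominant_threshold)),
            class = "statedcm_state_stats")
}

#' States dominant in every subject
#'
#' Mirrors the retention rule of keeping only states shared by all subjects:
#' a state is retained when its fractional occupancy exceeds `threshold` in
#' every subject.
#'
#' @param fit `statedcm_hmm`
#' @param threshold per-subject fractional-occupancy threshold
#' @return integer vector of retained state indices
#' @export
retain_states <- function(fit, threshold = 0.05) {
  stopifnot(inherits(fit, "statedcm_hmm"))
  occ <- vapply(fit$probs, function(s)
    colMeans(s[attr(s, "valid"), , drop = FALSE]), numeric(fit$K))
  which(apply(occ > threshold, 1, all))
}

#' Match state labels between two HMM fits
#'
#' States are compared by the Frobenius distance between their parametric
#' cross-spectral densities on a common frequency grid; the minimum-cost
#' assignment (exhaustive for the small K used here) gives the permutation.
#'
#' @param fit_a,fit_b `statedcm_hmm` fits with equal K, order, and node count
#' @param freqs frequency grid (defaults to 32 bins up to min(0.25, Nyquist))
#' @return integer permutation `p`: state i of `fit_a` matches state `p[i]`
#'   of `fit_b`
#' @export
match_states <- function(fit_a, fit_b, freqs = NULL) {
  stopifnot(inherits(fit_a, "statedcm_hmm"), inherits(fit_b, "statedcm_hmm"))
  if (fit_a$n != fit_b$n || fit_a$order != fit_b$order || fit_a$K != fit_b$K)
    stop("fits must share node count, order, and K")
  if (is.null(freqs)) {
    freqs <- seq(0.01, min(0.25, 0.5 / fit_a$tr), length.out = 32)
  }
  Ga <- lapply(seq_len(fit_a$K), function(k) state_spectra(fit_a, k, freqs)$values)
  Gb <- lapply(seq_len(fit_b$K), function(k) state_spectra(fit_b, k, freqs)$values)
  cost <- matrix(0, fit_a$K, fit_b$K)
  for (i in seq_len(fit_a$K)) {
    for (j in seq_len(fit_b$K)) {
      cost[i, j] <- sqrt(sum(Mod(Ga[[i]] - Gb[[j]])^2))
    }
  }
  min_cost_assignment(cost)
}


# fraction of samples on which two hard state paths agree, maximised over
# label permutations (K <= 8)
path_agreement <- function(p1, p2, K) {
  tab <- table(factor(p1, seq_len(K)), factor(p2, seq_len(K)))
  best <- 0
  for (pm in perm_all(K)) best <- max(best, sum(tab[cbind(seq_len(K), pm)]))
  best / length(p1)
}
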