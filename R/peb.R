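#' Build the state-regressor design matrix
#'
#' Columns are a constant (baseline) followed by the occupation indices of
#' the retained states, one row per window (concatenate rows across subjects
#' for fixed-effects use). Regressors are not mean-centred, so the constant
#' column models the zero-occupation baseline connectivity.
#'
#' @param u W x K occupation matrix
#' @param retained_states state indices to include as regressors
#' @param include_constant prepend a constant column
#' @return design matrix with column names `const`, `S<k>`, ...
#' @export
build_design <- function(u, retained_states, include_constant = TRUE) {

  u <- as.matrix(u)
  if (any(retained_states < 1 | retained_states > ncol(u)))
    stop("retained states outside the columns of the occupation matrix")
  X <- u[, retained_states, drop = FALSE]
  colnames(X) <- paste0("S", retained_states)
  if (include_constant) {
    X <- cbind(const = 1, X)
    if (length(retained_states) == ncol(u) &&
        max(abs(rowSums(u) - 1)) < 1e-8) {
      warning("constant plus all states is rank deficient (occupations sum to 1); drop one state column")
    }
  }
  if (any(!is.finite(X))) stop("design matrix must be finite")
  if (any(colSums(abs(X)) == 0)) stop("design matrix contains an all-zero column")
  X
}

# extract first-level Gaussian units (mean + covariance over the A
# parameters) from a set of window DCM posteriors
peb_units <- function(dcm_set, param_idx = NULL) {
  stopifnot(inherits(dcm_set, "statedcm_dcm_set"))
  keep <- !vapply(dcm_set$fits, is.null, logical(1))
  fits <- dcm_set$fits[keep]
  if (!length(fits)) stop("no successful first-level inversions")
  n <- fits[[1]]$n
  if (is.null(param_idx)) param_idx <- as.vector(dcm_A_param_index(n))
  units <- lapply(fits, function(f)
    list(mean = f$mean[param_idx],
         cov = f$cov[param_idx, param_idx, drop = FALSE]))
  attr(units, "keep") <- keep
  attr(units, "param_names") <- names(fits[[1]]$mean)[param_idx]
  units
}

#' Parametric-empirical-Bayes fit over first-level posteriors
#'
#' Hierarchical Bayesian GLM: each unit's first-level posterior (mean m_i,
#' covariance V_i) is treated as a Gaussian likelihood over its parameters,
#' generated as m_i ~ N(sum_r x_ir beta_r, V_i + Sigma_b) with between-unit
#' covariance Sigma_b = exp(gamma) I and prior beta ~ N(0, prior_var I). For
#' a given gamma the posterior over beta and the log evidence are closed
#' form; gamma is estimated by maximising the free energy (log evidence plus
#' its log prior), accepting only improvements so the recorded trace is
#' non-decreasing.
#'
#' @param units a `statedcm_dcm_set` (its A parameters are used) or a list of
#'   `list(mean, cov)` Gaussian units
#' @param X design matrix, one row per unit
#' @param prior_var prior variance of each second-level effect
#' @param gamma_prior `c(mean, var)` Gaussian prior on the log between-unit
#'   variance
#' @param fix_gamma fix the log between-unit variance instead of estimating
#'   it (`-Inf` gives the zero-between-variance generalised-least-squares
#'   limit)
#' @param level tag recorded on the result (`"subject"` or `"group"`)
#' @return object of class `statedcm_peb`: `beta` (p x R matrix of posterior
#'   means, one column per regressor), `beta_vec`, `cov` (Rp x Rp posterior
#'   covariance, regressor-major blocks), `gamma`, `F`, `trace`,
#'   `regressors`, `param_names`, `W`, `prior`
#' @export
peb_fit <- function(units, X, prior_var = 1, gamma_prior = c(-2, 4),
                    fix_gamma = NULL, level = "subject") {
  if (inherits(units, "statedcm_dcm_set")) {
    keep_set <- units
    units <- peb_units(units)
    keep <- attr(units, "keep")
    if (!all(keep)) X <- X[keep, , drop = FALSE]
  }
  X <- as.matrix(X)
  W <- length(units)
  if (nrow(X) != W)
    stop(sprintf("design has %d rows but there are %d first-level units", nrow(X), W))
  p <- length(units[[1]]$mean)
  R <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(R))
  pnames <- attr(units, "param_names") %||% names(units[[1]]$mean) %||%
    paste0("p", seq_len(p))

  evidence <- function(gamma) {
    Sb <- diag(exp(gamma), p)
    Pb <- diag(1 / prior_var, R * p)
    g <- numeric(R * p)
    quad <- 0
    ldet <- 0
    for (i in seq_len(W)) {
      Di <- solve(units[[i]]$cov + Sb)
      Di <- (Di + t(Di)) / 2
      ldet <- ldet + determinant(Di, logarithm = TRUE)$modulus
      m <- units[[i]]$mean
      quad <- quad + drop(m %*% Di %*% m)
      Pb <- Pb + kronecker(tcrossprod(X[i, ]), Di)
      g <- g + kronecker(X[i, ], drop(Di %*% m))
    }
    Pb <- (Pb + t(Pb)) / 2
    cb <- chol(Pb)
    bhat <- backsolve(cb, forwardsolve(t(cb), g))
    logp <- -0.5 * (W * p) * log(2 * pi) + 0.5 * ldet -
      0.5 * (R * p) * log(prior_var) - sum(log(diag(cb))) -
      0.5 * quad + 0.5 * sum(g * bhat)
    list(F = as.numeric(logp), bhat = bhat, Pb = Pb)
  }

  if (!is.null(fix_gamma)) {
    gamma <- fix_gamma
    if (is.infinite(gamma) && gamma < 0) {
      # zero between-unit variance: evaluate at a numerically tiny value
      gamma <- -30
    }
    ev <- evidence(gamma)
    F_val <- ev$F
    trace <- F_val
  } else {
    obj <- function(g) evidence(g)$F +
      stats::dnorm(g, gamma_prior[1], sqrt(gamma_prior[2]), log = TRUE)
    F_init <- obj(gamma_prior[1])
    opt <- stats::optimize(obj, interval = c(-12, 6), maximum = TRUE, tol = 1e-4)
    if (opt$objective > F_init) {
      gamma <- opt$maximum
      F_val <- opt$objective
      trace <- c(F_init, F_val)
    } else {
      gamma <- gamma_prior[1]
      F_val <- F_init
      trace <- F_init
    }
    ev <- evidence(gamma)
  }
  Sigma_post <- solve(ev$Pb)
  Sigma_post <- (Sigma_post + t(Sigma_post)) / 2
  beta <- matrix(ev$bhat, p, R)
  rownames(beta) <- pnames
  colnames(beta) <- colnames(X)
  structure(list(beta = beta, beta_vec = ev$bhat, cov = Sigma_post,
                 gamma = gamma, F = F_val, trace = trace,
                 regressors = colnames(X), param_names = pnames,
                 W = W, X = X, level = level,
                 prior = list(mean = numeric(R * p),
                              cov = diag(prior_var, R * p))),
            class = "statedcm_peb")
}

#' @export
print.statedcm_peb <- function(x, ...) {
  cat(sprintf("PEB (%s level): %d units, %d parameters x %d regressors (%s), F = %.2f\n",
              x$level, x$W, length(x$param_names), length(x$regressors),
              paste(x$regressors, collapse = ", "), x$F))
  invisible(x)
}

#' Bayesian model reduction for Gaussian posteriors
#'
#' Analytic re-evaluation of the log evidence and posterior under a reduced
#' prior, from the full posterior and both priors, without refitting:
#' with precisions Pq (posterior), P0 (full prior), P1 (reduced prior),
#' Pp = Pq + P1 - P0 and h = Pq mq + P1 m1 - P0 m0, the reduced posterior is
#' N(Pp^-1 h, Pp^-1) and the change in log evidence is
#' dF = (log|Pq| + log|P1| - log|P0| - log|Pp|)/2
#'      + (h' Pp^-1 h - mq' Pq mq - m1' P1 m1 + m0' P0 m0)/2.
#'
#' @param posterior list with `mean`, `cov` (e.g. a `statedcm_peb` via its
#'   `beta_vec`/`cov`, or a `statedcm_dcm`)
#' @param prior full prior: list with `mean`, `cov`
#' @param reduced_prior reduced prior: list with `mean`, `cov`
#' @return list: `dF` (log evidence of reduced minus full model), `mean`,
#'   `cov` of the reduced posterior
#' @export
bmr <- function(posterior, prior, reduced_prior) {
  if (inherits(posterior, "statedcm_peb"))
    posterior <- list(mean = posterior$beta_vec, cov = posterior$cov)
  mq <- posterior$mean; m0 <- prior$mean; m1 <- reduced_prior$mean
  Pq <- solve(posterior$cov); P0 <- solve(prior$cov); P1 <- solve(reduced_prior$cov)
  Pp <- Pq + P1 - P0
  ev <- eigen((Pp + t(Pp)) / 2, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("reduced prior makes the reduced posterior improper (non-positive precision)")
  h <- drop(Pq %*% mq + P1 %*% m1 - P0 %*% m0)
  mp <- solve(Pp, h)
  ld <- function(M) determinant(M, logarithm = TRUE)$modulus
  dF <- 0.5 * (ld(Pq) + ld(P1) - ld(P0) - ld(Pp)) +
    0.5 * (sum(h * mp) - drop(mq %*% Pq %*% mq) - drop(m1 %*% P1 %*% m1) +
             drop(m0 %*% P0 %*% m0))
  Sp <- solve(Pp)
  list(dF = as.numeric(dF), mean = drop(mp), cov = (Sp + t(Sp)) / 2)
}

#' Posterior of the reconstructed A matrix for one state
#'
#' The effective connectivity in state k is the baseline plus the state
#' component, A0 + A_(k); the posterior of each entry is the corresponding
#' linear contrast of the second-level effects with covariance propagated
#' from the full second-level posterior. Diagonal entries live in
#' self-connection log-scaling space; they (and their credible limits) are
#' mapped through the monotone transform -0.5 exp().
#'
#' @param peb `statedcm_peb` fitted over the A parameters
#' @param state regressor name (e.g. `"S2"`) or column index of the state;
#'   0 returns the baseline alone (for a state whose effect is absorbed into
#'   the constant when the occupation regressors are compositional)
#' @param n number of nodes
#' @param ci two-sided credible level for the reported interval
#' @return list: `A` (posterior mean matrix, diagonal transformed), `sd`
#'   (posterior sd in parameter space), `lo`, `hi` (credible limits,
#'   diagonal transformed), `theta` (untransformed mean matrix)
#' @export
reconstruct_state_A <- function(peb, state, n, ci = 0.95) {
  stopifnot(inherits(peb, "statedcm_peb"))
  R <- length(peb$regressors)
  p <- length(peb$param_names)
  if (is.character(state)) state <- match(state, peb$regressors)
  if (is.na(state) || state < 0 || state > R) stop("unknown state regressor")
  cvec <- numeric(R)
  ic <- match("const", peb$regressors)
  if (!is.na(ic)) cvec[ic] <- 1
  if (state != 0) cvec[state] <- 1
  mean_c <- drop(peb$beta %*% cvec)
  var_c <- numeric(p)
  for (jp in seq_len(p)) {
    idx <- (seq_len(R) - 1) * p + jp
    var_c[jp] <- drop(cvec %*% peb$cov[idx, idx] %*% cvec)
  }
  sd_c <- sqrt(pmax(var_c, 0))
  z <- qnorm(1 - (1 - ci) / 2)
  theta_m <- matrix(mean_c, n, n)
  lo_t <- matrix(mean_c - z * sd_c, n, n)
  hi_t <- matrix(mean_c + z * sd_c, n, n)
  A <- theta_m; lo <- lo_t; hi <- hi_t
  di <- cbind(seq_len(n), seq_len(n))
  A[di] <- self_connection_value(theta_m[di])
  # -0.5 exp() is monotone decreasing in theta, so the limits swap
  lo[di] <- self_connection_value(hi_t[di])
  hi[di] <- self_connection_value(lo_t[di])
  list(A = A, sd = matrix(sd_c, n, n), lo = lo, hi = hi, theta = theta_m)
}

#' Threshold second-level effects at 95 percent posterior confidence
#'
#' An effect survives when the posterior probability that it has the sign of
#' its mean exceeds `level` (strictly), i.e. |mean| > z * sd with
#' z = qnorm(level). Effects are reshaped into the baseline matrix A0 and
#' one matrix per state regressor.
#'
#' @param peb `statedcm_peb` fitted over the A parameters
#' @param n number of nodes
#' @param level one-sided posterior confidence (default 0.95)
#' @return object of class `statedcm_state_ec`: per regressor a list with
#'   `mean`, `sd`, `mask` matrices (diagonal entries in self-connection
#'   log-scaling space)
#' @export
threshold_95 <- function(peb, n, level = 0.95) {
  stopifnot(inherits(peb, "statedcm_peb"))
  p <- length(peb$param_names)
  R <- length(peb$regressors)
  z <- qnorm(level)
  out <- vector("list", R)
  names(out) <- ifelse(peb$regressors == "const", "A0", peb$regressors)
  for (r in seq_len(R)) {
    idx <- (r - 1) * p + seq_len(p)
    m <- peb$beta[, r]
    s <- sqrt(pmax(diag(peb$cov)[idx], 0))
    if (any(s == 0 & m != 0))
      warning("zero posterior sd treated as infinite confidence")
    mask <- abs(m) > z * s
    out[[r]] <- list(mean = matrix(m, n, n), sd = matrix(s, n, n),
                     mask = matrix(mask, n, n))
  }
  structure(out, class = "statedcm_state_ec", n = n, level = level)
}

#' Select window size and overlap by dynamic-vs-stationary log Bayes factor
#'
#' For each (window size, overlap) pair, windowed spectral DCMs are inverted
#' (fixed effects: all subjects' windows concatenated) and two PEBs are
#' compared on the same first-level posteriors: one with the state occupation
#' regressors plus constant (dynamic) and one with the constant only
#' (stationary). The log Bayes factor is the free-energy difference; the
#' pair with the largest log BF is selected.
#'
#' @param series_set list of subject series (T x n), demeaned
#' @param hmm `statedcm_hmm` fitted to the same series
#' @param retained retained state indices (regressor set)
#' @param tr sampling interval (s)
#' @param pairs list of `c(window_size, overlap)` pairs; the default grid
#'   uses steps of 15 or 30 samples
#' @param priors,opts passed to [invert_windows()]
#' @return data.frame with columns `window`, `overlap`, `n_windows`,
#'   `F_dynamic`, `F_stationary`, `logbf`; attribute `best` holds the
#'   selected pair
#' @export
window_selection <- function(series_set, hmm, retained, tr,
                             pairs = list(c(45, 30), c(45, 15), c(60, 45),
                                          c(60, 30), c(75, 60), c(75, 45),
                                          c(90, 75), c(90, 60), c(120, 105),
                                          c(120, 90), c(150, 135), c(150, 120)),
                             priors = NULL, opts = list()) {
  if (is.matrix(series_set)) series_set <- list(series_set)
  T_len <- min(vapply(series_set, nrow, integer(1)))
  rows <- list()
  for (pr in pairs) {
    ws <- pr[1]; ov <- pr[2]
    if (ws > T_len) {
      warning(sprintf("pair (%d, %d) skipped: window exceeds series", ws, ov))
      next
    }
    wn <- make_windows(T_len, ws, ov)
    if (wn$n < 3) {
      warning(sprintf("pair (%d, %d) skipped: only %d window(s)", ws, ov, wn$n))
      next
    }
    u_all <- do.call(rbind, lapply(hmm$probs, occupation_index, windows = wn))
    dcms <- invert_windows(series_set, wn, tr, priors, opts)
    X_dyn <- build_design(u_all, drop_redundant_state(u_all, retained))
    X_stat <- matrix(1, nrow(u_all), 1, dimnames = list(NULL, "const"))
    f_dyn <- peb_fit(dcms, X_dyn)$F
    f_stat <- peb_fit(dcms, X_stat)$F
    rows[[length(rows) + 1L]] <- data.frame(window = ws, overlap = ov,
                                            n_windows = wn$n,
                                            F_dynamic = f_dyn,
                                            F_stationary = f_stat,
                                            logbf = f_dyn - f_stat)
  }
  if (!length(rows)) stop("no valid window/overlap pairs")
  tab <- do.call(rbind, rows)
  best <- tab[which.max(tab$logbf), c("window", "overlap")]
  attr(tab, "best") <- c(window = best$window, overlap = best$overlap)
  tab
}

#' Group-level state-dependent effective connectivity
#'
#' Fixed-effects mode (default): per group, one PEB over the group's
#' concatenated window DCMs with the state design; then a second PEB across
#' the group-level posteriors with the group design X2 (default
#' `[1 1; 1 -1]`: common effect and group difference). Random-effects mode:
#' one PEB per subject, then a PEB of the subject posteriors with one X2 row
#' per subject.
#'
#' @param dcm_sets list of `statedcm_dcm_set` objects; fixed mode: one per
#'   group; random mode: one per subject
#' @param designs list of first-level design matrices aligned with
#'   `dcm_sets` (rows = windows)
#' @param X2 second-level design: fixed mode 2 x 2 (rows = groups), random
#'   mode one row per subject
#' @param mode `"fixed"` or `"random"`
#' @param prior_var second-level prior variance
#' @return list with class `statedcm_group`: `level2` (per-group or
#'   per-subject PEBs), `level3` (the group PEB; regressors `common`,
#'   `diff`), `mode`
#' @export
group_analysis <- function(dcm_sets, designs,
                           X2 = matrix(c(1, 1, 1, -1), 2, 2, byrow = TRUE,
                                       dimnames = list(NULL, c("common", "diff"))),
                           mode = c("fixed", "random"), prior_var = 1) {
  mode <- match.arg(mode)
  stopifnot(length(dcm_sets) == length(designs))
  pebs <- mapply(function(d, X) peb_fit(d, X, prior_var = prior_var),
                 dcm_sets, designs, SIMPLIFY = FALSE)
  regs <- lapply(pebs, function(p) p$regressors)
  if (length(unique(vapply(regs, paste, character(1), collapse = ","))) > 1)
    stop("units carry different retained-state sets; harmonise states before the group analysis")
  units <- lapply(pebs, function(p) list(mean = p$beta_vec, cov = p$cov))
  attr(units, "param_names") <- as.vector(outer(pebs[[1]]$param_names,
                                                pebs[[1]]$regressors,
                                                function(a, b) paste(b, a, sep = ":")))
  X2 <- as.matrix(X2)
  if (is.null(colnames(X2))) colnames(X2) <- c("common", "diff")[seq_len(ncol(X2))]
  if (nrow(X2) != length(units))
    stop(sprintf("X2 has %d rows but there are %d second-level units",
                 nrow(X2), length(units)))
  # a saturated group design (e.g. two groups, common + difference) leaves no
  # residual degrees of freedom: fix the between-unit variance at zero and let
  # the lower-level posterior covariances carry the uncertainty
  fg <- if (nrow(X2) <= ncol(X2)) -Inf else NULL
  level3 <- peb_fit(units, X2, prior_var = prior_var, level = "group",
                    fix_gamma = fg)
  structure(list(level2 = pebs, level3 = level3, mode = mode, X2 = X2),
            class = "statedcm_group")
}


# when the retained states cover every state and occupations sum to one, the
# constant plus all occupation columns are collinear; drop the last retained
# state (its effect is absorbed into the baseline)
drop_redundant_state <- function(u, retained) {
  if (length(retained) == ncol(u) && length(retained) > 1 &&
      max(abs(rowSums(u) - 1)) < 1e-8) {
    retained[-length(retained)]
  } else {
    retained
  }
}
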