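test_that("design matrix encodes occupation regressors with a baseline", {
  u <- rbind(c(0, 0, 1), c(1 / 3, 1 / 3, 1 / 3))
  X <- suppressWarnings(build_design(u, retained_states = c(1, 2, 3)))
  expect_equal(colnames(X), c("const", "S1", "S2", "S3"))
  expect_equal(X[1, ], c(const = 1, S1 = 0, S2 = 0, S3 = 1))
  expect_equal(X[2, ], c(const = 1, S1 = 1 / 3, S2 = 1 / 3, S3 = 1 / 3))
  expect_error(build_design(u, 4), "outside")
})

test_that("rank deficiency of constant plus all states is flagged", {
  set.seed(1)
  u <- matrix(rexp(30), 10, 3)
  u <- u / rowSums(u)
  expect_warning(build_design(u, 1:3), "rank deficient")
  expect_silent(X <- build_design(u, 1:2))
})

test_that("PEB with a constant design averages identical units exactly", {
  m <- c(0.4, -0.2, 0.1)
  V <- diag(0.01, 3)
  units <- replicate(8, list(mean = m, cov = V), simplify = FALSE)
  X <- matrix(1, 8, 1, dimnames = list(NULL, "const"))
  fit <- peb_fit(units, X, prior_var = 1e4, fix_gamma = -Inf)
  expect_equal(drop(fit$beta), m, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("zero between-unit variance recovers generalised least squares", {
  set.seed(7)
  p <- 3; W <- 12
  X <- cbind(1, rnorm(W))
  B_true <- matrix(rnorm(2 * p), p, 2)
  units <- vector("list", W)
  Vs <- list()
  for (i in seq_len(W)) {
    Vi <- diag(runif(p, 0.05, 0.5))       # heteroscedastic first levels
    Vs[[i]] <- Vi
    units[[i]] <- list(mean = drop(B_true %*% X[i, ]) + rnorm(p, sd = 0.1),
                       cov = Vi)
  }
  fit <- peb_fit(units, X, prior_var = 1e8, fix_gamma = -Inf)
  # closed-form GLS oracle on the stacked system
  XtX <- matrix(0, 2 * p, 2 * p)
  Xty <- numeric(2 * p)
  for (i in seq_len(W)) {
    Di <- solve(Vs[[i]])
    XtX <- XtX + kronecker(tcrossprod(X[i, ]), Di)
    Xty <- Xty + kronecker(X[i, ], drop(Di %*% units[[i]]$mean))
  }
  oracle <- solve(XtX, Xty)
  expect_equal(fit$beta_vec, oracle, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("PEB recovers planted linear-Gaussian effects within 2 posterior sd", {
  set.seed(8)
  p <- 4; W <- 40
  X <- cbind(const = 1, s = runif(W))
  B_true <- matrix(c(0.5, -0.3, 0.2, 0, 0.4, 0.1, -0.5, 0.3), p, 2)
  units <- lapply(seq_len(W), function(i)
    list(mean = drop(B_true %*% X[i, ]) + rnorm(p, sd = 0.03),
         cov = diag(0.001, p)))
  fit <- peb_fit(units, X)
  sd_b <- sqrt(diag(fit$cov))
  expect_true(all(abs(fit$beta_vec - as.vector(B_true)) <= 2 * sd_b + 0.05))
  expect_true(all(diff(fit$trace) >= -1e-9))
})

test_that("Bayesian model reduction is exact against a quadrature oracle", {
  # identity reduction changes nothing
  post <- list(mean = c(0.3, -0.1), cov = diag(c(0.05, 0.2)))
  pri <- list(mean = c(0, 0), cov = diag(c(1, 1)))
  id <- bmr(post, pri, pri)
  expect_equal(id$dF, 0, tolerance = 1e-12)
  expect_equal(id$mean, post$mean, tolerance = 1e-12)
  expect_equal(id$cov, post$cov, tolerance = 1e-12)

  # 1-D conjugate example: dF equals the numerically integrated evidence ratio
  v_lik <- 0.3; m_lik <- 0.7          # implied Gaussian likelihood
  pri0 <- list(mean = 0, cov = matrix(1, 1, 1))
  pri1 <- list(mean = 0, cov = matrix(0.05, 1, 1))
  post_prec <- 1 / v_lik + 1 / pri0$cov[1]
  post0 <- list(mean = (m_lik / v_lik) / post_prec,
                cov = matrix(1 / post_prec, 1, 1))
  red <- bmr(post0, pri0, pri1)
  lik <- function(th) dnorm(m_lik, th, sqrt(v_lik))
  ev0 <- integrate(function(th) lik(th) * dnorm(th, 0, 1), -10, 10)$value
  ev1 <- integrate(function(th) lik(th) * dnorm(th, 0, sqrt(0.05)), -10, 10)$value
  expect_equal(red$dF, log(ev1 / ev0), tolerance = 1e-6)

  # shrinking an uninformed parameter is almost free
  post2 <- list(mean = c(0.5, 0.001), cov = diag(c(0.01, 0.999)))
  pri_full <- list(mean = c(0, 0), cov = diag(c(1, 1)))
  pri_red <- list(mean = c(0, 0), cov = diag(c(1, 1e-4)))
  red2 <- bmr(post2, pri_full, pri_red)
  expect_lt(abs(red2$dF), 0.1)

  # an improper reduction is refused
  pri_bad <- list(mean = c(0, 0), cov = diag(c(25, 25)))
  post_tight <- list(mean = c(0, 0), cov = diag(c(0.9999, 0.9999)))
  expect_error(bmr(post_tight, list(mean = c(0, 0), cov = diag(c(1e-4, 1e-4))),
                   pri_bad), "improper")
})

test_that("95 percent posterior-confidence thresholding follows the sign rule", {
  beta <- matrix(c(0, 3, qnorm(0.95), -2.5), 4, 1)
  peb <- structure(list(beta = beta, beta_vec = drop(beta),
                        cov = diag(c(1, 1, 1, 1)),
                        regressors = "const",
                        param_names = paste0("p", 1:4), W = 10,
                        level = "subject"),
                   class = "statedcm_peb")
  ec <- threshold_95(peb, n = 2)
  expect_false(ec$A0$mask[1, 1])   # mean 0, sd 1
  expect_true(ec$A0$mask[2, 1])    # mean 3, sd 1
  expect_false(ec$A0$mask[1, 2])   # exact boundary excluded (strict rule)
  expect_true(ec$A0$mask[2, 2])    # mean -2.5: sign confidence either way
})

test_that("reconstructed state matrices equal design predictions at pure-state rows", {
  set.seed(10)
  n <- 2; p <- n * n
  A0 <- c(0.1, -0.2, 0.3, 0.05)
  A1 <- c(0.2, 0.1, -0.1, 0.15)
  X <- cbind(const = 1, S1 = c(rep(1, 10), rep(0, 10)))
  units <- lapply(seq_len(20), function(i)
    list(mean = A0 + X[i, 2] * A1 + rnorm(p, sd = 0.01),
         cov = diag(1e-4, p)))
  fit <- peb_fit(units, X)
  rec <- reconstruct_state_A(fit, "S1", n)
  pred_theta <- matrix(A0 + A1, n, n)
  expect_equal(rec$theta, pred_theta, tolerance = 0.05)
  # diagonal reported through the self-connection transform
  expect_equal(diag(rec$A), -0.5 * exp(diag(rec$theta)))
  expect_true(all(rec$lo <= rec$A & rec$A <= rec$hi))
})

test_that("log Bayes factor separates switching from stationary dynamics", {
  set.seed(12)
  p <- 4; W <- 30
  occ <- runif(W)
  X_units_state <- cbind(1, occ)
  B <- matrix(c(0.3, -0.2, 0.1, 0.4, 0.5, -0.4, 0.3, -0.3), p, 2)
  # units whose means genuinely follow the state regressor
  units_dyn <- lapply(seq_len(W), function(i)
    list(mean = drop(B %*% X_units_state[i, ]) + rnorm(p, sd = 0.02),
         cov = diag(5e-4, p)))
  # stationary units ignore the regressor
  units_stat <- lapply(seq_len(W), function(i)
    list(mean = B[, 1] + rnorm(p, sd = 0.02), cov = diag(5e-4, p)))
  X_dyn <- cbind(const = 1, S1 = occ)
  X_stat <- matrix(1, W, 1, dimnames = list(NULL, "const"))
  bf_dyn <- peb_fit(units_dyn, X_dyn)$F - peb_fit(units_dyn, X_stat)$F
  bf_stat <- peb_fit(units_stat, X_dyn)$F - peb_fit(units_stat, X_stat)$F
  expect_gt(bf_dyn, 3)
  expect_lt(bf_stat, 3)
})

test_that("group analysis decorrelates common and difference effects", {
  X2 <- matrix(c(1, 1, 1, -1), 2, 2, byrow = TRUE)
  expect_equal(sum(X2[, 1] * X2[, 2]), 0)

  # two identical synthetic groups: difference interval covers zero
  set.seed(14)
  p <- 4
  mk_units <- function(seed) {
    set.seed(seed)
    lapply(1:12, function(i) list(mean = c(0.4, -0.1, 0.2, 0) + rnorm(p, sd = 0.05),
                                  cov = diag(0.002, p)))
  }
  g1 <- peb_fit(mk_units(1), matrix(1, 12, 1, dimnames = list(NULL, "const")))
  g2 <- peb_fit(mk_units(2), matrix(1, 12, 1, dimnames = list(NULL, "const")))
  units3 <- list(list(mean = g1$beta_vec, cov = g1$cov),
                 list(mean = g2$beta_vec, cov = g2$cov))
  # saturated two-unit design: zero between-unit variance, as in the group
  # contrast of group_analysis()
  fit3 <- peb_fit(units3, X2, level = "group", fix_gamma = -Inf)
  diff_idx <- p + seq_len(p)
  d_m <- fit3$beta_vec[diff_idx]
  d_sd <- sqrt(diag(fit3$cov)[diff_idx])
  expect_true(all(abs(d_m) <= 1.96 * d_sd))

  # a planted shift in one entry is flagged in the difference map
  units_b <- mk_units(3)
  units_b <- lapply(units_b, function(u) { u$mean[2] <- u$mean[2] + 0.6; u })
  g2b <- peb_fit(units_b, matrix(1, 12, 1, dimnames = list(NULL, "const")))
  units3b <- list(list(mean = g1$beta_vec, cov = g1$cov),
                  list(mean = g2b$beta_vec, cov = g2b$cov))
  fit3b <- peb_fit(units3b, X2, level = "group", fix_gamma = -Inf)
  d_m <- fit3b$beta_vec[diff_idx]
  d_sd <- sqrt(diag(fit3b$cov)[diff_idx])
  flagged <- abs(d_m) > qnorm(0.95) * d_sd
  expect_true(flagged[2])
  expect_false(any(flagged[c(1, 3, 4)]))
})
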