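#' @importFrom stats rnorm runif optimize cov qnorm dnorm integrate cor sd
#' @importFrom utils head tail read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Matrix exponential (scaling and squaring with Pade approximation)
#'
#' Dense matrix exponential used by the exact discretisation of the linear
#' neural stochastic differential equation.
#'
#' @param M square numeric matrix
#' @return exp(M), a matrix of the same dimension
#' @keywords internal
expm_dense <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  n <- nrow(M)
  nrm <- max(rowSums(abs(M)))
  j <- max(0L, ceiling(log2(max(nrm, .Machine$double.xmin))) + 1L)
  Ms <- M / 2^j
  # 8th-order Pade
  q <- 8L
  c_k <- 1
  X <- diag(n)
  N <- diag(n); D <- diag(n)
  for (k in seq_len(q)) {
    c_k <- c_k * (q - k + 1) / (k * (2 * q - k + 1))
    X <- Ms %*% X
    N <- N + c_k * X
    D <- D + (-1)^k * c_k * X
  }
  E <- solve(D, N)
  for (k in seq_len(j)) E <- E %*% E
  E
}

#' Exact discretisation of a linear SDE dx = A x dt + dW, cov(dW) = Qc dt
#'
#' Van Loan (1978) block-exponential method: returns the discrete transition
#' matrix Ad = expm(A dt) and the discrete innovation covariance
#' Qd = integral_0^dt expm(A s) Qc expm(A s)' ds.
#'
#' @param A stable drift matrix
#' @param Qc continuous-time noise covariance (spectral density)
#' @param dt time step in seconds
#' @return list with elements `Ad` and `Qd`
#' @keywords internal
discretize_lti <- function(A, Qc, dt) {
  n <- nrow(A)
  M <- rbind(cbind(-A, Qc), cbind(matrix(0, n, n), t(A))) * dt
  E <- expm_dense(M)
  Ad <- t(E[(n + 1):(2 * n), (n + 1):(2 * n), drop = FALSE])
  Qd <- Ad %*% E[1:n, (n + 1):(2 * n), drop = FALSE]
  # symmetrise against roundoff
  list(Ad = Ad, Qd = (Qd + t(Qd)) / 2)
}

# log determinant of a symmetric positive definite matrix via Cholesky
logdet_spd <- function(S) 2 * sum(log(diag(chol(S))))

# draw m samples from N(0, S) as an m x n matrix
rmvnorm0 <- function(m, S) {
  R <- chol(S)
  matrix(rnorm(m * nrow(S)), m) %*% R
}

# derive a valid 32-bit sub-seed from a base seed and stream index
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647L)
}

#' Minimum-cost assignment for small problems
#'
#' Exhaustive search over permutations; intended for matching state labels
#' (K <= 8).
#'
#' @param cost square cost matrix; entry (i, j) is the cost of assigning i to j
#' @return integer permutation p minimising sum(cost[cbind(seq, p)])
#' @keywords internal
min_cost_assignment <- function(cost) {
  K <- nrow(cost)
  stopifnot(K == ncol(cost), K <= 8)
  perms <- perm_all(K)
  costs <- vapply(perms, function(p) sum(cost[cbind(seq_len(K), p)]), numeric(1))
  perms[[which.min(costs)]]
}

perm_all <- function(K) {
  if (K == 1) return(list(1L))
  sub <- perm_all(K - 1L)
  out <- vector("list", K * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(K)) {
      i <- i + 1L
      out[[i]] <- as.integer(append(p, K, after = pos - 1L))
    }
  }
  out
}

# solve with a graduated jitter fallback for near-singular SPD systems
solve_jit <- function(A, b = NULL) {
  for (j in c(0, 1e-12, 1e-9, 1e-6)) {
    Aj <- if (j > 0) A + diag(j * mean(abs(diag(A))), nrow(A)) else A
    out <- tryCatch(if (is.null(b)) solve(Aj) else solve(Aj, b),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("matrix is numerically singular even with jitter")
}
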