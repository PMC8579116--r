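#' Sliding-window specification
#'
#' Windows are 0-based, half-open intervals `[start, start + window_size)`,
#' starting at 0 and advancing by `step = window_size - overlap`; only full
#' windows are kept, so the count is `floor((T - window_size)/step) + 1`.
#'
#' @param T_len series length in samples
#' @param window_size window length in samples
#' @param overlap overlap between consecutive windows in samples
#' @return object of class `statedcm_windows` with fields `starts`,
#'   `window_size`, `overlap`, `step`, `n`, `T_len`
#' @export
make_windows <- function(T_len, window_size, overlap) {
  stopifnot(T_len >= 1, window_size >= 1)
  if (overlap < 0 || overlap >= window_size)
    stop("overlap must satisfy 0 <= overlap < window_size")
  if (window_size > T_len) stop("window_size exceeds the series length")
  step <- window_size - overlap
  n <- floor((T_len - window_size) / step) + 1
  starts <- (seq_len(n) - 1L) * step
  structure(list(starts = as.integer(starts), window_size = as.integer(window_size),
                 overlap = as.integer(overlap), step = as.integer(step),
                 n = as.integer(n), T_len = as.integer(T_len)),
            class = "statedcm_windows")
}

#' @export
print.statedcm_windows <- function(x, ...) {
  cat(sprintf("%d windows of %d samples (overlap %d, step %d) over %d samples\n",
              x$n, x$window_size, x$overlap, x$step, x$T_len))
  invisible(x)
}

# symmetric Hann window of length N (endpoints exactly zero)
hann_window <- function(N) {
  if (N < 2) stop("Hann taper needs at least 2 samples")
  0.5 * (1 - cos(2 * pi * (0:(N - 1)) / (N - 1)))
}

#' Mean-remove and Hann-taper a windowed segment
#'
#' Columns are demeaned, then multiplied elementwise by a symmetric Hann
#' window of the segment length.
#'
#' @param segment numeric vector or T x n matrix
#' @return tapered segment of the same shape
#' @export
hann_taper <- function(segment) {
  segment <- as.matrix(segment)
  w <- hann_window(nrow(segment))
  seg <- sweep(segment, 2, colMeans(segment))
  seg * w
}

#' Fit a multivariate autoregressive (MAR) model by least squares
#'
#' Regresses each sample on its `order` predecessors (no intercept; input is
#' expected demeaned) with optional ridge penalty; the innovation covariance
#' is the residual covariance. Order 0 degenerates to the sample covariance.
#'
#' @param segment T x n numeric matrix
#' @param order MAR order p >= 0
#' @param delta sampling interval in seconds (stored for spectral conversion)
#' @param ridge nonnegative ridge penalty, scaled by mean diagonal of the
#'   design Gram matrix
#' @return object of class `statedcm_mar` with fields `W` (list of p n x n
#'   lag-coefficient matrices, lag l matrix maps y(t-l) to y(t)), `Sigma`,
#'   `order`, `delta`
#' @export
fit_mar <- function(segment, order, delta = 1, ridge = 0) {
  Y_full <- as.matrix(segment)
  n <- ncol(Y_full); T_len <- nrow(Y_full)
  stopifnot(order >= 0)
  if (order == 0) {
    Sigma <- crossprod(Y_full) / T_len
    return(structure(list(W = list(), Sigma = Sigma, order = 0L, delta = delta),
                     class = "statedcm_mar"))
  }
  if (T_len <= n * order + order)
    stop(sprintf("segment too short for MAR(%d) in %d nodes: need > %d samples",
                 order, n, n * order + order))
  idx <- (order + 1):T_len
  Y <- Y_full[idx, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(order), function(l) Y_full[idx - l, , drop = FALSE]))
  G <- crossprod(X)
  if (ridge > 0) G <- G + diag(ridge * mean(diag(G)), ncol(X))
  coef <- tryCatch(solve(G, crossprod(X, Y)), error = function(e) {
    stop("rank-deficient MAR design; supply a positive ridge penalty")
  })
  E <- Y - X %*% coef
  Sigma <- crossprod(E) / nrow(Y)
  W <- lapply(seq_len(order), function(l) t(coef[((l - 1) * n + 1):(l * n), , drop = FALSE]))
  structure(list(W = W, Sigma = Sigma, order = as.integer(order), delta = delta),
            class = "statedcm_mar")
}

#' Parametric cross-spectral density of a MAR model
#'
#' The transfer function is `H(f) = (I - sum_l W_l exp(-i 2 pi f l delta))^-1`
#' and the two-sided spectral density `S(f) = delta * H(f) Sigma H(f)^*`
#' (units^2 per Hz), so that the integral of the auto-spectra over
#' `(-Nyquist, Nyquist]` recovers the process variance.
#'
#' @param model `statedcm_mar`
#' @param freqs frequency grid in Hz, within (0, Nyquist]
#' @return object of class `statedcm_csd`: `freqs` and `values`, an
#'   n x n x length(freqs) complex array, Hermitian at every frequency
#' @export
mar_to_csd <- function(model, freqs) {
  stopifnot(inherits(model, "statedcm_mar"))
  n <- nrow(model$Sigma)
  nf <- length(freqs)
  nyq <- 1 / (2 * model$delta)
  if (any(freqs <= 0 | freqs > nyq + 1e-12))
    stop("frequencies must lie in (0, Nyquist]")
  vals <- array(0i, c(n, n, nf))
  I_n <- diag(n)
  for (fi in seq_len(nf)) {
    Af <- I_n
    for (l in seq_along(model$W)) {
      Af <- Af - model$W[[l]] * exp(-2i * pi * freqs[fi] * l * model$delta)
    }
    H <- tryCatch(solve(Af), error = function(e)
      stop(sprintf("singular MAR transfer function at %.5g Hz", freqs[fi])))
    S <- model$delta * H %*% model$Sigma %*% Conj(t(H))
    vals[, , fi] <- (S + Conj(t(S))) / 2
  }
  structure(list(freqs = freqs, values = vals), class = "statedcm_csd")
}

#' Default spectral-DCM frequency grid
#'
#' 32 uniformly spaced frequencies from the fundamental of the window
#' (1/window length) up to min(0.25 Hz, Nyquist), covering the resting-state
#' band.
#'
#' @param window_s window length in seconds
#' @param tr sampling interval in seconds
#' @param nf number of frequency bins
#' @return numeric frequency grid (Hz)
#' @export
csd_freq_grid <- function(window_s, tr, nf = 32) {
  f_lo <- 1 / window_s
  f_hi <- min(0.25, 0.5 / tr)
  if (f_hi <= f_lo) stop("window too short for the requested band")
  seq(f_lo, f_hi, length.out = nf)
}
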