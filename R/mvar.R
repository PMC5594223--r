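#' Companion matrix of an MVAR coefficient stack
#'
#' @param model an \linkS4class{MVARModel}.
#' @return (m*p) x (m*p) companion matrix.
#' @export
companionMatrix <- function(model) {
  A <- model@coefficients
  m <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) C[seq_len(m), (k - 1) * m + seq_len(m)] <- A[, , k]
  if (p > 1) C[(m + 1):(m * p), seq_len(m * (p - 1))] <- diag(m * (p - 1))
  C
}

#' Spectral radius of the companion matrix
#' @inheritParams companionMatrix
#' @return largest eigenvalue modulus; < 1 for a stable model.
#' @export
spectralRadius <- function(model) {
  max(Mod(eigen(companionMatrix(model), only.values = TRUE)$values))
}

#' Is an MVAR model stable?
#' @inheritParams companionMatrix
#' @return TRUE if the companion spectral radius is < 1.
#' @export
isStable <- function(model) spectralRadius(model) < 1

#' Fit a multivariate autoregressive model
#'
#' Multichannel Levinson-type partial-correlation recursion (Vieira-Morf):
#' at each stage the empirical forward/backward prediction-error covariances
#' and their cross-covariance are computed with unbiased normalization
#' (divisor n - k at stage k), the normalized partial-correlation matrix is
#' formed through Cholesky square roots of the two error covariances, and the
#' reflection coefficients update both error series and the coefficient stack
#' by the Levinson-Wiggins-Robinson recursion. The residual covariance is the
#' forward prediction-error covariance at the final order.
#'
#' The per-channel mean is removed before fitting; no detrending or filtering
#' is applied.
#'
#' @param signal channels x samples numeric matrix.
#' @param order model order p.
#' @param samplingRate sampling rate in Hz attached to the result.
#' @param channelLabels optional channel names (default from rownames).
#' @return An \linkS4class{MVARModel}.
#' @examples
#' x <- matrix(rnorm(2 * 2000), 2)
#' fitMVAR(x, order = 1)
#' @export
fitMVAR <- function(signal, order, samplingRate = 200, channelLabels = NULL) {
  if (!is.matrix(signal)) signal <- as.matrix(signal)
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  m <- nrow(signal); n <- ncol(signal)
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  if (n <= order) stop("need more samples than the model order")
  if (n <= order * m)
    warning(sprintf("only %d samples for %d coefficients per equation; fit may be unstable",
                    n, order * m))
  if (is.null(channelLabels)) {
    channelLabels <- rownames(signal)
    if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(m))
  }

  X <- signal - rowMeans(signal)
  Fe <- X                      # forward prediction errors, valid at t = k+1..n
  Be <- X                      # backward errors, valid at t = 1..n-k
  ARF <- array(0, c(m, m, order))
  ARB <- array(0, c(m, m, order))

  for (k in seq_len(order)) {
    nk <- n - k
    Fk <- Fe[, (k + 1):n, drop = FALSE]
    Bk <- Be[, 1:nk, drop = FALSE]
    D  <- tcrossprod(Fk, Bk) / nk          # unbiased: divisor n - k
    Pf <- tcrossprod(Fk) / nk
    Pb <- tcrossprod(Bk) / nk
    Lf <- tryCatch(t(chol(Pf)), error = function(e) NULL)
    Lb <- tryCatch(t(chol(Pb)), error = function(e) NULL)
    if (is.null(Lf) || is.null(Lb))
      stop(sprintf("singular prediction-error covariance at order %d", k))
    # normalized partial correlation rho = Lf^-1 D Lb^-T (geometric-mean form)
    rho <- forwardsolve(Lf, D)
    rho <- t(forwardsolve(Lb, t(rho)))
    Kf <- Lf %*% rho %*% solve(Lb)         # forward reflection coefficient
    Kb <- Lb %*% t(rho) %*% solve(Lf)      # backward reflection coefficient
    if (k > 1) {
      for (j in seq_len(k - 1)) {
        tmp <- ARF[, , j] - Kf %*% ARB[, , k - j]
        ARB[, , k - j] <- ARB[, , k - j] - Kb %*% ARF[, , j]
        ARF[, , j] <- tmp
      }
    }
    ARF[, , k] <- Kf
    ARB[, , k] <- Kb
    Fnew <- Fk - Kf %*% Bk
    Bnew <- Bk - Kb %*% Fk
    Fe[, (k + 1):n] <- Fnew
    Be[, 1:nk] <- Bnew
  }

  resid <- Fe[, (order + 1):n, drop = FALSE]
  Sigma <- tcrossprod(resid) / (n - order)
  Sigma <- (Sigma + t(Sigma)) / 2
  MVARModel(ARF, Sigma, samplingRate = samplingRate,
            channelLabels = channelLabels)
}

#' Evaluate the frequency-domain transforms of an MVAR model
#'
#' Computes, on the analysis grid (default integers 2..80 Hz), the AR
#' polynomial Abar(f) = I - sum_k A_k exp(-i 2 pi f k / fs), the transfer
#' function H(f) = Abar(f)^-1, and the spectral matrix
#' S(f) = H(f) Sigma H(f)*. No 1/fs scaling is applied to S; only relative
#' values reach the downstream measures.
#'
#' @param model an \linkS4class{MVARModel}.
#' @param frequencies Hz grid; must lie in (0, fs/2].
#' @return A \linkS4class{SpectralMatrices}.
#' @export
spectralTransform <- function(model, frequencies = 2:80) {
  fs <- model@samplingRate
  if (any(frequencies <= 0) || any(frequencies > fs / 2))
    stop("frequencies must lie in (0, fs/2]")
  A <- model@coefficients
  m <- dim(A)[1]; p <- dim(A)[3]
  Sigma <- model@residualCovariance
  nf <- length(frequencies)
  Aflat <- matrix(A, m * m, p)             # columns = vec(A_k)
  Af <- array(0i, c(m, m, nf))
  H  <- array(0i, c(m, m, nf))
  S  <- array(0i, c(m, m, nf))
  I <- diag(m)
  for (fi in seq_len(nf)) {
    z <- exp(-2i * pi * frequencies[fi] * seq_len(p) / fs)
    Abar <- I - matrix(Aflat %*% z, m, m)
    Hf <- tryCatch(solve(Abar), error = function(e) NULL)
    if (is.null(Hf))
      stop(sprintf("AR polynomial numerically singular at %g Hz", frequencies[fi]))
    Af[, , fi] <- Abar
    H[, , fi]  <- Hf
    S[, , fi]  <- Hf %*% Sigma %*% Conj(t(Hf))
  }
  new("SpectralMatrices", frequencies = as.numeric(frequencies),
      Af = Af, H = H, S = S, residualCovariance = Sigma,
      channelLabels = model@channelLabels)
}

#' Serialize an MVAR model to JSON
#'
#' @param model an \linkS4class{MVARModel}.
#' @param path optional file to write to; if NULL the JSON string is returned.
#' @return JSON string (invisibly when writing to a file).
#' @export
mvarToJSON <- function(model, path = NULL) {
  obj <- list(order = model@order,
              coefficients = model@coefficients,
              residualCovariance = model@residualCovariance,
              samplingRate = model@samplingRate,
              channelLabels = model@channelLabels)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Restore an MVAR model from JSON
#' @param json JSON string or path to a JSON file.
#' @return An \linkS4class{MVARModel}.
#' @export
mvarFromJSON <- function(json) {
  obj <- jsonlite::fromJSON(json)
  A <- obj$coefficients
  if (length(dim(A)) == 2L) A <- array(A, c(dim(A), 1L))
  MVARModel(A, as.matrix(obj$residualCovariance),
            samplingRate = obj$samplingRate,
            channelLabels = obj$channelLabels)
}
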