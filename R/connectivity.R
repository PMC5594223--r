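#' @title Spectral interaction measures
#' @description The 14 frequency-domain measures derived from the MVAR
#' transforms. Entry (i, j) of every returned matrix refers to the influence
#' (directed measures) or association (symmetric measures) of source channel
#' j on sink channel i. All complex quantities are reduced to real values by
#' modulus before band averaging, except iCOH (imaginary part of coherency)
#' and GGC (already real).
#' @name connectivity
NULL

.mkTensor <- function(measure, spec, values) {
  ConnectivityArray(measure, spec@frequencies, values, spec@channelLabels)
}

#' Coherency family: COH, iCOH, pCOH
#'
#' Coherency C_ij(f) = S_ij(f) / sqrt(S_ii(f) S_jj(f)). COH is its modulus,
#' iCOH its imaginary part, and pCOH the normalized modulus of the inverse
#' spectral matrix P(f) = S(f)^-1: |P_ij| / sqrt(P_ii P_jj).
#'
#' @param spec a \linkS4class{SpectralMatrices}.
#' @return Named list of \linkS4class{ConnectivityArray}: COH, iCOH, pCOH.
#' @export
coherencyFamily <- function(spec) {
  S <- spec@S
  m <- dim(S)[1]; nf <- dim(S)[3]
  COH <- iCOH <- pCOH <- array(0, c(m, m, nf))
  for (fi in seq_len(nf)) {
    Sf <- S[, , fi]
    d <- Re(diag(Sf))
    if (any(d <= 0)) stop(sprintf("non-positive autospectrum at %g Hz",
                                  spec@frequencies[fi]))
    norm <- sqrt(outer(d, d))
    C <- Sf / norm
    COH[, , fi] <- Mod(C)
    iCOH[, , fi] <- Im(C)
    P <- tryCatch(solve(Sf), error = function(e) NULL)
    if (is.null(P))
      stop(sprintf("spectral matrix singular at %g Hz (pCOH)",
                   spec@frequencies[fi]))
    dp <- Re(diag(P))
    pCOH[, , fi] <- Mod(P) / sqrt(outer(abs(dp), abs(dp)))
  }
  list(COH = .mkTensor("COH", spec, COH),
       iCOH = .mkTensor("iCOH", spec, iCOH),
       pCOH = .mkTensor("pCOH", spec, pCOH))
}

#' Partial directed coherence family: PDC, PDCF, GPDC
#'
#' All three are column-normalized functions of the AR polynomial Abar(f):
#' PDC_ij = |Abar_ij| / sqrt(sum_k |Abar_kj|^2);
#' PDCF_ij = |Abar_ij| / sqrt(abar_j* Sigma^-1 abar_j) with abar_j the j-th
#' column of Abar; GPDC_ij = (|Abar_ij| / sqrt(Sigma_ii)) /
#' sqrt(sum_k |Abar_kj|^2 / Sigma_kk).
#'
#' @param spec a \linkS4class{SpectralMatrices}.
#' @param Sigma residual covariance (default taken from \code{spec}).
#' @return Named list of \linkS4class{ConnectivityArray}: PDC, PDCF, GPDC.
#' @export
pdcFamily <- function(spec, Sigma = spec@residualCovariance) {
  A <- spec@Af
  m <- dim(A)[1]; nf <- dim(A)[3]
  SigInv <- tryCatch(solve(Sigma), error = function(e) NULL)
  if (is.null(SigInv)) stop("residual covariance singular (PDCF/GPDC)")
  sdi <- sqrt(diag(Sigma))
  PDC <- PDCF <- GPDC <- array(0, c(m, m, nf))
  for (fi in seq_len(nf)) {
    Am <- Mod(A[, , fi])
    colnorm <- sqrt(colSums(Am^2))
    PDC[, , fi] <- sweep(Am, 2, colnorm, "/")
    qf <- vapply(seq_len(m), function(j) {
      aj <- A[, j, fi]
      Re(Conj(aj) %*% SigInv %*% aj)
    }, 0)
    PDCF[, , fi] <- sweep(Am, 2, sqrt(qf), "/")
    Gnum <- sweep(Am, 1, sdi, "/")
    Gden <- sqrt(colSums(Gnum^2))
    GPDC[, , fi] <- sweep(Gnum, 2, Gden, "/")
  }
  list(PDC = .mkTensor("PDC", spec, PDC),
       PDCF = .mkTensor("PDCF", spec, PDCF),
       GPDC = .mkTensor("GPDC", spec, GPDC))
}

#' Directed transfer function family: DTF, ffDTF, dDTF
#'
#' Row-normalized functions of the transfer function H(f):
#' DTF_ij = |H_ij| / sqrt(sum_k |H_ik|^2) (per frequency);
#' ffDTF_ij = |H_ij(f)| / sqrt(sum_f' sum_k |H_ik(f')|^2) (full-frequency
#' normalization); dDTF_ij(f) = ffDTF_ij(f) * pCOH_ij(f).
#'
#' @param spec a \linkS4class{SpectralMatrices}.
#' @param pCOH optional precomputed partial-coherence tensor (recomputed if
#'   missing).
#' @return Named list of \linkS4class{ConnectivityArray}: DTF, ffDTF, dDTF.
#' @export
dtfFamily <- function(spec, pCOH = NULL) {
  H <- spec@H
  m <- dim(H)[1]; nf <- dim(H)[3]
  Hm <- Mod(H)
  DTF <- ffDTF <- array(0, c(m, m, nf))
  # full-frequency row normalization: sum over frequencies and sources
  ffden <- sqrt(apply(Hm^2, 1, sum))
  for (fi in seq_len(nf)) {
    rn <- sqrt(rowSums(Hm[, , fi]^2))
    DTF[, , fi] <- Hm[, , fi] / rn
    ffDTF[, , fi] <- Hm[, , fi] / ffden
  }
  if (is.null(pCOH)) pCOH <- coherencyFamily(spec)$pCOH
  dDTF <- ffDTF * pCOH@values
  list(DTF = .mkTensor("DTF", spec, DTF),
       ffDTF = .mkTensor("ffDTF", spec, ffDTF),
       dDTF = .mkTensor("dDTF", spec, dDTF))
}

#' Granger family: GGC and DC
#'
#' GGC_ij(f) is Geweke's spectral Granger causality of source j on sink i,
#' ln( S_ii(f) / (S_ii(f) - (Sigma_jj - Sigma_ij^2 / Sigma_ii) |H_ij(f)|^2) ),
#' clipped below at zero (a negative or undefined argument yields 0). DC is
#' the direct causal gain of the AR polynomial, |Abar_ij(f)| off the
#' diagonal and 0 on it.
#'
#' @param spec a \linkS4class{SpectralMatrices}.
#' @param Sigma residual covariance (default taken from \code{spec}).
#' @return Named list of \linkS4class{ConnectivityArray}: GGC, DC.
#' @export
grangerFamily <- function(spec, Sigma = spec@residualCovariance) {
  H <- spec@H; S <- spec@S; A <- spec@Af
  m <- dim(H)[1]; nf <- dim(H)[3]
  GGC <- DC <- array(0, c(m, m, nf))
  # conditional innovation variance of source j given sink i
  condVar <- outer(seq_len(m), seq_len(m),
                   function(i, j) diag(Sigma)[j] - Sigma[cbind(i, j)]^2 / diag(Sigma)[i])
  for (fi in seq_len(nf)) {
    Sii <- Re(diag(S[, , fi]))
    Hm2 <- Mod(H[, , fi])^2
    denom <- matrix(Sii, m, m) - condVar * Hm2
    arg <- matrix(Sii, m, m) / denom
    g <- ifelse(is.finite(arg) & arg > 0, log(arg), 0)
    g[g < 0] <- 0
    diag(g) <- 0
    GGC[, , fi] <- g
    d <- Mod(A[, , fi])
    diag(d) <- 0
    DC[, , fi] <- d
  }
  list(GGC = .mkTensor("GGC", spec, GGC),
       DC = .mkTensor("DC", spec, DC))
}

#' Raw spectral tensors: S, h, Af
#'
#' Modulus reductions of the cross-spectrum, the transfer function and the
#' AR polynomial. Diagonals are retained (autospectra are informative).
#'
#' @param spec a \linkS4class{SpectralMatrices}.
#' @return Named list of \linkS4class{ConnectivityArray}: S, h, Af.
#' @export
rawFamily <- function(spec) {
  list(S = .mkTensor("S", spec, Mod(spec@S)),
       h = .mkTensor("h", spec, Mod(spec@H)),
       Af = .mkTensor("Af", spec, Mod(spec@Af)))
}

#' Average a connectivity tensor into the five canonical bands
#'
#' Arithmetic mean over the integer frequencies of each band: delta 2-4,
#' theta 5-7, alpha 8-13, beta 14-30, gamma 31-80 Hz. Requires the full
#' 2..80 Hz integer grid.
#'
#' @param tensor a \linkS4class{ConnectivityArray}.
#' @return A \linkS4class{BandedConnectivity}.
#' @export
bandAverage <- function(tensor) {
  if (!isTRUE(all.equal(tensor@frequencies, as.numeric(2:80))))
    stop("band averaging requires the integer 2..80 Hz grid")
  bands <- bandDefinitions()
  m <- dim(tensor@values)[1]
  out <- array(0, c(m, m, length(bands)),
               dimnames = list(tensor@channelLabels, tensor@channelLabels,
                               names(bands)))
  for (b in seq_along(bands)) {
    idx <- match(bands[[b]], tensor@frequencies)
    out[, , b] <- apply(tensor@values[, , idx, drop = FALSE], c(1, 2), mean)
  }
  new("BandedConnectivity", measure = tensor@measure, values = out,
      channelLabels = tensor@channelLabels)
}

#' Compute all 14 band-averaged measures for one model
#'
#' Runs the spectral transform once on the 2..80 Hz grid and derives the
#' band-averaged tensor of every measure.
#'
#' @param model an \linkS4class{MVARModel}.
#' @param frequencies analysis grid (default 2:80).
#' @return Named list of 14 \linkS4class{BandedConnectivity}, in the order of
#'   \code{connectivityMeasures()}.
#' @export
computeAllMeasures <- function(model, frequencies = 2:80) {
  spec <- spectralTransform(model, frequencies)
  coh <- coherencyFamily(spec)
  tensors <- c(rawFamily(spec),
               coh,
               pdcFamily(spec),
               dtfFamily(spec, pCOH = coh$pCOH),
               grangerFamily(spec))
  tensors <- tensors[connectivityMeasures()]
  out <- lapply(names(tensors), function(nm) {
    tryCatch(bandAverage(tensors[[nm]]),
             error = function(e) stop(sprintf("measure %s: %s", nm,
                                              conditionMessage(e))))
  })
  names(out) <- names(tensors)
  out
}

#' Export banded tensors to a long-format data frame
#'
#' @param banded named list of \linkS4class{BandedConnectivity} (as returned
#'   by \code{computeAllMeasures}).
#' @param subjectId identifier added as first column.
#' @return data.frame with columns subject_id, measure, band, source, sink,
#'   value.
#' @export
bandedToLong <- function(banded, subjectId = "subject") {
  rows <- lapply(banded, function(bc) {
    m <- dim(bc@values)[1]
    bands <- dimnames(bc@values)[[3]]
    do.call(rbind, lapply(bands, function(b) {
      data.frame(subject_id = subjectId, measure = bc@measure, band = b,
                 source = rep(bc@channelLabels, each = m),
                 sink = rep(bc@channelLabels, m),
                 value = as.vector(bc@values[, , b]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
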