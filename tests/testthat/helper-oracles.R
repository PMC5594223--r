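# Independent oracles and small fixtures, kept separate from the package
# implementation paths they check.

# least-squares MVAR oracle: lagged-regression normal equations
lsFitMVAR <- function(x, p) {
  m <- nrow(x); n <- ncol(x)
  x <- x - rowMeans(x)
  Y <- t(x[, (p + 1):n, drop = FALSE])                  # (n-p) x m
  Z <- do.call(cbind, lapply(seq_len(p), function(k)
    t(x[, (p + 1 - k):(n - k), drop = FALSE])))         # (n-p) x (m*p)
  B <- solve(crossprod(Z), crossprod(Z, Y))             # (m*p) x m
  A <- array(0, c(m, m, p))
  for (k in seq_len(p)) A[, , k] <- t(B[(k - 1) * m + seq_len(m), ])
  resid <- Y - Z %*% B
  list(A = A, Sigma = crossprod(resid) / (nrow(Y) - p))
}

# exhaustive maximum modularity over all partitions of <= 8 nodes
bruteForceModularity <- function(W) {
  Ws <- (W + t(W)) / 2
  diag(Ws) <- 0
  n <- nrow(Ws)
  stopifnot(n <= 8)
  m2 <- sum(Ws)
  k <- rowSums(Ws)
  qOf <- function(memb) {
    q <- 0
    for (c in unique(memb)) {
      inC <- memb == c
      q <- q + sum(Ws[inC, inC]) / m2 - (sum(k[inC]) / m2)^2
    }
    q
  }
  # enumerate set partitions in restricted-growth-string form
  best <- -Inf
  rec <- function(memb, i, maxUsed) {
    if (i > n) {
      q <- qOf(memb)
      if (q > best) best <<- q
      return(invisible())
    }
    for (c in seq_len(maxUsed + 1)) {
      memb[i] <- c
      rec(memb, i + 1, max(maxUsed, c))
    }
  }
  rec(integer(n), 1L, 0L)
  best
}

# bivariate template with one-way coupling used across tests
unidirTemplate <- function(a11 = 0.5, a21 = 0.4, a22 = 0.3) {
  MVARModel(matrix(c(a11, a21, 0, a22), 2, 2))
}

# synthetic feature SummarizedExperiment for classifier tests
makeFeatureSE <- function(x, groups, prefix = "f") {
  p <- ncol(x)
  ids <- paste0(prefix, seq_len(p))
  desc <- data.frame(id = ids, modality = "SPECT", measure = NA_character_,
                     band = NA_character_, source = NA_character_,
                     sink = NA_character_, metric = NA_character_,
                     region = ids, stringsAsFactors = FALSE)
  vals <- t(x)
  rownames(vals) <- ids
  colnames(vals) <- paste0("s", seq_len(nrow(x)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = vals),
    rowData = S4Vectors::DataFrame(desc),
    colData = S4Vectors::DataFrame(group = groups,
                                   row.names = colnames(vals)))
}

# two-group Gaussian feature matrix with a few informative columns
makeTwoGroupFeatures <- function(n1, n2, pNoise, informative = integer(0),
                                 shift = 2, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  p <- pNoise + length(informative)
  x <- matrix(rnorm(n * p), n, p)
  y <- factor(rep(c("g1", "g2"), c(n1, n2)), levels = c("g1", "g2"))
  for (j in informative) x[y == "g1", j] <- x[y == "g1", j] + shift
  list(x = x, y = y)
}
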