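#' Convert a connectivity matrix to a weighted directed graph
#'
#' Takes absolute values, zeroes the diagonal and rescales to [0, 1] by the
#' matrix maximum (an all-zero matrix stays all-zero). The orientation
#' convention is kept: entry (i, j) is the edge source j -> sink i.
#'
#' @param mat m x m real matrix.
#' @return m x m weight matrix W with W[i, j] = weight of edge j -> i.
#' @export
connectivityToGraph <- function(mat) {
  if (!all(is.finite(mat))) stop("connectivity matrix contains non-finite values")
  W <- abs(mat)
  diag(W) <- 0
  mx <- max(W)
  if (mx > 0) W <- W / mx
  W
}

# directed weighted assortativity: weighted Pearson correlation between the
# out-strength of each edge's source and the in-strength of its target
.assortativityOutIn <- function(W) {
  A <- W > 0
  if (sum(A) < 2) return(NA_real_)
  outS <- colSums(W)                 # source strength: column j sends W[, j]
  inS <- rowSums(W)                  # sink strength
  idx <- which(A, arr.ind = TRUE)    # rows = sinks (i), cols = sources (j)
  w <- W[idx]
  x <- outS[idx[, 2]]                # source out-strength
  y <- inS[idx[, 1]]                 # target in-strength
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw; vy <- sum(w * (y - my)^2) / sw
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sw / sqrt(vx * vy)
}

# global efficiency: mean over ordered node pairs of the inverse shortest
# path length with edge length 1/weight; disconnected pairs contribute 0
.globalEfficiency <- function(W) {
  m <- nrow(W)
  if (m < 2) return(NA_real_)
  g <- igraph::graph_from_adjacency_matrix(t(W), mode = "directed",
                                           weighted = TRUE)
  if (igraph::ecount(g) == 0) return(0)
  d <- igraph::distances(g, mode = "out",
                         weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (m * (m - 1))
}

# Fagiolo directed weighted clustering: per-node geometric-mean triangle
# intensity over the number of possible directed triangles
.clusteringTerms <- function(W) {
  A <- (W > 0) * 1
  Wh <- W^(1 / 3)
  Ws <- Wh + t(Wh)
  num <- diag(Ws %*% Ws %*% Ws) / 2
  dtot <- colSums(A) + rowSums(A)
  dbi <- diag(A %*% A)
  den <- dtot * (dtot - 1) - 2 * dbi
  list(num = num, den = den)
}

.meanClustering <- function(W) {
  tr <- .clusteringTerms(W)
  ci <- ifelse(tr$den > 0, tr$num / tr$den, 0)
  mean(ci)
}

# transitivity: ratio of total triangle intensity to total triple count
.transitivity <- function(W) {
  tr <- .clusteringTerms(W)
  if (sum(tr$den) <= 0) return(0)
  sum(tr$num) / sum(tr$den)
}

# deterministic greedy agglomerative modularity on the symmetrized matrix
.modularity <- function(W) {
  Ws <- (W + t(W)) / 2
  if (max(Ws) == 0) return(NA_real_)
  g <- igraph::graph_from_adjacency_matrix(Ws, mode = "undirected",
                                           weighted = TRUE)
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  q <- igraph::modularity(g, igraph::membership(cl),
                          weights = igraph::E(g)$weight)
  max(q, 0)   # never worse than the trivial one-block partition
}

#' Global graph summary of a connectivity matrix
#'
#' Reduces a (normalized) weighted directed graph to five global metrics:
#' out-in degree-correlation assortativity, global efficiency (mean inverse
#' shortest-path length with edge length 1/weight; disconnected pairs
#' contribute 0), mean directed weighted clustering coefficient
#' (geometric-mean triangle form), modularity of a deterministic greedy
#' agglomerative partition of the symmetrized graph, and weighted
#' transitivity (total triangle intensity over total triple count). Fully
#' weighted graphs are used throughout; no binarization threshold is applied.
#'
#' Degenerate graphs yield NA for metrics that are undefined there
#' (assortativity with < 2 edges or zero degree variance; modularity of an
#' empty graph); callers impute those to 0 when building feature vectors.
#'
#' @param W weight matrix from \code{\link{connectivityToGraph}} (raw
#'   matrices are normalized internally).
#' @return Named numeric vector: assortativity, efficiency, clustering,
#'   modularity, transitivity.
#' @export
graphSummary <- function(W) {
  W <- connectivityToGraph(W)
  c(assortativity = .assortativityOutIn(W),
    efficiency = .globalEfficiency(W),
    clustering = .meanClustering(W),
    modularity = .modularity(W),
    transitivity = .transitivity(W))
}
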