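# Build a CoNetwork from an explicit edge list (node labels "v1", "v2", ...)
# so graph-metric functions can be exercised on arbitrary small graphs.
netFromEdges <- function(edges, rho = 0.9) {
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  n <- length(nodes)
  R <- diag(n); P <- matrix(1, n, n); diag(P) <- 0
  dimnames(R) <- dimnames(P) <- list(nodes, nodes)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    R[i, j] <- R[j, i] <- rho
    P[i, j] <- P[j, i] <- 1e-9
  }
  buildNetwork(R, P, r_threshold = 0.75, p_threshold = 0.001)
}

edgesOf <- function(prefix, pairs) {
  cbind(paste0(prefix, pairs[, 1]), paste0(prefix, pairs[, 2]))
}

cliqueEdges <- function(ids) t(utils::combn(ids, 2))

# --- independent brute-force oracles (no igraph) ---------------------------

adjFromEdges <- function(edges) {
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    A[edges[k, 1], edges[k, 2]] <- 1L
    A[edges[k, 2], edges[k, 1]] <- 1L
  }
  A
}

oracleClustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) { ci[i] <- 0; next }
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      tri <- tri + A[nb[a], nb[b]]
    ci[i] <- tri / choose(k, 2)
  }
  mean(ci)
}

oraclePathLength <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  finite <- is.finite(D) & row(D) != col(D)
  mean(D[finite])
}

oracleModularity <- function(A, memb) {
  m <- sum(A) / 2
  deg <- rowSums(A)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    e_c <- sum(A[idx, idx]) / 2
    d_c <- sum(deg[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

oracleCentralization <- function(A) {
  k <- rowSums(A)
  n <- nrow(A)
  sum(max(k) - k) / ((n - 1) * (n - 2))
}

randomConnectedEdges <- function(n, p) {
  repeat {
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    if (!any(keep)) next
    el <- pairs[keep, , drop = FALSE]
    used <- sort(unique(c(el)))
    if (length(used) >= 3)
      return(cbind(paste0("v", el[, 1]), paste0("v", el[, 2])))
  }
}
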