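## Independent oracles, deliberately written against the raw edge list
## rather than the package's (or ape's) covariance code paths.

## Shared-path-length covariance by brute-force path enumeration:
## for every node, the set of edges (identified by their child node) on
## its root path; C[u, v] = sum of lengths of common edges (+ root.edge).
oracle_cov_nodes <- function(tree, nodes_a, nodes_b) {
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- length(tree$tip.label) + 1L
  path_edges <- function(v) {
    out <- integer(0)
    while (v != root) { out <- c(out, v); v <- parent[v] }
    out
  }
  r <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  outer_len <- matrix(0, length(nodes_a), length(nodes_b))
  pa <- lapply(nodes_a, path_edges)
  pb <- lapply(nodes_b, path_edges)
  for (i in seq_along(nodes_a))
    for (j in seq_along(nodes_b))
      outer_len[i, j] <- sum(elen[intersect(pa[[i]], pb[[j]])]) + r
  outer_len
}

## Tip-tip covariance oracle, rows/cols ordered as `taxa`.
oracle_cov <- function(tree, taxa = tree$tip.label) {
  idx <- match(taxa, tree$tip.label)
  C <- oracle_cov_nodes(tree, idx, idx)
  dimnames(C) <- list(taxa, taxa)
  C
}

## Brute-force GLS ancestral states using the explicit full-tree
## covariance (tips x tips and nodes x tips) from the oracle above.
oracle_ancestral <- function(tree, X) {
  X <- as.matrix(X)
  X <- X[tree$tip.label, , drop = FALSE]
  n <- length(tree$tip.label)
  nodes <- n + seq_len(tree$Nnode)
  C <- oracle_cov(tree)
  Cau <- oracle_cov_nodes(tree, nodes, seq_len(n))
  ## node-node "own depth" is irrelevant for the conditional mean
  Cinv <- solve(C)
  one <- rep(1, n)
  a <- drop((crossprod(one, Cinv) %*% X) / drop(crossprod(one, Cinv %*% one)))
  est <- sweep(Cau %*% Cinv %*% sweep(X, 2, a), 2, a, `+`)
  rownames(est) <- as.character(nodes)
  est
}

## Reshape a flattened (x/y interleaved) row back to k x 2.
.unflat <- function(v) matrix(v, ncol = 2L, byrow = TRUE)

## Random ultrametric chronogram (coalescent topology rescaled).
rand_chronogram <- function(n, age = 10) {
  phy <- ape::rcoal(n, tip.label = sprintf("t%02d", seq_len(n)))
  phy$edge.length <- phy$edge.length * (age / max(ape::node.depth.edgelength(phy)))
  phy
}

## Apply a rigid-motion + scale nuisance transform to a k x 2 matrix.
rigid_transform <- function(m, theta = 0, s = 1, dx = 0, dy = 0) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  out <- s * m %*% R
  out[, 1] <- out[, 1] + dx
  out[, 2] <- out[, 2] + dy
  out
}

## Noisy copies of a base shape wrapped as landmark_configs.
noisy_configs <- function(base, n, noise_sd = 0.01, nuisance = TRUE,
                          prefix = "s") {
  lapply(seq_len(n), function(i) {
    m <- base + matrix(rnorm(2 * nrow(base), sd = noise_sd), ncol = 2)
    if (nuisance)
      m <- rigid_transform(m, theta = runif(1, -pi, pi),
                           s = runif(1, 0.5, 3),
                           dx = runif(1, -5, 5), dy = runif(1, -5, 5))
    landmark_config(m, sprintf("%s%03d", prefix, i))
  })
}
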