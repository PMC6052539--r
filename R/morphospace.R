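## Phylomorphospace: PCA of species mean shapes, Brownian-motion
## ancestral-state estimates, and projection of tips, nodes, and tree
## edges into PC1-PC2.

#' Principal component analysis of a shape matrix
#'
#' Column-mean-centred PCA (no scaling) with components ordered by
#' decreasing variance and a deterministic sign convention: within each
#' loading vector the entry of largest magnitude is positive.
#'
#' @param Y n x p shape matrix with taxon rownames (n >= 3).
#' @return List with `scores` (n x r), `loadings` (p x r),
#'   `variance_explained` (length r, sums to 1 over the full spectrum),
#'   and `center` (length p).
#' @export
shape_pca <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 3L) .stopf("need at least 3 taxa for PCA")
  if (max(abs(sweep(Y, 2, colMeans(Y)))) == 0)
    .stopf("degenerate input: zero variance")
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    v[which.max(abs(v))] < 0
  }, logical(1))
  pc$rotation[, flip] <- -pc$rotation[, flip, drop = FALSE]
  pc$x[, flip] <- -pc$x[, flip, drop = FALSE]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation,
       variance_explained = ve, center = pc$center)
}

#' Brownian-motion ancestral-state estimates at internal nodes
#'
#' GLS (maximum-likelihood) estimates under Brownian motion, computed
#' per trait: the root takes the GLS phylogenetic mean `a`, and node u
#' takes `a + C_uY C^-1 (Y - 1a)` where `C_uY[i]` is the shared path
#' length between node u and tip i (the depth of their most recent
#' common ancestor).
#'
#' @param tree An `ape::phylo` with n tips.
#' @param X n x q matrix of tip values, rownames = tip labels (a vector
#'   is treated as one trait).
#' @return (number of internal nodes) x q matrix; rownames are ape node
#'   numbers (`n+1` = root) as characters.
#' @export
ancestral_states <- function(tree, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L,
                                   dimnames = list(names(X), NULL))
  X <- as.matrix(X)
  n <- length(tree$tip.label)
  if (nrow(X) != n) .stopf("X must have one row per tip")
  if (is.null(rownames(X)) || !setequal(rownames(X), tree$tip.label))
    .stopf("rownames of X must match the tree's tip labels")
  X <- X[tree$tip.label, , drop = FALSE]
  r <- tree$root.edge %||% 0
  nn <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree) + r
  ## ancestor list per node (including itself), root = n+1
  parent <- integer(n + nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  anc_of <- function(v) {
    out <- v
    while (v != n + 1L) { v <- parent[v]; out <- c(out, v) }
    out
  }
  anc <- lapply(seq_len(n + nn), anc_of)
  C <- phylo_covariance(tree)  # tip order = tree$tip.label
  Cinv <- solve(C)
  one <- rep(1, n)
  a <- drop((crossprod(one, Cinv) %*% X) / drop(crossprod(one, Cinv %*% one)))
  resid <- sweep(X, 2, a)
  nodes <- n + seq_len(nn)
  ## shared path length of node u with tip i = depth of mrca(u, i)
  Cau <- matrix(0, nn, n)
  for (ui in seq_len(nn)) {
    u <- nodes[ui]
    au <- anc[[u]]
    for (i in seq_len(n)) {
      common <- intersect(au, anc[[i]])  # mrca = common ancestor of max depth
      Cau[ui, i] <- max(depth[common])
    }
  }
  est <- sweep(Cau %*% Cinv %*% resid, 2, a, `+`)
  dimnames(est) <- list(as.character(nodes), colnames(X))
  est
}

#' Project species and phylogeny into PC1-PC2 morphospace
#'
#' Runs [shape_pca()] on the species mean shapes, places tips at their
#' PC1-PC2 scores and internal nodes at Brownian-motion ancestral-state
#' estimates of the score columns (by linearity this equals estimating
#' ancestral shapes and projecting them), and records the tree edges
#' for drawing.
#'
#' @param tree Chronogram whose tip set equals the rownames of `Y`.
#' @param Y n x p species shape matrix (n >= 3).
#' @param groups Optional named vector taxon -> group, carried through
#'   for coloring.
#' @return Object of class `morphospace`: `tip_scores` (n x 2, rownames
#'   = taxa), `node_scores`, `edges` (2-column matrix of ape node
#'   numbers), `variance_explained`, `loadings` (p x 2), `taxa`,
#'   `groups`.
#' @export
phylomorphospace <- function(tree, Y, groups = NULL) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 3L) .stopf("need at least 3 taxa")
  if (!setequal(rownames(Y), tree$tip.label))
    .stopf("taxa of Y and tree differ; prune/match first")
  Y <- Y[tree$tip.label, , drop = FALSE]
  pc <- shape_pca(Y)
  tips <- pc$scores[, 1:2, drop = FALSE]
  colnames(tips) <- c("PC1", "PC2")
  nodes <- ancestral_states(tree, tips)
  colnames(nodes) <- c("PC1", "PC2")
  structure(list(
    tip_scores = tips,
    node_scores = nodes,
    edges = tree$edge,
    variance_explained = pc$variance_explained,
    loadings = pc$loadings[, 1:2, drop = FALSE],
    taxa = tree$tip.label,
    groups = if (!is.null(groups)) groups[tree$tip.label] else NULL),
    class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf(
    "<morphospace> %d tips, %d internal nodes; PC1 %.1f%%, PC2 %.1f%% of variance\n",
    nrow(x$tip_scores), nrow(x$node_scores),
    100 * x$variance_explained[1], 100 * x$variance_explained[2]))
  invisible(x)
}

#' Morphospace as a flat data frame (for CSV export / plotting)
#' @param x A `morphospace`.
#' @param ... Unused.
#' @return Data frame with columns `label`, `type` (tip/node), `PC1`,
#'   `PC2`, `group`.
#' @export
as.data.frame.morphospace <- function(x, ...) {
  n <- nrow(x$tip_scores)
  data.frame(
    label = c(rownames(x$tip_scores), rownames(x$node_scores)),
    type = rep(c("tip", "node"), c(n, nrow(x$node_scores))),
    PC1 = c(x$tip_scores[, 1], x$node_scores[, 1]),
    PC2 = c(x$tip_scores[, 2], x$node_scores[, 2]),
    group = c(if (is.null(x$groups)) rep(NA_character_, n) else
      as.character(x$groups), rep(NA_character_, nrow(x$node_scores))),
    row.names = NULL)
}

#' Plot a phylomorphospace (thin base-graphics layer)
#' @param x A `morphospace`.
#' @param ... Passed to `plot()`.
#' @export
plot.morphospace <- function(x, ...) {
  n <- nrow(x$tip_scores)
  all_pts <- rbind(x$tip_scores, x$node_scores)
  pts <- function(id) {
    if (id <= n) x$tip_scores[id, ] else x$node_scores[as.character(id), ]
  }
  plot(all_pts[, 1], all_pts[, 2], type = "n",
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$variance_explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$variance_explained[2]), ...)
  for (e in seq_len(nrow(x$edges))) {
    a <- pts(x$edges[e, 1]); b <- pts(x$edges[e, 2])
    graphics::segments(a[1], a[2], b[1], b[2], col = "grey60")
  }
  grp <- x$groups %||% rep("all", n)
  cols <- as.integer(factor(grp)) + 1L
  graphics::points(x$tip_scores[, 1], x$tip_scores[, 2], pch = 19,
                   col = cols)
  invisible(x)
}
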