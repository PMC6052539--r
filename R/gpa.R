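## Generalized Procrustes analysis for 2-D landmark configurations.
##
## Full Procrustes: each configuration is centred, scaled to unit
## centroid size, and iteratively rotated (rotations only, det = +1; a
## reflection would indicate a digitizing error since all specimens are
## imaged from the same side) to the evolving consensus. The final
## consensus is rotated to its principal axes with a deterministic sign
## convention so orientation is reproducible across runs and input
## orders.

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks from
#' their centroid — the size measure removed by superimposition.
#'
#' @param config A [landmark_config] or a k x 2 coordinate matrix.
#' @return A positive number.
#' @export
centroid_size <- function(config) {
  m <- if (inherits(config, "landmark_config")) config$coords else
    as.matrix(config)
  if (nrow(m) < 2L) .stopf("need at least 2 landmarks")
  ctr <- colMeans(m)
  cs <- sqrt(sum(sweep(m, 2, ctr)^2))
  if (cs <= 0) .stopf("degenerate configuration: all landmarks coincide")
  cs
}

## Optimal 2-D rotation of each row-configuration of X (S x 2k, x/y
## interleaved) onto the flat target (length 2k), closed form:
## maximize tr(R' B'A) with R a proper rotation.
.rotate_rows_to <- function(X, target) {
  k <- length(target) / 2L
  xi <- seq(1L, 2L * k, by = 2L)
  yi <- xi + 1L
  tx <- target[xi]; ty <- target[yi]
  a <- X[, xi, drop = FALSE] %*% tx + X[, yi, drop = FALSE] %*% ty
  b <- X[, xi, drop = FALSE] %*% ty - X[, yi, drop = FALSE] %*% tx
  r <- sqrt(a^2 + b^2)
  co <- ifelse(r > 0, a / r, 1)
  si <- ifelse(r > 0, b / r, 0)
  Xr <- X
  Xr[, xi] <- as.vector(co) * X[, xi, drop = FALSE] -
    as.vector(si) * X[, yi, drop = FALSE]
  Xr[, yi] <- as.vector(si) * X[, xi, drop = FALSE] +
    as.vector(co) * X[, yi, drop = FALSE]
  Xr
}

## Centre each row-configuration and scale it to unit centroid size.
## Returns list(X, cs).
.center_scale_rows <- function(X) {
  k <- ncol(X) / 2L
  xi <- seq(1L, 2L * k, by = 2L)
  yi <- xi + 1L
  X[, xi] <- X[, xi, drop = FALSE] - rowMeans(X[, xi, drop = FALSE])
  X[, yi] <- X[, yi, drop = FALSE] - rowMeans(X[, yi, drop = FALSE])
  cs <- sqrt(rowSums(X^2))
  if (any(cs <= 0)) .stopf("degenerate configuration in input")
  list(X = X / cs, cs = cs)
}

#' Generalized Procrustes superimposition
#'
#' Aligns configurations by translation, scaling (to unit centroid
#' size), and rotation, leaving pure shape variation. Convergence is
#' declared when the root summed squared change of the consensus falls
#' below `tol`.
#'
#' @param configs List of [landmark_config] objects (>= 2, common k).
#' @param tol Consensus convergence tolerance (default `1e-8`).
#' @param max_iter Maximum GPA iterations (default 100). Non-convergence
#'   is reported via `converged = FALSE`, not an error.
#' @param project_tangent Orthogonally project aligned shapes onto the
#'   tangent space at the consensus (off by default; at typical shape
#'   distances the difference is ~1e-6).
#' @return An object of class `gpa_fit`: `aligned` (S x 2k matrix,
#'   columns `lm1_x, lm1_y, ...`, rownames = specimen ids), `consensus`
#'   (k x 2), `centroid_sizes`, `iterations`, `converged`, `k`.
#' @export
align_gpa <- function(configs, tol = 1e-8, max_iter = 100L,
                      project_tangent = FALSE) {
  if (length(configs) < 2L) .stopf("need at least 2 configurations")
  ks <- vapply(configs, function(cfg) nrow(cfg$coords), 1L)
  if (length(unique(ks)) != 1L)
    .stopf("configurations have differing landmark counts")
  k <- ks[1]
  if (k < 3L) .stopf("need at least 3 landmarks for 2-D superimposition")
  X <- do.call(rbind, lapply(configs, function(cfg) .flatten(cfg$coords)))
  rownames(X) <- vapply(configs, `[[`, character(1), "specimen_id")
  colnames(X) <- .flat_names(k)
  cs0 <- .center_scale_rows(X)
  X <- cs0$X
  consensus <- X[1L, ]  # first configuration initializes the consensus
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    X <- .rotate_rows_to(X, consensus)
    new_cons <- colMeans(X)
    new_cons <- .flatten(scale_unit(.unflatten(new_cons)))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    .warnf("GPA did not converge in %d iterations", max_iter)
  ## Rotate everything to the principal axes of the consensus, with a
  ## deterministic sign convention (largest |loading| positive on axis 1;
  ## axis 2 sign fixed by det = +1).
  cm <- .unflatten(consensus)
  ev <- eigen(stats::cov(cm), symmetric = TRUE)
  V <- ev$vectors
  j <- which.max(abs(V[, 1]))
  if (V[j, 1] < 0) V[, 1] <- -V[, 1]
  if (det(V) < 0) V[, 2] <- -V[, 2]
  rot_flat <- function(M, V) .flatten(.unflatten(M) %*% V)
  consensus <- rot_flat(consensus, V)
  X <- t(apply(X, 1L, rot_flat, V = V))
  ## One final fit, then report the consensus as the arithmetic mean of
  ## the aligned configurations (the unit-rescaled reference is an
  ## iteration device only).
  X <- .rotate_rows_to(X, consensus)
  consensus <- colMeans(X)
  if (project_tangent) {
    u <- consensus / sqrt(sum(consensus^2))
    dev <- sweep(X, 2, consensus)
    dev <- dev - (dev %*% u) %*% t(u)
    X <- sweep(dev, 2, consensus, `+`)
  }
  dimnames(X) <- list(vapply(configs, `[[`, character(1), "specimen_id"),
                      .flat_names(k))
  structure(list(aligned = X,
                 consensus = .unflatten(consensus),
                 centroid_sizes = stats::setNames(cs0$cs, rownames(X)),
                 iterations = it,
                 converged = converged,
                 k = k,
                 tol = tol,
                 project_tangent = project_tangent),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf(
    "<gpa_fit> %d specimens, %d landmarks; %d iterations (%s)\n",
    nrow(x$aligned), x$k, x$iterations,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Centre a configuration and scale it to unit centroid size
#' @param m k x 2 coordinate matrix.
#' @return k x 2 matrix with centroid at the origin and centroid size 1.
#' @export
scale_unit <- function(m) {
  m <- sweep(as.matrix(m), 2, colMeans(m))
  m / sqrt(sum(m^2))
}

#' Full Procrustes distance between two configurations
#'
#' Both configurations are centred and scaled to unit centroid size,
#' the second is optimally rotated (no reflection) onto the first, and
#' the Frobenius distance is returned.
#'
#' @param a,b k x 2 coordinate matrices or [landmark_config]s.
#' @return Non-negative number.
#' @export
procrustes_distance <- function(a, b) {
  ga <- if (inherits(a, "landmark_config")) a$coords else as.matrix(a)
  gb <- if (inherits(b, "landmark_config")) b$coords else as.matrix(b)
  fa <- .flatten(scale_unit(ga))
  fb <- matrix(.flatten(scale_unit(gb)), nrow = 1L)
  sqrt(sum((.rotate_rows_to(fb, fa)[1L, ] - fa)^2))
}

#' Per-species mean shapes from aligned specimens
#'
#' @param fit A `gpa_fit` from [align_gpa()].
#' @param species_map Either a named character vector
#'   (specimen id -> species) or a data frame with columns
#'   `specimen`, `species`.
#' @return n x 2k matrix of species mean Procrustes coordinates,
#'   rownames = species (sorted), same column layout as `fit$aligned`.
#' @export
species_means <- function(fit, species_map) {
  if (is.data.frame(species_map)) {
    if (!all(c("specimen", "species") %in% names(species_map)))
      .stopf("species_map data frame needs columns 'specimen', 'species'")
    species_map <- stats::setNames(as.character(species_map$species),
                                   as.character(species_map$specimen))
  }
  ids <- rownames(fit$aligned)
  unmapped <- setdiff(ids, names(species_map))
  if (length(unmapped))
    .stopf("specimens without a species mapping: %s",
           paste(utils::head(unmapped, 5), collapse = ", "))
  sp <- species_map[ids]
  species <- sort(unique(sp))
  Y <- do.call(rbind, lapply(species, function(s)
    colMeans(fit$aligned[sp == s, , drop = FALSE])))
  dimnames(Y) <- list(species, colnames(fit$aligned))
  Y
}

#' Restrict a shape matrix to a subset of landmarks
#'
#' Keeps the x/y column pairs of the selected (1-based) landmark
#' indices; row (taxon) order is preserved.
#'
#' @param Y n x 2k shape matrix (columns `lm1_x, lm1_y, ...`).
#' @param indices 1-based landmark indices.
#' @return n x (2 |indices|) matrix.
#' @export
subset_landmarks <- function(Y, indices) {
  k <- ncol(Y) / 2L
  indices <- sort(unique(as.integer(indices)))
  if (!length(indices)) .stopf("empty landmark index set")
  if (any(indices < 1L | indices > k))
    .stopf("landmark index out of range 1..%d", k)
  Y[, .lm_cols(indices), drop = FALSE]
}

#' Export a shape matrix as CSV (taxon, lm1_x, lm1_y, ...)
#' @param Y Shape matrix with taxon rownames.
#' @param file Output path.
#' @export
write_shapes_csv <- function(Y, file) {
  df <- data.frame(taxon = rownames(Y), Y, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
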