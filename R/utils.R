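`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' @noRd
.assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    .stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

## Symmetric PSD matrix square root via eigendecomposition.
## Small negative eigenvalues (numerical noise) are clipped at zero; a
## negative eigenvalue below -1e-9 * max(eigenvalue) is a genuine PSD
## violation and errors.
.mat_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  lmax <- max(e$values, 0)
  if (any(e$values < -1e-9 * max(lmax, .Machine$double.eps)))
    .stopf("matrix is not positive semidefinite (min eigenvalue %.3g)",
           min(e$values))
  lam <- pmax(e$values, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

## Symmetric inverse square root; errors on (numerically) singular input.
.mat_inv_sqrt <- function(M, tol = 1e-12) {
  e <- eigen(M, symmetric = TRUE)
  lmax <- max(abs(e$values))
  if (min(e$values) <= tol * lmax)
    .stopf("matrix is singular within tolerance (min/max eigenvalue %.3g)",
           min(e$values) / lmax)
  e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
}

## Column names for flattened k x 2 configurations: lm1_x, lm1_y, lm2_x, ...
.flat_names <- function(k) {
  as.vector(rbind(paste0("lm", seq_len(k), "_x"),
                  paste0("lm", seq_len(k), "_y")))
}

## Columns of the flattened layout belonging to 1-based landmark indices.
.lm_cols <- function(idx) as.vector(rbind(2L * idx - 1L, 2L * idx))

## Flatten k x 2 -> length 2k (x/y interleaved); inverse of .unflatten.
.flatten <- function(m) as.vector(t(m))

.unflatten <- function(v) matrix(v, ncol = 2L, byrow = TRUE)

## Deterministic doubles -> text: round-trip exact under read-back.
.fmt_num <- function(x) sprintf("%.17g", x)
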