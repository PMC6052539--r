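## Module rate tests: do named landmark subsets (e.g. head vs. trunk)
## evolve at different net rates tree-wide, and does the clade rate
## ratio hold within each module?

#' Define a landmark partition into modules
#'
#' @param ... Named integer vectors of 1-based landmark indices (e.g.
#'   `head = c(1:8, 15:18), trunk = 9:14`). Sets must be non-empty and
#'   pairwise disjoint; landmarks outside every module are permitted
#'   (they are ignored by module statistics, with a note).
#' @param k Total number of landmarks in the scheme.
#' @return Object of class `module_partition` (named list of sorted
#'   index vectors with attribute `k`).
#' @export
module_partition <- function(..., k = 18L) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && is.null(names(sets)[1]))
    sets <- sets[[1]]
  if (length(sets) < 2L) .stopf("need at least 2 modules")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    .stopf("modules must be named")
  sets <- lapply(sets, function(s) sort(unique(as.integer(s))))
  if (any(vapply(sets, length, 1L) == 0L)) .stopf("empty module set")
  all_idx <- unlist(sets)
  if (anyDuplicated(all_idx)) .stopf("modules overlap")
  if (any(all_idx < 1L | all_idx > k))
    .stopf("landmark index out of range 1..%d", k)
  if (length(all_idx) < k)
    message(sprintf("note: %d landmark(s) outside all modules are ignored",
                    k - length(all_idx)))
  structure(sets, k = as.integer(k), class = "module_partition")
}

#' Default head/trunk partition of the 18-landmark scheme
#'
#' Head (trophic region): landmarks 1-8 and 15-18; trunk (locomotor
#' region): landmarks 9-14.
#'
#' @return A [module_partition()].
#' @export
default_partition <- function() {
  module_partition(head = c(1:8, 15:18), trunk = 9:14, k = 18L)
}

#' Per-module evolutionary rates from whitened data
#'
#' For module m spanning p_m = 2 |landmarks_m| traits,
#' `sigma2_m = sum_i ||Yt_i restricted to m||^2 / (n * p_m)`.
#'
#' @param Yt Whitened n x 2k matrix from [phylo_transform()].
#' @param partition A [module_partition()].
#' @return Named numeric vector of per-trait rates.
#' @export
module_rates <- function(Yt, partition) {
  if (!inherits(partition, "module_partition"))
    .stopf("'partition' must be a module_partition")
  k <- ncol(Yt) / 2L
  if (attr(partition, "k") != k)
    .stopf("partition is for k = %d landmarks, data have k = %d",
           attr(partition, "k"), k)
  n <- nrow(Yt)
  vapply(partition, function(idx) {
    cols <- .lm_cols(idx)
    sum(Yt[, cols, drop = FALSE]^2) / (n * length(cols))
  }, numeric(1))
}

#' Module rate-ratio test (are modules evolving at different rates?)
#'
#' Tests the observed max/min ratio of per-module rates (`R_mult`)
#' against `nsim` simulations under a common per-trait rate: the null
#' rate matrix is the whitened-residual trait covariance with each
#' module's block rescaled to the pooled per-trait rate (trait
#' correlations preserved), or isotropic on request.
#'
#' @inheritParams rate_ratio_test
#' @param partition A [module_partition()].
#' @return Object of class `modularity_result` with `sigma2_by_module`,
#'   `r_mult`, `ratio_modules`, `p_value`, `nsim`, `seed`.
#' @export
modularity_rate_test <- function(Y, tree, partition, nsim = 9999L,
                                 seed = NULL,
                                 null_cov = c("empirical", "isotropic")) {
  null_cov <- match.arg(null_cov)
  nsim <- .assert_scalar_count(nsim, "nsim", min = 1L)
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) .stopf("Y must have taxon rownames")
  if (!setequal(rownames(Y), tree$tip.label))
    .stopf("taxa of Y and tree differ; prune/match first")
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_covariance(tree, rownames(Y))
  tr <- phylo_transform(Y, C)
  rates <- module_rates(tr$Yt, partition)
  o <- order(rates, decreasing = TRUE)
  r_obs <- rates[o[1]] / rates[o[2]]
  ## Common per-trait rate over module-covered columns only.
  cols_by_mod <- lapply(partition, .lm_cols)
  cov_cols <- unlist(cols_by_mod)
  n <- nrow(Y)
  common <- sum(tr$Yt[, cov_cols, drop = FALSE]^2) / (n * length(cov_cols))
  ## Equalize the modules first (rescale each module's whitened columns
  ## to the common per-trait rate), then estimate the trait covariance
  ## of the rescaled residuals — so the null preserves correlations but
  ## carries no module rate difference.
  d <- rep(1, ncol(Y))
  for (m in names(partition)) d[cols_by_mod[[m]]] <- sqrt(common / rates[m])
  Ytd <- sweep(tr$Yt, 2, d, `*`)
  R <- .null_rate_matrix(Ytd, common, null_cov)
  Lr <- .mat_sqrt(R)
  stat_fun <- function(Yt_sim) {
    r <- vapply(cols_by_mod, function(cols)
      sum(Yt_sim[, cols, drop = FALSE]^2) / (n * length(cols)), numeric(1))
    max(r) / min(r)
  }
  sim <- .null_ratios(C, tr$P, tr$w, Lr, nsim, stat_fun)
  structure(list(
    sigma2_by_module = rates,
    r_mult = unname(r_obs),
    ratio_modules = c(numerator = names(rates)[o[1]],
                      denominator = names(rates)[o[2]]),
    p_value = (1 + sum(sim >= r_obs)) / (1 + nsim),
    nsim = nsim,
    seed = seed,
    trait_dim = stats::setNames(lengths(cols_by_mod), names(partition)),
    null_cov = null_cov), class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat("<modularity_result>\n")
  for (m in names(x$sigma2_by_module))
    cat(sprintf("  sigma2[%s] = %.4g  (%d traits)\n", m,
                x$sigma2_by_module[m], x$trait_dim[m]))
  cat(sprintf("  R_mult (%s / %s) = %.4g, p = %.4g  [nsim = %d]\n",
              x$ratio_modules["numerator"], x$ratio_modules["denominator"],
              x$r_mult, x$p_value, x$nsim))
  invisible(x)
}

#' Clade rate-ratio test restricted to one module
#'
#' Runs [rate_ratio_test()] on the columns of a single landmark module.
#' Because the whitening transform acts on rows only, subsetting
#' columns before or after the transform is equivalent; with
#' `module = all landmarks` and the same seed this reproduces the
#' overall test exactly.
#'
#' @inheritParams rate_ratio_test
#' @param module 1-based landmark indices of the module.
#' @export
within_module_clade_test <- function(Y, tree, groups, module,
                                     nsim = 9999L, seed = NULL,
                                     null_cov = c("empirical", "isotropic")) {
  rate_ratio_test(subset_landmarks(Y, module), tree, groups,
                  nsim = nsim, seed = seed, null_cov = null_cov)
}
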