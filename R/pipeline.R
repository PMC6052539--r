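## End-to-end orchestration: read inputs -> GPA -> species means ->
## prune/match -> overall, per-module, and modularity rate tests ->
## morphospace exports, with a machine-readable JSON report.

#' Build a run configuration
#'
#' @param tree Path to a newick chronogram.
#' @param tps Path to a TPS landmark file.
#' @param species_map Path to a CSV with columns `specimen`, `species`.
#' @param groups Path to a CSV with columns `species`, `group`.
#' @param partition A [module_partition()] (default head/trunk on 18
#'   landmarks).
#' @param nsim Null simulations per test (>= 99; default 9999).
#' @param seed Integer master seed; each test uses a fixed offset from
#'   it and the seeds are recorded in every output.
#' @param project_tangent,isotropic_null Analysis toggles.
#' @param strict_match Error (instead of prune + census) when shape and
#'   tree taxa disagree.
#' @param out_dir Optional output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(tree, tps, species_map, groups,
                       partition = default_partition(),
                       nsim = 9999L, seed = 1L,
                       project_tangent = FALSE, isotropic_null = FALSE,
                       strict_match = FALSE, out_dir = NULL) {
  cfg <- list(tree = tree, tps = tps, species_map = species_map,
              groups = groups, partition = partition,
              nsim = .assert_scalar_count(nsim, "nsim", min = 99L),
              seed = as.integer(seed),
              project_tangent = isTRUE(project_tangent),
              isotropic_null = isTRUE(isotropic_null),
              strict_match = isTRUE(strict_match),
              out_dir = out_dir)
  for (f in c("tree", "tps", "species_map", "groups"))
    if (!file.exists(cfg[[f]])) .stopf("config: %s file not found: %s",
                                       f, cfg[[f]])
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Relative paths are resolved against the JSON file's directory.
#' Recognized keys mirror the arguments of [run_config()]; `partition`
#' is a named list of 1-based landmark index vectors plus `k`.
#'
#' @param path Path to a JSON config.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (!is.null(p) && !grepl("^/", p))
    file.path(base, p) else p
  part <- if (is.null(j$partition)) default_partition() else {
    k <- j$partition$k %||% 18L
    module_partition(j$partition[setdiff(names(j$partition), "k")], k = k)
  }
  run_config(tree = resolve(j$tree), tps = resolve(j$tps),
             species_map = resolve(j$species_map),
             groups = resolve(j$groups), partition = part,
             nsim = j$nsim %||% 9999L, seed = j$seed %||% 1L,
             project_tangent = j$project_tangent %||% FALSE,
             isotropic_null = j$isotropic_null %||% FALSE,
             strict_match = j$strict_match %||% FALSE,
             out_dir = resolve(j$out_dir))
}

.load_inputs <- function(config) {
  tree <- read_newick(file = config$tree)
  configs <- read_tps(config$tps)
  smap_df <- utils::read.csv(config$species_map,
                             colClasses = "character")
  if (!all(c("specimen", "species") %in% names(smap_df)))
    .stopf("species map needs columns 'specimen', 'species'")
  gmap_df <- utils::read.csv(config$groups, colClasses = "character")
  if (!all(c("species", "group") %in% names(gmap_df)))
    .stopf("group map needs columns 'species', 'group'")
  list(tree = tree, configs = configs,
       species_map = stats::setNames(smap_df$species, smap_df$specimen),
       groups = stats::setNames(gmap_df$group, gmap_df$species))
}

#' Census of input agreement (no side effects)
#'
#' Counts specimens, species, and tree tips, and lists taxa present on
#' only one side of the shape-data/tree match.
#'
#' @param config A [run_config()] or path to a JSON config.
#' @return List: `n_specimens`, `n_species_shapes`, `n_tree_tips`,
#'   `n_matched`, `unmatched_shapes`, `unmatched_tips`,
#'   `unmapped_specimens`.
#' @export
validate_inputs <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  inp <- .load_inputs(config)
  ids <- vapply(inp$configs, `[[`, character(1), "specimen_id")
  mapped <- ids %in% names(inp$species_map)
  shape_species <- sort(unique(inp$species_map[ids[mapped]]))
  matched <- intersect(shape_species, inp$tree$tip.label)
  list(n_specimens = length(ids),
       n_species_shapes = length(shape_species),
       n_tree_tips = length(inp$tree$tip.label),
       n_matched = length(matched),
       unmatched_shapes = setdiff(shape_species, inp$tree$tip.label),
       unmatched_tips = setdiff(inp$tree$tip.label, shape_species),
       unmapped_specimens = ids[!mapped])
}

#' Run the full shape-rate analysis
#'
#' read -> GPA -> species means -> prune/match -> overall clade test ->
#' within-module clade tests -> module-ratio test -> morphospaces
#' (overall and per module). Taxa present in only one of tree/shapes
#' are dropped with a census (set `strict_match` to make that fatal);
#' zero matched taxa is always fatal.
#'
#' Sub-seeds are fixed offsets of `config$seed`: overall test `seed`,
#' per-module clade tests `seed + 1, 2, ...`, modularity test
#' `seed + 100`.
#'
#' @param config A [run_config()] or path to a JSON config.
#' @return Object of class `study_report`; when `out_dir` is set also
#'   writes `report.json`, `rates_table.csv`, `morphospace_*.csv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stage <- "read inputs"
  report <- tryCatch({
    inp <- .load_inputs(config)
    census <- validate_inputs(config)
    if (length(census$unmapped_specimens))
      .stopf("%d specimens have no species mapping",
             length(census$unmapped_specimens))
    if (census$n_matched == 0L) .stopf("zero taxa matched between shapes and tree")
    if (config$strict_match &&
        (length(census$unmatched_shapes) || length(census$unmatched_tips)))
      .stopf("taxon mismatch with strict_match=TRUE (%d/%d unmatched)",
             length(census$unmatched_shapes), length(census$unmatched_tips))
    stage <- "GPA"
    fit <- align_gpa(inp$configs, project_tangent = config$project_tangent)
    stage <- "species means"
    Y <- species_means(fit, inp$species_map)
    stage <- "prune/match"
    matched <- intersect(rownames(Y), inp$tree$tip.label)
    if (length(matched) < 3L) .stopf("fewer than 3 matched taxa")
    tree <- prune_to(inp$tree, matched)
    Y <- Y[tree$tip.label, , drop = FALSE]
    groups <- inp$groups[tree$tip.label]
    if (anyNA(groups)) .stopf("matched taxa missing from group map")
    null_cov <- if (config$isotropic_null) "isotropic" else "empirical"
    stage <- "overall rate test"
    overall <- rate_ratio_test(Y, tree, groups, nsim = config$nsim,
                               seed = config$seed, null_cov = null_cov)
    stage <- "within-module clade tests"
    per_module <- list()
    for (i in seq_along(config$partition)) {
      m <- names(config$partition)[i]
      per_module[[m]] <- within_module_clade_test(
        Y, tree, groups, config$partition[[m]], nsim = config$nsim,
        seed = config$seed + i, null_cov = null_cov)
    }
    stage <- "modularity rate test"
    modularity <- modularity_rate_test(Y, tree, config$partition,
                                       nsim = config$nsim,
                                       seed = config$seed + 100L,
                                       null_cov = null_cov)
    stage <- "morphospace"
    spaces <- list(overall = phylomorphospace(tree, Y, groups))
    for (m in names(config$partition))
      spaces[[m]] <- phylomorphospace(
        tree, subset_landmarks(Y, config$partition[[m]]), groups)
    structure(list(
      census = census,
      gpa = list(n_specimens = nrow(fit$aligned), iterations = fit$iterations,
                 converged = fit$converged),
      overall = overall,
      per_module = per_module,
      modularity = modularity,
      morphospace = lapply(spaces, function(s) list(
        variance_explained = s$variance_explained[1:2],
        tip_scores = s$tip_scores)),
      version = as.character(utils::packageVersion("shaperates")),
      config = list(nsim = config$nsim, seed = config$seed,
                    project_tangent = config$project_tangent,
                    isotropic_null = config$isotropic_null,
                    partition = lapply(unclass(config$partition),
                                       as.integer))),
      class = "study_report")
  }, error = function(e) {
    .stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(report_json(report),
               file.path(config$out_dir, "report.json"))
    utils::write.csv(rates_table(report),
                     file.path(config$out_dir, "rates_table.csv"),
                     row.names = FALSE)
    for (m in names(report$morphospace)) {
      df <- data.frame(label = rownames(report$morphospace[[m]]$tip_scores),
                       report$morphospace[[m]]$tip_scores)
      utils::write.csv(df,
                       file.path(config$out_dir,
                                 sprintf("morphospace_%s.csv", m)),
                       row.names = FALSE)
    }
  }
  report
}

#' Flat per-test rate table from a study report
#' @param report A `study_report`.
#' @return Data frame, one row per test.
#' @export
rates_table <- function(report) {
  row_of <- function(name, x) {
    g <- names(x$sigma2_by_group)
    data.frame(comparison = name,
               ratio = x$ratio,
               p_value = x$p_value,
               sigma2_1 = unname(x$sigma2_by_group[1]),
               group_1 = g[1],
               sigma2_2 = unname(x$sigma2_by_group[2]),
               group_2 = g[2],
               nsim = x$nsim, seed = x$seed, trait_dim = x$trait_dim)
  }
  out <- rbind(row_of("overall", report$overall),
               do.call(rbind, lapply(names(report$per_module), function(m)
                 row_of(m, report$per_module[[m]]))))
  mod <- report$modularity
  g <- names(mod$sigma2_by_module)
  rbind(out, data.frame(comparison = "modules", ratio = mod$r_mult,
                        p_value = mod$p_value,
                        sigma2_1 = unname(mod$sigma2_by_module[1]),
                        group_1 = g[1],
                        sigma2_2 = unname(mod$sigma2_by_module[2]),
                        group_2 = g[2],
                        nsim = mod$nsim, seed = mod$seed,
                        trait_dim = sum(mod$trait_dim)))
}

#' Serialize a study report as canonical JSON
#' @param report A `study_report`.
#' @return JSON string (deterministic for a fixed config + seed).
#' @export
report_json <- function(report) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  as.character(jsonlite::toJSON(strip(report), auto_unbox = TRUE,
                                digits = NA, null = "null",
                                pretty = TRUE))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d matched taxa, %d specimens\n",
              x$census$n_matched, x$census$n_specimens))
  print(x$overall)
  for (m in names(x$per_module)) { cat(m, ":\n"); print(x$per_module[[m]]) }
  print(x$modularity)
  invisible(x)
}
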