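## Known-truth synthetic studies: a two-clade chronogram, Brownian
## shape evolution with clade- and module-specific rates, specimen-level
## digitizing noise, and nuisance rotation/translation/scaling of the
## raw configurations written to TPS.

#' An 18-landmark fish-like template shape
#'
#' A stylized left-lateral body outline matching the standard
#' 18-landmark scheme (snout, mouth, jaw, neurocranium, eye ring,
#' dorsal/caudal/anal fin insertions, gill opening, pectoral fin),
#' centred at the origin and scaled to unit centroid size. Versioned
#' constant: changing it invalidates stored truth records.
#'
#' @return 18 x 2 coordinate matrix.
#' @export
goodeid_template <- function() {
  m <- matrix(c(
    0.00, 0.48,   # 1 anterior tip of snout
    0.02, 0.44,   # 2 opening of mouth
    0.10, 0.41,   # 3 posterior edge of jaw
    0.22, 0.60,   # 4 posterior edge of neurocranium (dorsal)
    0.10, 0.56,   # 5 upper edge of eye
    0.13, 0.52,   # 6 posterior edge of eye
    0.10, 0.48,   # 7 ventral edge of eye
    0.07, 0.52,   # 8 anterior edge of eye
    0.52, 0.68,   # 9 anterior insertion of dorsal fin
    0.70, 0.63,   # 10 posterior insertion of dorsal fin
    0.92, 0.56,   # 11 dorsal edge of caudal fin
    0.92, 0.40,   # 12 ventral edge of caudal fin
    0.56, 0.30,   # 13 anterior insertion of anal fin
    0.70, 0.34,   # 14 posterior insertion of anal fin
    0.20, 0.33,   # 15 gill opening at ventral margin
    0.26, 0.57,   # 16 posterior-most edge of neurocranium
    0.27, 0.46,   # 17 upper insertion of pectoral fin
    0.26, 0.38),  # 18 lower insertion of pectoral fin
    ncol = 2L, byrow = TRUE)
  scale_unit(m)
}

#' Generate a two-clade ultrametric chronogram
#'
#' The root split joins two clades at `root_age`; within-clade
#' topologies are seeded random coalescent trees rescaled so each crown
#' age is exact. Defaults mirror a 40-species vs. 4-species sister-pair
#' design with an 18.02 Myr root split and crown ages of 14.05 and
#' 6.88 Myr.
#'
#' @param n_clade1,n_clade2 Tip counts (>= 1 each).
#' @param root_age Root split age in Myr.
#' @param crown_ages Length-2 vector of crown ages (Myr), each strictly
#'   less than `root_age` (ignored for single-tip clades).
#' @param min_split Minimum species divergence age (Myr). Random
#'   branching processes produce arbitrarily recent splits, which real
#'   species-level chronograms do not have and which amplify
#'   finite-specimen measurement noise under phylogenetic whitening
#'   (contrast variance gets a `noise/branch-length` term); node ages
#'   are floored at this value. Default 0.25 Myr.
#' @param labels Length-2 character prefixes for tip names.
#' @param group_names Length-2 clade labels for the returned group map.
#' @param seed Optional integer seed.
#' @return List with `tree` (`phylo`) and `groups` (named vector
#'   taxon -> clade label).
#' @export
generate_chronogram <- function(n_clade1 = 40L, n_clade2 = 4L,
                                root_age = 18.02,
                                crown_ages = c(14.05, 6.88),
                                min_split = 0.25,
                                labels = c("G", "E"),
                                group_names = c("Goodeinae",
                                                "Empetrichthyinae"),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n1 <- .assert_scalar_count(n_clade1, "n_clade1")
  n2 <- .assert_scalar_count(n_clade2, "n_clade2")
  if (length(crown_ages) != 2L || any(crown_ages >= root_age) ||
      any(crown_ages < 0))
    .stopf("crown_ages must be two values in [0, root_age)")
  clade_newick <- function(n, crown, prefix) {
    tips <- sprintf("%s%02d", prefix, seq_len(n))
    if (n == 1L) return(list(token = tips, stem = root_age, tips = tips))
    ## Yule topology/heights (the prior behind published chronograms),
    ## rescaled to the crown age, with a floor on split ages.
    phy <- ape::rphylo(n, birth = 1, death = 0)
    phy$tip.label <- tips[as.integer(sub("^t", "", phy$tip.label))]
    depth <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * (crown / depth)
    phy <- .floor_split_ages(phy, crown, min(min_split, crown / 4))
    token <- sub(";$", "", ape::write.tree(phy, digits = 17))
    list(token = token, stem = root_age - crown, tips = tips)
  }
  c1 <- clade_newick(n1, crown_ages[1], labels[1])
  c2 <- clade_newick(n2, crown_ages[2], labels[2])
  txt <- sprintf("(%s:%s,%s:%s);", c1$token, .fmt_num(c1$stem),
                 c2$token, .fmt_num(c2$stem))
  tree <- read_newick(text = txt)
  groups <- stats::setNames(rep(group_names, c(n1, n2)),
                            c(c1$tips, c2$tips))
  list(tree = tree, groups = groups)
}

#' Assemble a truth record for a synthetic study
#'
#' Holds every parameter needed to regenerate a dataset bit-exactly.
#' Defaults state a world shaped like the motivating study: per-trait
#' per-Myr rates of 2e-4 vs. 1e-4 (true clade ratio 2.0), no module
#' rate difference, digitizing noise of 1% of centroid size, and 38
#' specimens per species (44 species x 38 ~ 1670 specimens).
#'
#' @param seed Integer seed driving all randomness downstream.
#' @param base_shape k x 2 ancestral template (unit centroid size).
#' @param sigma2_by_group Named per-trait per-Myr Brownian rates, one
#'   per clade label.
#' @param module_multipliers Named per-module multipliers of the
#'   per-trait rate (names must be modules of `partition`).
#' @param partition [module_partition()] giving the module layout.
#' @param specimen_noise_sd Isotropic digitizing noise sd, in units of
#'   the (unit) centroid size; a length-k vector gives per-landmark sds.
#' @param specimens_per_species Specimens digitized per species.
#' @param nuisance List with `rotation` (logical), `scale_range`
#'   (length 2), `translation_range` (scalar half-width) applied to raw
#'   configurations before writing.
#' @return Object of class `truth_record`.
#' @export
truth_record <- function(seed = 1L,
                         base_shape = goodeid_template(),
                         sigma2_by_group = c(Goodeinae = 2e-4,
                                             Empetrichthyinae = 1e-4),
                         module_multipliers = c(head = 1, trunk = 1),
                         partition = default_partition(),
                         specimen_noise_sd = 0.01,
                         specimens_per_species = 38L,
                         nuisance = list(rotation = TRUE,
                                         scale_range = c(80, 320),
                                         translation_range = 500)) {
  if (is.null(names(sigma2_by_group)) || any(sigma2_by_group < 0))
    .stopf("sigma2_by_group must be named and non-negative")
  if (!all(names(module_multipliers) %in% names(partition)))
    .stopf("module_multipliers names must match the partition")
  if (any(module_multipliers <= 0)) .stopf("multipliers must be positive")
  structure(list(seed = as.integer(seed),
                 base_shape = as.matrix(base_shape),
                 sigma2_by_group = sigma2_by_group,
                 module_multipliers = module_multipliers,
                 partition = partition,
                 specimen_noise_sd = specimen_noise_sd,
                 specimens_per_species =
                   .assert_scalar_count(specimens_per_species,
                                        "specimens_per_species"),
                 nuisance = nuisance),
            class = "truth_record")
}

## Floor internal-node ages of an ultrametric tree at `min_split`
## (pushing too-recent splits back in time), keeping the crown age and
## parent-older-than-child ordering, then rebuild branch lengths.
.floor_split_ages <- function(phy, crown, min_split) {
  n <- length(phy$tip.label)
  nn <- phy$Nnode
  depth <- ape::node.depth.edgelength(phy)
  age <- crown - depth
  age[seq_len(n)] <- 0
  idx_int <- n + seq_len(nn)
  age[idx_int] <- pmax(age[idx_int], min_split)
  age[n + 1L] <- crown  # root fixed at the crown age
  ## enforce parent strictly older than child, shallowest first
  eps <- min_split / 4
  repeat {
    moved <- FALSE
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      if (p != n + 1L && age[p] < age[ch] + eps) {
        age[p] <- age[ch] + eps
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  phy$edge.length <- age[phy$edge[, 1]] - age[phy$edge[, 2]]
  phy
}

## Per-edge clade assignment: rate of an edge is the rate of the clade
## of its descendant tips (edges are never shared between clades in a
## two-clade tree rooted at the split; a mixed edge gets the mean rate).
.edge_rates <- function(tree, groups, sigma2_by_group) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) {  # append each tip to all its ancestors
    v <- i
    repeat {
      desc[[v]] <- c(desc[[v]], i)
      if (v == root) break
      v <- parent[v]
    }
  }
  vapply(seq_len(nrow(tree$edge)), function(e) {
    tips <- tree$tip.label[desc[[tree$edge[e, 2]]]]
    mean(sigma2_by_group[unique(groups[tips])])
  }, numeric(1))
}

#' Simulate a complete landmark study with known truth
#'
#' Species mean shapes evolve by Brownian motion from `base_shape` in
#' its Procrustes tangent frame (so simulated means remain valid
#' shapes): each branch runs at its clade's per-trait rate, and module
#' columns are scaled by their rate multipliers. Specimens are the
#' species mean plus isotropic digitizing noise, then randomly rotated,
#' translated, and scaled ("digitizer units") before being written —
#' so superimposition has real work to do.
#'
#' @param tree Chronogram.
#' @param groups Named vector taxon -> clade label covering all tips.
#' @param truth A [truth_record()].
#' @param out_dir Optional directory; when given, writes
#'   `specimens.tps`, `tree.nwk`, `species_map.csv`, `groups.csv`,
#'   `truth.json`.
#' @return List with `configs` (list of [landmark_config]),
#'   `species_map` (named vector specimen -> species), `groups`,
#'   `species_means_true` (n x 2k, tangent-frame means), `tree`,
#'   `truth`.
#' @export
simulate_study <- function(tree, groups, truth = truth_record(),
                           out_dir = NULL) {
  stopifnot(inherits(truth, "truth_record"))
  missing <- setdiff(tree$tip.label, names(groups))
  if (length(missing))
    .stopf("tips without a clade label: %s",
           paste(utils::head(missing, 5), collapse = ", "))
  set.seed(truth$seed)
  k <- nrow(truth$base_shape)
  p <- 2L * k
  base_flat <- .flatten(truth$base_shape)
  ## clade-specific rates enter through branch rescaling
  scaled <- tree
  scaled$edge.length <- tree$edge.length *
    .edge_rates(tree, groups, truth$sigma2_by_group)
  Cs <- ape::vcv.phylo(scaled)[tree$tip.label, tree$tip.label] +
    (scaled$root.edge %||% 0)
  Ls <- .mat_sqrt(Cs)
  mult <- rep(1, p)
  for (m in names(truth$module_multipliers))
    mult[.lm_cols(truth$partition[[m]])] <- truth$module_multipliers[m]
  n <- length(tree$tip.label)
  dev <- Ls %*% matrix(stats::rnorm(n * p), n, p)
  dev <- sweep(dev, 2, sqrt(mult), `*`)
  ## Project deviations onto the Procrustes tangent space of the
  ## template: remove the scaling, rotation, and translation directions
  ## so the simulated means are pure shape deviations (otherwise GPA
  ## strips those components later, attenuating module rate contrasts
  ## asymmetrically).
  xi <- seq(1L, p, by = 2L)
  rot_b <- base_flat
  rot_b[xi] <- -base_flat[xi + 1L]
  rot_b[xi + 1L] <- base_flat[xi]
  U <- cbind(base_flat,                        # scale (unit norm already)
             rot_b / sqrt(sum(rot_b^2)),       # infinitesimal rotation
             rep(c(1, 0), k) / sqrt(k),        # x translation
             rep(c(0, 1), k) / sqrt(k))        # y translation
  dev <- dev - (dev %*% U) %*% t(U)
  means <- sweep(dev, 2, base_flat, `+`)
  dimnames(means) <- list(tree$tip.label, .flat_names(k))
  ## specimens: mean + digitizing noise, then nuisance transforms
  noise_sd <- rep(truth$specimen_noise_sd, length.out = k)
  ns <- truth$specimens_per_species
  nu <- truth$nuisance
  configs <- vector("list", n * ns)
  ids <- character(n * ns)
  sp_of <- character(n * ns)
  idx <- 0L
  for (i in seq_len(n)) {
    sp <- tree$tip.label[i]
    m0 <- .unflatten(means[i, ])
    for (j in seq_len(ns)) {
      idx <- idx + 1L
      cfg <- m0 + cbind(stats::rnorm(k, sd = noise_sd),
                        stats::rnorm(k, sd = noise_sd))
      if (isTRUE(nu$rotation)) {
        th <- stats::runif(1, -pi, pi)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
        cfg <- cfg %*% R
      }
      s <- stats::runif(1, nu$scale_range[1], nu$scale_range[2])
      tr <- stats::runif(2, -nu$translation_range, nu$translation_range)
      cfg <- s * cfg
      cfg[, 1] <- cfg[, 1] + tr[1]
      cfg[, 2] <- cfg[, 2] + tr[2]
      id <- sprintf("%s_s%03d", sp, j)
      configs[[idx]] <- landmark_config(cfg, id, sp)
      ids[idx] <- id
      sp_of[idx] <- sp
    }
  }
  species_map <- stats::setNames(sp_of, ids)
  out <- list(configs = configs, species_map = species_map,
              groups = groups[tree$tip.label], species_means_true = means,
              tree = tree, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tps(configs, file.path(out_dir, "specimens.tps"))
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    utils::write.csv(data.frame(specimen = ids, species = sp_of),
                     file.path(out_dir, "species_map.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(species = tree$tip.label,
                                group = unname(groups[tree$tip.label])),
                     file.path(out_dir, "groups.csv"), row.names = FALSE)
    writeLines(truth_json(truth), file.path(out_dir, "truth.json"))
  }
  out
}

#' Serialize a truth record as JSON
#' @param truth A [truth_record()].
#' @return JSON string.
#' @export
truth_json <- function(truth) {
  x <- unclass(truth)
  x$partition <- lapply(unclass(x$partition), as.integer)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE))
}

#' Packaged deterministic fixtures
#'
#' Registry of small, fully deterministic synthetic studies:
#' \describe{
#'   \item{`tiny-6taxa`}{6 species (4 + 2 clades), 3 specimens each;
#'     runs end-to-end in seconds.}
#'   \item{`paper-scale-44taxa`}{44 species split 40/4, root age 18.02
#'     Myr, 38 specimens per species (~1670 specimens).}
#' }
#'
#' @param name Fixture name.
#' @param dir Optional directory to write the file set to.
#' @return As [simulate_study()].
#' @export
make_fixture <- function(name, dir = NULL) {
  registry <- list(
    "tiny-6taxa" = function() {
      gc <- generate_chronogram(4L, 2L, seed = 601L)
      simulate_study(gc$tree, gc$groups,
                     truth_record(seed = 602L, specimens_per_species = 3L),
                     out_dir = dir)
    },
    "paper-scale-44taxa" = function() {
      gc <- generate_chronogram(40L, 4L, seed = 4401L)
      simulate_study(gc$tree, gc$groups,
                     truth_record(seed = 4402L,
                                  specimens_per_species = 38L),
                     out_dir = dir)
    })
  if (!name %in% names(registry))
    .stopf("unknown fixture '%s'; available: %s", name,
           paste(names(registry), collapse = ", "))
  registry[[name]]()
}
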