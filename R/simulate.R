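# Synthetic comparative-genomics data with the statistical structure the
# downstream analysis assumes: a Yule phylogeny, gene loss structured by
# functional class, convergent loss in a polyphyletic focal group, and
# genome sizes coupled to total gene content.
#
# Base gene loss follows a dispensability-threshold model: family f carries
# a per-exposure loss rate Lambda_f (class rate x gamma family effect) and a
# dispensability threshold E_f ~ Exp(1) shared across lineages; a lineage
# with cumulative loss exposure T has lost f iff Lambda_f * T >= E_f. The
# marginal per-lineage loss law is the usual 1 - exp(-Lambda_f T), but the
# ORDER in which families are lost is shared across lineages, so independent
# heavily-reduced lineages converge on the same retained core - the pattern
# the pan-genome clustering stage is designed to detect. Lineage exposure
# accumulates per edge as m_e * b_e with gamma rate multipliers m_e
# (loss-rate heterogeneity across lineages), and entering the focal niche
# lifts exposure to a common optimum (see evolve_gene_content).

#' Simulation configuration
#'
#' Collects all parameters of the synthetic-data generator. Defaults
#' reproduce the shape of the motivating study: 174 strains, a 2340-family
#' metabolic pan-genome, 21 functional classes, a 10-strain focal group
#' split over two phylogenetically distant clades, 16 planted focal-missing
#' families and 1 planted focal-specific family.
#'
#' @param n_strains Number of strains (tree leaves).
#' @param n_focal Number of focal strains.
#' @param n_focal_clades Number of disjoint monophyletic clades the focal
#'   strains are drawn from (2 makes the focal group polyphyletic).
#' @param n_families Number of metabolic gene families in the pan-genome.
#' @param n_classes Number of functional classes (must be
#'   `length(cog_classes())`).
#' @param class_weights Named probability vector over class codes used to
#'   assign families to classes; must sum to 1. Default: class G 0.09,
#'   class E 0.06, remainder uniform.
#' @param base_loss_prob Per-branch per-family loss probability at mean
#'   branch length for a class with loss scale 1.
#' @param class_loss_scale Named per-class multiplier on `base_loss_prob`
#'   (default G = 3, E = 2, others 1): carbohydrate genes are the most
#'   volatile under genome reduction.
#' @param n_planted_missing Number of planted focal-missing marker families.
#' @param n_planted_specific Number of planted focal-specific marker
#'   families.
#' @param focal_extra_loss Strength of the focal convergent-loss regime in
#'   \[0, 1\]. 0 disables the regime entirely (the control condition);
#'   planted-missing families additionally suffer this per-branch loss
#'   probability on branches within focal clades, and planted-specific
#'   families suffer it on all branches without focal descendants.
#' @param kb_per_gene Genome-size coupling, kilobases per gene.
#' @param size_noise_sd_mbp Gaussian noise on genome sizes, Mbp.
#' @param seed Integer seed; every random substream is derived from it.
#' @param family_rate_shape Shape of the gamma family-rate heterogeneity
#'   (mean 1). Smaller values widen the core/dispensable split.
#' @param edge_rate_shape Shape of the gamma per-edge lineage rate
#'   multipliers (mean 1), the source of genome-size spread.
#' @param niche_exposure_factor The focal niche optimum: entering a focal
#'   clade lifts lineage loss exposure to
#'   `niche_exposure_factor * focal_extra_loss` (tree depth units).
#' @param focal_class_bias Multiplier on the niche exposure lift for class
#'   G families (carbohydrate-biased reduction).
#' @param focal_damp Damping of within-clade exposure accrual after the
#'   niche shift (reduced genomes have little left to lose).
#' @param padding_genes Size of the non-metabolic genome at the root
#'   (genes); it shrinks deterministically with lineage exposure and is
#'   reported separately from the metabolic class counts.
#' @param planted_window Fractions of the niche optimum spanned by the
#'   planted-missing dispensability thresholds.
#' @return An object of class `simulation_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_strains = 12, n_families = 60, seed = 1)
#' cfg$n_focal
simulation_config <- function(n_strains = 174L,
                              n_focal = 10L,
                              n_focal_clades = 2L,
                              n_families = 2340L,
                              n_classes = 21L,
                              class_weights = NULL,
                              base_loss_prob = 0.02,
                              class_loss_scale = NULL,
                              n_planted_missing = 16L,
                              n_planted_specific = 1L,
                              focal_extra_loss = 0.5,
                              kb_per_gene = 1.0,
                              size_noise_sd_mbp = 0.05,
                              seed = 1L,
                              family_rate_shape = 1.0,
                              edge_rate_shape = 2.0,
                              niche_exposure_factor = 7.0,
                              focal_class_bias = 2.5,
                              focal_damp = 0.15,
                              padding_genes = 900L,
                              planted_window = c(0.3, 0.6)) {
  classes <- cog_classes()
  if (n_classes != length(classes)) {
    abort_format(sprintf("n_classes must be %d", length(classes)))
  }
  if (is.null(class_weights)) {
    class_weights <- setNames(rep((1 - 0.09 - 0.06) / (n_classes - 2), n_classes), classes)
    class_weights["G"] <- 0.09
    class_weights["E"] <- 0.06
  }
  if (is.null(class_loss_scale)) {
    class_loss_scale <- setNames(rep(1, n_classes), classes)
    class_loss_scale["G"] <- 3
    class_loss_scale["E"] <- 2
  }
  cfg <- list(
    n_strains = as.integer(n_strains), n_focal = as.integer(n_focal),
    n_focal_clades = as.integer(n_focal_clades),
    n_families = as.integer(n_families), n_classes = as.integer(n_classes),
    class_weights = class_weights, base_loss_prob = base_loss_prob,
    class_loss_scale = class_loss_scale,
    n_planted_missing = as.integer(n_planted_missing),
    n_planted_specific = as.integer(n_planted_specific),
    focal_extra_loss = focal_extra_loss, kb_per_gene = kb_per_gene,
    size_noise_sd_mbp = size_noise_sd_mbp, seed = as.integer(seed),
    family_rate_shape = family_rate_shape, edge_rate_shape = edge_rate_shape,
    niche_exposure_factor = niche_exposure_factor,
    focal_class_bias = focal_class_bias, focal_damp = focal_damp,
    padding_genes = as.integer(padding_genes),
    planted_window = planted_window
  )
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (abs(sum(class_weights) - 1) > 1e-12) {
      abort_format("class_weights must sum to 1")
    }
    probs <- c(base_loss_prob, focal_extra_loss)
    if (any(probs < 0 | probs > 1)) abort_format("probabilities must be in [0, 1]")
    if (n_focal > n_strains) abort_format("n_focal must not exceed n_strains")
    if (n_focal_clades > n_focal) abort_format("n_focal_clades must not exceed n_focal")
    if (n_planted_missing + n_planted_specific > n_families) {
      abort_format("planted families must not exceed n_families")
    }
    if (any(class_loss_scale < 0) || any(class_weights < 0)) {
      abort_format("class weights and loss scales must be non-negative")
    }
    if (size_noise_sd_mbp < 0 || kb_per_gene <= 0) {
      abort_format("kb_per_gene must be positive and size noise non-negative")
    }
  })
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d strains (%d focal in %d clades), %d families, seed %d\n",
    x$n_strains, x$n_focal, x$n_focal_clades, x$n_families, x$seed))
  invisible(x)
}

#' Simulate a Yule phylogeny
#'
#' A pure-birth (Yule) rooted binary ultrametric tree with exponential
#' waiting times, branch lengths rescaled so the root depth is 1, and leaf
#' labels `S1..Sn`.
#'
#' @param n_strains Number of leaves (at least 2).
#' @param seed Integer seed.
#' @return An `ape::phylo` object.
#' @export
#' @examples
#' tr <- simulate_tree(8, seed = 1)
#' ape::Ntip(tr)
simulate_tree <- function(n_strains, seed = 1L) {
  if (n_strains < 2) abort_format("n_strains must be at least 2")
  withr_seed(substream_seed(seed, "tree"))
  tr <- ape::rphylo(n_strains, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr$tip.label <- sprintf("S%d", seq_len(n_strains))
  tr
}

# set.seed scoped to the call (no global RNG side channel between stages)
withr_seed <- function(seed) {
  set.seed(seed)
  invisible(seed)
}

# list of tip index sets per edge (descendants of the edge's child node)
edge_descendants <- function(tree) {
  ntip <- ape::Ntip(tree)
  parts <- ape::prop.part(tree)
  lapply(seq_len(nrow(tree$edge)), function(i) {
    nd <- tree$edge[i, 2]
    if (nd <= ntip) nd else parts[[nd - ntip]]
  })
}

#' Select a polyphyletic focal group
#'
#' Draws `n_focal` leaves from `n_focal_clades` disjoint monophyletic
#' clades. For two or more clades the most recent common ancestor of the
#' focal set is forced to be the tree root, making the focal group
#' polyphyletic (the clades sit on opposite sides of the root). Clade
#' sizes are split as evenly as possible.
#'
#' @param tree An `ape::phylo` object.
#' @param n_focal Number of focal leaves.
#' @param n_focal_clades Number of clades (at most `n_focal`).
#' @param seed Integer seed.
#' @param max_tries Retry bound for the randomized clade search.
#' @return Character vector of focal leaf labels.
#' @export
select_focal_clades <- function(tree, n_focal, n_focal_clades = 2L, seed = 1L,
                                max_tries = 100L) {
  ntip <- ape::Ntip(tree)
  if (n_focal_clades > n_focal) abort_format("n_focal_clades must not exceed n_focal")
  if (n_focal > ntip) abort_format("n_focal must not exceed the number of leaves")
  if (n_focal == ntip) return(tree$tip.label)
  sizes <- rep(n_focal %/% n_focal_clades, n_focal_clades)
  rem <- n_focal %% n_focal_clades
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  parts <- ape::prop.part(tree)
  clade_tips <- c(as.list(seq_len(ntip)), parts)      # tips count as size-1 clades
  clade_sizes <- lengths(clade_tips)
  root <- ntip + 1L
  for (try in seq_len(max_tries)) {
    withr_seed(substream_seed(seed, "clades", try))
    chosen <- list()
    used <- integer(0)
    ok <- TRUE
    for (s in sizes) {
      cand <- which(clade_sizes == s &
                      !vapply(clade_tips, function(tp) any(tp %in% used), TRUE))
      if (!length(cand)) { ok <- FALSE; break }
      pick <- cand[sample.int(length(cand), 1)]
      chosen[[length(chosen) + 1]] <- clade_tips[[pick]]
      used <- c(used, clade_tips[[pick]])
    }
    if (!ok) next
    if (n_focal_clades >= 2) {
      mrca <- ape::getMRCA(tree, used)
      if (mrca != root) next
    }
    return(tree$tip.label[sort(used)])
  }
  abort_format("no valid focal clade arrangement found; try other sizes or a new tree")
}

# edge classification relative to the focal leaf set
focal_edge_flags <- function(tree, focal_ids) {
  ntip <- ape::Ntip(tree)
  focal_idx <- match(focal_ids, tree$tip.label)
  desc <- edge_descendants(tree)
  focal_edge <- vapply(desc, function(d) all(d %in% focal_idx), TRUE)
  nonfocal_edge <- vapply(desc, function(d) !any(d %in% focal_idx), TRUE)
  # stems: focal edges whose parent node is not itself below a focal edge
  below_focal <- tree$edge[focal_edge, 2]
  stem_edge <- focal_edge & !(tree$edge[, 1] %in% below_focal)
  list(focal = focal_edge, nonfocal = nonfocal_edge, stem = stem_edge)
}

#' Evolve gene content along a phylogeny
#'
#' Simulates loss-only gene-family evolution from an all-present ancestral
#' state. Base loss follows a dispensability-threshold model (see
#' `?simulate_dataset` and the package vignette): each family has a
#' per-exposure loss rate (class rate times a gamma family effect) and an
#' exponential dispensability threshold shared across lineages, so
#' independent heavily-reduced lineages lose the same families. Lineage
#' exposure accumulates along edges with gamma rate multipliers; the stem
#' of each focal clade lifts exposure to a common niche optimum
#' (`niche_exposure_factor * focal_extra_loss`), with class G experiencing
#' the lift `focal_class_bias`-fold. Planted focal-missing families are
#' core families whose dispensability threshold sits inside the niche
#' window, and additionally suffer per-branch Bernoulli loss
#' `focal_extra_loss` on branches within focal clades; planted
#' focal-specific families are lost with probability `focal_extra_loss` on
#' every branch without focal descendants. Lost families are never
#' regained.
#'
#' @param tree An `ape::phylo` tree (leaf labels are strain ids).
#' @param config A [simulation_config()].
#' @param focal_ids Character vector of focal leaf labels.
#' @return A list with elements `presence` (0/1 integer matrix, families x
#'   strains), `classes` (named character vector of class codes per
#'   family), `truth` (planted family ids and per-family loss rates) and
#'   `exposure` (per-strain realized loss exposures, used by
#'   [simulate_dataset()] for the analytic coupling slopes).
#' @export
evolve_gene_content <- function(tree, config, focal_ids = character(0)) {
  validate_config(config)
  ntip <- ape::Ntip(tree)
  nfam <- config$n_families
  classes <- cog_classes()
  flags <- focal_edge_flags(tree, focal_ids)

  withr_seed(substream_seed(config$seed, "content"))
  cls <- sample(classes, nfam, replace = TRUE, prob = config$class_weights[classes])
  miss_id <- seq_len(config$n_planted_missing)
  spec_id <- config$n_planted_missing + seq_len(config$n_planted_specific)
  cls[c(miss_id, spec_id)] <- "G"        # planted markers are carbohydrate genes
  fam_ids <- sprintf("K%05d", seq_len(nfam))

  # per-unit-exposure loss rates, calibrated so one mean-length branch at
  # unit rate multiplier loses a class-c family with probability
  # base_loss_prob * class_loss_scale[c]
  bbar <- mean(tree$edge.length)
  lam_class <- -log(1 - config$base_loss_prob * config$class_loss_scale[classes]) / bbar
  g <- rgamma(nfam, config$family_rate_shape, config$family_rate_shape)
  lam <- lam_class[cls] * g
  ef <- rexp(nfam)

  delta <- config$niche_exposure_factor * config$focal_extra_loss
  # planted-missing: core families dispensable only under the niche shift
  lam[miss_id] <- 1
  ef[miss_id] <- if (delta > 0) {
    1 + delta * runif(config$n_planted_missing,
                      config$planted_window[1], config$planted_window[2])
  } else Inf
  lam[spec_id] <- 0
  ef[spec_id] <- Inf
  bias <- ifelse(cls == "G", config$focal_class_bias, 1)
  bias[c(miss_id, spec_id)] <- 1

  nedge <- nrow(tree$edge)
  m <- rgamma(nedge, config$edge_rate_shape, config$edge_rate_shape)
  u <- m * tree$edge.length
  inclade <- flags$focal & !flags$stem
  u[inclade] <- u[inclade] * if (config$focal_extra_loss > 0) config$focal_damp else 1

  depths <- ape::node.depth.edgelength(tree)
  ord <- order(depths[tree$edge[, 1]])   # preorder: parents before children
  nnode <- ntip + tree$Nnode
  present <- matrix(TRUE, nnode, nfam)
  t_base <- numeric(nnode)
  t_lift <- numeric(nnode)
  for (i in ord) {
    par <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    t_base[ch] <- t_base[par] + u[i]
    t_lift[ch] <- t_lift[par]
    if (flags$stem[i]) {
      t_lift[ch] <- t_lift[ch] + max(0, delta - (t_base[ch] + t_lift[ch]))
    }
    keep <- lam * (t_base[ch] + bias * t_lift[ch]) < ef
    if (flags$focal[i] && config$focal_extra_loss > 0) {
      keep[miss_id] <- keep[miss_id] &
        (runif(config$n_planted_missing) > config$focal_extra_loss)
    }
    if (flags$nonfocal[i] && config$focal_extra_loss > 0) {
      keep[spec_id] <- keep[spec_id] &
        (runif(config$n_planted_specific) > config$focal_extra_loss)
    }
    present[ch, ] <- present[par, ] & keep
  }

  presence <- t(present[seq_len(ntip), , drop = FALSE]) * 1L
  dimnames(presence) <- list(fam_ids, tree$tip.label)
  names(cls) <- fam_ids

  # number of focal-free edges on each leaf's root path (for the expected
  # retention of planted-specific families)
  nonfocal_path <- numeric(ntip)
  node_nf <- numeric(nnode)
  for (i in ord) {
    par <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    node_nf[ch] <- node_nf[par] + as.numeric(flags$nonfocal[i])
  }
  nonfocal_path <- node_nf[seq_len(ntip)]

  list(
    presence = presence,
    classes = cls,
    truth = list(planted_missing = fam_ids[miss_id],
                 planted_specific = fam_ids[spec_id],
                 loss_rate = setNames(lam, fam_ids),
                 threshold = setNames(ef, fam_ids)),
    exposure = list(base = setNames(t_base[seq_len(ntip)], tree$tip.label),
                    lift = setNames(t_lift[seq_len(ntip)], tree$tip.label),
                    nonfocal_edges = setNames(nonfocal_path, tree$tip.label),
                    lam = lam, bias = bias, cls = cls, delta = delta,
                    bbar = bbar)
  )
}

#' Couple genome sizes to gene content
#'
#' Genome size is total gene count (metabolic families plus non-metabolic
#' padding) times `kb_per_gene`, converted to Mbp, plus Gaussian noise,
#' truncated below at 0.5 Mbp.
#'
#' @param class_counts Tibble with `strain_id` and one count column per
#'   class (as from [read_class_counts()]).
#' @param padding Non-metabolic gene count per strain (scalar or vector
#'   aligned with `class_counts` rows).
#' @param kb_per_gene Kilobases per gene.
#' @param size_noise_sd_mbp Gaussian noise standard deviation, Mbp.
#' @param seed Integer seed.
#' @return Named numeric vector of genome sizes (Mbp) per strain.
#' @export
couple_genome_sizes <- function(class_counts, padding = 0,
                                kb_per_gene = 1.0, size_noise_sd_mbp = 0.05,
                                seed = 1L) {
  counts <- as.matrix(class_counts[setdiff(names(class_counts), "strain_id")])
  total <- rowSums(counts) + padding
  withr_seed(substream_seed(seed, "sizes"))
  size <- total * kb_per_gene / 1000 + rnorm(length(total), 0, size_noise_sd_mbp)
  size <- pmax(size, 0.5)
  setNames(size, class_counts$strain_id)
}

# analytic (expectation-level) per-class coupling slopes, conditional on the
# realized tree, family rates and lineage exposures: OLS of expected class
# counts on expected genome size, free of presence sampling and size noise
true_coupling_slopes <- function(evo, config) {
  ex <- evo$exposure
  ntip <- length(ex$base)
  nfam <- length(ex$lam)
  t_eff <- outer(ex$base, rep(1, nfam)) + outer(ex$lift, ex$bias)
  ep <- exp(-rep(ex$lam, each = ntip) * t_eff)
  miss <- match(evo$truth$planted_missing, names(ex$cls))
  spec <- match(evo$truth$planted_specific, names(ex$cls))
  if (ex$delta > 0) {
    lo <- 1 + ex$delta * config$planted_window[1]
    hi <- 1 + ex$delta * config$planted_window[2]
    pmiss <- pmin(pmax((hi - t_eff[, miss, drop = FALSE]) / (hi - lo), 0), 1)
    ep[, miss] <- pmiss
    ep[, spec] <- (1 - config$focal_extra_loss)^ex$nonfocal_edges
  } else {
    ep[, miss] <- 1
    ep[, spec] <- 1
  }
  lam_pad <- -log(1 - config$base_loss_prob) / ex$bbar
  pad <- config$padding_genes * exp(-lam_pad * (ex$base + ex$lift))
  exp_size <- (rowSums(ep) + pad) * config$kb_per_gene / 1000
  classes <- cog_classes()
  slopes <- vapply(classes, function(cl) {
    y <- rowSums(ep[, ex$cls == cl, drop = FALSE])
    unname(coef(lm(y ~ exp_size))[2])
  }, numeric(1))
  tibble::tibble(class = classes, true_slope = unname(slopes))
}

#' Simulate a complete comparative-genomics dataset
#'
#' Composes [simulate_tree()], [select_focal_clades()],
#' [evolve_gene_content()] and [couple_genome_sizes()] into one bundle:
#' tree, strain metadata, per-class gene counts, presence/absence matrix
#' and the planted truth (marker family ids and analytic per-class
#' size-coupling slopes). Pure: writes nothing, deterministic given
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_bundle`: a list with elements
#'   `tree` (`phylo`), `metadata` (tibble), `class_counts` (tibble),
#'   `presence` (tibble with `family_id` column), `truth` (list: planted
#'   ids, analytic slopes, padding counts, exposures) and `config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_strains = 16, n_families = 80,
#'                          n_focal = 4, padding_genes = 40, seed = 7)
#' b <- simulate_dataset(cfg)
#' b$metadata
simulate_dataset <- function(config) {
  validate_config(config)
  tree <- NULL
  focal <- NULL
  for (try in seq_len(25L)) {
    tree <- simulate_tree(config$n_strains,
                          seed = substream_seed(config$seed, "dataset", try))
    focal <- tryCatch(
      select_focal_clades(tree, config$n_focal, config$n_focal_clades,
                          seed = substream_seed(config$seed, "pick", try)),
      error = function(e) NULL)
    if (!is.null(focal)) break
  }
  if (is.null(focal)) abort_format("could not place focal clades; adjust configuration")

  evo <- evolve_gene_content(tree, config, focal)

  classes <- cog_classes()
  counts <- t(rowsum((evo$presence), group = evo$classes[rownames(evo$presence)]))
  # ensure every class column exists even if empty
  full <- matrix(0L, nrow(counts), length(classes),
                 dimnames = list(rownames(counts), classes))
  full[, colnames(counts)] <- counts
  class_counts <- tibble::as_tibble(full, rownames = "strain_id")

  lam_pad <- -log(1 - config$base_loss_prob) / evo$exposure$bbar
  exposure_total <- evo$exposure$base + evo$exposure$lift
  padding <- round(config$padding_genes * exp(-lam_pad * exposure_total))

  sizes <- couple_genome_sizes(class_counts, padding = padding,
                               kb_per_gene = config$kb_per_gene,
                               size_noise_sd_mbp = config$size_noise_sd_mbp,
                               seed = substream_seed(config$seed, "noise"))

  # phylogenetic group labels from the tree itself (coarse clades)
  k_groups <- min(20L, config$n_strains)
  grp <- cutree(stats::as.hclust(tree), k = k_groups)
  metadata <- tibble::tibble(
    strain_id = tree$tip.label,
    genome_size_mbp = unname(sizes[tree$tip.label]),
    group = sprintf("G%02d", grp[tree$tip.label]),
    is_focal = tree$tip.label %in% focal,
    padding_genes = as.integer(padding[tree$tip.label])
  )

  truth <- list(
    classes = evo$classes,
    planted_missing = evo$truth$planted_missing,
    planted_specific = evo$truth$planted_specific,
    true_slopes = true_coupling_slopes(evo, config),
    focal_ids = focal,
    padding = setNames(as.integer(padding), tree$tip.label),
    exposure = exposure_total
  )

  structure(list(
    tree = tree,
    metadata = metadata,
    class_counts = class_counts,
    presence = tibble::as_tibble(evo$presence, rownames = "family_id"),
    truth = truth,
    config = config
  ), class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bundle> %d strains (%d focal), %d families, sizes %.2f-%.2f Mbp\n",
    nrow(x$metadata), sum(x$metadata$is_focal), nrow(x$presence),
    min(x$metadata$genome_size_mbp), max(x$metadata$genome_size_mbp)))
  invisible(x)
}

#' Write a synthetic bundle to a directory
#'
#' Writes `metadata.tsv`, `class_counts.tsv`, `presence.tsv`, `tree.nwk`
#' and `truth.json` under `dir`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_metadata(bundle$metadata[, c("strain_id", "genome_size_mbp",
                                            "group", "is_focal")],
                        file.path(dir, "metadata.tsv"))
  write_class_counts(bundle$class_counts, file.path(dir, "class_counts.tsv"))
  write_presence_matrix(bundle$presence, file.path(dir, "presence.tsv"))
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  truth <- bundle$truth
  truth$true_slopes <- as.list(setNames(truth$true_slopes$true_slope,
                                        truth$true_slopes$class))
  truth$exposure <- NULL
  truth$classes <- NULL
  truth$padding <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
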