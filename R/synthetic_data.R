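# Ground-truth generators. Every generator is a pure function of
# (seed, config): one global seed fans out to per-generator substreams via
# a fixed counter scheme, so adding a generator never perturbs the outputs
# of the others. Defaults state the world the pipeline expects: clusters
# of binding sites roughly 600 bp wide with geometric within-cluster gaps
# of mean 46 bp on a single 10-Mb test chromosome.

substream_seed <- function(seed, component) {
  as.integer((as.numeric(seed) * 48271 + component * 96731) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Default landscape generator configuration
#'
#' @param genome_length chromosome length in bp (default 10 Mb).
#' @param chrom chromosome name (default "chrS1").
#' @param n_cells number of cell types (default 6).
#' @param n_tfs TF alphabet size (default 50).
#' @param n_clusters planted cluster loci (default 300).
#' @param sites_per_cluster_mean mean sites per cluster (default 8; the
#'   count is `1 + Poisson(mean - 1)` so every cluster has a site).
#' @param gap_mean within-cluster gap mean in bp (default 46, geometric).
#' @param min_separation minimum distance between cluster start points
#'   (default 5000 bp, comfortably above twice the contribution cutoff so
#'   planted clusters are recoverable one-to-one).
#' @param share_prob probability a cluster is present in each cell type
#'   (default 0.6; clusters absent everywhere are given one random cell).
#' @param site_width width of each site interval (default 10 bp).
#' @export
landscape_config <- function(genome_length = 1e7, chrom = "chrS1",
                             n_cells = 6L, n_tfs = 50L, n_clusters = 300L,
                             sites_per_cluster_mean = 8,
                             gap_mean = 46, min_separation = 5000,
                             share_prob = 0.6, site_width = 10L) {
  list(genome_length = genome_length, chrom = chrom, n_cells = n_cells,
       n_tfs = n_tfs, n_clusters = n_clusters,
       sites_per_cluster_mean = sites_per_cluster_mean,
       gap_mean = gap_mean, min_separation = min_separation,
       share_prob = share_prob, site_width = site_width)
}

#' Generate a multi-cell TFBS landscape with known cluster truth
#'
#' Cluster loci are placed with a guaranteed minimum separation; each
#' cluster lays down sites with geometric (mean `gap_mean`) gaps and a
#' random TF per site, and is shared across cell types under a Bernoulli
#' sharing model.
#'
#' @param config a [landscape_config()].
#' @param seed global seed.
#' @return list of class `landscape`: `records` (TFBS table over all
#'   cells), `cells` (named list of per-cell tables), `truth` (data.frame
#'   per cluster: `cluster`, `centre`, `n_sites`, `n_tfs`, `cells`
#'   comma-joined), `config`, `seed`.
#' @export
gen_tfbs_landscape <- function(config = landscape_config(), seed = 1L) {
  cfg <- config
  with_seed(substream_seed(seed, 1L), {
    est_width <- cfg$sites_per_cluster_mean * cfg$gap_mean * 4
    free <- cfg$genome_length - cfg$n_clusters * (cfg$min_separation +
                                                    est_width)
    if (free <= 0) stop("clusters overflow genome")
    starts <- sort(runif(cfg$n_clusters) * free) +
      (seq_len(cfg$n_clusters) - 1L) * (cfg$min_separation + est_width) +
      cfg$min_separation / 2
    starts <- floor(starts)
    recs <- NULL
    truth <- NULL
    cells <- paste0("cell", seq_len(cfg$n_cells))
    for (cl in seq_len(cfg$n_clusters)) {
      k <- 1L + rpois(1, cfg$sites_per_cluster_mean - 1)
      gaps <- if (k > 1L) rgeom(k - 1L, 1 / cfg$gap_mean) + 1L else integer(0)
      pos <- starts[cl] + cumsum(c(0L, gaps))
      tfs <- paste0("TF", sample.int(cfg$n_tfs, k, replace = TRUE))
      present <- which(runif(cfg$n_cells) < cfg$share_prob)
      if (!length(present)) present <- sample.int(cfg$n_cells, 1L)
      hw <- cfg$site_width %/% 2L
      df <- data.frame(chrom = cfg$chrom, start = pos - hw,
                       end = pos - hw + cfg$site_width, tf_id = tfs,
                       cluster = cl, stringsAsFactors = FALSE)
      for (ci in present) {
        d <- df; d$cell_type <- cells[ci]
        recs <- rbind(recs, d)
      }
      truth <- rbind(truth, data.frame(
        cluster = cl, centre = floor((min(pos) + max(pos)) / 2),
        n_sites = k, n_tfs = length(unique(tfs)),
        cells = paste(cells[present], collapse = ","),
        stringsAsFactors = FALSE))
    }
    if (max(recs$end) > cfg$genome_length) stop("clusters overflow genome")
    recs <- recs[order(recs$cell_type, recs$chrom, recs$start), ,
                 drop = FALSE]
    rownames(recs) <- NULL
    structure(list(records = recs,
                   cells = split(recs, recs$cell_type),
                   truth = truth, config = cfg, seed = seed),
              class = "landscape")
  })
}

#' Generate a nucleosome occupancy track with planted structure
#'
#' Baseline 1.0; an oscillation of the given period phased outward from
#' each region edge (zero inside the region) whose amplitude decays
#' exponentially with distance from the edge, as positioned nucleosome
#' arrays do; a Gaussian dip of depth `depletion_depth` at each region
#' centre; and additive Gaussian noise. Overlapping regions have their
#' deviations summed (with a warning).
#'
#' @param regions region table (windows; anchors are their centres).
#' @param period oscillation period in bp (default 200).
#' @param amplitude oscillation amplitude at the region edge (default
#'   0.3).
#' @param depletion_depth central dip depth (default 0.5).
#' @param noise_sd Gaussian noise sd (default 0.05).
#' @param flank bp of track generated beyond each region (default 2500).
#' @param dip_sd Gaussian dip sd in bp (default 300; near-flat across the
#'   +/-50 bp centre window and negligible at 2 kb).
#' @param decay_tau e-folding distance of the oscillation amplitude in bp
#'   (default 500, a few nucleosomal repeats; keeps the 2-kb background
#'   windows essentially oscillation-free).
#' @param seed global seed.
#' @return list of class `occupancy_truth`: `track` (a `signal_track`),
#'   `period`, `amplitude`, `depletion_depth`, `seed`.
#' @export
gen_occupancy_track <- function(regions, period = 200, amplitude = 0.3,
                                depletion_depth = 0.5, noise_sd = 0.05,
                                flank = 2500L, dip_sd = 300,
                                decay_tau = 500, seed = 1L) {
  if (period <= 0) stop("period must be positive")
  with_seed(substream_seed(seed, 2L), {
    centre <- floor((regions$start + regions$end) / 2)
    halfw <- (regions$end - regions$start) / 2
    gre <- GenomicRanges::reduce(gr0(
      data.frame(chrom = regions$chrom, start = pmax(centre - flank, 0),
                 end = centre + flank)))
    if (length(gre) < nrow(regions))
      warning("overlapping regions: planted deviations are summed")
    rles <- list()
    spans <- df0(gre)
    for (chrom in unique(spans$chrom)) {
      sp <- spans[spans$chrom == chrom, , drop = FALSE]
      L <- max(sp$end)
      v <- numeric(L)
      covered <- logical(L)
      for (i in seq_len(nrow(sp))) {
        idx <- (sp$start[i] + 1L):sp$end[i]
        v[idx] <- 1
        covered[idx] <- TRUE
      }
      sel <- which(regions$chrom == chrom)
      for (i in sel) {
        idx <- (pmax(centre[i] - flank, 0) + 1L):min(centre[i] + flank, L)
        d <- (idx - 1L) - centre[i]
        osc <- ifelse(abs(d) >= halfw[i],
                      amplitude * exp(-(abs(d) - halfw[i]) / decay_tau) *
                        cos(2 * pi * (abs(d) - halfw[i]) / period),
                      0)
        dip <- depletion_depth * exp(-d^2 / (2 * dip_sd^2))
        v[idx] <- v[idx] + osc - dip
      }
      if (noise_sd > 0) {
        nz <- which(covered)
        v[nz] <- v[nz] + rnorm(length(nz), 0, noise_sd)
      }
      v[!covered] <- 0
      rles[[chrom]] <- S4Vectors::Rle(v)
    }
    structure(list(track = new_signal_track(rles), period = period,
                   amplitude = amplitude,
                   depletion_depth = depletion_depth, seed = seed),
              class = "occupancy_truth")
  })
}

#' Generate a lineage dataset along a known tree
#'
#' Every branch of the (rooted, binary) tree gains a fresh block of
#' non-overlapping elements; each leaf's region set is the union of the
#' gains on its root path. No losses, so clustering the leaves recovers
#' the generating topology.
#'
#' @param tree_newick Newick string (or `phylo` object).
#' @param gains_per_branch elements gained per branch: a scalar, or a
#'   named vector keyed by the edge's child (tip label, or internal node
#'   number as character) with unnamed branches defaulting to 0
#'   (default 60 everywhere).
#' @param clock when TRUE, the scalar `gains_per_branch` is scaled by the
#'   drop in node age across each branch (age 0 at tips, parent age =
#'   1 + max child age), so every root-to-tip path accumulates the same
#'   number of elements. This makes the presence distance ultrametric --
#'   the regime in which nearest-neighbour clustering provably recovers
#'   the generating topology even for unbalanced trees.
#' @param element_width element width in bp (default 500).
#' @param gap gap between consecutive elements in bp (default 200).
#' @param chrom chromosome name (default "chrS1").
#' @param genome_length available genome (default 10 Mb).
#' @param seed global seed (randomises the element-block layout and the
#'   inter-element gaps; the truth structure is unaffected).
#' @return list of class `lineage_truth`: `leaf_regions` (named list of
#'   region tables), `tree` (`phylo`), `branch_elements` (list of element
#'   tables per edge, named by child node), `seed`.
#' @export
gen_lineage_dataset <- function(tree_newick, gains_per_branch = 60L,
                                element_width = 500L, gap = 200L,
                                chrom = "chrS1", genome_length = 1e7,
                                clock = FALSE, seed = 1L) {
  phy <- if (inherits(tree_newick, "phylo")) tree_newick
         else ape::read.tree(text = tree_newick)
  if (is.null(phy)) stop("could not parse tree")
  n_edge <- nrow(phy$edge)
  child_key <- ifelse(phy$edge[, 2] <= length(phy$tip.label),
                      phy$tip.label[phy$edge[, 2]],
                      as.character(phy$edge[, 2]))
  if (clock) {
    if (!is.null(names(gains_per_branch)))
      stop("clock mode takes a scalar gains_per_branch")
    age <- node_ages(phy)
    gains <- as.integer(gains_per_branch *
                          (age[phy$edge[, 1]] - age[phy$edge[, 2]]))
  } else if (is.null(names(gains_per_branch))) {
    gains <- rep(as.integer(gains_per_branch), length.out = n_edge)
  } else {
    gains <- integer(n_edge)
    found <- names(gains_per_branch) %in% child_key
    if (!all(found))
      stop("unknown branch name(s): ",
           paste(names(gains_per_branch)[!found], collapse = ", "))
    gains[match(names(gains_per_branch), child_key)] <-
      as.integer(gains_per_branch)
  }
  total <- sum(gains)
  if (total * (element_width + gap) > genome_length)
    stop("element supply exceeds genome")
  with_seed(substream_seed(seed, 3L), {
    # non-overlapping elements with jittered gaps, shuffled over branches
    gaps_bp <- gap + rgeom(total, 1 / max(gap, 1))
    el_start <- cumsum(c(0, (element_width + gaps_bp)[-total]))
    el_order <- sample.int(max(total, 1L))
    blocks <- split(el_order, rep(seq_len(n_edge), times = gains))
    empty <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE)
    branch_elements <- lapply(seq_len(n_edge), function(e) {
      ix <- sort(blocks[[as.character(e)]])
      if (!length(ix)) return(empty)
      data.frame(chrom = chrom, start = el_start[ix],
                 end = el_start[ix] + element_width,
                 stringsAsFactors = FALSE)
    })
    names(branch_elements) <- as.character(phy$edge[, 2])
  })
  n_tip <- length(phy$tip.label)
  parent <- integer(max(phy$edge))
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  leaf_regions <- lapply(seq_len(n_tip), function(tip) {
    node <- tip
    dfs <- list()
    while (node != root) {
      dfs[[length(dfs) + 1L]] <- branch_elements[[as.character(node)]]
      node <- parent[node]
    }
    df <- do.call(rbind, dfs)
    if (is.null(df))
      df <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
    df[order(df$start), , drop = FALSE]
  })
  names(leaf_regions) <- phy$tip.label
  structure(list(leaf_regions = leaf_regions, tree = phy,
                 branch_elements = branch_elements, seed = seed),
            class = "lineage_truth")
}

# node ages: 0 at tips, parent = 1 + max over children (post-order)
node_ages <- function(phy) {
  n_node <- max(phy$edge)
  age <- numeric(n_node)
  # edges in ape's cladewise order: process children before parents by
  # iterating until fixed point (trees are small)
  repeat {
    new_age <- age
    for (e in seq_len(nrow(phy$edge))) {
      u <- phy$edge[e, 1]; v <- phy$edge[e, 2]
      new_age[u] <- max(new_age[u], new_age[v] + 1)
    }
    if (identical(new_age, age)) break
    age <- new_age
  }
  age
}

#' Generate a score track encoding a complexity trend
#'
#' Per-base score `base + slope * category_index` inside each region
#' (TC0 has index 0), `base` outside, plus Gaussian noise.
#'
#' @param regions region table with a `category` column (TC0..TC9).
#' @param base baseline score (default 0.1).
#' @param slope per-category increment (default 0.05).
#' @param noise_sd Gaussian noise sd (default 0).
#' @param seed global seed.
#' @return a `signal_track`.
#' @export
gen_score_track <- function(regions, base = 0.1, slope = 0.05,
                            noise_sd = 0, seed = 1L) {
  stopifnot(is.finite(slope))
  with_seed(substream_seed(seed, 4L), {
    cat_idx <- as.integer(sub("^TC", "", regions$category))
    rles <- list()
    for (chrom in unique(regions$chrom)) {
      sel <- which(regions$chrom == chrom)
      L <- max(regions$end[sel]) + 1000L
      v <- rep(base, L)
      for (i in sel) {
        idx <- (regions$start[i] + 1L):regions$end[i]
        v[idx] <- base + slope * cat_idx[i]
      }
      if (noise_sd > 0) v <- v + rnorm(L, 0, noise_sd)
      rles[[chrom]] <- S4Vectors::Rle(v)
    }
    new_signal_track(rles)
  })
}
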