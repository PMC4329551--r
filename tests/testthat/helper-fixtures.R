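# shared fixtures and independent oracles, built in code at test time

# TFBS table from point positions (width-10 intervals whose midpoints are
# the given positions)
sites_df <- function(pos, tf = "TF1", chrom = "chr1", cell = "cellA") {
  data.frame(chrom = rep_len(chrom, length(pos)), start = pos - 5L,
             end = pos + 5L, tf_id = rep_len(tf, length(pos)),
             cell_type = rep_len(cell, length(pos)),
             stringsAsFactors = FALSE)
}

# brute-force per-base kernel density: incremental site-by-site
# accumulation, independent of compute_density's windowed path
brute_density <- function(sites, params, from, to) {
  pos <- seq.int(from, to)
  dens <- numeric(length(pos))
  for (s in sort(sites))
    dens <- dens + exp(-as.numeric(pos - s)^2 / (2 * params$bandwidth^2))
  list(positions = pos, density = dens)
}

# brute-force peak + complexity caller on a density grid
brute_call <- function(sites, params) {
  sites <- sort(sites)
  prof <- brute_density(sites, params, min(sites) - 2L, max(sites) + 2L)
  d <- prof$density
  peaks <- c()
  r <- rle(d)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (i == 1 || i == length(r$values)) next
    if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1])
      peaks <- c(peaks, floor((prof$positions[starts[i]] +
                                 prof$positions[ends[i]]) / 2))
  }
  lapply(peaks, function(p) {
    w <- exp(-as.numeric(p - sites)^2 / (2 * params$bandwidth^2))
    keep <- w >= params$theta
    list(peak = p, C = sum(w[keep]), n = sum(keep))
  })
}

# brute-force minimum-cost injective assignment by pruned DFS
brute_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  rec <- function(row, used, acc) {
    if (acc >= best) return()
    if (row > n) { best <<- acc; return() }
    for (j in seq_len(m)[!used]) {
      used[j] <- TRUE
      rec(row + 1L, used, acc + cost[row, j])
      used[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best
}

random_binary_tree <- function(n_tips, seed) {
  set.seed(seed)
  ape::rtree(n_tips, rooted = TRUE, br = NULL)
}

# canonical non-trivial bipartition keys of a phylo tree, in the same
# representation tfcr uses for hclust trees
phylo_bipartitions <- function(phy) {
  labs <- phy$tip.label
  n <- length(labs)
  keys <- character(0)
  for (node in (n + 1):(n + phy$Nnode)) {
    tips <- ape::extract.clade(phy, node)$tip.label
    if (length(tips) >= 2 && length(tips) <= n - 2)
      keys <- c(keys, tfcr:::bipartition_key(tips, labs))
  }
  unique(keys)
}

# tiny landscape shared by several tests (cheap: ~100 clusters, 2 cells)
tiny_landscape <- function(seed = 5, n_cells = 2, n_clusters = 100) {
  gen_tfbs_landscape(landscape_config(n_cells = n_cells,
                                      n_clusters = n_clusters),
                     seed = seed)
}
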