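# Cell-lineage inference from binary region presence: cells are rows of a
# presence/absence matrix over a merged reference element set, compared by
# Euclidean distance and agglomerated by single linkage ("nearest
# neighbour"), with precursor cell types placed onto internal nodes by the
# Hungarian algorithm.

#' Binary presence matrix of cells over reference elements
#'
#' An entry is 1 iff the cell has at least one region window fully
#' contained in the reference element (100% containment, as with
#' bedmap --fraction-map 1).
#'
#' @param region_lists named list of per-cell region tables.
#' @param reference reference element table, normally
#'   `merge_intervals(rbind(...))` over all cells.
#' @return binary matrix, cells x elements; element names are
#'   `chrom:start-end`.
#' @export
presence_matrix <- function(region_lists, reference) {
  if (!nrow(reference)) stop("empty reference element set")
  ref_gr <- gr0(reference)
  M <- matrix(0L, length(region_lists), nrow(reference),
              dimnames = list(names(region_lists),
                              paste0(reference$chrom, ":", reference$start,
                                     "-", reference$end)))
  for (i in seq_along(region_lists)) {
    rl <- region_lists[[i]]
    if (!nrow(rl)) next
    hits <- GenomicRanges::findOverlaps(gr0(rl), ref_gr, type = "within")
    M[i, unique(S4Vectors::subjectHits(hits))] <- 1L
  }
  M
}

#' Pairwise Euclidean distance between presence rows
#'
#' For binary rows this is the square root of the Hamming distance.
#'
#' @param M presence matrix (rows = cells).
#' @return symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(M) {
  if (nrow(M) < 2L) stop("need at least 2 cell types")
  as.matrix(dist(M, method = "euclidean"))
}

#' Single-linkage ("nearest neighbour") hierarchical clustering
#'
#' Deterministic: among tied merge candidates the pair with the smallest
#' (minimum-leaf-index i, j) wins. Returns a standard `hclust` object.
#'
#' @param D distance matrix (or `dist`).
#' @return an `hclust` object (method "single").
#' @export
cluster_nearest_neighbour <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2L) stop("need at least 2 leaves")
  # active clusters: id (merge-step index, negative = leaf), min leaf,
  # members; distances maintained as a shrinking matrix
  ids <- -seq_len(n)
  minleaf <- seq_len(n)
  d <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  merged_members <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    k <- nrow(d)
    dd <- d; dd[!upper.tri(dd)] <- Inf
    best <- which(dd == min(dd), arr.ind = TRUE)
    if (nrow(best) > 1L) {
      # tie-break on (min leaf of first cluster, min leaf of second)
      a <- pmin(minleaf[best[, 1]], minleaf[best[, 2]])
      b <- pmax(minleaf[best[, 1]], minleaf[best[, 2]])
      best <- best[order(a, b)[1], , drop = FALSE]
    }
    i <- best[1, 1]; j <- best[1, 2]
    merge[s, ] <- sort_pair(ids[i], ids[j])
    height[s] <- d[i, j]
    merged_members[[s]] <- sort(c(members[[i]], members[[j]]))
    # single linkage: distance to the union is the pairwise minimum
    new_d <- pmin(d[i, ], d[j, ])[-c(i, j)]
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d),
               c(new_d, 0))
    ids <- c(ids[keep], s)
    minleaf <- c(minleaf[keep], min(minleaf[c(i, j)]))
    members <- c(members[keep], list(merged_members[[s]]))
  }
  structure(list(merge = merge, height = height,
                 order = hclust_order(merge, n), labels = labels,
                 method = "single", dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}

sort_pair <- function(a, b) {
  # hclust convention: two singletons by label (-1 before -2), a
  # singleton before a cluster, two clusters by merge order
  if (a < 0 && b < 0) c(max(a, b), min(a, b))
  else if (a < 0) c(a, b)
  else if (b < 0) c(b, a)
  else c(min(a, b), max(a, b))
}

hclust_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1L)
}

# leaf indices under each internal node (merge step) of an hclust tree
tree_node_members <- function(tree) {
  n <- length(tree$labels)
  out <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    get <- function(x) if (x < 0) -x else out[[x]]
    out[[s]] <- sort(c(get(tree$merge[s, 1]), get(tree$merge[s, 2])))
  }
  out
}

# membership vector after cutting the tree into k clusters: apply the
# first n-k merges (deterministic under tied heights, unlike a height cut)
cut_tree_k <- function(tree, k) {
  n <- length(tree$labels)
  stopifnot(k >= 1L, k <= n)
  memb <- seq_len(n)
  if (k == n) return(memb)
  nodes <- tree_node_members(tree)
  for (s in seq_len(n - k)) memb[nodes[[s]]] <- n + s
  match(memb, unique(memb))
}

#' Place precursor cell types onto internal tree nodes
#'
#' The cost of assigning a precursor to a node is the Euclidean distance
#' between the precursor's presence vector and the centroid of the
#' presence vectors of the leaves under that node; the minimum-cost
#' injective assignment is found with the Hungarian algorithm.
#'
#' @param tree `hclust` tree over the leaf cell types.
#' @param precursors presence matrix rows for the precursor cells.
#' @param leaves presence matrix for the leaf cells (rows in
#'   `tree$labels` order).
#' @return list of class `precursor_assignment`: `node` (named merge-step
#'   index per precursor), `cost` (total), `cost_matrix`.
#' @export
place_precursors <- function(tree, precursors, leaves) {
  precursors <- rbind(precursors)
  n <- length(tree$labels)
  if (nrow(precursors) > n - 1L)
    stop("more precursors than internal nodes")
  leaves <- leaves[tree$labels, , drop = FALSE]
  nodes <- tree_node_members(tree)
  centroids <- t(vapply(nodes, function(mem) colMeans(leaves[mem, ,
                                                             drop = FALSE]),
                        numeric(ncol(leaves))))
  cost <- as.matrix(dist(rbind(precursors, centroids)))[
    seq_len(nrow(precursors)), nrow(precursors) + seq_len(n - 1L),
    drop = FALSE]
  sol <- hungarian_assignment(cost)
  node <- setNames(sol$assignment, rownames(precursors))
  structure(list(node = node, cost = sol$cost, cost_matrix = cost),
            class = "precursor_assignment")
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical scaling: the doubly centred `-0.5 * D^2` matrix is
#' eigendecomposed and coordinates are eigenvectors scaled by the square
#' roots of positive eigenvalues. Requested dimensions beyond the positive
#' spectrum are dropped with a warning.
#'
#' @param D distance matrix.
#' @param dims target dimensionality (default 3).
#' @return matrix of coordinates (rows = objects); attribute `eig` holds
#'   the eigenvalues.
#' @export
pcoa <- function(D, dims = 3L) {
  D <- as.matrix(D)
  n <- nrow(D)
  B <- -0.5 * D^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > max(e$values[1], 0) * 1e-12)
  if (length(pos) < dims) {
    warning("only ", length(pos), " positive eigenvalue(s); coordinates ",
            "truncated")
    dims <- length(pos)
  }
  if (any(e$values < -max(abs(e$values)) * 1e-8))
    warning("negative eigenvalues dropped (distances not fully Euclidean)")
  co <- e$vectors[, seq_len(dims), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(dims)]), dims)
  rownames(co) <- rownames(D)
  attr(co, "eig") <- e$values
  co
}

# canonical root-agnostic bipartition key of a leaf-label set
bipartition_key <- function(labels_in, all_labels) {
  other <- setdiff(all_labels, labels_in)
  a <- paste(sort(labels_in), collapse = "|")
  b <- paste(sort(other), collapse = "|")
  if (a < b) paste(a, b, sep = "//") else paste(b, a, sep = "//")
}

tree_bipartitions <- function(tree) {
  labs <- tree$labels
  n <- length(labs)
  nodes <- tree_node_members(tree)
  keep <- vapply(nodes, function(m) length(m) >= 2L && length(m) <= n - 2L,
                 TRUE)
  keys <- vapply(nodes[keep], function(m) bipartition_key(labs[m], labs), "")
  setNames(keys, which(keep))
}

#' Bootstrap support of internal branches
#'
#' Columns of the presence matrix are resampled with replacement,
#' distances recomputed and the tree rebuilt; support for each internal
#' branch of the reference tree is the percentage of bootstrap trees
#' containing the same (root-agnostic) leaf bipartition.
#'
#' @param M presence matrix.
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @return list of class `branch_support`: `tree` (the reference tree),
#'   `support` (named percentage vector indexed by merge step),
#'   `n_iter`.
#' @export
bootstrap_branch_support <- function(M, n_iter = 1000L, seed = 1L) {
  if (ncol(M) < 3L) stop("need at least 3 columns to resample")
  ref <- cluster_nearest_neighbour(distance_matrix(M))
  ref_bip <- tree_bipartitions(ref)
  count <- setNames(numeric(length(ref_bip)), names(ref_bip))
  old_seed <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = .GlobalEnv))
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    cols <- sample.int(ncol(M), replace = TRUE)
    bt <- cluster_nearest_neighbour(distance_matrix(M[, cols,
                                                      drop = FALSE]))
    hit <- ref_bip %in% tree_bipartitions(bt)
    count <- count + hit
  }
  structure(list(tree = ref, support = 100 * count / n_iter,
                 n_iter = n_iter),
            class = "branch_support")
}

#' All leave-category-out subsets
#'
#' Every subset of the distinct categories retaining at least one and
#' excluding at least one category, in ascending binary-mask order
#' (bit i set = category i retained). For the ten complexity categories
#' this is the 1022-member sensitivity ensemble.
#'
#' @param categories vector of category labels (>= 2 distinct).
#' @return list of character vectors of retained categories.
#' @export
leave_category_out_ensemble <- function(categories = paste0("TC", 0:9)) {
  cats <- sort(unique(as.character(categories)))
  m <- length(cats)
  if (m < 2L) stop("need at least 2 distinct categories")
  if (m > 25L) stop("too many categories to enumerate")
  lapply(seq_len(2L^m - 2L), function(mask) {
    cats[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L]
  })
}

#' Lineage-restricted region groups
#'
#' An element belongs to a branch when its presence fraction among the
#' branch's descendant leaves is at least `alpha` and among all other
#' leaves at most `beta`; elements are assigned to the deepest (fewest
#' leaves) qualifying branch.
#'
#' @param M presence matrix.
#' @param tree `hclust` tree over the rows of `M`.
#' @param branch_nodes named integer vector of merge-step indices defining
#'   the candidate branches.
#' @param alpha minimum within-branch presence fraction (default 1).
#' @param beta maximum outside presence fraction (default 0).
#' @return data.frame: `element`, `branch` (one row per assigned element).
#' @export
lineage_restricted_regions <- function(M, tree, branch_nodes,
                                       alpha = 1.0, beta = 0.0) {
  if (alpha <= beta) stop("alpha must exceed beta")
  M <- M[tree$labels, , drop = FALSE]
  nodes <- tree_node_members(tree)
  n <- nrow(M)
  sizes <- vapply(branch_nodes, function(v) length(nodes[[v]]), 0L)
  rows_el <- lapply(seq_along(branch_nodes), function(bi) {
    v <- branch_nodes[bi]
    inside <- nodes[[v]]
    outside <- setdiff(seq_len(n), inside)
    f_in <- colMeans(M[inside, , drop = FALSE])
    f_out <- if (length(outside)) colMeans(M[outside, , drop = FALSE])
             else rep(0, ncol(M))
    which(f_in >= alpha & f_out <= beta)
  })
  el_names <- colnames(M)
  if (is.null(el_names)) el_names <- as.character(seq_len(ncol(M)))
  assigned <- character(0); branch <- character(0)
  bnames <- names(branch_nodes)
  if (is.null(bnames)) bnames <- as.character(branch_nodes)
  for (el in seq_len(ncol(M))) {
    qual <- which(vapply(rows_el, function(ix) el %in% ix, TRUE))
    if (!length(qual)) next
    pick <- qual[order(sizes[qual], branch_nodes[qual])][1]
    assigned <- c(assigned, el_names[el])
    branch <- c(branch, bnames[pick])
  }
  data.frame(element = assigned, branch = branch, stringsAsFactors = FALSE)
}

#' Write an hclust tree (with optional branch support) as Newick
#'
#' @param tree `hclust` object.
#' @param path output file.
#' @param support optional named support vector from
#'   [bootstrap_branch_support()].
#' @export
write_tree_newick <- function(tree, path, support = NULL) {
  phy <- ape::as.phylo(tree)
  if (!is.null(support)) {
    nodes <- tree_node_members(tree)
    labs <- tree$labels
    key2sup <- setNames(support,
                        vapply(as.integer(names(support)),
                               function(s) bipartition_key(labs[nodes[[s]]],
                                                           labs), ""))
    nl <- character(phy$Nnode)
    for (nd in seq_len(phy$Nnode)) {
      tips <- ape::extract.clade(phy, nd + length(labs))$tip.label
      key <- bipartition_key(tips, labs)
      nl[nd] <- if (key %in% names(key2sup))
        format(key2sup[[key]], trim = TRUE) else ""
    }
    phy$node.label <- nl
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}
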