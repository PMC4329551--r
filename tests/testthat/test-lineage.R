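test_that("presence needs full containment in the reference element", {
  ref <- data.frame(chrom = "c1", start = 0, end = 100)
  inside <- list(A = data.frame(chrom = "c1", start = 10, end = 20))
  straddle <- list(A = data.frame(chrom = "c1", start = 90, end = 110))
  expect_equal(as.vector(presence_matrix(inside, ref)), 1L)
  expect_equal(as.vector(presence_matrix(straddle, ref)), 0L)
  expect_error(presence_matrix(inside, ref[0, ]), "empty")
})

test_that("union-built reference maps each region to exactly one element", {
  lt <- gen_lineage_dataset("(((A,B),(C,D)),(E,F));", 20, seed = 3)
  ref <- merge_intervals(do.call(rbind, lt$leaf_regions))
  for (leaf in names(lt$leaf_regions)) {
    rl <- lt$leaf_regions[[leaf]]
    hits <- GenomicRanges::findOverlaps(
      tfcr:::gr0(rl), tfcr:::gr0(ref), type = "within")
    expect_equal(length(hits), nrow(rl))
    expect_equal(anyDuplicated(S4Vectors::queryHits(hits)), 0)
  }
})

test_that("distances are Euclidean on binary rows", {
  M <- rbind(a = c(1, 0, 1), b = c(1, 1, 0), c = c(1, 0, 1),
             d = c(0, 1, 0))
  D <- distance_matrix(M)
  expect_equal(D["a", "c"], 0)
  expect_equal(D["a", "b"], sqrt(2))
  expect_equal(D["a", "d"], sqrt(3))  # complementary rows of length 3
  expect_equal(D, t(D))
})

test_that("single linkage merges match a hand trace and stats::hclust", {
  D <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- cluster_nearest_neighbour(D)
  expect_equal(tr$height, c(1, 5))
  expect_equal(sort(tr$merge[1, ]), c(-2, -1))

  set.seed(20)
  for (i in 1:5) {
    M <- matrix(rbinom(7 * 40, 1, 0.4), 7,
                dimnames = list(paste0("L", 1:7), NULL))
    D2 <- distance_matrix(M)
    ours <- cluster_nearest_neighbour(D2)
    ref <- stats::hclust(stats::as.dist(D2), method = "single")
    expect_equal(ours$height, ref$height)
  }
})

test_that("tied distances break deterministically to a caterpillar", {
  D <- matrix(1, 4, 4); diag(D) <- 0
  dimnames(D) <- list(letters[1:4], letters[1:4])
  tr <- cluster_nearest_neighbour(D)
  expect_equal(tr$merge[1, ], c(-1L, -2L))
  expect_equal(tr$merge[2, ], c(-3L, 1L))
  expect_equal(tr$merge[3, ], c(-4L, 2L))
})

test_that("hungarian solves the worked 2x2 examples", {
  s1 <- hungarian_assignment(matrix(c(1, 3, 2, 1), 2))
  expect_equal(s1$assignment, c(1, 2))
  expect_equal(s1$cost, 2)
  s2 <- hungarian_assignment(matrix(c(2, 1, 1, 2), 2))
  expect_equal(s2$assignment, c(2, 1))
  expect_equal(s2$cost, 2)
  expect_error(hungarian_assignment(matrix(1, 3, 2)), "injective")
})

test_that("precursor placement puts an ancestral profile on its clade", {
  lt <- gen_lineage_dataset("(((A,B),(C,D)),(E,F));", 40, seed = 6)
  ref <- merge_intervals(do.call(rbind, lt$leaf_regions))
  M <- presence_matrix(lt$leaf_regions, ref)
  tree <- cluster_nearest_neighbour(distance_matrix(M))
  nodes <- tfcr:::tree_node_members(tree)
  # a precursor carrying exactly the shared A/B content
  prec <- matrix(as.integer(M["A", ] & M["B", ]), 1,
                 dimnames = list("pAB", NULL))
  pa <- place_precursors(tree, prec, M)
  expect_equal(sort(tree$labels[nodes[[pa$node]]]), c("A", "B"))
  # single precursor equals the argmin over nodes
  expect_equal(pa$cost, min(pa$cost_matrix))
  expect_error(place_precursors(tree, M[rep(1, 6), ], M), "more precursors")
})

test_that("pcoa reconstructs Euclidean configurations", {
  # three equidistant points
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  co <- tfcr::pcoa(D3, dims = 2)
  expect_equal(as.matrix(dist(co)), D3, ignore_attr = TRUE)
  # collinear points: one dimension reconstructs all distances
  x <- c(0, 1, 3)
  Dl <- as.matrix(dist(x))
  col <- suppressWarnings(tfcr::pcoa(Dl, dims = 2))
  expect_lt(max(abs(as.matrix(dist(col[, 1])) - Dl)), 1e-8)
  # duplicates coincide
  Dd <- as.matrix(dist(c(0, 0, 2)))
  cd <- suppressWarnings(tfcr::pcoa(Dd, dims = 1))
  expect_equal(unname(cd[1, 1]), unname(cd[2, 1]))
  # full-dimension reconstruction
  set.seed(8)
  M <- matrix(rbinom(6 * 50, 1, 0.5), 6)
  D <- distance_matrix(M)
  cf <- suppressWarnings(tfcr::pcoa(D, dims = 5))
  expect_lt(max(abs(as.matrix(dist(cf)) - D)), 1e-8)
})

test_that("bootstrap support is 100% for separated clades", {
  lt <- gen_lineage_dataset("((A,B),(C,D));",
                            gains_per_branch = c("6" = 40, "7" = 40,
                                                 A = 5, B = 5, C = 5,
                                                 D = 5),
                            seed = 2)
  ref <- merge_intervals(do.call(rbind, lt$leaf_regions))
  M <- presence_matrix(lt$leaf_regions, ref)
  bs <- bootstrap_branch_support(M, n_iter = 60, seed = 4)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  expect_true(all(bs$support == 100))
  bs2 <- bootstrap_branch_support(M, n_iter = 60, seed = 4)
  expect_identical(bs$support, bs2$support)
})

test_that("leave-category-out ensembles enumerate proper subsets", {
  expect_length(leave_category_out_ensemble(paste0("TC", 0:9)), 1022)
  e3 <- leave_category_out_ensemble(c("a", "b", "c"))
  expect_length(e3, 6)
  expect_equal(e3[[1]], "a")  # ascending binary-mask order
  expect_equal(e3[[3]], c("a", "b"))
  expect_length(leave_category_out_ensemble(c("x", "y")), 2)
  expect_error(leave_category_out_ensemble("x"), "2 distinct")
})

test_that("baker's gamma is 1 for identical trees, ~0 for random pairs", {
  set.seed(5)
  M <- matrix(rbinom(8 * 60, 1, 0.5), 8,
              dimnames = list(paste0("L", 1:8), NULL))
  tr <- cluster_nearest_neighbour(distance_matrix(M))
  expect_equal(bakers_gamma(tr, tr)$gamma, 1)
  # same data, permuted leaf input order: still gamma = 1
  perm <- sample(8)
  tr2 <- cluster_nearest_neighbour(distance_matrix(M[perm, ]))
  expect_equal(bakers_gamma(tr, tr2)$gamma, 1)
  # random trees: mean gamma near 0
  gs <- vapply(1:60, function(s) {
    set.seed(100 + s)
    M1 <- matrix(rbinom(8 * 40, 1, 0.5), 8,
                 dimnames = list(paste0("L", 1:8), NULL))
    M2 <- matrix(rbinom(8 * 40, 1, 0.5), 8,
                 dimnames = list(paste0("L", 1:8), NULL))
    bakers_gamma(cluster_nearest_neighbour(distance_matrix(M1)),
                 cluster_nearest_neighbour(distance_matrix(M2)))$gamma
  }, 0)
  expect_lt(abs(mean(gs)), 0.1)
  expect_error(bakers_gamma(tr, cluster_nearest_neighbour(
    distance_matrix(M[1:4, ]))), "leaf sets")
})

test_that("Bk is 1 for identical trees and matches the hand example", {
  set.seed(6)
  M <- matrix(rbinom(7 * 60, 1, 0.5), 7,
              dimnames = list(paste0("L", 1:7), NULL))
  tr <- cluster_nearest_neighbour(distance_matrix(M))
  bk <- fowlkes_mallows_bk(tr, tr)
  expect_true(all(abs(bk$Bk - 1) < 1e-12 | is.na(bk$Bk)))
  # n = 6 contingency [[2,1],[1,2]]
  st <- tfcr:::bk_statistics(matrix(c(2, 1, 1, 2), 2))
  expect_equal(st$Tk, 4)
  expect_equal(st$Pk, 12)
  expect_equal(st$Bk, 1 / 3)
  expect_equal(st$E, 0.4)
})

test_that("lineage-restricted groups recover planted branch gains", {
  lt <- gen_lineage_dataset("(((A,B),(C,D)),(E,F));", 50, seed = 9)
  ref <- merge_intervals(do.call(rbind, lt$leaf_regions))
  M <- presence_matrix(lt$leaf_regions, ref)
  tree <- cluster_nearest_neighbour(distance_matrix(M))
  nodes <- tfcr:::tree_node_members(tree)
  bn <- setNames(seq_along(nodes), vapply(nodes, function(m)
    paste(sort(tree$labels[m]), collapse = ""), ""))
  lr <- lineage_restricted_regions(M, tree, bn, alpha = 0.9, beta = 0.1)
  # every element gained on an internal branch lands on that branch
  ok <- 0; tot <- 0
  phy <- lt$tree
  n_tip <- length(phy$tip.label)
  for (edge in seq_len(nrow(phy$edge))) {
    child <- phy$edge[edge, 2]
    if (child <= n_tip) next  # leaf-private gains have no internal branch
    tips <- sort(ape::extract.clade(phy, child)$tip.label)
    els <- lt$branch_elements[[as.character(child)]]
    keys <- paste0(els$chrom, ":", els$start, "-", els$end)
    assigned <- lr$branch[match(keys, lr$element)]
    tot <- tot + length(keys)
    ok <- ok + sum(assigned == paste(tips, collapse = ""), na.rm = TRUE)
  }
  expect_gte(ok / tot, 0.95)
  # element present everywhere maps to the root branch
  Mr <- cbind(M, all = 1L)
  colnames(Mr)[ncol(Mr)] <- "everywhere"
  lr2 <- lineage_restricted_regions(Mr, tree, bn)
  expect_equal(lr2$branch[lr2$element == "everywhere"], "ABCDEF")
  expect_error(lineage_restricted_regions(M, tree, bn, alpha = 0.1,
                                          beta = 0.5), "alpha")
})

test_that("newick output carries leaf set and support labels", {
  set.seed(12)
  M <- matrix(rbinom(5 * 30, 1, 0.5), 5,
              dimnames = list(paste0("L", 1:5), NULL))
  bs <- bootstrap_branch_support(M, n_iter = 20, seed = 1)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(bs$tree, f, support = bs$support)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, paste0("L", 1:5))
})
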