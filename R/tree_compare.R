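# Dendrogram comparison: Baker's Gamma (rank correlation of pairwise
# merge stages) and the Fowlkes-Mallows Bk curve with its permutation-null
# expectation and variance. Merge "stage" is the cluster-count level, not
# the raw height, so both statistics are invariant to monotone height
# transforms.

# per-leaf-pair merge stage matrix, rows/cols in sorted label order.
# The stage is the dense rank of the pair's cophenetic merge height, so
# it is invariant both to monotone height transforms and to the
# arbitrary ordering of merges at tied heights.
pair_merge_steps <- function(tree) {
  labs <- sort(tree$labels)
  n <- length(labs)
  idx <- match(tree$labels, labs)
  S <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  nodes <- tree_node_members(tree)
  stage <- match(tree$height, sort(unique(tree$height)))
  for (s in seq_along(nodes)) {
    left <- tree$merge[s, 1]; right <- tree$merge[s, 2]
    get <- function(x) if (x < 0) -x else nodes[[x]]
    li <- idx[get(left)]; ri <- idx[get(right)]
    S[li, ri] <- stage[s]
    S[ri, li] <- stage[s]
  }
  diag(S) <- 0
  S
}

#' Baker's Gamma correlation between two dendrograms
#'
#' Spearman rank correlation between the merge stages (cluster-count
#' levels) at which each leaf pair first co-clusters in the two trees.
#'
#' @param tree1,tree2 `hclust` trees over the same leaf set.
#' @return list of class `gamma_result`: `gamma` in \[-1, 1\], `n_pairs`.
#' @export
bakers_gamma <- function(tree1, tree2) {
  if (!setequal(tree1$labels, tree2$labels))
    stop("trees have different leaf sets")
  s1 <- pair_merge_steps(tree1)
  s2 <- pair_merge_steps(tree2)
  v1 <- s1[upper.tri(s1)]
  v2 <- s2[upper.tri(s2)]
  structure(list(gamma = suppressWarnings(cor(v1, v2,
                                              method = "spearman")),
                 n_pairs = length(v1)),
            class = "gamma_result")
}

# Bk and its permutation-null moments from a k x k contingency table
bk_statistics <- function(m) {
  n <- sum(m)
  Tk <- sum(m^2) - n
  pr <- rowSums(m); qc <- colSums(m)
  Pk <- sum(pr^2) - n
  Qk <- sum(qc^2) - n
  if (Pk == 0 || Qk == 0)
    return(list(Bk = NA_real_, E = NA_real_, var = NA_real_,
                Tk = Tk, Pk = Pk, Qk = Qk))
  Pk2 <- sum(pr * (pr - 1) * (pr - 2))
  Qk2 <- sum(qc * (qc - 1) * (qc - 2))
  E_Tk <- Pk * Qk / (n * (n - 1))
  var_Tk <- 2 * Pk * Qk / (n * (n - 1)) +
    4 * Pk2 * Qk2 / (n * (n - 1) * (n - 2)) +
    (Pk^2 - 4 * Pk2 - 2 * Pk) * (Qk^2 - 4 * Qk2 - 2 * Qk) /
      (n * (n - 1) * (n - 2) * (n - 3)) -
    E_Tk^2
  list(Bk = Tk / sqrt(Pk * Qk), E = sqrt(Pk * Qk) / (n * (n - 1)),
       var = var_Tk / (Pk * Qk), Tk = Tk, Pk = Pk, Qk = Qk)
}

#' Fowlkes-Mallows Bk curve between two dendrograms
#'
#' Both trees are cut into k clusters for each k; from the contingency
#' table of the two partitions, `Bk = Tk / sqrt(Pk Qk)` with
#' `Tk = sum m_ij^2 - n`, `Pk`/`Qk` the analogous marginal sums. The
#' permutation-null expectation `E(Bk) = sqrt(Pk Qk) / (n(n-1))` and
#' closed-form variance give the limits `E(Bk) +/- 2 sqrt(var(Bk))`.
#'
#' @param tree1,tree2 `hclust` trees over the same n leaves.
#' @param ks cluster counts (default `2:(n-1)`).
#' @return data.frame of class `bk_curve`: `k`, `Bk`, `E_Bk`, `var_Bk`,
#'   `lower`, `upper`, `significant` (Bk outside the limits; `NA` rows
#'   flag degenerate cuts).
#' @export
fowlkes_mallows_bk <- function(tree1, tree2, ks = NULL) {
  if (!setequal(tree1$labels, tree2$labels))
    stop("trees have different leaf sets")
  n <- length(tree1$labels)
  if (is.null(ks)) ks <- 2:(n - 1)
  labs <- sort(tree1$labels)
  i1 <- match(labs, tree1$labels)
  i2 <- match(labs, tree2$labels)
  rows <- lapply(ks, function(k) {
    c1 <- cut_tree_k(tree1, k)[i1]
    c2 <- cut_tree_k(tree2, k)[i2]
    st <- bk_statistics(table(c1, c2))
    lower <- st$E - 2 * sqrt(st$var)
    upper <- st$E + 2 * sqrt(st$var)
    data.frame(k = k, Bk = st$Bk, E_Bk = st$E, var_Bk = st$var,
               lower = lower, upper = upper,
               significant = !is.na(st$Bk) &
                 (st$Bk < lower | st$Bk > upper))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bk_curve", "data.frame")
  out
}

# Fowlkes-Mallows moments for two fixed partitions by label permutation --
# the Monte-Carlo oracle used by the test suite to validate the closed
# forms above (exported for the acceptance tests)
#' Monte-Carlo permutation moments of Bk for two partitions
#'
#' @param c1,c2 cluster membership vectors of equal length.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return list with `mean` and `var` of Bk under random relabelling.
#' @export
bk_permutation_moments <- function(c1, c2, n_perm = 1e5, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = .GlobalEnv))
  set.seed(seed)
  n <- length(c1)
  f1 <- as.integer(factor(c1)); f2 <- as.integer(factor(c2))
  k1 <- max(f1); k2 <- max(f2)
  # marginals are permutation-invariant; only Tk varies
  Pk <- sum(tabulate(f1, k1)^2) - n
  Qk <- sum(tabulate(f2, k2)^2) - n
  vals <- vapply(seq_len(n_perm), function(i) {
    cnt <- tabulate(f1 + (f2[sample.int(n)] - 1L) * k1, k1 * k2)
    (sum(cnt^2) - n) / sqrt(Pk * Qk)
  }, 0)
  v <- sum((vals - mean(vals))^2) / length(vals)
  m4 <- sum((vals - mean(vals))^4) / length(vals)
  list(mean = mean(vals), var = v,
       se_mean = sqrt(v / n_perm),
       se_var = sqrt(max(m4 - v^2, 0) / n_perm))
}
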