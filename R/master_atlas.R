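# Cross-cell-type consolidation: within every connected component of
# overlapping windows the highest-complexity region is kept, the regions it
# overlaps are discarded, and the selection repeats on the remainder --
# the literal one-winner-at-a-time greedy.

#' Build the non-overlapping master list of clustered regions
#'
#' @param region_lists list of `clustered_regions` tables (one per cell
#'   type; each must carry `cell_type`).
#' @return data.frame of class `master_list`: the selected regions (pairwise
#'   disjoint windows) plus an `ubiquity` column (distinct cell types with
#'   >= 1 bp window overlap).
#' @export
build_master_list <- function(region_lists) {
  pool <- do.call(rbind, lapply(region_lists, as.data.frame))
  if (is.null(pool) || !nrow(pool)) stop("no regions supplied")
  pool <- pool[order(pool$chrom, pool$start, pool$end), , drop = FALSE]
  keep <- NULL
  for (chrom in unique(pool$chrom)) {
    p <- pool[pool$chrom == chrom, , drop = FALSE]
    # connected components of the overlap graph: new component whenever a
    # start clears the running max end (half-open: touching != overlapping)
    run_max <- cummax(p$end)
    comp <- cumsum(c(TRUE, p$start[-1] >= run_max[-nrow(p)]))
    for (cc in split(seq_len(nrow(p)), comp)) {
      q <- p[cc, , drop = FALSE]
      while (nrow(q)) {
        o <- order(-q$complexity, q$start, q$cell_type)
        sel <- q[o[1], , drop = FALSE]
        keep <- rbind(keep, sel)
        q <- q[!(q$start < sel$end & q$end > sel$start), , drop = FALSE]
      }
    }
  }
  keep <- keep[order(keep$chrom, keep$start), , drop = FALSE]
  rownames(keep) <- NULL
  keep$ubiquity <- cell_ubiquity(keep, region_lists)
  class(keep) <- c("master_list", "data.frame")
  keep
}

#' Cell-type ubiquity of master-list entries
#'
#' Number of distinct cell types having at least 1 bp of window overlap
#' with each entry.
#'
#' @param master master-list table.
#' @param region_lists the per-cell region tables the master was built from.
#' @return integer vector, one count per master entry.
#' @export
cell_ubiquity <- function(master, region_lists) {
  counts <- integer(nrow(master))
  mgr <- gr0(master)
  for (rl in region_lists) {
    if (!nrow(rl)) next
    hit <- GenomicRanges::countOverlaps(mgr, gr0(rl), minoverlap = 1L) > 0
    counts <- counts + hit
  }
  counts
}

#' Saturation of unique elements with increasing cell-type count
#'
#' For each subset size x, cell-type combinations are drawn (all of them
#' when fewer than `n_samples` exist, otherwise random draws), the member
#' cells' windows are merged, merged runs longer than `max_element_len` are
#' chunked into consecutive pieces of at most that length, and the element
#' count and bp coverage are averaged over draws.
#'
#' @param region_lists list of per-cell region tables.
#' @param n_samples combinations per subset size (default 20000).
#' @param max_element_len element length cap in bp (default 5000).
#' @param seed RNG seed.
#' @return data.frame of class `saturation_curve`: `x`, `mean_elements`,
#'   `mean_bp`, `n_draws`.
#' @export
saturation_curve <- function(region_lists, n_samples = 20000L,
                             max_element_len = 5000L, seed = 1L) {
  N <- length(region_lists)
  if (N < 2L) stop("need at least 2 cell types")
  grs <- lapply(region_lists, gr0)
  old_seed <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = .GlobalEnv))
  set.seed(seed)
  measure <- function(members) {
    m <- GenomicRanges::reduce(do.call(c, unname(grs[members])))
    w <- GenomicRanges::width(m)
    c(elements = sum(ceiling(w / max_element_len)), bp = sum(w))
  }
  rows <- lapply(seq_len(N), function(x) {
    n_comb <- choose(N, x)
    if (n_comb <= n_samples) {
      draws <- combn(N, x, simplify = FALSE)
    } else {
      draws <- replicate(n_samples, sort(sample.int(N, x)),
                         simplify = FALSE)
    }
    m <- vapply(draws, measure, c(elements = 0, bp = 0))
    data.frame(x = x, mean_elements = mean(m["elements", ]),
               mean_bp = mean(m["bp", ]), n_draws = length(draws))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("saturation_curve", "data.frame")
  out
}

#' Fit a Weibull saturation model
#'
#' Least squares fit of `y(x) = A (1 - exp(-(x/lambda)^k))`; the asymptote
#' A is the extrapolated saturation level. Multi-start optimisation on log
#' parameters; standard errors from the Gauss-Newton covariance.
#'
#' @param x subset sizes (>= 4 distinct values).
#' @param y mean element counts (or bp) at each x.
#' @return list of class `weibull_fit`: `A`, `lambda`, `shape`, `se`
#'   (named vector), `fitted`, `sse`.
#' @export
fit_weibull_saturation <- function(x, y) {
  if (inherits(x, "saturation_curve")) {
    y <- x$mean_elements
    x <- x$x
  }
  if (length(unique(x)) < 4L) stop("need at least 4 distinct x values")
  model <- function(th, x) th[1] * (1 - exp(-(x / th[2])^th[3]))
  sse <- function(lth, x, y) {
    r <- y - model(exp(lth), x)
    sum(r * r)
  }
  ymax <- max(y)
  starts <- expand.grid(A = ymax * c(1.01, 1.2, 2, 5),
                        lambda = stats::median(x) * c(0.5, 1, 2),
                        k = c(0.7, 1, 1.5))
  fits <- list()
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(log(as.numeric(starts[i, ])), sse, x = x, y = y,
            method = "BFGS", control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value)) fits[[length(fits) + 1]] <- fit
  }
  if (!length(fits))
    stop("Weibull fit did not converge from any start (n = ",
         length(x), ", ymax = ", ymax, ")")
  vals <- vapply(fits, `[[`, 0, "value")
  # a saturated (constant) curve leaves A unidentified along a flat SSE
  # ridge; among numerically tied optima take the smallest asymptote
  tol <- max(min(vals) * 1e-6, 1e-9 * max(1, ymax)^2)
  cand <- fits[vals <= min(vals) + tol]
  best <- cand[[which.min(vapply(cand, function(f) f$par[1], 0))]]
  th <- exp(best$par)
  fitted <- model(th, x)
  dof <- length(x) - 3L
  s2 <- if (dof > 0) best$value / dof else NA_real_
  J <- jacobian_numeric(function(p) model(p, x), th)
  se <- rep(NA_real_, 3)
  cv <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  names(se) <- c("A", "lambda", "shape")
  structure(list(A = th[1], lambda = th[2], shape = th[3], se = se,
                 fitted = fitted, sse = best$value),
            class = "weibull_fit")
}

jacobian_numeric <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(abs(p[j]), 1)
    pj <- p; pj[j] <- pj[j] + h
    J[, j] <- (f(pj) - f0) / h
  }
  J
}

#' Genomic class of master-list entries
#'
#' Priority promoter > exon > UTR > intron > intergenic: promoter when the
#' region peak lies within 1 kb of any TSS; exon when some single CDS
#' segment overlaps the window by >= 75 bp; UTR and intron on >= 1 bp
#' overlap; intergenic otherwise.
#'
#' @param master master-list table (needs `peak` or window centre).
#' @param annotation a [read_gene_annotation()] object.
#' @param promoter_dist TSS distance for the promoter class (default 1000).
#' @param exon_min_overlap minimum single-segment CDS overlap (default 75).
#' @return character vector of classes.
#' @export
annotate_region_classes <- function(master, annotation,
                                    promoter_dist = 1000L,
                                    exon_min_overlap = 75L) {
  peak <- if ("peak" %in% names(master)) master$peak
          else floor((master$start + master$end) / 2)
  cls <- rep("intergenic", nrow(master))
  genes <- annotation$genes
  mgr <- gr0(master)
  overlap_width <- function(feat) {
    w <- integer(nrow(master))
    if (!nrow(feat)) return(w)
    hits <- GenomicRanges::findOverlaps(mgr, gr0(feat))
    if (!length(hits)) return(w)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(
      mgr[S4Vectors::queryHits(hits)], gr0(feat)[S4Vectors::subjectHits(hits)]))
    best <- tapply(ov, S4Vectors::queryHits(hits), max)
    w[as.integer(names(best))] <- as.integer(best)
    w
  }
  intron_w <- overlap_width(annotation$introns)
  utr_w <- overlap_width(annotation$utr)
  cds_w <- overlap_width(annotation$cds)
  cls[intron_w >= 1L] <- "intron"
  cls[utr_w >= 1L] <- "UTR"
  cls[cds_w >= exon_min_overlap] <- "exon"
  is_prom <- vapply(seq_len(nrow(master)), function(i) {
    g <- genes[genes$chrom == master$chrom[i], , drop = FALSE]
    nrow(g) > 0 && any(abs(g$tss - peak[i]) <= promoter_dist)
  }, TRUE)
  cls[is_prom] <- "promoter"
  cls
}

#' Nearest gene by TSS distance to the region centre
#'
#' @param master master-list table.
#' @param annotation a [read_gene_annotation()] object.
#' @return character vector of gene ids (ties broken lexicographically;
#'   `NA` when the chromosome has no gene, with a warning).
#' @export
assign_nearest_gene <- function(master, annotation) {
  genes <- annotation$genes
  if (!nrow(genes)) stop("empty gene annotation")
  centre <- floor((master$start + master$end) / 2)
  out <- vapply(seq_len(nrow(master)), function(i) {
    g <- genes[genes$chrom == master$chrom[i], , drop = FALSE]
    if (!nrow(g)) return(NA_character_)
    d <- abs(g$tss - centre[i])
    cand <- g$gene_id[d == min(d)]
    sort(cand)[1]
  }, "")
  if (anyNA(out)) warning("regions on chromosomes without genes got NA")
  out
}
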