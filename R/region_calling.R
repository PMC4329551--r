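# TFBS-clustered region calling: an unnormalised Gaussian kernel (k(0) = 1)
# is centred on each binding-site anchor, so the density is an effective
# local site count and the complexity C -- the sum of per-site contributions
# of at least `theta` at a density peak -- lives on the same count-like
# scale as the TC category bounds (6 .. 30).

#' Kernel parameters for region calling
#'
#' @param bandwidth Gaussian bandwidth in bp (default 300).
#' @param theta minimum kernel weight for a site to count towards a peak's
#'   complexity (default 0.1).
#' @param grid_step density evaluation step in bp (default 1).
#' @return list of class `kernel_params`.
#' @export
kernel_params <- function(bandwidth = 300, theta = 0.1, grid_step = 1L) {
  stopifnot(bandwidth > 0, theta > 0, theta < 1, grid_step >= 1)
  structure(list(bandwidth = bandwidth, theta = theta,
                 grid_step = as.integer(grid_step)),
            class = "kernel_params")
}

#' Gaussian kernel weight at distance d
#'
#' `k(d) = exp(-d^2 / (2 b^2))`; unnormalised so `k(0) = 1`.
#'
#' @param d distance(s) in bp.
#' @param params a [kernel_params()].
#' @export
kernel_weight <- function(d, params = kernel_params()) {
  d <- as.numeric(d)  # avoid 32-bit overflow of d^2 at genomic distances
  exp(-(d * d) / (2 * params$bandwidth^2))
}

#' Distance beyond which a site cannot contribute `theta`
#'
#' Closed form `b * sqrt(2 * log(1/theta))` (about 643.8 bp at defaults).
#'
#' @param params a [kernel_params()].
#' @export
kernel_cutoff <- function(params = kernel_params()) {
  params$bandwidth * sqrt(2 * log(1 / params$theta))
}

# radius past which the kernel underflows to exactly 0 in double precision;
# truncating there leaves the evaluated density bit-identical to a full sum
kernel_zero_radius <- function(params) {
  ceiling(params$bandwidth * sqrt(2 * 746))
}

#' Kernel density of site positions along one chromosome
#'
#' Evaluates `rho(x) = sum_i k(x - s_i)` on a regular grid spanning the
#' sites (padded by two grid steps). All sites contribute to the density;
#' the `theta` truncation applies only to complexity accounting in
#' [call_regions()].
#'
#' @param sites integer site positions (bp, one chromosome), any order.
#' @param params a [kernel_params()].
#' @param from,to optional grid bounds; default `min(sites)`/`max(sites)`
#'   padded by two steps.
#' @return list with `positions` and `density` (empty for no sites).
#' @export
compute_density <- function(sites, params = kernel_params(),
                            from = NULL, to = NULL) {
  if (!length(sites))
    return(list(positions = integer(0), density = numeric(0)))
  sites <- sort(as.integer(sites))
  step <- params$grid_step
  if (is.null(from)) from <- min(sites) - 2L * step
  if (is.null(to)) to <- max(sites) + 2L * step
  pos <- seq.int(from, to, by = step)
  dens <- numeric(length(pos))
  R <- kernel_zero_radius(params)
  for (s in sites) {
    i1 <- max(1L, ceiling((s - R - from) / step) + 1L)
    i2 <- min(length(pos), floor((s + R - from) / step) + 1L)
    if (i1 > i2) next
    idx <- i1:i2
    dens[idx] <- dens[idx] + kernel_weight(pos[idx] - s, params)
  }
  list(positions = pos, density = dens)
}

# strict local maxima of a density vector; a flat run higher than both of
# its neighbours yields its midpoint (rounded down); boundary runs excluded
density_peaks <- function(positions, density) {
  r <- rle(density)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(seq_len(k) > 1L & seq_len(k) < k &
                  r$values > c(-Inf, r$values[-k])[seq_len(k)] &
                  r$values > c(r$values[-1L], -Inf)[seq_len(k)])
  if (!length(keep)) return(integer(0))
  as.integer(floor((positions[starts[keep]] + positions[ends[keep]]) / 2))
}

#' Call TFBS-clustered regions for one cell type
#'
#' Each strict local maximum of the kernel density is a candidate region.
#' Sites whose kernel weight at the peak is at least `theta` contribute;
#' their weights sum to the complexity C, and the window extends from the
#' peak by the maximum contributing distance plus half the bandwidth
#' (150 bp at defaults) on each side. Peaks with no contributing site are
#' dropped.
#'
#' @param records TFBS table (`chrom`, `start`, `end`, `tf_id`, optional
#'   `cell_type`).
#' @param params a [kernel_params()].
#' @param scheme a [category_scheme()].
#' @param hot_tf_count HOT threshold on distinct TFs (strictly more than
#'   this count; default 40).
#' @return data.frame of class `clustered_regions`: `cell_type`, `chrom`,
#'   `peak`, `start`, `end` (window), `complexity`, `n_sites`,
#'   `n_distinct_tfs`, `category`, `band`, `is_hot`, `is_cold`.
#' @export
call_regions <- function(records, params = kernel_params(),
                         scheme = category_scheme(), hot_tf_count = 40L) {
  cell <- if ("cell_type" %in% names(records) && nrow(records))
    records$cell_type[1] else NA_character_
  out <- NULL
  if (nrow(records)) {
    if (!"tf_id" %in% names(records)) records$tf_id <- "TF"
    pos_all <- site_positions(records)
    for (chrom in unique(records$chrom)) {
      sel <- records$chrom == chrom
      sites <- sort(pos_all[sel])
      tf <- records$tf_id[sel][order(pos_all[sel])]
      prof <- compute_density(sites, params)
      peaks <- density_peaks(prof$positions, prof$density)
      for (p in peaks) {
        w <- kernel_weight(p - sites, params)
        contrib <- w >= params$theta
        if (!any(contrib)) next
        C <- sum(w[contrib])
        hw <- max(abs(p - sites)[contrib]) + params$bandwidth / 2
        out <- rbind(out, data.frame(
          cell_type = cell, chrom = chrom, peak = p,
          start = as.integer(p - hw), end = as.integer(p + hw),
          complexity = C, n_sites = sum(contrib),
          n_distinct_tfs = length(unique(tf[contrib])),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(cell_type = character(), chrom = character(),
                      peak = integer(), start = integer(), end = integer(),
                      complexity = numeric(), n_sites = integer(),
                      n_distinct_tfs = integer(), stringsAsFactors = FALSE)
  cat <- categorize(out$complexity, scheme)
  out$category <- cat$category
  out$band <- cat$band
  fl <- flag_hot_cold(out, hot_tf_count = hot_tf_count)
  out$is_hot <- fl$is_hot
  out$is_cold <- fl$is_cold
  class(out) <- c("clustered_regions", "data.frame")
  out
}

#' The ten-category complexity scheme
#'
#' Categories TC0..TC8 hold complexities below 6, 8, 10, 12, 14, 16, 19,
#' 23 and 30; TC9 holds everything from 30 up (the boundary value 30 is
#' assigned upward for consistency with the other half-open bounds).
#' Bands: TC0-TC2 low, TC3-TC7 median, TC8-TC9 high.
#'
#' @param bounds strictly increasing upper bounds for TC0..TC8.
#' @export
category_scheme <- function(bounds = c(6, 8, 10, 12, 14, 16, 19, 23, 30)) {
  stopifnot(length(bounds) == 9, all(diff(bounds) > 0))
  structure(list(bounds = bounds,
                 labels = paste0("TC", 0:9),
                 bands = c(rep("low", 3), rep("median", 5), rep("high", 2))),
            class = "category_scheme")
}

#' Assign complexity categories and bands
#'
#' @param C numeric complexity values (>= 0).
#' @param scheme a [category_scheme()].
#' @return data.frame with `category` (TC0..TC9) and `band`.
#' @export
categorize <- function(C, scheme = category_scheme()) {
  if (any(C < 0)) stop("negative complexity")
  idx <- findInterval(C, scheme$bounds) + 1L   # 1..10
  data.frame(category = scheme$labels[idx], band = scheme$bands[idx],
             stringsAsFactors = FALSE)
}

#' Flag HOT and COLD regions
#'
#' HOT: strictly more than `hot_tf_count` distinct TFs among the
#' contributing sites. COLD: lowest complexity category.
#'
#' @param regions `clustered_regions` table (needs `n_distinct_tfs`,
#'   `category`).
#' @param hot_tf_count HOT threshold (default 40).
#' @param cold_category COLD category label (default "TC0").
#' @export
flag_hot_cold <- function(regions, hot_tf_count = 40L,
                          cold_category = "TC0") {
  data.frame(is_hot = regions$n_distinct_tfs > hot_tf_count,
             is_cold = regions$category == cold_category)
}

#' Site concentration curve
#'
#' Adjacent-site intervals (within chromosomes) sorted ascending by length;
#' the curve plots the cumulative fraction of intervals (y) against the
#' cumulative fraction of the spanned genome (x). Tight clustering shows as
#' a steep rise at small x ("91% of sites in 0.8% of the genome").
#'
#' @param records TFBS table (>= 2 sites on some chromosome).
#' @return data.frame with `genome_fraction`, `interval_fraction`.
#' @export
site_concentration_curve <- function(records) {
  pos <- site_positions(records)
  gaps <- unlist(lapply(split(pos, records$chrom), function(p) {
    if (length(p) < 2L) numeric(0) else diff(sort(p))
  }), use.names = FALSE)
  if (length(gaps) < 1L) stop("need at least 2 sites on one chromosome")
  gaps <- sort(gaps)
  data.frame(genome_fraction = cumsum(gaps) / sum(gaps),
             interval_fraction = seq_along(gaps) / length(gaps))
}

## ------------------------------------------- geometric interval mixture

dgeom1 <- function(x, p, log = FALSE) {
  # geometric on {1, 2, ...}: P(X = x) = (1-p)^(x-1) p, mean 1/p
  lv <- (x - 1) * log1p(-p) + log(p)
  if (log) lv else exp(lv)
}

#' Quantile of the support-{1,2,...} geometric distribution
#'
#' `F(x) = 1 - (1-p)^x`, so `q(u) = ceil(log(1-u) / log(1-p))`.
#'
#' @param u probability.
#' @param mean distribution mean (`p = 1/mean`).
#' @export
geometric_quantile <- function(u, mean) {
  as.integer(ceiling(log(1 - u) / log1p(-1 / mean)))
}

#' Fit a two-component geometric mixture to adjacent-site gaps
#'
#' EM on gaps (bp, support 1, 2, ...) with k-means-on-log-gaps
#' initialisation and random restarts; separates within-cluster from
#' between-cluster intervals. Reports the within-component 99.5% quantile,
#' the model's estimate of cluster width.
#'
#' @param gaps positive integer gaps (>= 50 values).
#' @param max_iter,tol EM stopping rule (log-likelihood change below `tol`).
#' @param n_restarts number of jittered initialisations.
#' @param seed RNG seed for the restarts.
#' @return list of class `interval_mixture`: `within_mean`, `between_mean`,
#'   `weight` (within-component mixing weight), `within_q995`, `loglik`,
#'   `degenerate`.
#' @export
fit_interval_mixture <- function(gaps, max_iter = 500L, tol = 1e-8,
                                 n_restarts = 10L, seed = 1L) {
  if (any(gaps <= 0)) stop("gaps must be positive")
  if (length(gaps) < 50L) stop("need at least 50 gaps")
  gaps <- as.numeric(gaps)
  if (length(unique(gaps)) == 1L) {
    return(structure(list(within_mean = gaps[1], between_mean = NA_real_,
                          weight = 1, within_q995 = NA_integer_,
                          loglik = sum(dgeom1(gaps, 1 / gaps[1], log = TRUE)),
                          degenerate = TRUE),
                     class = "interval_mixture"))
  }
  best <- NULL
  old_seed <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = .GlobalEnv))
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    km <- tryCatch(kmeans(log(gaps), centers = 2, nstart = 1),
                   error = function(e) NULL)
    if (is.null(km)) next
    mu <- vapply(1:2, function(k) mean(gaps[km$cluster == k]), 0)
    ord <- order(mu)
    p <- pmin(1 / mu[ord], 0.999)
    w <- mean(km$cluster == which.min(mu))
    fit <- em_geometric(gaps, p, w, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("mixture fit failed to initialise")
  within_mean <- 1 / best$p[1]
  structure(list(within_mean = within_mean, between_mean = 1 / best$p[2],
                 weight = best$w,
                 within_q995 = geometric_quantile(0.995, within_mean),
                 loglik = best$loglik,
                 degenerate = best$degenerate),
            class = "interval_mixture")
}

em_geometric <- function(x, p, w, max_iter, tol) {
  ll_old <- -Inf
  degenerate <- FALSE
  for (it in seq_len(max_iter)) {
    l1 <- log(w) + dgeom1(x, p[1], log = TRUE)
    l2 <- log1p(-w) + dgeom1(x, p[2], log = TRUE)
    m <- pmax(l1, l2)
    ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
    g <- 1 / (1 + exp(l2 - l1))
    w <- mean(g)
    if (w < 1e-10 || w > 1 - 1e-10 || abs(p[1] - p[2]) < 1e-12) {
      degenerate <- TRUE
      break
    }
    p[1] <- min(sum(g) / sum(g * x), 0.999999)
    p[2] <- min(sum(1 - g) / sum((1 - g) * x), 0.999999)
    if (is.finite(ll) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (p[1] < p[2]) {  # keep within (short gaps, larger p) first
    p <- rev(p); w <- 1 - w
  }
  list(p = p, w = w, loglik = ll, degenerate = degenerate)
}
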