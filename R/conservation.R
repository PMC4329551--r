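# Evolutionary summaries over region groups: best 100-bp window
# conservation per region, bootstrap confidence intervals of group means,
# and per-nucleotide diversity (pi) from variant allele frequencies with
# mask removal.

#' Maximum sliding-window mean score within a region
#'
#' The best `window`-bp window of mean per-base score inside the region;
#' regions narrower than the window score as a single whole-region window.
#'
#' @param region one-row region table (`chrom`, `start`, `end`).
#' @param track score `signal_track` (phastCons-style).
#' @param window window width in bp (default 100).
#' @return list: `score`, `missing` (TRUE when the track has no data on
#'   the region's chromosome span).
#' @export
region_max_window_score <- function(region, track, window = 100L) {
  v <- track_values(track, region$chrom[1], region$start[1], region$end[1])
  r <- track$values[[region$chrom[1]]]
  missing <- is.null(r) || region$start[1] >= length(r)
  if (length(v) <= window)
    return(list(score = mean(v), missing = missing))
  cs <- c(0, cumsum(v))
  win_means <- (cs[(window + 1):length(cs)] -
                  cs[1:(length(cs) - window)]) / window
  list(score = max(win_means), missing = missing)
}

#' Per-region best-window scores for a region set
#'
#' @param regions region table.
#' @param track score `signal_track`.
#' @param window window width (default 100).
#' @return numeric vector of scores (NA for flagged-missing regions).
#' @export
region_scores <- function(regions, track, window = 100L) {
  vapply(seq_len(nrow(regions)), function(i) {
    r <- region_max_window_score(regions[i, , drop = FALSE], track, window)
    if (r$missing) NA_real_ else r$score
  }, 0)
}

#' Bootstrap mean and 95% CI of a group of scores
#'
#' `n_reps` bootstrap replicates each draw `n_values` values with
#' replacement; reports the grand mean of all draws and the 2.5% / 97.5%
#' quantiles of the replicate means.
#'
#' @param values numeric scores (non-empty; NAs dropped).
#' @param n_values draws per replicate (default 1000).
#' @param n_reps replicates (default 1000).
#' @param seed RNG seed.
#' @return list of class `conservation_summary`: `mean`, `ci_lo`,
#'   `ci_hi`, `n`.
#' @export
group_bootstrap_ci <- function(values, n_values = 1000L, n_reps = 1000L,
                               seed = 1L) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to resample")
  old_seed <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = .GlobalEnv))
  set.seed(seed)
  reps <- vapply(seq_len(n_reps), function(i) {
    mean(values[sample.int(length(values), n_values, replace = TRUE)])
  }, 0)
  ci <- quantile(reps, c(0.025, 0.975), names = FALSE)
  structure(list(mean = mean(reps), ci_lo = ci[1], ci_hi = ci[2],
                 n = length(values)),
            class = "conservation_summary")
}

#' Nucleotide diversity (pi) per base over a region set
#'
#' Unbiased per-site heterozygosity `2 p (1-p) n_h / (n_h - 1)` summed
#' over variant sites inside the unmasked region bases and divided by the
#' unmasked base count L. Mask intervals (e.g. repeats, exons, CpGs) are
#' removed from both the length and the site set.
#'
#' @param regions region table.
#' @param variants data.frame: `chrom`, `pos` (0-based), `p` (alternate
#'   allele frequency), `n_h` (haplotype count, >= 2).
#' @param masks optional interval table of bases to exclude.
#' @return list of class `diversity_summary`: `pi`, `L` (bases
#'   considered), `n_sites`, `masked_bp`.
#' @export
nucleotide_diversity <- function(regions, variants, masks = NULL) {
  if (nrow(variants) && any(variants$n_h < 2))
    stop("haplotype count below 2")
  reg <- GenomicRanges::reduce(gr0(regions))
  total_bp <- sum(GenomicRanges::width(reg))
  if (!is.null(masks) && nrow(masks))
    reg <- GenomicRanges::setdiff(reg, gr0(masks))
  L <- sum(GenomicRanges::width(reg))
  if (L <= 0) stop("no unmasked bases")
  n_sites <- 0L; num <- 0
  if (nrow(variants)) {
    vg <- gr0(data.frame(chrom = variants$chrom, start = variants$pos,
                         end = variants$pos + 1L))
    inside <- GenomicRanges::countOverlaps(vg, reg) > 0
    n_sites <- sum(inside)
    if (n_sites) {
      p <- variants$p[inside]; nh <- variants$n_h[inside]
      num <- sum(2 * p * (1 - p) * nh / (nh - 1))
    }
  }
  structure(list(pi = num / L, L = L, n_sites = n_sites,
                 masked_bp = total_bp - L),
            class = "diversity_summary")
}
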