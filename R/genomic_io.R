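#' @importFrom stats cor dist fft optim quantile rgeom rnorm rpois runif
#'   sd setNames median kmeans
#' @importFrom utils combn read.table write.table head tail
NULL

# All interval coordinates inside the package follow the BED convention:
# 0-based, half-open [start, end). Conversion to the 1-based closed
# convention of IRanges/GenomicRanges happens only inside the helpers below.

#' Construct a validated interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param ... further equal-length columns (e.g. `tf_id`, `cell_type`).
#' @return A `data.frame` with columns `chrom`, `start`, `end` and any extras,
#'   sorted by (chrom, start).
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-integer interval coordinates")
  if (any(start < 0L)) stop("negative start coordinate")
  bad <- which(start >= end)
  if (length(bad))
    stop("zero- or negative-width interval at entry ", bad[1],
         " (start >= end)")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   ..., stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# interval table -> GRanges (1-based closed), for overlap machinery only
gr0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# GRanges -> interval table (back to 0-based half-open)
df0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a BED3+ file of intervals or TF binding sites
#'
#' Column 4, when present, is taken as the TF identifier; `cell_type` can be
#' supplied to tag every record. Malformed lines are reported by number.
#'
#' @param path BED file path.
#' @param cell_type optional cell-type label attached to every record.
#' @return interval table with `tf_id` (if column 4 present) and `cell_type`
#'   (if given), sorted by (chrom, start).
#' @export
read_bed <- function(path, cell_type = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stop("coordinate error at BED line ", bad[1],
         ": need 0 <= start < end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(nf >= 4L)) df$tf_id <- vapply(fields, `[[`, "", 4L)
  if (!is.null(cell_type)) df$cell_type <- cell_type
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Write an interval table as BED
#'
#' @param df interval table (`chrom`, `start`, `end`, optional `tf_id`).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  if ("tf_id" %in% names(df)) cols <- c(cols, "tf_id")
  write.table(df[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Point position of TFBS records
#'
#' The anchor of a site is its interval midpoint, rounded down (the kernel in
#' [call_regions()] is centred on this point).
#'
#' @param df interval table.
#' @return integer vector of 0-based positions.
#' @export
site_positions <- function(df) {
  as.integer(floor((df$start + df$end) / 2))
}

## ------------------------------------------------------------------ tracks

new_signal_track <- function(rles) {
  structure(list(values = rles,
                 total = sum(vapply(rles, function(r) sum(as.numeric(r)),
                                    0))),
            class = "signal_track")
}

#' Build a per-base signal track from intervals and values
#'
#' Overlapping records are summed (tracks are additive read counts);
#' bases not covered by any record read as 0.
#'
#' @param df interval table.
#' @param value numeric vector, one value per interval.
#' @return a `signal_track` object.
#' @export
signal_track <- function(df, value) {
  stopifnot(nrow(df) == length(value))
  if (any(!is.finite(value))) stop("non-finite track values")
  gr <- gr0(df)
  cov <- GenomicRanges::coverage(gr, weight = value)
  new_signal_track(as.list(cov))
}

#' Read a bedGraph or wiggle signal track
#'
#' bedGraph records that overlap are summed. Both `fixedStep` and
#' `variableStep` wiggle sections are supported.
#'
#' @param path file path; format sniffed from content.
#' @return a `signal_track` object.
#' @export
read_signal_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(new_signal_track(list()))
  if (any(grepl("^(fixedStep|variableStep)", lines))) {
    return(parse_wig(lines))
  }
  fields <- strsplit(lines, "[ \t]+")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  val <- as.numeric(vapply(fields, `[[`, "", 4L))
  if (any(is.na(start) | is.na(end) | is.na(val)))
    stop("malformed bedGraph record")
  signal_track(data.frame(chrom = chrom, start = start, end = end,
                          stringsAsFactors = FALSE), val)
}

parse_wig <- function(lines) {
  hdr <- grepl("^(fixedStep|variableStep)", lines)
  sec <- cumsum(hdr)
  if (sec[1] == 0) stop("wig data before first step header")
  chroms <- character(); starts <- integer(); ends <- integer()
  vals <- numeric()
  for (s in unique(sec)) {
    block <- lines[sec == s]
    h <- block[1]
    get_attr <- function(name) {
      m <- regmatches(h, regexec(paste0(name, "=([^ \t]+)"), h))[[1]]
      if (length(m) < 2) NA_character_ else m[2]
    }
    chrom <- get_attr("chrom")
    span <- get_attr("span")
    span <- if (is.na(span)) 1L else as.integer(span)
    if (span <= 0L) stop("non-positive wig span")
    body <- block[-1]
    if (!length(body)) next
    if (grepl("^fixedStep", h)) {
      wstart <- as.integer(get_attr("start"))  # wig is 1-based
      step <- as.integer(get_attr("step"))
      if (is.na(step) || step <= 0L) stop("non-positive wig step")
      v <- as.numeric(body)
      st0 <- (wstart - 1L) + step * (seq_along(v) - 1L)
      chroms <- c(chroms, rep(chrom, length(v)))
      starts <- c(starts, st0); ends <- c(ends, st0 + span)
      vals <- c(vals, v)
    } else {
      f <- strsplit(body, "[ \t]+")
      pos <- as.integer(vapply(f, `[[`, "", 1L))
      v <- as.numeric(vapply(f, `[[`, "", 2L))
      st0 <- pos - 1L
      chroms <- c(chroms, rep(chrom, length(v)))
      starts <- c(starts, st0); ends <- c(ends, st0 + span)
      vals <- c(vals, v)
    }
  }
  signal_track(data.frame(chrom = chroms, start = starts, end = ends,
                          stringsAsFactors = FALSE), vals)
}

#' Write a signal track as bedGraph
#'
#' @param track a `signal_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    r <- track$values[[chrom]]
    rl <- S4Vectors::runLength(r); rv <- S4Vectors::runValue(r)
    end1 <- cumsum(rl)
    start0 <- end1 - rl
    keep <- rv != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, start0[keep], end1[keep],
                         format(rv[keep], trim = TRUE, scientific = FALSE)),
                 con)
  }
  invisible(path)
}

#' Extract per-base values from a track
#'
#' @param track a `signal_track`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open span.
#' @return numeric vector of length `end - start`; bases outside any record
#'   are 0.
#' @export
track_values <- function(track, chrom, start, end) {
  n <- end - start
  if (n <= 0L) return(numeric(0))
  r <- track$values[[chrom]]
  out <- numeric(n)
  if (is.null(r)) return(out)
  L <- length(r)
  lo <- max(start, 0L); hi <- min(end, L)
  if (hi > lo)
    out[(lo - start + 1L):(hi - start)] <-
      as.numeric(S4Vectors::window(r, lo + 1L, hi))
  out
}

#' Total signal over the whole track
#' @param track a `signal_track`.
#' @export
track_total <- function(track) track$total

## ---------------------------------------------------------------- merging

#' Merge intervals into their union
#'
#' Minimal set of disjoint intervals covering the union; abutting half-open
#' intervals ([0,10) and [10,20)) are treated as contiguous and merged.
#'
#' @param df interval table.
#' @return merged interval table, sorted.
#' @export
merge_intervals <- function(df) {
  if (!nrow(df)) return(df[, c("chrom", "start", "end")])
  df0(GenomicRanges::reduce(gr0(df)))
}

## ------------------------------------------------------------- annotation

#' Read a gene annotation (GFF3/GTF or BED12)
#'
#' Extracts per-gene TSS (strand-aware: 5' end), CDS and UTR segments and
#' derives introns as the gaps between exon blocks (between CDS/UTR blocks
#' when no exon features are present). Features extending outside their gene
#' span are clamped with a warning.
#'
#' @param path GFF3/GTF (`.gff`, `.gff3`, `.gtf`) or BED12 file.
#' @return object of class `gene_annotation`: list with `genes` (data.frame
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`), `cds`, `utr`,
#'   `introns` interval tables carrying `gene_id`.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.bed(12)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    return(annotation_from_bed12(gr))
  }
  gr <- rtracklayer::import(path)
  type <- tolower(as.character(gr$type))
  is_gene <- type == "gene"
  if (!any(is_gene)) stop("annotation has no gene features")
  gid <- annotation_gene_ids(gr)
  genes_gr <- gr[is_gene]
  genes <- data.frame(gene_id = gid[is_gene],
                      chrom = as.character(GenomicRanges::seqnames(genes_gr)),
                      start = GenomicRanges::start(genes_gr) - 1L,
                      end = GenomicRanges::end(genes_gr),
                      strand = as.character(GenomicRanges::strand(genes_gr)),
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  pick <- function(types) {
    sel <- type %in% types
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr[sel])),
               start = GenomicRanges::start(gr[sel]) - 1L,
               end = GenomicRanges::end(gr[sel]),
               gene_id = gid[sel], stringsAsFactors = FALSE)
  }
  cds <- pick("cds")
  utr <- pick(c("utr", "five_prime_utr", "three_prime_utr"))
  exon <- pick("exon")
  build_annotation(genes, cds, utr, exon)
}

annotation_gene_ids <- function(gr) {
  m <- S4Vectors::mcols(gr)
  for (col in c("gene_id", "ID", "Parent", "Name")) {
    if (col %in% names(m)) {
      v <- m[[col]]
      if (methods::is(v, "List") || is.list(v))
        v <- vapply(v, function(x) if (length(x)) as.character(x[1]) else NA_character_,
                    "")
      v <- as.character(v)
      if (!all(is.na(v))) return(v)
    }
  }
  rep(NA_character_, length(gr))
}

annotation_from_bed12 <- function(gr) {
  genes <- data.frame(gene_id = as.character(gr$name),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  exon <- cds <- utr <- NULL
  for (i in seq_along(gr)) {
    bl <- gr$blocks[[i]]
    ex <- data.frame(chrom = genes$chrom[i],
                     start = genes$start[i] + GenomicRanges::start(bl) - 1L,
                     end = genes$start[i] + GenomicRanges::end(bl),
                     gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
    exon <- rbind(exon, ex)
    th <- gr$thick[i]
    ts <- GenomicRanges::start(th) - 1L; te <- GenomicRanges::end(th)
    if (te > ts) {
      cg <- GenomicRanges::pintersect(
        gr0(ex), GenomicRanges::GRanges(ex$chrom[1],
                                        IRanges::IRanges(ts + 1L, te)),
        resolve.empty = "start.x")
      keep <- GenomicRanges::width(cg) > 0
      cd <- df0(cg[keep])
      if (nrow(cd)) {
        cd$gene_id <- genes$gene_id[i]
        cds <- rbind(cds, cd)
      }
      ug <- GenomicRanges::setdiff(gr0(ex), gr0(cd))
      if (length(ug)) {
        ut <- df0(ug); ut$gene_id <- genes$gene_id[i]
        utr <- rbind(utr, ut)
      }
    }
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      stringsAsFactors = FALSE)
  build_annotation(genes, if (is.null(cds)) empty else cds,
                   if (is.null(utr)) empty else utr,
                   if (is.null(exon)) empty else exon)
}

build_annotation <- function(genes, cds, utr, exon) {
  clamp <- function(df) {
    if (!nrow(df)) return(df)
    i <- match(df$gene_id, genes$gene_id)
    lo <- genes$start[i]; hi <- genes$end[i]
    out <- df$start < lo | df$end > hi
    if (any(out, na.rm = TRUE)) {
      warning(sum(out, na.rm = TRUE),
              " feature(s) outside gene span were clamped")
      df$start <- pmax(df$start, lo)
      df$end <- pmin(df$end, hi)
      df <- df[df$start < df$end, , drop = FALSE]
    }
    df
  }
  cds <- clamp(cds); utr <- clamp(utr); exon <- clamp(exon)
  introns <- derive_introns(genes, cds, utr, exon)
  structure(list(genes = genes, cds = cds, utr = utr, introns = introns),
            class = "gene_annotation")
}

derive_introns <- function(genes, cds, utr, exon) {
  out <- NULL
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    blocks <- exon[exon$gene_id == gid, , drop = FALSE]
    if (!nrow(blocks))
      blocks <- rbind(cds[cds$gene_id == gid, , drop = FALSE],
                      utr[utr$gene_id == gid, , drop = FALSE])
    if (nrow(blocks) < 2L) next
    merged <- merge_intervals(blocks)
    if (nrow(merged) < 2L) next
    gaps <- data.frame(chrom = merged$chrom[-nrow(merged)],
                       start = merged$end[-nrow(merged)],
                       end = merged$start[-1L],
                       gene_id = gid, stringsAsFactors = FALSE)
    gaps <- gaps[gaps$start < gaps$end, , drop = FALSE]
    out <- rbind(out, gaps)
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      stringsAsFactors = FALSE)
  out
}
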