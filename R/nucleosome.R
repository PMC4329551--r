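# Nucleosome structure around region sets: average occupancy anchored on
# region centres, positioning strength as the raw DFT magnitude at the
# nucleosomal repeat frequency (no taper; profile length is held fixed
# within a comparison so magnitudes are comparable), and central depletion
# as background-minus-centre occupancy.

#' Region-anchored average occupancy profile
#'
#' @param regions region table; anchors are window centres.
#' @param track occupancy `signal_track`.
#' @param flank half-window in bp (default 2000); the profile covers
#'   offsets `-flank..+flank` at 1 bp.
#' @return list of class `occupancy_profile`: `offset`, `occupancy`,
#'   `n_regions`.
#' @export
anchored_occupancy <- function(regions, track, flank = 2000L) {
  if (!nrow(regions)) stop("no regions")
  centre <- floor((regions$start + regions$end) / 2)
  acc <- numeric(2L * flank + 1L)
  n_used <- 0L
  for (i in seq_len(nrow(regions))) {
    if (centre[i] - flank < 0L) {
      warning("region ", i, " within flank of chromosome edge; skipped")
      next
    }
    acc <- acc + track_values(track, regions$chrom[i], centre[i] - flank,
                              centre[i] + flank + 1L)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no usable regions")
  structure(list(offset = seq.int(-flank, flank), occupancy = acc / n_used,
                 n_regions = n_used),
            class = "occupancy_profile")
}

#' Positioning power spectrum of an occupancy profile
#'
#' The mean-subtracted profile is Fourier transformed; positioning
#' strength is the magnitude at the frequency bin nearest
#' `1/repeat_length`. With `repeat_length = "auto"` the strongest bin in
#' the 150-250 bp period band is used.
#'
#' @param profile an [anchored_occupancy()] result (or plain numeric
#'   vector).
#' @param repeat_length nucleosomal repeat in bp (default 200) or
#'   `"auto"`.
#' @return list of class `positioning_spectrum`: `frequency` (cycles/bp),
#'   `power`, `repeat_length`, `power_at_repeat`, `peak_period` (period of
#'   the strongest band-limited bin).
#' @export
positioning_power <- function(profile, repeat_length = 200L) {
  x <- if (inherits(profile, "occupancy_profile")) profile$occupancy
       else as.numeric(profile)
  n <- length(x)
  auto <- identical(repeat_length, "auto")
  if (!auto && repeat_length <= 0) stop("repeat_length must be positive")
  if (!auto && n < 4L * repeat_length)
    stop("profile shorter than 4 repeat lengths")
  p <- Mod(fft(x - mean(x)))
  nyq <- floor(n / 2)
  freq <- (0:nyq) / n
  power <- p[1:(nyq + 1L)]
  band <- which(freq > 0 & freq >= 1 / 250 & freq <= 1 / 150)
  peak_period <- if (length(band)) 1 / freq[band[which.max(power[band])]]
                 else NA_real_
  if (auto) repeat_length <- peak_period
  idx <- which.min(abs(freq[-1] - 1 / repeat_length)) + 1L
  structure(list(frequency = freq, power = power,
                 repeat_length = repeat_length,
                 power_at_repeat = power[idx],
                 peak_period = peak_period),
            class = "positioning_spectrum")
}

#' Central nucleosome depletion of an occupancy profile
#'
#' `D` = mean occupancy over the two symmetric background windows (at
#' +/- `bg_offset`, extending `bg_halfwidth` inward) minus mean occupancy
#' over the centre window (offsets within `centre_halfwidth`). Positive D
#' means the centre is depleted.
#'
#' @param profile an [anchored_occupancy()] result.
#' @param centre_halfwidth centre window half-width in bp (default 50).
#' @param bg_offset background distance from centre in bp (default 2000).
#' @param bg_halfwidth background window half-width in bp (default 100).
#' @return list of class `depletion_stat`: `D`, `centre_mean`, `bg_mean`.
#' @export
nucleosome_depletion <- function(profile, centre_halfwidth = 50L,
                                 bg_offset = 2000L, bg_halfwidth = 100L) {
  off <- profile$offset
  if (max(off) < bg_offset || min(off) > -bg_offset)
    stop("profile does not span the background offset")
  # two symmetric windows extending inward from +/- bg_offset
  bg <- (off >= bg_offset - bg_halfwidth & off <= bg_offset) |
    (off <= -(bg_offset - bg_halfwidth) & off >= -bg_offset)
  if (!any(bg)) stop("background window outside profile")
  ctr <- abs(off) <= centre_halfwidth
  bg_mean <- mean(profile$occupancy[bg])
  centre_mean <- mean(profile$occupancy[ctr])
  structure(list(D = bg_mean - centre_mean, centre_mean = centre_mean,
                 bg_mean = bg_mean),
            class = "depletion_stat")
}
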