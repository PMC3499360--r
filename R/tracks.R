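#' Probe and base-resolution signal tracks
#'
#' A *probe track* is a tibble with columns `chrom`, `pos` and `value`: one
#' row per array probe, `pos` the probe midpoint in 0-based base pairs and
#' `value` the log2 ChIP/input enrichment (or a raw intensity before
#' [log2_ratio()]). Positions are strictly increasing within a chromosome.
#' Per-base tracks (e.g. DNase cleavage counts or densities) use the same
#' shape with one row per covered base, so every probe-track operation also
#' applies to them.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Numeric vector of 0-based positions (probe midpoints or bases).
#' @param value Numeric vector of finite signal values.
#' @return A tibble with columns `chrom`, `pos`, `value`, sorted by
#'   `(chrom, pos)`.
#' @examples
#' probe_track("chr4", c(50, 150, 250), c(0.1, 1.4, 0.2))
#' @export
probe_track <- function(chrom = character(), pos = numeric(), value = numeric()) {
  trk <- tibble(chrom = as.character(chrom), pos = as.numeric(pos),
                value = as.numeric(value))
  trk <- arrange(trk, .data$chrom, .data$pos)
  validate_track(trk)
  trk
}

validate_track <- function(trk) {
  stopifnot(is.data.frame(trk), all(c("chrom", "pos", "value") %in% names(trk)))
  if (nrow(trk) == 0) return(invisible(trk))
  if (any(!is.finite(trk$value))) stop("track values must be finite")
  dup <- trk |> group_by(.data$chrom) |>
    summarise(bad = any(diff(.data$pos) <= 0), .groups = "drop")
  if (any(dup$bad)) {
    stop("probe positions must be strictly increasing within chromosome ",
         dup$chrom[which(dup$bad)[1]])
  }
  invisible(trk)
}

# Apply a function per chromosome and reassemble, preserving sort order.
track_by_chrom <- function(trk, f) {
  if (nrow(trk) == 0) return(trk)
  parts <- split(trk, trk$chrom)
  out <- bind_rows(lapply(parts, f))
  arrange(out, .data$chrom, .data$pos)
}

# Indices of probes with start <= pos < end on one chromosome (pos sorted).
# Returns an integer range (lo, hi) with lo > hi when empty.
probe_range <- function(pos, start, end) {
  lo <- findInterval(start - 0.5, pos) + 1L
  hi <- findInterval(end - 0.5, pos)
  c(lo, hi)
}

#' Log2 ChIP/input enrichment ratio
#'
#' Converts paired intensity tracks on the same probe grid into a log2
#' enrichment track: `log2((chip + pseudocount) / (input + pseudocount))`.
#'
#' @param chip,input Probe tracks of non-negative intensities on an identical
#'   probe grid (same chromosomes and positions).
#' @param pseudocount Non-negative value added to both channels before the
#'   ratio; required when intensities can be zero.
#' @return A probe track of log2 ratios on the same grid.
#' @examples
#' chip  <- probe_track("chr4", c(50, 150), c(4, 3))
#' input <- probe_track("chr4", c(50, 150), c(1, 2))
#' log2_ratio(chip, input)
#' @export
log2_ratio <- function(chip, input, pseudocount = 0) {
  validate_track(chip); validate_track(input)
  stopifnot(pseudocount >= 0)
  check_same_grid(chip, input)
  num <- chip$value + pseudocount
  den <- input$value + pseudocount
  if (any(num <= 0) || any(den <= 0)) {
    stop("non-positive intensity with pseudocount ", pseudocount,
         "; use a positive pseudocount")
  }
  mutate(chip, value = log2(num / den))
}

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(a$chrom, b$chrom) || !identical(a$pos, b$pos)) {
    ka <- paste(a$chrom, a$pos); kb <- paste(b$chrom, b$pos)
    first <- c(setdiff(ka, kb), setdiff(kb, ka))[1]
    stop("probe grids differ (first discordant probe: ",
         if (is.na(first)) "row count" else first, ")")
  }
  invisible(TRUE)
}

#' Sliding-window smoothing of a probe track
#'
#' Replaces each probe value by the unweighted mean of all probes within
#' `bandwidth / 2` bp of it (both window ends inclusive), mirroring the
#' bandwidth convention of tiling-array smoothing. The probe grid is
#' unchanged.
#'
#' @param track A probe track.
#' @param bandwidth Window width in bp; default 200.
#' @return The smoothed probe track.
#' @examples
#' smooth_track(probe_track("chr4", c(0, 100, 200), c(0, 3, 0)), 200)
#' @export
smooth_track <- function(track, bandwidth = 200) {
  validate_track(track)
  stopifnot(bandwidth > 0)
  h <- bandwidth / 2
  track_by_chrom(track, function(d) {
    pos <- d$pos
    cs <- c(0, cumsum(d$value))
    lo <- findInterval(pos - h - 0.5, pos) + 1L
    hi <- findInterval(pos + h + 0.5 - 1e-9, pos)
    mutate(d, value = (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
  })
}

#' Average replicate tracks probe-wise
#'
#' @param tracks A list of probe tracks on identical grids.
#' @return A probe track of per-probe arithmetic means.
#' @export
average_replicates <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1)
  ref <- tracks[[1]]
  validate_track(ref)
  for (t in tracks[-1]) {
    validate_track(t)
    check_same_grid(ref, t)
  }
  vals <- rowMeans(do.call(cbind, lapply(tracks, `[[`, "value")))
  mutate(ref, value = vals)
}
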