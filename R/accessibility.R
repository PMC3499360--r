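#' DNase cleavage density in a sliding window
#'
#' For every covered base `p`, sums the cleavage counts in the `window`-bp
#' window `[p - floor(window/2), p + window - 1 - floor(window/2)]`
#' (centered, left-heavy by one base for even windows). Density is computed
#' only where counts are defined; at the edges of a covered run the window
#' is truncated to the run.
#'
#' @param counts Per-base count track (`chrom`, `pos`, `value`), with
#'   explicit zero rows across covered intervals; values must be >= 0.
#' @param window Window width in bp (default 150).
#' @param circular Treat each covered run as circular (no edge truncation);
#'   mainly for conservation checks. Default `FALSE`.
#' @return A per-base density track on the same positions.
#' @export
cleavage_density <- function(counts, window = 150, circular = FALSE) {
  validate_track(counts)
  stopifnot(window >= 1)
  if (any(counts$value < 0)) stop("cleavage counts must be >= 0")
  left <- window %/% 2
  right <- window - 1 - left
  track_by_chrom(counts, function(d) {
    runs <- cumsum(c(TRUE, diff(d$pos) != 1))
    for (rid in unique(runs)) {
      sel <- which(runs == rid)
      v <- d$value[sel]
      n <- length(v)
      i <- seq_len(n)
      if (circular) {
        vv <- c(v, v, v)
        cs <- c(0, cumsum(vv))
        dens <- cs[n + i + right + 1] - cs[n + i - left]
      } else {
        cs <- c(0, cumsum(v))
        dens <- cs[pmin(i + right, n) + 1] - cs[pmax(i - left, 1)]
      }
      d$value[sel] <- dens
    }
    d
  })
}

#' Region-stratified metagene profile of DNase accessibility
#'
#' The same eight-feature average gene profile as [region_metagene()], but
#' computed on a per-base density track: feature values are per-base means
#' of the density over the feature's intervals, then averaged gene-weighted
#' within regions.
#'
#' @param density Per-base density track from [cleavage_density()].
#' @inheritParams region_metagene
#' @return A `metagene_profile` tibble.
#' @export
accessibility_metagene <- function(density, ann, regions,
                                   expression_threshold = 0,
                                   promoter_width = 500) {
  region_metagene(density, ann, regions, expression_threshold, promoter_width)
}
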