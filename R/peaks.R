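#' Detect promoter peaks of a smoothed enrichment track
#'
#' Scans, per gene, the promoter interval extended by `flank` bp on both
#' sides and reports the probe of maximal value as the gene's promoter peak
#' when it reaches `min_height` and is a local maximum of the full track
#' (no smaller than either flanking probe). Ties go to the leftmost probe;
#' at most one peak per gene. Genes with an empty promoter are skipped.
#'
#' @param track A smoothed probe track (see [smooth_track()]).
#' @param feature_map Feature intervals from [build_feature_map()] (only the
#'   `P` rows are used).
#' @param min_height Minimum peak height in log2 units (> 0).
#' @param flank Extension of the promoter scan window in bp (default 100).
#' @return A tibble `gene_id`, `chrom`, `center`, `height`, one row per
#'   detected peak.
#' @export
detect_promoter_peaks <- function(track, feature_map, min_height, flank = 100) {
  validate_track(track)
  stopifnot(min_height > 0)
  proms <- feature_map |>
    filter(.data$feature == "P") |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), .groups = "drop")
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  out <- list()
  for (i in seq_len(nrow(proms))) {
    tr_idx <- by_chrom[[proms$chrom[i]]]
    if (is.null(tr_idx)) next
    pos <- track$pos[tr_idx]; val <- track$value[tr_idx]
    rng <- probe_range(pos, proms$start[i] - flank, proms$end[i] + flank)
    if (rng[1] > rng[2]) next
    win <- rng[1]:rng[2]
    j <- win[which.max(val[win])]       # which.max is leftmost on ties
    left_ok <- j == 1L || val[j] >= val[j - 1L]
    right_ok <- j == length(val) || val[j] >= val[j + 1L]
    if (val[j] >= min_height && left_ok && right_ok) {
      out[[length(out) + 1]] <- tibble(gene_id = proms$gene_id[i],
                                       chrom = proms$chrom[i],
                                       center = pos[j], height = val[j])
    }
  }
  if (length(out) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  center = numeric(), height = numeric()))
  }
  arrange(bind_rows(out), .data$chrom, .data$center)
}

#' Classify promoter-peak persistence across mutant genotypes
#'
#' A wild-type promoter peak is *methylation independent* when, in the
#' mutant lacking the region's methyltransferase, the peak is retained while
#' the gene-body enrichment is lost:
#' mutant height (maximum within `flank` bp of the wild-type center) at
#' least `retention_ratio` times the wild-type height AND mutant gene-body
#' mean at most `body_loss` times the wild-type gene-body mean. A peak whose
#' mutant height falls below the retention threshold is *methylation
#' dependent*; anything else (including peaks in regions with no mutant
#' track supplied) is *ambiguous*. Gene-body means are taken over the
#' exon-bin features `E1`-`E5`.
#'
#' @param peaks Wild-type peaks from [detect_promoter_peaks()].
#' @param wildtype_track The wild-type enrichment track used for detection.
#' @param mutant_tracks Named list of mutant tracks (names are genotypes,
#'   e.g. `"Setdb1"`, `"Su(var)3-9"`).
#' @param feature_map Feature intervals from [build_feature_map()].
#' @param gene_regions Tibble `gene_id`, `region` (from [assign_regions()]).
#' @param retention_ratio Minimum mutant/wild-type height ratio for
#'   retention (default 0.5).
#' @param body_loss Maximum mutant/wild-type body-mean ratio for loss
#'   (default 0.5).
#' @param region_genotype Named character vector mapping each region label
#'   to the mutant genotype whose methyltransferase serves it.
#' @param flank Search halfwidth around the wild-type center in bp
#'   (default 100).
#' @return `peaks` with added columns `region`, `mutant_genotype`,
#'   `mutant_height`, `body_wt`, `body_mutant`, `classification`
#'   (`"methylation_independent"`, `"methylation_dependent"` or
#'   `"ambiguous"`).
#' @export
classify_peak_persistence <- function(peaks, wildtype_track, mutant_tracks,
                                      feature_map, gene_regions,
                                      retention_ratio = 0.5, body_loss = 0.5,
                                      region_genotype = c(
                                        chr4 = "Setdb1", r2L31 = "Setdb1",
                                        pericentromeric = "Su(var)3-9"),
                                      flank = 100) {
  stopifnot(retention_ratio > 0, retention_ratio < 1, body_loss > 0)
  body_fm <- filter(feature_map, .data$feature %in% paste0("E", 1:5))
  body_wt <- body_means(wildtype_track, body_fm)
  body_mut <- lapply(mutant_tracks, body_means, body_fm = body_fm)

  out <- left_join(peaks, gene_regions[c("gene_id", "region")], by = "gene_id")
  out$region[is.na(out$region)] <- "excluded"
  out$mutant_genotype <- unname(region_genotype[out$region])
  out$mutant_height <- NA_real_
  out$body_wt <- unname(body_wt[out$gene_id])
  out$body_mutant <- NA_real_
  out$classification <- "ambiguous"

  missing_regions <- character()
  for (i in seq_len(nrow(out))) {
    gt <- out$mutant_genotype[i]
    if (is.na(gt) || is.null(mutant_tracks[[gt]])) {
      if (!is.na(gt)) missing_regions <- union(missing_regions, out$region[i])
      next
    }
    mt <- mutant_tracks[[gt]]
    sel <- mt$chrom == out$chrom[i]
    pos <- mt$pos[sel]; val <- mt$value[sel]
    rng <- probe_range(pos, out$center[i] - flank, out$center[i] + flank + 1)
    if (rng[1] > rng[2]) next
    mh <- max(val[rng[1]:rng[2]])
    out$mutant_height[i] <- mh
    bm <- body_mut[[gt]][out$gene_id[i]]
    out$body_mutant[i] <- unname(bm)
    retained <- mh >= retention_ratio * out$height[i]
    body_lost <- !is.na(bm) && !is.na(out$body_wt[i]) &&
      bm <= body_loss * out$body_wt[i]
    out$classification[i] <-
      if (retained && body_lost) "methylation_independent"
      else if (!retained) "methylation_dependent"
      else "ambiguous"
  }
  if (length(missing_regions)) {
    warning("no mutant track for region(s) ",
            paste(missing_regions, collapse = ", "),
            "; peaks there classified ambiguous")
  }
  out
}

body_means <- function(track, body_fm) {
  gp <- gene_profile(track, body_fm)
  agg <- gp |>
    filter(!is.na(.data$mean)) |>
    group_by(.data$gene_id) |>
    summarise(body = sum(.data$mean * .data$n_probes) / sum(.data$n_probes),
              .groups = "drop")
  setNames(agg$body, agg$gene_id)
}

#' Average signal of a track around a set of peak centers
#'
#' Pools the offsets `probe position - center` over all centers and averages
#' the track values in offset bins of width `binsize` covering
#' `[-halfwidth, +halfwidth)`. Used e.g. to profile a co-factor around
#' promoter-peak centers.
#'
#' @param track A probe track.
#' @param centers Tibble with `chrom` and `center` columns (e.g. peaks from
#'   [detect_promoter_peaks()]), or a numeric vector of centers when the
#'   track has a single chromosome.
#' @param halfwidth Window halfwidth in bp (a multiple of `binsize`).
#' @param binsize Offset bin width in bp.
#' @return A `peak_profile` tibble: `offset` (bin left edge),
#'   `offset_mid` (bin midpoint), `mean`, `n`; `mean` is `NA` for bins with
#'   no probes.
#' @export
peak_centered_profile <- function(track, centers, halfwidth = 1000,
                                  binsize = 100) {
  validate_track(track)
  stopifnot(halfwidth > 0, binsize > 0, halfwidth %% binsize == 0)
  if (is.numeric(centers)) {
    ch <- unique(track$chrom)
    stopifnot(length(ch) == 1)
    centers <- tibble(chrom = ch, center = as.numeric(centers))
  }
  nbin <- 2 * halfwidth / binsize
  sums <- numeric(nbin); ns <- integer(nbin)
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  for (i in seq_len(nrow(centers))) {
    tr_idx <- by_chrom[[centers$chrom[i]]]
    if (is.null(tr_idx)) next
    pos <- track$pos[tr_idx]
    rng <- probe_range(pos, centers$center[i] - halfwidth,
                       centers$center[i] + halfwidth)
    if (rng[1] > rng[2]) next
    idx <- rng[1]:rng[2]
    bin <- floor((pos[idx] - centers$center[i] + halfwidth) / binsize) + 1L
    v <- track$value[tr_idx][idx]
    for (b in unique(bin)) {
      sel <- bin == b
      sums[b] <- sums[b] + sum(v[sel])
      ns[b] <- ns[b] + sum(sel)
    }
  }
  out <- tibble(offset = -halfwidth + (seq_len(nbin) - 1L) * binsize,
                offset_mid = -halfwidth + (seq_len(nbin) - 0.5) * binsize,
                mean = ifelse(ns > 0, sums / pmax(ns, 1L), NA_real_),
                n = ns)
  class(out) <- c("peak_profile", class(out))
  out
}
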