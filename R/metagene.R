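#' Select the representative transcript of each gene
#'
#' Keeps, per gene, the most strongly expressed transcript; ties are broken
#' by longer span, then lexicographically smallest transcript id. This is the
#' transcript whose TSS, exons and promoter define all downstream features.
#'
#' @param ann An annotation tibble (see [annotation]).
#' @return An annotation tibble with one row per gene.
#' @export
select_transcripts <- function(ann) {
  validate_annotation(ann)
  ann |>
    mutate(.len = .data$span_end - .data$span_start) |>
    arrange(.data$gene_id, desc(.data$expression), desc(.data$.len),
            .data$transcript_id) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup() |>
    select(-".len") |>
    arrange(.data$chrom, .data$span_start, .data$gene_id)
}

#' Define promoter and intergenic intervals for selected transcripts
#'
#' The promoter extends 500 bp (by default) upstream of the TSS, truncated at
#' the nearest neighboring transcript boundary if that is closer; the
#' intergenic interval continues upstream of the promoter to the next
#' boundary. Boundaries are the span endpoints (as half-open cut points) of
#' all *other* selected transcripts on the same chromosome. Either interval
#' may be empty: the promoter when the TSS sits at the chromosome start (or
#' at a neighbor boundary), the intergenic interval when no further boundary
#' exists upstream.
#'
#' @param selected Annotation tibble with one row per gene (from
#'   [select_transcripts()]).
#' @param promoter_width Maximum promoter length in bp (default 500).
#' @return `selected` with added numeric columns `tss`, `p_start`, `p_end`,
#'   `ig_start`, `ig_end` (`NA` for empty intervals).
#' @export
define_promoters <- function(selected, promoter_width = 500) {
  stopifnot(promoter_width > 0)
  if (anyDuplicated(selected$gene_id)) {
    stop("define_promoters() expects one selected transcript per gene")
  }
  out <- selected
  out$tss <- tss(selected)
  out$p_start <- out$p_end <- out$ig_start <- out$ig_end <- NA_real_
  for (ch in unique(selected$chrom)) {
    idx <- which(selected$chrom == ch)
    for (i in idx) {
      own <- c(selected$span_start[i], selected$span_end[i])
      others <- setdiff(idx, i)
      cuts <- sort(c(selected$span_start[others], selected$span_end[others]))
      piv <- promoter_one(selected$strand[i], selected$span_start[i],
                          selected$span_end[i], cuts, promoter_width)
      out$p_start[i] <- piv$p[1]; out$p_end[i] <- piv$p[2]
      out$ig_start[i] <- piv$ig[1]; out$ig_end[i] <- piv$ig[2]
    }
  }
  out
}

# Promoter/intergenic cut-point arithmetic for one transcript.
# cuts: sorted half-open span endpoints of the other selected transcripts.
promoter_one <- function(strand, span_start, span_end, cuts, width) {
  empty <- c(NA_real_, NA_real_)
  if (strand == "+") {
    t0 <- span_start
    b1 <- max(c(cuts[cuts <= t0], 0))
    p <- c(max(t0 - width, b1), t0)
    if (p[1] >= p[2]) p <- empty
    ig <- empty
    if (!anyNA(p)) {
      b2 <- cuts[cuts <= p[1]]
      if (length(b2) && max(b2) < p[1]) ig <- c(max(b2), p[1])
    }
  } else {
    t0 <- span_end               # half-open cut just downstream of the TSS base
    up <- cuts[cuts >= t0]
    p <- c(t0, min(t0 + width, if (length(up)) min(up) else Inf))
    if (p[1] >= p[2]) p <- empty
    ig <- empty
    if (!anyNA(p)) {
      b2 <- cuts[cuts >= p[2]]
      if (length(b2) && min(b2) > p[2]) ig <- c(p[2], min(b2))
    }
  }
  list(p = p, ig = ig)
}

#' Build the 8-feature map of each gene
#'
#' For every selected transcript, produces the genomic intervals of the eight
#' metagene features: `IG` and `P` from [define_promoters()], `E1`-`E5` as
#' five equal bins over the *concatenated exons* in transcript (5' to 3')
#' order mapped back to genomic coordinates (a bin may split across an exon
#' junction), and `IN` as the span minus the exons. With concatenated exon
#' length `L`, bin `k` covers concatenated positions
#' `[floor((k-1) L / 5), floor(k L / 5))`; bins may be empty when `L < 5`.
#'
#' @param selected Annotation tibble with one row per gene; promoter columns
#'   are added via [define_promoters()] if absent.
#' @param promoter_width Passed to [define_promoters()] when needed.
#' @return A tidy tibble with columns `gene_id`, `chrom`, `strand`,
#'   `feature` (one of [metagene_features()]), `start`, `end`. Empty
#'   features have no rows.
#' @export
build_feature_map <- function(selected, promoter_width = 500) {
  if (!all(c("p_start", "ig_start") %in% names(selected))) {
    selected <- define_promoters(selected, promoter_width)
  }
  rows <- purrr::pmap(
    list(selected$gene_id, selected$chrom, selected$strand,
         selected$span_start, selected$span_end, selected$exons,
         selected$p_start, selected$p_end, selected$ig_start,
         selected$ig_end),
    feature_map_one)
  bind_rows(rows)
}

feature_map_one <- function(gene_id, chrom, strand, span_start, span_end,
                            exons, p_start, p_end, ig_start, ig_end) {
  feat <- list()
  if (!is.na(ig_start)) feat$IG <- cbind(ig_start, ig_end)
  if (!is.na(p_start)) feat$P <- cbind(p_start, p_end)
  bins <- exon_bins(exons, strand)
  for (k in 1:5) {
    b <- bins[[k]]
    if (nrow(b)) feat[[paste0("E", k)]] <- as.matrix(b)
  }
  if (nrow(exons) > 1) {
    feat$IN <- cbind(exons$end[-nrow(exons)], exons$start[-1])
  }
  present <- names(feat)
  bind_rows(lapply(present, function(f) {
    m <- feat[[f]]
    tibble(gene_id = gene_id, chrom = chrom, strand = strand, feature = f,
           start = as.numeric(m[, 1]), end = as.numeric(m[, 2]))
  }))
}

# Split the concatenated exons of one transcript into 5 genomic bin interval
# sets. Exons arrive in genomic order; transcript order reverses them (and
# the within-exon direction) on the minus strand.
exon_bins <- function(exons, strand) {
  lens <- exons$end - exons$start
  L <- sum(lens)
  edges <- floor((0:5) * L / 5)
  ord <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  offs <- cumsum(c(0, lens[ord]))   # concatenated start offset of each exon
  out <- vector("list", 5)
  for (k in 1:5) {
    a <- edges[k]; b <- edges[k + 1]
    pieces <- list()
    if (b > a) {
      for (j in seq_along(ord)) {
        e <- ord[j]
        lo <- max(a, offs[j]); hi <- min(b, offs[j] + lens[e])
        if (hi > lo) {
          if (strand == "+") {
            g <- c(exons$start[e] + (lo - offs[j]),
                   exons$start[e] + (hi - offs[j]))
          } else {
            g <- c(exons$end[e] - (hi - offs[j]),
                   exons$end[e] - (lo - offs[j]))
          }
          pieces[[length(pieces) + 1]] <- g
        }
      }
    }
    out[[k]] <- if (length(pieces)) {
      m <- do.call(rbind, pieces)
      as.data.frame(m[order(m[, 1]), , drop = FALSE])
    } else data.frame(V1 = numeric(), V2 = numeric())
  }
  out
}

#' Per-gene feature means of a signal track
#'
#' The value of feature `f` for a gene is the mean of all track values whose
#' position falls in any interval of `f` (half-open); features with no
#' covered position are `NA`.
#'
#' @param track A probe track (or per-base track; see [probe_track]).
#' @param feature_map Tidy feature intervals from [build_feature_map()].
#' @return A tibble `gene_id`, `feature`, `mean`, `n_probes`, one row per
#'   (gene, feature) present in `feature_map`.
#' @export
gene_profile <- function(track, feature_map) {
  validate_track(track)
  if (nrow(feature_map) == 0) {
    return(tibble(gene_id = character(), feature = character(),
                  mean = numeric(), n_probes = integer()))
  }
  pos_by_chrom <- split(seq_len(nrow(track)), track$chrom)
  sums <- numeric(nrow(feature_map))
  ns <- integer(nrow(feature_map))
  for (ch in unique(feature_map$chrom)) {
    rows <- which(feature_map$chrom == ch)
    tr_idx <- pos_by_chrom[[ch]]
    if (is.null(tr_idx)) next
    pos <- track$pos[tr_idx]
    cs <- c(0, cumsum(track$value[tr_idx]))
    lo <- findInterval(feature_map$start[rows] - 0.5, pos) + 1L
    hi <- findInterval(feature_map$end[rows] - 0.5, pos)
    ok <- hi >= lo
    sums[rows[ok]] <- cs[hi[ok] + 1L] - cs[lo[ok]]
    ns[rows[ok]] <- hi[ok] - lo[ok] + 1L
  }
  feature_map |>
    mutate(.sum = sums, .n = ns) |>
    group_by(.data$gene_id, .data$feature) |>
    summarise(mean = if (sum(.data$.n) > 0) sum(.data$.sum) / sum(.data$.n)
              else NA_real_,
              n_probes = sum(.data$.n), .groups = "drop")
}

#' Assign genes to regions by TSS position
#'
#' @param selected Annotation tibble with one row per gene.
#' @param regions Tibble with `chrom`, `start`, `end`, `region` defining
#'   disjoint labeled intervals.
#' @return `selected` with a `region` column; genes whose TSS falls in no
#'   labeled interval get `"excluded"`.
#' @export
assign_regions <- function(selected, regions) {
  t <- tss(selected)
  lab <- rep("excluded", nrow(selected))
  for (i in seq_len(nrow(regions))) {
    hit <- selected$chrom == regions$chrom[i] & t >= regions$start[i] &
      t < regions$end[i]
    lab[hit] <- regions$region[i]
  }
  mutate(selected, region = lab)
}

#' Region-stratified 8-feature average gene profile
#'
#' Computes, for every region, the gene-weighted metagene profile of a signal
#' track over active genes: each active gene contributes its eight per-gene
#' feature means (from [gene_profile()]), and the region value of a feature
#' is the unweighted mean over genes with at least one covered position in
#' that feature. A gene is *active* when the expression of its selected
#' transcript exceeds `expression_threshold`.
#'
#' @param track A probe track of log2 enrichment (or a per-base density
#'   track).
#' @param ann An annotation tibble.
#' @param regions Region partition tibble (`chrom`, `start`, `end`,
#'   `region`).
#' @param expression_threshold Activity cutoff; default 0 (active means
#'   expression > 0).
#' @param promoter_width Promoter length in bp (default 500).
#' @return A `metagene_profile` tibble: `region`, `feature`, `mean`,
#'   `n_genes`, with `feature` ordered `IG, P, E1..E5, IN` and `NA` means
#'   where no gene contributed.
#' @export
region_metagene <- function(track, ann, regions, expression_threshold = 0,
                            promoter_width = 500) {
  stopifnot(expression_threshold >= 0)
  sel <- select_transcripts(ann)
  sel <- define_promoters(sel, promoter_width)
  sel <- assign_regions(sel, regions)
  active <- sel[sel$expression > expression_threshold, ]
  grid <- tidyr::expand_grid(region = setdiff(unique(regions$region), NA),
                             feature = METAGENE_FEATURES)
  if (nrow(active) == 0) {
    out <- mutate(grid, mean = NA_real_, n_genes = 0L)
    return(new_metagene_profile(out))
  }
  fm <- build_feature_map(active, promoter_width)
  gp <- gene_profile(track, fm)
  gp <- left_join(gp, active[c("gene_id", "region")], by = "gene_id")
  agg <- gp |>
    filter(!is.na(.data$mean)) |>
    group_by(.data$region, .data$feature) |>
    summarise(mean = mean(.data$mean), n_genes = dplyr::n(), .groups = "drop")
  out <- left_join(grid, agg, by = c("region", "feature")) |>
    mutate(n_genes = ifelse(is.na(.data$n_genes), 0L, .data$n_genes))
  new_metagene_profile(out)
}

new_metagene_profile <- function(df, genotype = NULL, antibody = NULL) {
  df$feature <- factor(df$feature, levels = METAGENE_FEATURES)
  df <- arrange(df, .data$region, .data$feature)
  if (!is.null(genotype)) df$genotype <- genotype
  if (!is.null(antibody)) df$antibody <- antibody
  class(df) <- c("metagene_profile", class(df))
  df
}
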