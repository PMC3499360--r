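#' Is a promoter bound by a factor?
#'
#' A promoter counts as bound when any factor interval overlaps it by at
#' least `min_overlap` bp (half-open semantics: abutting intervals do not
#' overlap).
#'
#' @param factor_intervals Tibble with `chrom`, `start`, `end` (e.g. from
#'   [read_intervals()]).
#' @param promoter A one-row tibble or list with `chrom`, `start`, `end`.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return `1L` or `0L`.
#' @examples
#' classify_promoter_bound(tibble::tibble(chrom = "chr4", start = 900, end = 1100),
#'                         list(chrom = "chr4", start = 1000, end = 1500))
#' @export
classify_promoter_bound <- function(factor_intervals, promoter,
                                    min_overlap = 1) {
  ov <- overlap_widths(factor_intervals, promoter$chrom[[1]],
                       promoter$start[[1]], promoter$end[[1]])
  as.integer(any(ov >= min_overlap))
}

overlap_widths <- function(iv, chrom, start, end) {
  sel <- iv$chrom == chrom
  pmax(0, pmin(iv$end[sel], end) - pmax(iv$start[sel], start))
}

#' Binary factor-occupancy matrix with a prevalence filter
#'
#' Classifies every promoter as bound/unbound by every factor (interval
#' overlap, see [classify_promoter_bound()]), computes each factor's
#' prevalence among *active-gene* promoters of the prevalence region, and
#' keeps the factors whose prevalence strictly exceeds `threshold`. The
#' emitted matrix covers all supplied promoters (ordered by chromosome,
#' then coordinate) and the passing factors, in input order.
#'
#' @param promoters Tibble with `gene_id`, `chrom`, `start`, `end`,
#'   `region`, `active` (logical) - one row per promoter.
#' @param factors Named list of factor interval tibbles (`chrom`, `start`,
#'   `end`).
#' @param prevalence_region Region whose active promoters define prevalence
#'   (default `"chr4"`).
#' @param threshold Strict prevalence cutoff (default 0.5: "> 50%").
#' @param min_overlap Minimum overlap in bp for "bound" (default 1).
#' @return An `occupancy_matrix` object: a list with `matrix` (wide tibble,
#'   `gene_id` + one 0/1 column per passing factor), `long` (all factors,
#'   `gene_id`, `factor`, `bound`), `prevalence` (`factor`,
#'   `prevalence`, `passing`), `passing` (character vector), plus the
#'   parameters. [tidy()], [glance()] and [autoplot()] methods are
#'   provided.
#' @export
occupancy_matrix <- function(promoters, factors, prevalence_region = "chr4",
                             threshold = 0.5, min_overlap = 1) {
  stopifnot(length(factors) >= 1, !is.null(names(factors)),
            all(nzchar(names(factors))),
            all(c("gene_id", "chrom", "start", "end", "region", "active") %in%
                  names(promoters)))
  promoters <- arrange(promoters, .data$chrom, .data$start)
  prev_idx <- promoters$region == prevalence_region & promoters$active
  if (!any(prev_idx)) {
    stop("no active promoters in prevalence region '", prevalence_region, "'")
  }
  long <- bind_rows(lapply(names(factors), function(f) {
    iv <- factors[[f]]
    bound <- vapply(seq_len(nrow(promoters)), function(i)
      as.integer(any(overlap_widths(iv, promoters$chrom[i],
                                    promoters$start[i],
                                    promoters$end[i]) >= min_overlap)),
      integer(1))
    tibble(gene_id = promoters$gene_id, factor = f, bound = bound)
  }))
  prevalence <- long |>
    filter(.data$gene_id %in% promoters$gene_id[prev_idx]) |>
    group_by(.data$factor) |>
    summarise(prevalence = mean(.data$bound), .groups = "drop")
  prevalence <- prevalence[match(names(factors), prevalence$factor), ]
  prevalence$passing <- prevalence$prevalence > threshold
  passing <- prevalence$factor[prevalence$passing]
  wide <- long |>
    filter(.data$factor %in% passing) |>
    tidyr::pivot_wider(names_from = "factor", values_from = "bound")
  wide <- left_join(promoters[c("gene_id", "chrom", "start", "region")],
                    wide, by = "gene_id")
  structure(list(matrix = wide, long = long, prevalence = prevalence,
                 passing = passing, prevalence_region = prevalence_region,
                 threshold = threshold, min_overlap = min_overlap),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat("Promoter occupancy matrix: ", nrow(x$matrix), " promoters x ",
      nrow(x$prevalence), " factors; ", length(x$passing),
      " factor(s) bound to > ", x$threshold * 100, "% of active ",
      x$prevalence_region, " promoters\n", sep = "")
  invisible(x)
}

#' @rdname occupancy_matrix
#' @param x An `occupancy_matrix`.
#' @param ... Unused.
#' @export
tidy.occupancy_matrix <- function(x, ...) x$long

#' @rdname occupancy_matrix
#' @export
glance.occupancy_matrix <- function(x, ...) {
  tibble(n_promoters = nrow(x$matrix), n_factors = nrow(x$prevalence),
         n_passing = length(x$passing), threshold = x$threshold,
         prevalence_region = x$prevalence_region)
}

#' Promoter table for occupancy analysis
#'
#' Convenience builder: selected transcripts + promoter definitions +
#' region labels, reduced to one promoter interval per gene.
#'
#' @param ann Annotation tibble.
#' @param regions Region partition tibble.
#' @param expression_threshold Activity cutoff (default 0).
#' @param promoter_width Promoter length in bp (default 500).
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, `region`, `active`
#'   (promoterless genes are dropped).
#' @export
promoter_table <- function(ann, regions, expression_threshold = 0,
                           promoter_width = 500) {
  sel <- define_promoters(select_transcripts(ann), promoter_width)
  sel <- assign_regions(sel, regions)
  sel <- filter(sel, !is.na(.data$p_start))
  tibble(gene_id = sel$gene_id, chrom = sel$chrom, start = sel$p_start,
         end = sel$p_end, region = sel$region,
         active = sel$expression > expression_threshold)
}
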