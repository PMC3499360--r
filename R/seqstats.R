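#' Extract fixed-width sequence flanks around peak centers
#'
#' Returns one sequence of `2 * flank + 1` bp per peak, centered on the peak
#' center (half-open genomic window `[center - flank, center + flank + 1)`),
#' clipped with a warning at chromosome ends. Peaks whose center lies
#' outside the chromosome are skipped with a warning.
#'
#' @param peaks Tibble with `gene_id`, `chrom`, `center` columns.
#' @param sequences Named character vector of chromosome sequences (see
#'   [read_fasta()]).
#' @param flank Halfwidth in bp (default 50).
#' @return A tibble `gene_id`, `chrom`, `center`, `seq`. Use
#'   [write_fasta()] with `name = paste(gene_id, center, sep = "_")` style
#'   headers to serialize.
#' @export
extract_peak_flanks <- function(peaks, sequences, flank = 50) {
  stopifnot(flank >= 0)
  keep <- logical(nrow(peaks))
  seqs <- character(nrow(peaks))
  clipped <- FALSE
  for (i in seq_len(nrow(peaks))) {
    s <- sequences[[peaks$chrom[i]]]
    if (is.null(s) || peaks$center[i] < 0 || peaks$center[i] >= nchar(s)) {
      warning("peak center outside sequence: ", peaks$gene_id[i],
              " (", peaks$chrom[i], ":", peaks$center[i], "); skipped")
      next
    }
    lo <- max(0, peaks$center[i] - flank)
    hi <- min(nchar(s), peaks$center[i] + flank + 1)
    if (hi - lo < 2 * flank + 1) clipped <- TRUE
    seqs[i] <- substr(s, lo + 1, hi)
    keep[i] <- TRUE
  }
  if (clipped) warning("flank window clipped at chromosome end")
  out <- peaks[keep, c("gene_id", "chrom", "center")]
  out$seq <- seqs[keep]
  out
}

#' A/T fraction of DNA sequences
#'
#' `(#A + #T) / (#A + #C + #G + #T)`; `N` bases count in neither numerator
#' nor denominator. A sequence with no informative base yields `NA`.
#'
#' @param seq Character vector of sequences (alphabet `ACGTN`,
#'   case-insensitive).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' at_content(c("AATT", "ACGT", "ACGN"))
#' @export
at_content <- function(seq) {
  seq <- toupper(seq)
  at <- nchar(gsub("[^AT]", "", seq))
  acgt <- nchar(gsub("[^ACGT]", "", seq))
  ifelse(acgt > 0, at / acgt, NA_real_)
}

#' Position-weight-matrix motif model
#'
#' @param prob Numeric matrix of per-position base probabilities, L rows and
#'   4 columns named `A`, `C`, `G`, `T`; rows must sum to 1. A pseudocount
#'   can be folded in beforehand so all entries are positive.
#' @param background Background base probabilities (named, summing to 1).
#' @return A `motif_model` list with elements `prob`, `background` and the
#'   log2-odds matrix `log_odds`.
#' @export
motif_model <- function(prob, background = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25)) {
  prob <- as.matrix(prob)
  stopifnot(ncol(prob) == 4)
  colnames(prob) <- toupper(colnames(prob))
  stopifnot(identical(sort(colnames(prob)), c("A", "C", "G", "T")))
  prob <- prob[, c("A", "C", "G", "T"), drop = FALSE]
  background <- background[c("A", "C", "G", "T")]
  if (any(abs(rowSums(prob) - 1) > 1e-9)) stop("PWM rows must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (any(prob <= 0) || any(background <= 0)) {
    stop("probabilities must be positive (apply a pseudocount)")
  }
  structure(list(prob = prob, background = background,
                 log_odds = log2(sweep(prob, 2, background, `/`))),
            class = "motif_model")
}

#' Read a PWM from a 4-column whitespace table
#'
#' One row per motif position, columns `A C G T` (a header row naming them
#' is optional; column order A, C, G, T is assumed without one). Counts are
#' normalized to probabilities with an added pseudocount.
#'
#' @param path Path to the table.
#' @param background Background base probabilities.
#' @param pseudocount Added to every cell before normalization
#'   (default 1e-3).
#' @return A [motif_model()].
#' @export
read_pwm <- function(path, background = c(A = 0.25, C = 0.25, G = 0.25,
                                          T = 0.25), pseudocount = 1e-3) {
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (is.character(raw[[1]])) {  # header row present
    raw <- utils::read.table(path, header = TRUE, comment.char = "#")
  }
  m <- as.matrix(raw)
  colnames(m) <- c("A", "C", "G", "T")
  m <- m + pseudocount
  motif_model(m / rowSums(m), background)
}

#' Maximum log-odds motif score of a sequence
#'
#' Scans every window of motif length on both strands and returns the
#' maximum (or, with `aggregate = "sum"`, the sum over all valid windows) of
#' the per-window score `sum_i log2(p_i(base_i) / bg(base_i))` in bits.
#' Windows containing `N` are skipped; a sequence with no valid window
#' (including sequences shorter than the motif, which also warn) yields
#' `NA`.
#'
#' @param seq Character vector of sequences.
#' @param motif A [motif_model()].
#' @param aggregate `"max"` (default) or `"sum"` over valid windows.
#' @return Numeric vector of scores in bits.
#' @export
pwm_max_score <- function(seq, motif, aggregate = c("max", "sum")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(motif, "motif_model"))
  vapply(toupper(seq), pwm_score_one, numeric(1), motif = motif,
         aggregate = aggregate, USE.NAMES = FALSE)
}

pwm_score_one <- function(s, motif, aggregate) {
  L <- nrow(motif$log_odds)
  if (nchar(s) < L) {
    warning("sequence shorter than motif (", nchar(s), " < ", L, ")")
    return(NA_real_)
  }
  scores <- c(pwm_window_scores(s, motif$log_odds),
              pwm_window_scores(revcomp(s), motif$log_odds))
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) return(NA_real_)
  if (aggregate == "max") max(scores) else sum(scores)
}

pwm_window_scores <- function(s, lom) {
  L <- nrow(lom)
  code <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  n <- length(code) - L + 1
  if (n < 1) return(numeric())
  vapply(seq_len(n), function(w) {
    b <- code[w:(w + L - 1)]
    if (anyNA(b)) NA_real_ else sum(lom[cbind(seq_len(L), b)])
  }, numeric(1))
}

#' Reverse complement of DNA strings
#'
#' @param seq Character vector (alphabet `ACGTN`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s)
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(s), "",
                                                fixed = TRUE)[[1]]),
                                   collapse = "")),
    character(1), USE.NAMES = FALSE)
}

#' Mann-Whitney U test (two-sided)
#'
#' Computes the rank-sum statistic `U` (for `x`, with midranks on ties) and
#' a two-sided p value: exactly, from the full permutation distribution,
#' when `mode = "exact"` or in auto mode when `n1 + n2 <= 16` with no ties;
#' otherwise by the normal approximation with tie correction and continuity
#' correction. Two samples with all values identical are flagged degenerate
#' with `p = 1`.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @return An object of class `mwu` with elements `statistic` (U of `x`),
#'   `p.value`, `n1`, `n2`, `method`, `degenerate`. [tidy()] and [glance()]
#'   methods are provided.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1) {
    return(new_mwu(U, 1, n1, n2, "degenerate", TRUE))
  }
  exact <- switch(mode, exact = TRUE, approx = FALSE,
                  auto = (n1 + n2 <= 16) && !ties)
  if (exact && ties) {
    warning("ties present; falling back to the normal approximation")
    exact <- FALSE
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  new_mwu(U, wt$p.value, n1, n2, if (exact) "exact" else "normal approximation",
          FALSE)
}

new_mwu <- function(U, p, n1, n2, method, degenerate) {
  structure(list(statistic = U, p.value = p, n1 = n1, n2 = n2,
                 method = method, degenerate = degenerate), class = "mwu")
}

#' @export
print.mwu <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ")\n", sep = "")
  cat("  U = ", x$statistic, ", n = (", x$n1, ", ", x$n2, "), p = ",
      format(x$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname mann_whitney_u
#' @param x An `mwu` object.
#' @param ... Unused.
#' @export
tidy.mwu <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, n1 = x$n1, n2 = x$n2,
         method = x$method, degenerate = x$degenerate)
}

#' @rdname mann_whitney_u
#' @export
glance.mwu <- function(x, ...) tidy.mwu(x)

#' Compare a promoter statistic between regions and a control region
#'
#' Runs one two-sided Mann-Whitney U test per non-control region against the
#' control region (e.g. A/T content or motif scores of promoters on
#' chromosome 4, region 2L:31 and the pericentromeric blocks against the
#' remaining euchromatin). No multiple-testing correction is applied by
#' default; set `adjust = "bonferroni"` to opt in.
#'
#' @param data Tibble with a region column and a value column.
#' @param value Name of the value column (default `"value"`).
#' @param region Name of the region column (default `"region"`).
#' @param control Label of the control region (default `"euchromatic"`).
#' @param alpha Significance level for the flag (default 0.01).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @param mode Passed to [mann_whitney_u()].
#' @return A tibble with one row per tested region: `region`, `control`,
#'   `n1`, `n2`, `statistic`, `p.value`, `significant`.
#' @export
compare_promoter_groups <- function(data, value = "value", region = "region",
                                    control = "euchromatic", alpha = 0.01,
                                    adjust = c("none", "bonferroni"),
                                    mode = "auto") {
  adjust <- match.arg(adjust)
  vals <- data[[value]]; regs <- data[[region]]
  keep <- !is.na(vals)
  vals <- vals[keep]; regs <- regs[keep]
  ctrl <- vals[regs == control]
  if (length(ctrl) == 0) stop("no values in control region '", control, "'")
  test_regions <- setdiff(unique(regs), c(control, "excluded"))
  rows <- list()
  for (rg in test_regions) {
    g <- vals[regs == rg]
    if (length(g) < 3) {
      warning("region ", rg, " has fewer than 3 values; skipped")
      next
    }
    m <- mann_whitney_u(g, ctrl, mode = mode)
    rows[[length(rows) + 1]] <- tibble(region = rg, control = control,
                                       n1 = m$n1, n2 = m$n2,
                                       statistic = m$statistic,
                                       p.value = m$p.value)
  }
  out <- bind_rows(rows)
  if (nrow(out)) {
    if (adjust == "bonferroni") {
      out$p.value <- stats::p.adjust(out$p.value, method = "bonferroni")
    }
    out$significant <- out$p.value < alpha
  }
  out
}
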