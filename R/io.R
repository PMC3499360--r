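#' Gene annotation tables
#'
#' Annotations are tibbles with one row per transcript and columns
#' `gene_id`, `transcript_id`, `chrom`, `strand` (`"+"`/`"-"`), `span_start`,
#' `span_end` (0-based half-open), `expression` (non-negative, arbitrary
#' units) and `exons`, a list-column of data frames with `start`/`end`
#' columns. Exons are sorted, non-overlapping, contained in the span, and the
#' first/last exon boundaries coincide with the span boundaries. The TSS is
#' the 5'-most transcribed base: `span_start` on `+`, `span_end - 1` on `-`.
#'
#' @name annotation
NULL

#' Read a GFF3 annotation plus a transcript expression table
#'
#' Parses `gene`/`mRNA`/`exon` records linked by `Parent` attributes and
#' joins per-transcript expression values. GFF3's 1-based closed coordinates
#' are converted to the package's 0-based half-open convention on read.
#' Transcripts missing from the expression table get expression 0 with a
#' warning.
#'
#' @param path Path to a GFF3 file.
#' @param expression Path to a tab-separated table with columns
#'   `transcript_id` and `expression`, or a data frame with those columns,
#'   or `NULL` (all transcripts get expression 0, silently).
#' @return An annotation tibble (see [annotation]), ordered by
#'   `(chrom, span_start, gene_id, transcript_id)`.
#' @export
read_annotation <- function(path, expression = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("failed to parse GFF3 '", path, "': ",
                                          conditionMessage(e)))
  type <- as.character(gr$type)
  md <- S4Vectors::mcols(gr)
  ids <- as.character(md$ID)
  parents <- vapply(as.list(md$Parent), function(p)
    if (length(p) == 0) NA_character_ else as.character(p[1]), character(1))

  gene_ids <- ids[type == "gene"]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene_id in '", path, "': ",
         gene_ids[duplicated(gene_ids)][1])
  }

  is_mrna <- type == "mRNA"
  if (any(is_mrna & is.na(parents))) {
    stop("mRNA record without Parent gene in '", path, "': ",
         ids[is_mrna & is.na(parents)][1])
  }
  is_exon <- type == "exon"
  if (any(is_exon & is.na(parents))) {
    stop("exon without parent mRNA in '", path, "' at line ",
         orphan_exon_line(path))
  }

  mrna <- tibble(
    transcript_id = ids[is_mrna],
    gene_id = parents[is_mrna],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_mrna],
    strand = as.character(BiocGenerics::strand(gr))[is_mrna],
    span_start = GenomicRanges::start(gr)[is_mrna] - 1,
    span_end = as.numeric(GenomicRanges::end(gr)[is_mrna])
  )
  if (any(!mrna$strand %in% c("+", "-"))) {
    stop("mRNA with undefined strand: ",
         mrna$transcript_id[!mrna$strand %in% c("+", "-")][1])
  }

  ex <- tibble(
    transcript_id = parents[is_exon],
    start = GenomicRanges::start(gr)[is_exon] - 1,
    end = as.numeric(GenomicRanges::end(gr)[is_exon])
  )
  ex_by_tx <- split(ex[c("start", "end")], ex$transcript_id)

  mrna$exons <- lapply(mrna$transcript_id, function(txid) {
    e <- ex_by_tx[[txid]]
    if (is.null(e)) stop("mRNA without exons: ", txid)
    as.data.frame(e[order(e$start), , drop = FALSE], row.names = NULL)
  })

  expr <- read_expression(expression)
  mrna <- left_join(mrna, expr, by = "transcript_id")
  if (anyNA(mrna$expression)) {
    missing <- mrna$transcript_id[is.na(mrna$expression)]
    if (!is.null(expression)) {
      warning("no expression value for ", length(missing),
              " transcript(s) (e.g. ", missing[1], "); using 0")
    }
    mrna$expression[is.na(mrna$expression)] <- 0
  }

  ann <- arrange(mrna, .data$chrom, .data$span_start, .data$gene_id,
                 .data$transcript_id)
  ann <- ann[c("gene_id", "transcript_id", "chrom", "strand",
               "span_start", "span_end", "expression", "exons")]
  validate_annotation(ann)
  ann
}

orphan_exon_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hit <- which(vapply(fields, function(f)
    length(f) >= 9 && f[3] == "exon" && !grepl("Parent=", f[9]), logical(1)))
  if (length(hit)) hit[1] else NA_integer_
}

read_expression <- function(expression) {
  if (is.null(expression)) {
    return(tibble(transcript_id = character(), expression = numeric()))
  }
  if (is.character(expression)) {
    expression <- utils::read.delim(expression, comment.char = "#",
                                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("transcript_id", "expression") %in% names(expression)))
  if (any(expression$expression < 0)) stop("expression values must be >= 0")
  as_tibble(expression[c("transcript_id", "expression")])
}

#' Validate the invariants of an annotation tibble
#'
#' Checks column presence, strand values, coordinate sanity, exon ordering,
#' containment and span agreement, and chrom/strand consistency within
#' genes. Called by every function that consumes annotations.
#'
#' @param ann An annotation tibble.
#' @return `ann`, invisibly; errors describe the first violation.
#' @export
validate_annotation <- function(ann) {
  stopifnot(is.data.frame(ann),
            all(c("gene_id", "transcript_id", "chrom", "strand",
                  "span_start", "span_end", "expression", "exons") %in% names(ann)))
  if (nrow(ann) == 0) return(invisible(ann))
  stopifnot(all(ann$strand %in% c("+", "-")),
            all(ann$span_start >= 0), all(ann$span_end > ann$span_start),
            all(ann$expression >= 0))
  if (anyDuplicated(ann$transcript_id)) stop("duplicate transcript_id")
  for (i in seq_len(nrow(ann))) {
    e <- ann$exons[[i]]
    if (nrow(e) == 0) stop("transcript without exons: ", ann$transcript_id[i])
    if (is.unsorted(e$start, strictly = TRUE) ||
        any(e$end[-nrow(e)] > e$start[-1])) {
      stop("exons must be sorted and non-overlapping: ", ann$transcript_id[i])
    }
    if (e$start[1] != ann$span_start[i] || e$end[nrow(e)] != ann$span_end[i]) {
      stop("first/last exon must coincide with transcript span: ",
           ann$transcript_id[i])
    }
    if (any(e$start < ann$span_start[i]) || any(e$end > ann$span_end[i])) {
      stop("exon outside mRNA span: ", ann$transcript_id[i])
    }
  }
  bad <- ann |> group_by(.data$gene_id) |>
    summarise(ok = dplyr::n_distinct(.data$chrom) == 1 &&
                dplyr::n_distinct(.data$strand) == 1, .groups = "drop")
  if (!all(bad$ok)) {
    stop("transcripts of gene ", bad$gene_id[!bad$ok][1],
         " disagree on chrom/strand")
  }
  invisible(ann)
}

#' Transcription start sites of an annotation
#'
#' @param ann An annotation tibble.
#' @return Numeric vector of TSS base coordinates (0-based), one per row:
#'   `span_start` for `+` transcripts, `span_end - 1` for `-` transcripts.
#' @export
tss <- function(ann) {
  ifelse(ann$strand == "+", ann$span_start, ann$span_end - 1)
}

#' Write an annotation as GFF3 (with optional expression table)
#'
#' Coordinates are converted back to GFF3's 1-based closed convention, so
#' [read_annotation()] of the result reproduces the input exactly.
#'
#' @param ann An annotation tibble.
#' @param path Output GFF3 path.
#' @param expression_path Optional path for the transcript expression TSV.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, expression_path = NULL) {
  validate_annotation(ann)
  ann <- arrange(ann, .data$chrom, .data$span_start, .data$gene_id,
                 .data$transcript_id)
  lines <- c("##gff-version 3", writer_comment("gff3"))
  genes <- ann |> group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              start = min(.data$span_start), end = max(.data$span_end),
              .groups = "drop") |>
    arrange(.data$chrom, .data$start, .data$gene_id)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, gff_line(g$chrom, "gene", g$start, g$end, g$strand,
                               paste0("ID=", g$gene_id)))
    txs <- ann[ann$gene_id == g$gene_id, ]
    for (j in seq_len(nrow(txs))) {
      t <- txs[j, ]
      lines <- c(lines, gff_line(t$chrom, "mRNA", t$span_start, t$span_end,
                                 t$strand, paste0("ID=", t$transcript_id,
                                                  ";Parent=", g$gene_id)))
      e <- t$exons[[1]]
      for (k in seq_len(nrow(e))) {
        lines <- c(lines, gff_line(t$chrom, "exon", e$start[k], e$end[k],
                                   t$strand, paste0("ID=", t$transcript_id,
                                                    ".e", k, ";Parent=",
                                                    t$transcript_id)))
      }
    }
  }
  writeLines(lines, path)
  if (!is.null(expression_path)) {
    write_result_tsv(ann[c("transcript_id", "expression")], expression_path,
                     params = "expression")
  }
  invisible(path)
}

gff_line <- function(chrom, type, start0, end0, strand, attrs) {
  paste(chrom, "metachip", type, format(start0 + 1, scientific = FALSE),
        format(end0, scientific = FALSE), ".", strand, ".", attrs,
        sep = "\t")
}

writer_comment <- function(...) {
  paste0("# metachip ", as.character(packageVersion("metachip")), " ",
         paste(..., collapse = " "))
}

# rtracklayer's parsers do not all tolerate '#' comment lines, which our
# writers emit; strip them into a temp file first.
strip_comments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#")
  tmp <- tempfile(fileext = paste0(".", sub(".*\\.", "", basename(path))))
  writeLines(lines[keep], tmp)
  list(path = tmp, lines = lines[keep])
}

#' Read a signal track (bedGraph or fixed-step WIG) as a probe track
#'
#' Each interval becomes one probe at its midpoint, `floor((start + end)/2)`
#' in 0-based coordinates, carrying the interval's value. Intervals must not
#' overlap within a chromosome. Comment (`#`) and `track` lines are skipped;
#' an empty file yields an empty track.
#'
#' @param path Path to a bedGraph or WIG file.
#' @param format `"auto"` (sniff fixedStep/variableStep headers),
#'   `"bedGraph"` or `"wig"`.
#' @return A probe track tibble (see [probe_track]).
#' @export
read_probe_track <- function(path, format = c("auto", "bedGraph", "wig")) {
  format <- match.arg(format)
  sc <- strip_comments(path)
  body <- sc$lines[!startsWith(trimws(sc$lines), "track") &
                     nzchar(trimws(sc$lines))]
  if (length(body) == 0) return(probe_track())
  if (format == "auto") {
    format <- if (grepl("^(fixedStep|variableStep)", body[1])) "wig" else "bedGraph"
  }
  gr <- tryCatch(rtracklayer::import(sc$path, format = format),
                 error = function(e) stop("failed to parse ", format, " '",
                                          path, "': ", conditionMessage(e)))
  iv <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1,
               end = as.numeric(GenomicRanges::end(gr)),
               value = as.numeric(gr$score))
  if (any(!is.finite(iv$value))) stop("non-numeric signal value in '", path, "'")
  iv <- arrange(iv, .data$chrom, .data$start)
  ovl <- iv |> group_by(.data$chrom) |>
    summarise(bad = any(.data$start[-1] < .data$end[-n()]), .groups = "drop")
  if (any(ovl$bad)) {
    stop("overlapping intervals on ", ovl$chrom[which(ovl$bad)[1]],
         " in '", path, "'")
  }
  probe_track(iv$chrom, floor((iv$start + iv$end) / 2), iv$value)
}

#' Write a probe track as bedGraph
#'
#' Each probe becomes an interval of width `span` whose midpoint is the probe
#' position, so reading the file back with [read_probe_track()] reproduces
#' the track (positions exactly, values to 6 decimals).
#'
#' @param track A probe track.
#' @param path Output path.
#' @param span Interval width in bp (default 1).
#' @return `path`, invisibly.
#' @export
write_probe_track <- function(track, path, span = 1) {
  validate_track(track)
  stopifnot(span >= 1)
  start <- track$pos - span %/% 2
  lines <- c(writer_comment("bedGraph", paste0("span=", span)),
             sprintf("%s\t%d\t%d\t%.6f", track$chrom, as.integer(start),
                     as.integer(start + span), track$value))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of named intervals
#'
#' BED's 0-based half-open coordinates are kept as-is. Lines starting with
#' `#`, `track` or `browser` are skipped; a missing name column yields `""`.
#'
#' @param path Path to a BED file (>= 3 columns).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
read_intervals <- function(path) {
  sc <- strip_comments(path)
  body <- sc$lines[!grepl("^(track|browser)", trimws(sc$lines)) &
                     nzchar(trimws(sc$lines))]
  if (length(body) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character()))
  }
  # BED permits ragged 3/4+ column files, which strict table parsers
  # reject; read the leading columns with fill and validate ourselves.
  raw <- tryCatch(
    utils::read.table(text = body, sep = "\t", fill = TRUE,
                      stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("failed to parse BED '", path, "': ",
                             conditionMessage(e)))
  if (ncol(raw) < 3) stop("BED file '", path, "' has fewer than 3 columns")
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric coordinate in BED '", path, "'")
  }
  out <- tibble(chrom = raw[[1]], start = start, end = end,
                name = if (ncol(raw) >= 4) raw[[4]] else "")
  out$name[is.na(out$name)] <- ""
  if (any(out$end <= out$start)) {
    bad <- which(out$end <= out$start)[1]
    stop("interval with end <= start in '", path, "': ", out$chrom[bad], ":",
         out$start[bad], "-", out$end[bad])
  }
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write intervals as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name` (plus `score`/`strand`, written as BED6 when present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  nm <- if ("name" %in% names(intervals)) intervals$name else NULL
  cols <- list(intervals$chrom, as.integer(intervals$start),
               as.integer(intervals$end))
  if (!is.null(nm)) {
    cols <- c(cols, list(nm))
    if (all(c("score", "strand") %in% names(intervals))) {
      cols <- c(cols, list(sprintf("%.6f", intervals$score), intervals$strand))
    }
  }
  lines <- c(writer_comment("bed"), do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file of chromosome sequences
#'
#' @param path Path to a FASTA file (alphabet `A`/`C`/`G`/`T`/`N`,
#'   case-insensitive; sequences are upper-cased).
#' @return A named character vector, one element per chromosome.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate FASTA header: ", nm[duplicated(nm)][1])
  freq <- Biostrings::alphabetFrequency(ss)
  extra <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(extra > 0)) {
    stop("sequence ", nm[extra > 0][1], " contains characters outside ACGTN")
  }
  setNames(toupper(as.character(ss)), nm)
}

#' Write chromosome sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  ss <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write a result table as TSV with a tool-version header comment
#'
#' @param df A data frame.
#' @param path Output path.
#' @param params Short character description of the parameters that produced
#'   the table (recorded in the header comment).
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, params = "") {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(writer_comment(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result TSV written by [write_result_tsv()]
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_result_tsv <- function(path) {
  as_tibble(utils::read.delim(path, comment.char = "#",
                              stringsAsFactors = FALSE))
}
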