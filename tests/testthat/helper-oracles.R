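# Independent oracles: deliberately naive per-base / enumeration
# implementations of the pipeline's operations, used to pin down the fast
# interval-arithmetic code paths.

# ---- toy genomes ----------------------------------------------------------

# A small random annotation with promoter-truncating gene spacings, mixed
# strands, multi-exon transcripts, expression ties and inactive genes.
make_toy_genome <- function(seed, n_genes = 8, max_exons = 5) {
  set.seed(seed)
  chroms <- c("chr4", "chr2L")
  rows <- list()
  for (ch in chroms) {
    pos <- 500
    n <- max(1, rpois(1, n_genes / 2))
    for (i in seq_len(n)) {
      gap <- sample(c(80, 200, 450, 700, 1500, 2500), 1)
      len <- sample(300:2000, 1)
      start <- pos + gap
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("%s_t%02d", ch, i)
      k <- sample(seq_len(max_exons), 1)
      exons <- random_exons(start, start + len, k)
      expr <- if (i == 1) 10 else sample(c(0, 0, 5, 5, 10, 20), 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = gid, transcript_id = paste0(gid, ".1"), chrom = ch,
        strand = strand, span_start = start, span_end = start + len,
        expression = expr, exons = list(exons))
      if (runif(1) < 0.3) {   # competing transcript, possibly tied
        e2 <- if (runif(1) < 0.5) expr else round(expr / 2, 1)
        s2 <- start + 100
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene_id = gid, transcript_id = paste0(gid, ".2"), chrom = ch,
          strand = strand, span_start = s2, span_end = start + len,
          expression = e2,
          exons = list(data.frame(start = s2, end = start + len)))
      }
      pos <- start + len
    }
  }
  ann <- dplyr::bind_rows(rows)
  ann <- dplyr::arrange(ann, chrom, span_start, gene_id, transcript_id)
  max2l <- max(ann$span_end[ann$chrom == "chr2L"], 1000) + 1000
  max4 <- max(ann$span_end[ann$chrom == "chr4"], 1000) + 1000
  regions <- tibble::tibble(
    chrom = c("chr4", "chr2L", "chr2L", "chr2L"),
    start = c(0, 0, floor(max2l / 3), floor(2 * max2l / 3)),
    end = c(max4, floor(max2l / 3), floor(2 * max2l / 3), max2l),
    region = c("chr4", "pericentromeric", "r2L31", "euchromatic"))
  track <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr4", pos = seq(25, max4, by = 50)),
    tibble::tibble(chrom = "chr2L", pos = seq(25, max2l, by = 50)))
  track$value <- rnorm(nrow(track))
  list(ann = ann, regions = regions, track = track)
}

random_exons <- function(start, end, k) {
  len <- end - start
  nseg <- 2 * k - 1
  if (nseg == 1 || len < 40 * nseg) {
    return(data.frame(start = start, end = end))
  }
  w <- rexp(nseg)
  seg <- floor((len - 20 * nseg) * w / sum(w)) + 20
  seg[nseg] <- len - sum(seg[-nseg])
  bounds <- start + cumsum(c(0, seg))
  idx <- seq(1, nseg, by = 2)
  data.frame(start = bounds[idx], end = bounds[idx + 1])
}

# ---- per-base metagene oracle ---------------------------------------------

# Assigns every base of every gene to one of the 8 features by explicit
# enumeration (sets of base coordinates, no interval arithmetic), then
# averages probes by set membership and genes within regions.
oracle_region_metagene <- function(track, ann, regions,
                                   expression_threshold = 0,
                                   promoter_width = 500) {
  sel <- oracle_select(ann)
  res <- list()
  for (i in seq_len(nrow(sel))) {
    g <- sel[i, ]
    feats <- oracle_feature_bases(g, sel, promoter_width)
    tpos <- track$pos[track$chrom == g$chrom]
    tval <- track$value[track$chrom == g$chrom]
    t <- if (g$strand == "+") g$span_start else g$span_end - 1
    reg <- "excluded"
    for (r in seq_len(nrow(regions))) {
      if (regions$chrom[r] == g$chrom && t >= regions$start[r] &&
          t < regions$end[r]) reg <- regions$region[r]
    }
    for (f in names(feats)) {
      hit <- tpos %in% feats[[f]]
      res[[length(res) + 1]] <- data.frame(
        gene_id = g$gene_id, region = reg, feature = f,
        mean = if (any(hit)) mean(tval[hit]) else NA_real_,
        active = g$expression > expression_threshold)
    }
  }
  df <- do.call(rbind, res)
  df <- df[df$active & !is.na(df$mean), ]
  agg <- aggregate(mean ~ region + feature, data = df, FUN = mean)
  n <- aggregate(gene_id ~ region + feature, data = df, FUN = length)
  names(n)[3] <- "n_genes"
  merge(agg, n)
}

oracle_select <- function(ann) {
  out <- list()
  for (gid in unique(ann$gene_id)) {
    sub <- ann[ann$gene_id == gid, ]
    sub$len <- sub$span_end - sub$span_start
    sub <- sub[order(-sub$expression, -sub$len, sub$transcript_id), ]
    out[[gid]] <- sub[1, ]
  }
  do.call(rbind, out)
}

# base-coordinate sets of the 8 features of one selected transcript
oracle_feature_bases <- function(g, sel, promoter_width = 500) {
  others <- sel[sel$gene_id != g$gene_id & sel$chrom == g$chrom, ]
  cuts <- sort(c(others$span_start, others$span_end))
  feats <- list()
  if (g$strand == "+") {
    t <- g$span_start
    b1 <- max(c(cuts[cuts <= t], 0))
    p_lo <- max(t - promoter_width, b1)
    if (p_lo < t) {
      feats$P <- p_lo:(t - 1)
      b2 <- cuts[cuts <= p_lo]
      if (length(b2) && max(b2) < p_lo) feats$IG <- max(b2):(p_lo - 1)
    }
  } else {
    t <- g$span_end
    up <- cuts[cuts >= t]
    p_hi <- min(t + promoter_width, if (length(up)) min(up) else Inf)
    if (p_hi > t) {
      feats$P <- t:(p_hi - 1)
      b2 <- cuts[cuts >= p_hi]
      if (length(b2) && min(b2) > p_hi) feats$IG <- p_hi:(min(b2) - 1)
    }
  }
  ex <- g$exons[[1]]
  tx_bases <- unlist(lapply(seq_len(nrow(ex)),
                            function(k) ex$start[k]:(ex$end[k] - 1)))
  if (g$strand == "-") tx_bases <- rev(tx_bases)
  L <- length(tx_bases)
  for (k in 1:5) {
    c_lo <- floor((k - 1) * L / 5); c_hi <- floor(k * L / 5)
    if (c_hi > c_lo) {
      feats[[paste0("E", k)]] <- tx_bases[(c_lo + 1):c_hi]
    }
  }
  all_span <- g$span_start:(g$span_end - 1)
  intr <- setdiff(all_span, sort(unlist(lapply(
    seq_len(nrow(ex)), function(k) ex$start[k]:(ex$end[k] - 1)))))
  if (length(intr)) feats$IN <- intr
  feats
}

# ---- other enumeration oracles --------------------------------------------

oracle_smooth <- function(track, bandwidth) {
  h <- bandwidth / 2
  out <- track
  for (i in seq_len(nrow(track))) {
    sel <- track$chrom == track$chrom[i] &
      abs(track$pos - track$pos[i]) <= h
    out$value[i] <- mean(track$value[sel])
  }
  out
}

oracle_density <- function(counts, window) {
  left <- window %/% 2
  right <- window - 1 - left
  out <- counts
  for (i in seq_len(nrow(counts))) {
    sel <- counts$chrom == counts$chrom[i] &
      counts$pos >= counts$pos[i] - left &
      counts$pos <= counts$pos[i] + right
    out$value[i] <- sum(counts$value[sel])
  }
  out
}

# Exhaustive window x strand PWM scan, character by character.
oracle_pwm_max <- function(seq, prob, bg) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(comp[strsplit(toupper(seq), "")[[1]]]), collapse = "")
  best <- -Inf
  for (s in c(toupper(seq), rc)) {
    L <- nrow(prob)
    for (w in seq_len(max(0, nchar(s) - L + 1))) {
      win <- substr(s, w, w + L - 1)
      if (grepl("N", win)) next
      sc <- 0
      for (j in seq_len(L)) {
        b <- substr(win, j, j)
        sc <- sc + log2(prob[j, b] / bg[[b]])
      }
      best <- max(best, sc)
    }
  }
  if (is.finite(best)) best else NA_real_
}

# Exact two-sided Mann-Whitney p by full enumeration of labelings.
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  u_obs <- sum(rank(vals)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  labelings <- utils::combn(n1 + n2, n1)
  us <- apply(labelings, 2, function(idx)
    sum(rank(vals)[idx]) - n1 * (n1 + 1) / 2)
  m <- n1 * n2 / 2
  p <- if (u_obs > m) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(1, p)
}
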