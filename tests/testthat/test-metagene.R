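# Transcript selection, promoter/intergenic definition, exon binning and
# the region-stratified average gene profile, pinned against per-base
# enumeration oracles.

one_tx <- function(gene_id, tx, chrom, strand, start, end, expr,
                   exons = NULL) {
  tibble::tibble(gene_id = gene_id, transcript_id = tx, chrom = chrom,
                 strand = strand, span_start = start, span_end = end,
                 expression = expr,
                 exons = list(exons %||% data.frame(start = start,
                                                    end = end)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("transcript selection takes max expression with documented tie-breaks", {
  ann <- dplyr::bind_rows(
    one_tx("g1", "g1.a", "chr4", "+", 1000, 1800, 5),
    one_tx("g1", "g1.b", "chr4", "+", 1000, 2000, 10),
    one_tx("g2", "g2.a", "chr4", "+", 5000, 5800, 10),
    one_tx("g2", "g2.b", "chr4", "+", 5000, 6200, 10),
    one_tx("g3", "g3.a", "chr4", "+", 9000, 9500, 0))
  sel <- select_transcripts(ann)
  expect_equal(sel$transcript_id[sel$gene_id == "g1"], "g1.b")  # expression
  expect_equal(sel$transcript_id[sel$gene_id == "g2"], "g2.b")  # longer span
  expect_equal(sel$transcript_id[sel$gene_id == "g3"], "g3.a")  # singleton
  # equal expression and span: lexicographically first id
  tie <- dplyr::bind_rows(one_tx("g4", "g4.b", "chr4", "+", 1, 100, 2),
                          one_tx("g4", "g4.a", "chr4", "+", 1, 100, 2))
  expect_equal(select_transcripts(tie)$transcript_id, "g4.a")
})

test_that("promoter and intergenic intervals follow the 500 bp / nearest-boundary rule", {
  # + strand, boundary 2000 bp upstream: full promoter, intergenic to boundary
  ann <- dplyr::bind_rows(
    one_tx("up", "up.1", "chr4", "+", 7000, 8000, 1),
    one_tx("g", "g.1", "chr4", "+", 10000, 11000, 1))
  sel <- define_promoters(select_transcripts(ann))
  g <- sel[sel$gene_id == "g", ]
  expect_equal(c(g$p_start, g$p_end), c(9500, 10000))
  expect_equal(c(g$ig_start, g$ig_end), c(8000, 9500))

  # + strand, neighbor stop only 300 bp upstream: truncated P, empty IG
  ann2 <- dplyr::bind_rows(
    one_tx("up", "up.1", "chr4", "+", 9000, 9700, 1),
    one_tx("g", "g.1", "chr4", "+", 10000, 11000, 1))
  g2 <- define_promoters(select_transcripts(ann2))
  g2 <- g2[g2$gene_id == "g", ]
  expect_equal(c(g2$p_start, g2$p_end), c(9700, 10000))
  expect_true(is.na(g2$ig_start))

  # - strand mirror: span [4000,5000), next boundary at 5800
  ann3 <- dplyr::bind_rows(
    one_tx("g", "g.1", "chr4", "-", 4000, 5000, 1),
    one_tx("dn", "dn.1", "chr4", "+", 5800, 6500, 1))
  g3 <- define_promoters(select_transcripts(ann3))
  g3 <- g3[g3$gene_id == "g", ]
  expect_equal(c(g3$p_start, g3$p_end), c(5000, 5500))
  expect_equal(c(g3$ig_start, g3$ig_end), c(5500, 5800))

  # TSS at the chromosome start: empty promoter
  ann4 <- one_tx("g0", "g0.1", "chr4", "+", 0, 900, 1)
  g4 <- define_promoters(select_transcripts(ann4))
  expect_true(is.na(g4$p_start))
})

test_that("exon bins partition the concatenated exons by the floor formula", {
  # single 1000 bp exon: five 200 bp genomic bins, no introns
  sel <- define_promoters(one_tx("g", "g.1", "chr4", "+", 1000, 2000, 1))
  fm <- build_feature_map(sel)
  e <- fm[grepl("^E", fm$feature), ]
  expect_equal(e$start, seq(1000, 1800, 200))
  expect_equal(e$end, seq(1200, 2000, 200))
  expect_false("IN" %in% fm$feature)

  # exons 250+250 (L=500): 100 bp concatenated bins; the junction at
  # concatenated position 250 falls inside E3, which maps to two genomic
  # pieces
  ex <- data.frame(start = c(1000, 1500), end = c(1250, 1750))
  sel2 <- define_promoters(one_tx("g", "g.1", "chr4", "+", 1000, 1750, 1,
                                  exons = ex))
  fm2 <- build_feature_map(sel2)
  e3 <- fm2[fm2$feature == "E3", ]
  expect_equal(e3$start, c(1200, 1500))
  expect_equal(e3$end, c(1250, 1550))
  expect_equal(fm2[fm2$feature == "IN", ]$start, 1250)
  expect_equal(fm2[fm2$feature == "IN", ]$end, 1500)

  # L=7: concatenated boundaries 0,1,2,4,5,7 -> bin sizes 1,1,2,1,2
  sel3 <- define_promoters(one_tx("g", "g.1", "chr4", "+", 100, 107, 1))
  fm3 <- build_feature_map(sel3)
  sizes <- fm3 |>
    dplyr::filter(grepl("^E", feature)) |>
    dplyr::group_by(feature) |>
    dplyr::summarise(size = sum(end - start))
  expect_equal(sizes$size, c(1, 1, 2, 1, 2))
})

test_that("bin partition property: bins are disjoint and sum to L", {
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(1:5, 1)
    len <- sample(40:2000, 1)
    strand <- sample(c("+", "-"), 1)
    ex <- random_exons(1000, 1000 + len, k)
    sel <- define_promoters(one_tx("g", "g.1", "chr4", strand, 1000,
                                   1000 + len, 1, exons = ex))
    fm <- build_feature_map(sel)
    bins <- fm[grepl("^E", fm$feature), ]
    L <- sum(ex$end - ex$start)
    expect_equal(sum(bins$end - bins$start), L)
    bases <- unlist(lapply(seq_len(nrow(bins)),
                           function(i) bins$start[i]:(bins$end[i] - 1)))
    expect_false(any(duplicated(bases)))   # disjoint
    exon_bases <- unlist(lapply(seq_len(nrow(ex)),
                                function(i) ex$start[i]:(ex$end[i] - 1)))
    expect_setequal(bases, exon_bases)     # full cover of exons
  }
})

test_that("gene_profile matches feature membership and flags missing features", {
  ex <- data.frame(start = c(1000, 1600), end = c(1400, 2000))
  sel <- define_promoters(one_tx("g", "g.1", "chr4", "+", 1000, 2000, 1,
                                 exons = ex))
  fm <- build_feature_map(sel)
  const <- probe_track("chr4", seq(25, 2975, 50), rep(1, 60))
  gp <- gene_profile(const, fm)
  expect_true(all(gp$mean == 1))
  # no probes inside the intron -> IN missing
  sparse <- probe_track("chr4", c(1100, 1700), c(2, 4))
  gp2 <- gene_profile(sparse, fm)
  expect_true(is.na(gp2$mean[gp2$feature == "IN"]))
})

test_that("region metagene equals the per-base oracle on random toy genomes", {
  for (seed in 1:6) {
    toy <- make_toy_genome(seed)
    got <- region_metagene(toy$track, toy$ann, toy$regions)
    exp <- oracle_region_metagene(toy$track, toy$ann, toy$regions)
    merged <- merge(as.data.frame(got), exp,
                    by = c("region", "feature"), suffixes = c("_got", "_exp"))
    expect_gt(nrow(merged), 0)
    expect_lt(max(abs(merged$mean_got - merged$mean_exp)), 1e-9)
    expect_equal(merged$n_genes_got, merged$n_genes_exp)
    # features the oracle found empty must be NA in the fast path
    empty <- dplyr::anti_join(as.data.frame(got), exp,
                              by = c("region", "feature"))
    expect_true(all(is.na(empty$mean)))
  }
})

test_that("region averaging is gene-weighted, not probe-weighted", {
  ann <- dplyr::bind_rows(
    one_tx("a", "a.1", "chr4", "+", 2000, 3000, 5),
    one_tx("b", "b.1", "chr4", "+", 8000, 9000, 5))
  regions <- tibble::tibble(chrom = "chr4", start = 0, end = 20000,
                            region = "chr4")
  # gene a sampled at 4x the probe density of gene b
  trk <- probe_track("chr4", c(seq(2025, 2975, 25), seq(8050, 8950, 100)),
                     c(rep(1, 39), rep(3, 10)))
  mg <- region_metagene(trk, ann, regions)
  body <- mg$mean[mg$feature %in% paste0("E", 1:5)]
  expect_equal(body, rep(2, 5))   # (1 + 3) / 2 regardless of density
})

test_that("adding a constant inside one feature moves only that feature", {
  toy <- make_toy_genome(4)
  base <- region_metagene(toy$track, toy$ann, toy$regions)
  sel <- define_promoters(select_transcripts(toy$ann))
  fm <- build_feature_map(sel)
  p_iv <- fm[fm$feature == "P", ]
  trk <- toy$track
  in_p <- rep(FALSE, nrow(trk))
  for (i in seq_len(nrow(p_iv))) {
    in_p <- in_p | (trk$chrom == p_iv$chrom[i] & trk$pos >= p_iv$start[i] &
                      trk$pos < p_iv$end[i])
  }
  trk$value[in_p] <- trk$value[in_p] + 2
  shifted <- region_metagene(trk, toy$ann, toy$regions)
  # P shifts by exactly +2 wherever promoters share no probes with other
  # features of the same genes; all-feature invariance is not expected
  # because bidirectional promoters may overlap neighbors' IG.
  p0 <- base$mean[base$feature == "P"]
  p1 <- shifted$mean[shifted$feature == "P"]
  expect_equal(p1[!is.na(p1)], p0[!is.na(p0)] + 2)
})
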