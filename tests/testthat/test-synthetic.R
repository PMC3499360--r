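# Determinism, layout contracts, and generative fidelity of the
# synthetic-genome generator.

small_cfg <- function(seed = 11, ...) {
  synthetic_config(seed = seed,
                   n_genes = c(chr4 = 20, r2L31 = 8, pericentromeric = 8,
                               euchromatic = 16), ...)
}

test_that("config validation catches impossible layouts and bad values", {
  expect_error(synthetic_config(gene_slot = 1000), "gene_slot too small")
  expect_error(synthetic_config(region_size = c(chr4 = 1000, r2L31 = 1e6,
                                                pericentromeric = 1e6,
                                                euchromatic = 1e6)),
               "too small.*suggested minimum")
  expect_error(synthetic_config(sigma = -1))
  expect_error(synthetic_config(inactive_fraction = 2))
})

test_that("the generator honors gene counts and region placement", {
  g <- generate_genome(small_cfg())
  sel <- assign_regions(define_promoters(select_transcripts(g$annotation)),
                        g$regions)
  expect_equal(sum(sel$region == "chr4"), 20)
  expect_equal(sum(sel$region == "r2L31"), 8)
  expect_equal(sum(sel$region == "pericentromeric"), 8)
  expect_equal(sum(sel$region == "euchromatic"), 16)
  expect_false(any(sel$region == "excluded"))
  # genes do not overlap within a chromosome
  by_chrom <- split(sel, sel$chrom)
  for (s in by_chrom) {
    s <- s[order(s$span_start), ]
    expect_true(all(s$span_start[-1] >= s$span_end[-nrow(s)]))
  }
})

test_that("identical seeds give byte-identical serialized outputs", {
  write_all <- function(dir) {
    g <- generate_genome(small_cfg())
    dir.create(dir)
    write_fasta(g$sequences, file.path(dir, "genome.fa"))
    write_annotation(g$annotation, file.path(dir, "ann.gff3"),
                     file.path(dir, "expr.tsv"))
    write_intervals(dplyr::rename(g$regions, name = "region"),
                    file.path(dir, "regions.bed"))
    trk <- generate_chip_track(g, "wildtype", "HP1a")
    write_probe_track(trk, file.path(dir, "track.bedGraph"))
    dir
  }
  d1 <- write_all(tempfile()); d2 <- write_all(tempfile())
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # different seed changes the output
  g2 <- generate_genome(small_cfg(seed = 12))
  g1 <- generate_genome(small_cfg(seed = 11))
  expect_false(identical(g1$sequences, g2$sequences))
})

test_that("promoter A/T composition matches the configured fraction", {
  cfg <- synthetic_config(seed = 5, n_genes = c(chr4 = 90, r2L31 = 0,
                                                pericentromeric = 0,
                                                euchromatic = 20))
  g <- generate_genome(cfg)
  prom <- g$promoters[grepl("^chr4", g$promoters$gene_id), ]
  seqs <- substring(g$sequences[prom$chrom], prom$p_start + 1, prom$p_end)
  expect_gte(length(seqs), 80)
  expect_lt(abs(mean(at_content(seqs)) - 0.65), 0.03)
})

test_that("track means recover the configured effect heights", {
  cfg <- small_cfg(seed = 3, inactive_fraction = 0,
                   n_silent_hp1a_targets = 0)
  g <- generate_genome(cfg)
  sel <- assign_regions(define_promoters(select_transcripts(g$annotation)),
                        g$regions)
  fm <- build_feature_map(sel)
  chr4_active <- sel$gene_id[sel$region == "chr4"]

  wt <- generate_chip_track(g, "wildtype", "HP1a")
  gp <- gene_profile(wt, fm[fm$gene_id %in% chr4_active, ])
  pm <- mean(gp$mean[gp$feature == "P"], na.rm = TRUE)
  n_p <- sum(gp$n_probes[gp$feature == "P"])
  expect_lt(abs(pm - cfg$h_p), 3 * cfg$sigma / sqrt(n_p) + 0.02)
  body <- gp[gp$feature %in% paste0("E", 1:5) & !is.na(gp$mean), ]
  bm <- sum(body$mean * body$n_probes) / sum(body$n_probes)
  expect_lt(abs(bm - cfg$h_b), 3 * cfg$sigma / sqrt(sum(body$n_probes)) + 0.02)

  # Setdb1: chr4 bodies drop to baseline, promoter peaks persist
  mut <- generate_chip_track(g, "Setdb1", "HP1a")
  gpm <- gene_profile(mut, fm[fm$gene_id %in% chr4_active, ])
  bodym <- gpm[gpm$feature %in% paste0("E", 1:5) & !is.na(gpm$mean), ]
  bmm <- sum(bodym$mean * bodym$n_probes) / sum(bodym$n_probes)
  expect_lt(abs(bmm), 3 * cfg$sigma / sqrt(sum(bodym$n_probes)) + 0.02)
  pmm <- mean(gpm$mean[gpm$feature == "P"], na.rm = TRUE)
  expect_lt(abs(pmm - cfg$h_p), 3 * cfg$sigma / sqrt(n_p) + 0.02)
})

test_that("the noiseless limit is the exact deterministic bump profile", {
  cfg <- small_cfg(seed = 9, sigma = 0, inactive_fraction = 0,
                   n_silent_hp1a_targets = 0)
  g <- generate_genome(cfg)
  trk <- generate_chip_track(g, "wildtype", "HP1a")
  expect_true(all(trk$value %in% c(0, cfg$h_b, cfg$h_p, cfg$h_p + cfg$h_b)))
  sel <- assign_regions(define_promoters(select_transcripts(g$annotation)),
                        g$regions)
  fm <- build_feature_map(sel)
  het <- sel$gene_id[sel$region != "euchromatic"]
  gp <- gene_profile(trk, fm[fm$gene_id %in% het, ])
  expect_true(all(gp$mean[gp$feature == "P"] == cfg$h_p))
  expect_true(all(gp$mean[grepl("^E", gp$feature)] == cfg$h_b, na.rm = TRUE))
})

test_that("no leakage: H3K9me never gets promoter peaks, euchromatin stays flat", {
  cfg <- small_cfg(seed = 13, sigma = 0, inactive_fraction = 0,
                   n_silent_hp1a_targets = 0)
  g <- generate_genome(cfg)
  sel <- assign_regions(define_promoters(select_transcripts(g$annotation)),
                        g$regions)
  fm <- build_feature_map(sel)
  for (gt in c("wildtype", "Setdb1", "Su(var)3-9", "G9a", "Pof")) {
    hp1a <- generate_chip_track(g, gt, "HP1a")
    euch <- sel$gene_id[sel$region == "euchromatic"]
    gp <- gene_profile(hp1a, fm[fm$gene_id %in% euch, ])
    expect_true(all(gp$mean[!is.na(gp$mean)] == 0),
                label = paste("euchromatin flat in", gt))
  }
  me <- generate_chip_track(g, "wildtype", "H3K9me3")
  gp <- gene_profile(me, fm)
  expect_true(all(gp$mean[gp$feature == "P"] == 0))  # no promoter signal
})

test_that("genotype map encodes the region-specific methyltransferase division", {
  gm <- default_genotype_map()
  pick <- function(gt, ab, rg, what) {
    gm[[what]][gm$genotype == gt & gm$antibody == ab & gm$region == rg]
  }
  # Setdb1 mutants lose chr4 and 2L:31 bodies, keep pericentromeric
  expect_false(pick("Setdb1", "HP1a", "chr4", "body_retained"))
  expect_false(pick("Setdb1", "HP1a", "r2L31", "body_retained"))
  expect_true(pick("Setdb1", "HP1a", "pericentromeric", "body_retained"))
  # Su(var)3-9 mutants: the mirror image
  expect_true(pick("Su(var)3-9", "HP1a", "chr4", "body_retained"))
  expect_false(pick("Su(var)3-9", "HP1a", "pericentromeric",
                    "body_retained"))
  # Pof loss removes chr4 bodies only; G9a changes nothing
  expect_false(pick("Pof", "HP1a", "chr4", "body_retained"))
  expect_true(pick("Pof", "HP1a", "r2L31", "body_retained"))
  expect_true(all(gm$body_retained[gm$genotype == "G9a" &
                                     gm$region != "euchromatic"]))
  # promoter peaks persist in every genotype, HP1a only
  expect_true(all(gm$promoter_retained[gm$antibody == "HP1a" &
                                         gm$region != "euchromatic"]))
  expect_false(any(gm$promoter_retained[gm$antibody != "HP1a"]))
})

test_that("silenced HP1a-target genes keep HP1a in all genotypes", {
  cfg <- small_cfg(seed = 21, sigma = 0)
  g <- generate_genome(cfg)
  expect_length(g$silent_targets, 2)
  sel <- select_transcripts(g$annotation)
  expect_true(all(sel$expression[sel$gene_id %in% g$silent_targets] == 0))
  fm <- build_feature_map(define_promoters(sel))
  for (gt in c("Setdb1", "Pof")) {
    trk <- generate_chip_track(g, gt, "HP1a")
    gp <- gene_profile(trk, fm[fm$gene_id %in% g$silent_targets, ])
    expect_true(all(gp$mean[gp$feature == "P"] == cfg$h_p))
    expect_true(all(gp$mean[grepl("^E", gp$feature)] == cfg$h_b,
                    na.rm = TRUE))
  }
})

test_that("auxiliary tracks have the documented structure", {
  cfg <- small_cfg(seed = 31, sigma = 0, inactive_fraction = 0,
                   n_silent_hp1a_targets = 0,
                   factors = tibble::tibble(name = c("all", "none"),
                                            chr4 = c(1, 0), r2L31 = c(1, 0),
                                            pericentromeric = c(1, 0),
                                            euchromatic = c(1, 0)))
  g <- generate_genome(cfg)
  aux <- generate_aux_tracks(g)
  # degenerate probabilities: one interval per promoter vs none
  expect_equal(nrow(aux$factors$all), nrow(g$promoters))
  expect_equal(nrow(aux$factors$none), 0)
  # noiseless HP2 restricted to +-500 bp of a peak center is maximal at 0
  prom <- g$promoters[1, ]
  ctr <- floor((prom$p_start + prom$p_end) / 2)
  win <- aux$hp2[aux$hp2$chrom == prom$chrom &
                   abs(aux$hp2$pos - ctr) <= 500, ]
  expect_equal(win$pos[which.max(win$value)], win$pos[which.min(abs(win$pos - ctr))])
  # DNase counts are defined, non-negative integers over gene territories
  expect_true(all(aux$dnase$value >= 0))
  expect_true(all(aux$dnase$value == floor(aux$dnase$value)))
})

test_that("factor binding frequencies follow their Bernoulli probabilities", {
  cfg <- synthetic_config(
    seed = 2, n_genes = c(chr4 = 100, r2L31 = 0, pericentromeric = 0,
                          euchromatic = 10),
    factors = tibble::tibble(name = "f", chr4 = 0.8, r2L31 = 0.8,
                             pericentromeric = 0.8, euchromatic = 0.8))
  g <- generate_genome(cfg)
  aux <- generate_aux_tracks(g, which = "factors")
  prom <- g$promoters[grepl("chr4", g$promoters$gene_id), ]
  centers <- floor((prom$p_start + prom$p_end) / 2)
  bound <- vapply(seq_len(nrow(prom)), function(i)
    any(aux$factors$f$chrom == prom$chrom[i] &
          aux$factors$f$start <= centers[i] &
          aux$factors$f$end > centers[i]), logical(1))
  frac <- mean(bound)
  expect_gte(frac, 0.66)   # central 99% binomial interval at p = 0.8, n = 100
  expect_lte(frac, 0.91)
})
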