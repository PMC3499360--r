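# Promoter peak detection, persistence classification, peak-centered
# profiles.

peak_fixture <- function(values, p_start = 1000, p_end = 1500,
                         spacing = 100) {
  pos <- seq(p_start - 200 + spacing / 2, by = spacing,
             length.out = length(values))
  track <- probe_track("chr4", pos, values)
  fm <- tibble::tibble(gene_id = "g", chrom = "chr4", strand = "+",
                       feature = "P", start = p_start, end = p_end)
  list(track = track, fm = fm)
}

test_that("detection reports the maximal promoter probe above threshold", {
  fx <- peak_fixture(c(0, 0.2, 0.9, 2.0, 1.2, 0.8, 0.1, 0, 0))
  pk <- detect_promoter_peaks(fx$track, fx$fm, min_height = 1.0)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$height, 2.0)
  expect_equal(pk$center, fx$track$pos[4])
  # flat zero promoter: nothing
  flat <- peak_fixture(rep(0, 9))
  expect_equal(nrow(detect_promoter_peaks(flat$track, flat$fm, 1.0)), 0)
  # below threshold: nothing
  low <- peak_fixture(c(0, 0.2, 0.5, 0.9, 0.5, 0.2, 0, 0, 0))
  expect_equal(nrow(detect_promoter_peaks(low$track, low$fm, 1.0)), 0)
})

test_that("equal maxima resolve to the leftmost probe", {
  fx <- peak_fixture(c(0, 0.5, 2.0, 1.5, 2.0, 0.5, 0, 0, 0))
  pk <- detect_promoter_peaks(fx$track, fx$fm, 1.0)
  expect_equal(pk$center, fx$track$pos[3])
})

test_that("detection is translation equivariant", {
  fx <- peak_fixture(c(0, 0.2, 0.9, 2.0, 1.2, 0.8, 0.1, 0, 0))
  pk <- detect_promoter_peaks(fx$track, fx$fm, 1.0)
  delta <- 12345
  trk2 <- dplyr::mutate(fx$track, pos = pos + delta)
  fm2 <- dplyr::mutate(fx$fm, start = start + delta, end = end + delta)
  pk2 <- detect_promoter_peaks(trk2, fm2, 1.0)
  expect_equal(pk2$center, pk$center + delta)
  expect_equal(pk2$height, pk$height)
})

test_that("persistence classification applies the retention and body rules", {
  toy_class <- function(mut_height, mut_body, wt_height = 2, wt_body = 1) {
    peaks <- tibble::tibble(gene_id = "g", chrom = "chr4", center = 1250,
                            height = wt_height)
    fm <- tibble::tibble(gene_id = "g", chrom = "chr4", strand = "+",
                         feature = "E1", start = 1500, end = 2000)
    pos <- seq(1050, 1950, 100)
    wt <- probe_track("chr4", pos,
                      ifelse(pos < 1500, wt_height, wt_body))
    mut <- probe_track("chr4", pos,
                       ifelse(pos < 1500, mut_height, mut_body))
    regions <- tibble::tibble(gene_id = "g", region = "chr4")
    classify_peak_persistence(peaks, wt, list(Setdb1 = mut), fm,
                              regions)$classification
  }
  expect_equal(toy_class(1.6, 0.1), "methylation_independent")
  expect_equal(toy_class(0.2, 0.1), "methylation_dependent")
  expect_equal(toy_class(1.6, 0.9), "ambiguous")   # peak kept, body kept
})

test_that("peaks in regions without a mutant track become ambiguous with a warning", {
  peaks <- tibble::tibble(gene_id = "g", chrom = "chr2L", center = 1250,
                          height = 2)
  fm <- tibble::tibble(gene_id = "g", chrom = "chr2L", strand = "+",
                       feature = "E1", start = 1500, end = 2000)
  trk <- probe_track("chr2L", seq(1050, 1950, 100), rep(1, 10))
  regions <- tibble::tibble(gene_id = "g", region = "pericentromeric")
  expect_warning(
    cls <- classify_peak_persistence(peaks, trk, list(Setdb1 = trk), fm,
                                     regions),
    "no mutant track")
  expect_equal(cls$classification, "ambiguous")
})

test_that("noiseless synthetic classification is perfect for any retention ratio", {
  cfg <- synthetic_config(seed = 17, sigma = 0,
                          n_genes = c(chr4 = 15, r2L31 = 6,
                                      pericentromeric = 6, euchromatic = 10),
                          inactive_fraction = 0, n_silent_hp1a_targets = 0)
  g <- generate_genome(cfg)
  sel <- assign_regions(define_promoters(select_transcripts(g$annotation)),
                        g$regions)
  fm <- build_feature_map(sel)
  wt <- smooth_track(generate_chip_track(g, "wildtype", "HP1a"), 200)
  muts <- list(`Setdb1` = smooth_track(generate_chip_track(g, "Setdb1",
                                                           "HP1a"), 200),
               `Su(var)3-9` = smooth_track(
                 generate_chip_track(g, "Su(var)3-9", "HP1a"), 200))
  for (r in c(0.2, 0.5, 0.8)) {
    pk <- detect_promoter_peaks(wt, fm, min_height = 0.5)
    cls <- classify_peak_persistence(pk, wt, muts, fm, sel,
                                     retention_ratio = r)
    het <- cls[cls$region %in% c("chr4", "r2L31", "pericentromeric"), ]
    expect_true(all(het$classification == "methylation_independent"),
                label = paste("r =", r))
    expect_equal(nrow(cls[cls$region == "euchromatic", ]), 0)
  }
})

test_that("peak-centered profiles match brute-force pooled means", {
  set.seed(42)
  trk <- probe_track("chr4", seq(25, 9975, 50), rnorm(200))
  centers <- c(2500, 7100)
  prof <- peak_centered_profile(trk, centers, halfwidth = 600, binsize = 100)
  for (i in seq_len(nrow(prof))) {
    vals <- c()
    for (ctr in centers) {
      off <- trk$pos - ctr
      vals <- c(vals, trk$value[off >= prof$offset[i] &
                                  off < prof$offset[i] + 100])
    }
    if (length(vals)) expect_equal(prof$mean[i], mean(vals))
    else expect_true(is.na(prof$mean[i]))
    expect_equal(prof$n[i], length(vals))
  }
})

test_that("single-center profile at probe spacing reproduces the raw window", {
  trk <- probe_track("chr4", seq(50, 1950, 100), rnorm(20))
  prof <- peak_centered_profile(trk, 1050, halfwidth = 300, binsize = 100)
  win <- trk$value[trk$pos >= 750 & trk$pos < 1350]
  expect_equal(prof$mean, win)
  # constant track gives a flat profile at that constant
  const <- probe_track("chr4", seq(50, 1950, 100), rep(1.5, 20))
  expect_true(all(peak_centered_profile(const, 1050, 300, 100)$mean == 1.5))
  # symmetric bump: maximum in the bin containing offset zero
  bump <- probe_track("chr4", seq(50, 1950, 100),
                      exp(-(seq(50, 1950, 100) - 1050)^2 / (2 * 150^2)))
  bp <- peak_centered_profile(bump, 1050, 500, 100)
  expect_equal(bp$offset[which.max(bp$mean)], 0)
})
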