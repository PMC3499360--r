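#' Pipeline configuration
#'
#' A run is driven either by a synthetic-genome block (a
#' [synthetic_config()]) or by paths to real input files, never both, plus
#' the analysis parameters. All randomness flows from the synthetic
#' config's seed.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when `paths` is
#'   given.
#' @param paths Named list of input paths (`annotation`, `expression`,
#'   `regions`, `fasta`, `tracks` - a named list
#'   `"<genotype>:<antibody>" = path` -, `factors` - named list of BED
#'   paths -, `dnase`), or `NULL`.
#' @param bandwidth Smoothing bandwidth in bp (default 200).
#' @param pseudocount Pseudocount for [log2_ratio()] when raw intensity
#'   pairs are supplied (unused for pre-computed ratio tracks).
#' @param min_height Peak detection threshold, log2 units (default 0.75).
#' @param retention_ratio,body_loss Persistence-classification parameters
#'   (defaults 0.5, 0.5).
#' @param peak_flank Promoter scan / mutant-height search halfwidth in bp
#'   (default 100).
#' @param seq_flank Peak-flank extraction halfwidth in bp (default 50).
#' @param dnase_window DNase density window in bp (default 150).
#' @param alpha Significance level of the group comparisons (default 0.01).
#' @param expression_threshold Activity cutoff (default 0).
#' @param occupancy_threshold Strict prevalence cutoff (default 0.5).
#' @param promoter_width Promoter length in bp (default 500).
#' @param profile_halfwidth,profile_binsize Peak-centered profile window
#'   (defaults 1000, 100).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), paths = NULL,
                            bandwidth = 200, pseudocount = 1,
                            min_height = 0.75, retention_ratio = 0.5,
                            body_loss = 0.5, peak_flank = 100,
                            seq_flank = 50, dnase_window = 150,
                            alpha = 0.01, expression_threshold = 0,
                            occupancy_threshold = 0.5, promoter_width = 500,
                            profile_halfwidth = 1000, profile_binsize = 100) {
  if (is.null(synthetic) == is.null(paths)) {
    stop("exactly one of 'synthetic' and 'paths' must be given")
  }
  stopifnot(bandwidth > 0, min_height > 0, retention_ratio > 0,
            retention_ratio < 1, body_loss > 0, peak_flank >= 0,
            seq_flank >= 0, dnase_window >= 1, alpha > 0, alpha < 1,
            expression_threshold >= 0, occupancy_threshold >= 0,
            occupancy_threshold < 1)
  structure(list(synthetic = synthetic, paths = paths, bandwidth = bandwidth,
                 pseudocount = pseudocount, min_height = min_height,
                 retention_ratio = retention_ratio, body_loss = body_loss,
                 peak_flank = peak_flank, seq_flank = seq_flank,
                 dnase_window = dnase_window, alpha = alpha,
                 expression_threshold = expression_threshold,
                 occupancy_threshold = occupancy_threshold,
                 promoter_width = promoter_width,
                 profile_halfwidth = profile_halfwidth,
                 profile_binsize = profile_binsize),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `synthetic` block mirrors [synthetic_config()] (scalar fields and named
#' maps only; the motif and genotype map use package defaults unless a
#' `motif_pwm` path is given).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    for (nm in c("n_genes", "promoter_at", "motif_insert_prob",
                 "dnase_promoter_mult", "dnase_body_mult", "region_size")) {
      if (!is.null(s[[nm]])) s[[nm]] <- unlist(s[[nm]])
    }
    if (!is.null(s$motif_pwm)) s$motif_pwm <- read_pwm(s$motif_pwm)
    if (!is.null(s$factors)) s$factors <- as_tibble(as.data.frame(s$factors))
    syn <- do.call(synthetic_config, s)
  }
  args <- y[setdiff(names(y), c("synthetic", "paths"))]
  do.call(pipeline_config, c(list(synthetic = syn, paths = y$paths), args))
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: simulate (or load) genome and tracks, smooth,
#' region metagenes per genotype and antibody, promoter peak detection and
#' persistence classification, peak-flank sequence statistics and group
#' comparisons, factor co-occupancy with the prevalence filter, HP2
#' peak-centered profile, and the DNase density metagene. Every output
#' lands in `outdir`; `manifest.tsv` lists each file with its MD5 content
#' hash, so two runs with an identical config produce byte-identical
#' manifests.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a `metachip_run` list with the in-memory results and
#'   the manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "tracks"), showWarnings = FALSE)
  dir.create(file.path(outdir, "factors"), showWarnings = FALSE)
  out <- function(...) file.path(outdir, ...)

  if (!is.null(config$synthetic)) {
    message("[simulate] generating synthetic genome (seed ",
            config$synthetic$seed, ")")
    genome <- generate_genome(config$synthetic)
    write_fasta(genome$sequences, out("genome.fa"))
    write_annotation(genome$annotation, out("annotation.gff3"),
                     out("expression.tsv"))
    write_intervals(dplyr::rename(genome$regions, name = "region"),
                    out("regions.bed"))
    ann <- genome$annotation
    regions <- genome$regions
    sequences <- genome$sequences
    track_pairs <- c(lapply(GENOTYPES, function(g) c(g, "HP1a")),
                     lapply(setdiff(GENOTYPES, "Pof"),
                            function(g) c(g, "H3K9me2")),
                     lapply(setdiff(GENOTYPES, "Pof"),
                            function(g) c(g, "H3K9me3")))
    tracks <- list()
    for (tp in track_pairs) {
      key <- paste(tp[1], tp[2], sep = ":")
      tracks[[key]] <- generate_chip_track(genome, tp[1], tp[2])
      write_probe_track(tracks[[key]], out("tracks", track_filename(key)),
                        span = config$synthetic$probe_spacing)
    }
    aux <- generate_aux_tracks(genome)
    for (nm in names(aux$factors)) {
      write_intervals(aux$factors[[nm]],
                      out("factors", paste0(safe_name(nm), ".bed")))
    }
    write_probe_track(aux$dnase, out("dnase_counts.bedGraph"))
    hp2 <- aux$hp2
    factors <- aux$factors
    dnase_counts <- aux$dnase
    motif <- config$synthetic$motif_pwm
  } else {
    message("[load] reading input files")
    p <- config$paths
    ann <- read_annotation(p$annotation, p$expression)
    regions <- dplyr::rename(read_intervals(p$regions), region = "name")
    sequences <- read_fasta(p$fasta)
    tracks <- lapply(p$tracks, read_probe_track)
    factors <- lapply(p$factors, read_intervals)
    dnase_counts <- if (!is.null(p$dnase)) read_probe_track(p$dnase)
    hp2 <- if (!is.null(p$hp2)) read_probe_track(p$hp2)
    motif <- if (!is.null(p$motif_pwm)) read_pwm(p$motif_pwm)
    else default_motif_pwm()
  }
  n_genes <- length(unique(ann$gene_id))
  message("[annotation] ", n_genes, " genes / ", nrow(ann), " transcripts")

  message("[signal] smoothing ", length(tracks), " tracks (bandwidth ",
          config$bandwidth, " bp)")
  smoothed <- lapply(tracks, smooth_track, bandwidth = config$bandwidth)

  sel <- define_promoters(select_transcripts(ann), config$promoter_width)
  sel <- assign_regions(sel, regions)
  fm <- build_feature_map(sel, config$promoter_width)

  message("[metagene] region profiles")
  mg <- bind_rows(lapply(names(tracks), function(key) {
    gt <- strsplit(key, ":", fixed = TRUE)[[1]]
    prof <- region_metagene(tracks[[key]], ann, regions,
                            config$expression_threshold,
                            config$promoter_width)
    mutate(prof, genotype = gt[1], antibody = gt[2])
  }))
  write_result_tsv(mg, out("metagene.tsv"),
                   paste0("region metagene; expression_threshold=",
                          config$expression_threshold))

  wt_key <- grep("^wildtype:HP1a$", names(tracks), value = TRUE)
  peaks_cls <- NULL
  if (length(wt_key)) {
    message("[peaks] detecting promoter peaks (min_height ",
            config$min_height, ")")
    peaks <- detect_promoter_peaks(smoothed[[wt_key]], fm,
                                   config$min_height, config$peak_flank)
    mut <- list()
    for (g in c("Setdb1", "Su(var)3-9")) {
      k <- paste0(g, ":HP1a")
      if (k %in% names(smoothed)) mut[[g]] <- smoothed[[k]]
    }
    peaks_cls <- classify_peak_persistence(
      peaks, smoothed[[wt_key]], mut, fm, sel,
      retention_ratio = config$retention_ratio,
      body_loss = config$body_loss, flank = config$peak_flank)
    message("[peaks] ", nrow(peaks_cls), " peaks; ",
            sum(peaks_cls$classification == "methylation_independent"),
            " methylation independent")
    write_result_tsv(peaks_cls, out("peaks.tsv"),
                     paste0("min_height=", config$min_height,
                            " retention_ratio=", config$retention_ratio,
                            " body_loss=", config$body_loss))
    write_intervals(tibble(chrom = peaks_cls$chrom,
                           start = peaks_cls$center,
                           end = peaks_cls$center + 1,
                           name = peaks_cls$gene_id,
                           score = peaks_cls$height,
                           strand = "."),
                    out("peaks.bed"))
  }

  message("[seqstats] promoter sequence statistics")
  proms <- promoter_table(ann, regions, config$expression_threshold,
                          config$promoter_width)
  prom_seq <- substring(sequences[proms$chrom], proms$start + 1, proms$end)
  stats <- proms |>
    mutate(at = at_content(prom_seq),
           motif_score = pwm_max_score(prom_seq, motif))
  write_result_tsv(stats, out("promoter_stats.tsv"), "per-promoter A/T and motif score")
  grp <- bind_rows(
    mutate(compare_promoter_groups(
      mutate(stats, value = .data$at), alpha = config$alpha),
      statistic_name = "at_content"),
    mutate(compare_promoter_groups(
      mutate(stats, value = .data$motif_score), alpha = config$alpha),
      statistic_name = "motif_score"))
  write_result_tsv(grp, out("group_comparisons.tsv"),
                   paste0("Mann-Whitney U vs euchromatic control; alpha=",
                          config$alpha))
  if (!is.null(peaks_cls) && nrow(peaks_cls)) {
    flanks <- extract_peak_flanks(peaks_cls, sequences, config$seq_flank)
    write_fasta(setNames(flanks$seq,
                         paste(flanks$gene_id, flanks$center, sep = "|")),
                out("peak_flanks.fa"))
  }

  message("[occupancy] ", length(factors), " factors")
  occ <- occupancy_matrix(proms, factors,
                          threshold = config$occupancy_threshold)
  message("[occupancy] ", length(occ$passing), " factor(s) pass the >",
          config$occupancy_threshold * 100, "% filter")
  write_result_tsv(occ$matrix, out("occupancy_matrix.tsv"),
                   paste0("binary occupancy; threshold=",
                          config$occupancy_threshold))
  write_result_tsv(occ$prevalence, out("occupancy_prevalence.tsv"),
                   "chr4 active-promoter prevalence per factor")

  profile <- NULL
  if (!is.null(hp2) && !is.null(peaks_cls) && nrow(peaks_cls)) {
    centers <- filter(peaks_cls,
                      .data$classification == "methylation_independent")
    if (nrow(centers) == 0) centers <- peaks_cls
    profile <- peak_centered_profile(hp2, centers,
                                     config$profile_halfwidth,
                                     config$profile_binsize)
    write_result_tsv(profile, out("hp2_peak_profile.tsv"),
                     paste0("HP2 around ", nrow(centers), " peak centers"))
  }

  dnase_mg <- NULL
  if (!is.null(dnase_counts)) {
    message("[dnase] density metagene (window ", config$dnase_window, " bp)")
    dens <- cleavage_density(dnase_counts, config$dnase_window)
    dnase_mg <- accessibility_metagene(dens, ann, regions,
                                       config$expression_threshold,
                                       config$promoter_width)
    write_result_tsv(dnase_mg, out("dnase_metagene.tsv"),
                     paste0("window=", config$dnase_window))
  }

  manifest <- build_manifest(outdir)
  write_result_tsv(manifest, out("manifest.tsv"), "md5 content hashes")
  message("[done] ", nrow(manifest), " files in ", outdir)

  invisible(structure(list(outdir = outdir, metagene = mg,
                           peaks = peaks_cls, promoter_stats = stats,
                           group_comparisons = grp, occupancy = occ,
                           hp2_profile = profile, dnase_metagene = dnase_mg,
                           manifest = manifest),
                      class = "metachip_run"))
}

safe_name <- function(x) gsub("[^A-Za-z0-9_.-]", "", x)

track_filename <- function(key) {
  paste0(safe_name(gsub(":", "_", key)), ".bedGraph")
}

build_manifest <- function(outdir) {
  files <- sort(list.files(outdir, recursive = TRUE))
  files <- setdiff(files, "manifest.tsv")
  md5 <- unname(tools::md5sum(file.path(outdir, files)))
  tibble(file = files, md5 = md5)
}

#' One-command demo run on a compact synthetic genome
#'
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @return The [run_pipeline()] result, invisibly.
#' @export
run_demo <- function(seed = 7, outdir = tempfile("metachip_demo_")) {
  run_pipeline(demo_config(seed), outdir)
}

#' @rdname run_demo
#' @export
demo_config <- function(seed = 7) {
  pipeline_config(synthetic = synthetic_config(
    seed = seed,
    n_genes = c(chr4 = 40, r2L31 = 20, pericentromeric = 20,
                euchromatic = 40)))
}
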