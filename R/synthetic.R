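#' Configuration of the synthetic-genome generator
#'
#' Bundles every knob of the generator: genome layout (gene counts and
#' region sizes), probe grid, effect sizes in log2 units, the
#' genotype-by-region response map, promoter sequence composition, the
#' planted motif, factor-binding probabilities and DNase rate multipliers.
#' One integer seed fixes all outputs bit-for-bit.
#'
#' The default effect sizes (`h_p = 1.5`, `h_b = 1.0`, `sigma = 0.3` log2
#' units) are calibration choices for a clearly resolvable promoter peak
#' over gene-body enrichment at realistic tiling-array noise; see the
#' package vignette.
#'
#' @param seed Integer seed (all randomness derives from it).
#' @param n_genes Named integer vector: genes per region label.
#' @param gene_slot Genomic bp reserved per gene (default 4000); regions are
#'   sized `n_genes * gene_slot` unless `region_size` overrides.
#' @param region_size Optional named vector of region sizes in bp; must be
#'   at least `n_genes * gene_slot`.
#' @param probe_spacing Probe grid spacing in bp (default 100).
#' @param gene_length_range Uniform range of gene lengths in bp.
#' @param max_exons Maximum exon count per transcript (uniform 1..max).
#' @param expression_meanlog,expression_sdlog Log-normal expression
#'   parameters for active genes.
#' @param inactive_fraction Fraction of genes with expression 0.
#' @param multi_transcript_fraction Fraction of genes given a second,
#'   shorter and more weakly expressed transcript.
#' @param n_silent_hp1a_targets Number of chromosome-4 genes that are
#'   unexpressed yet carry HP1a promoter and body enrichment in every
#'   genotype (emulating silent HP1a-bound domains).
#' @param h_p Promoter peak height, log2 units.
#' @param h_b Gene-body enrichment height, log2 units.
#' @param sigma Probe noise standard deviation, log2 units (>= 0; 0 gives
#'   the noiseless bump profile).
#' @param bump_shape `"flat"` (default: `h_p` across the defined promoter,
#'   so feature means recover the configured heights exactly) or
#'   `"gaussian"` (sd `gaussian_sd`, centered at the promoter midpoint).
#' @param gaussian_sd Bump standard deviation in bp for
#'   `bump_shape = "gaussian"` (default 150).
#' @param genotype_map Tibble from [default_genotype_map()] (columns
#'   `genotype`, `antibody`, `region`, `body_retained`,
#'   `promoter_retained`).
#' @param hp2_height HP2 co-factor peak height, log2 units.
#' @param factors Tibble `name` + one binding-probability column per region
#'   label; see [default_factor_table()].
#' @param promoter_at Named vector of promoter A/T fractions per region.
#' @param background_at Background A/T fraction outside promoters.
#' @param motif_pwm A [motif_model()] planted in promoters.
#' @param motif_insert_prob Named vector: probability of one motif instance
#'   per promoter, by region.
#' @param dnase_base_rate Poisson cleavage rate per bp outside promoters.
#' @param dnase_promoter_mult,dnase_body_mult Named per-region rate
#'   multipliers at promoters / over gene bodies.
#' @param promoter_width Promoter length in bp (default 500).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_genes = c(chr4 = 100, r2L31 = 60,
                                         pericentromeric = 60,
                                         euchromatic = 100),
                             gene_slot = 4000,
                             region_size = NULL,
                             probe_spacing = 100,
                             gene_length_range = c(800, 2200),
                             max_exons = 5,
                             expression_meanlog = 3,
                             expression_sdlog = 1,
                             inactive_fraction = 0.2,
                             multi_transcript_fraction = 0.25,
                             n_silent_hp1a_targets = 2,
                             h_p = 1.5, h_b = 1.0, sigma = 0.3,
                             bump_shape = c("flat", "gaussian"),
                             gaussian_sd = 150,
                             genotype_map = default_genotype_map(),
                             hp2_height = 1.2,
                             factors = default_factor_table(),
                             promoter_at = c(chr4 = 0.65, r2L31 = 0.62,
                                             pericentromeric = 0.62,
                                             euchromatic = 0.55),
                             background_at = 0.5,
                             motif_pwm = default_motif_pwm(),
                             motif_insert_prob = c(chr4 = 0.6, r2L31 = 0.5,
                                                   pericentromeric = 0.5,
                                                   euchromatic = 0.1),
                             dnase_base_rate = 0.02,
                             dnase_promoter_mult = c(chr4 = 8, r2L31 = 5,
                                                     pericentromeric = 5,
                                                     euchromatic = 4),
                             dnase_body_mult = c(chr4 = 0.5, r2L31 = 1,
                                                 pericentromeric = 1,
                                                 euchromatic = 1),
                             promoter_width = 500) {
  bump_shape <- match.arg(bump_shape)
  labels <- c("chr4", "r2L31", "pericentromeric", "euchromatic")
  stopifnot(length(seed) == 1, is.finite(seed),
            all(labels %in% names(n_genes)),
            all(n_genes >= 0), sum(n_genes) > 0,
            h_p >= 0, h_b >= 0, sigma >= 0, hp2_height >= 0,
            probe_spacing >= 1, promoter_width > 0,
            gene_length_range[1] >= 200,
            max_exons >= 1,
            inactive_fraction >= 0, inactive_fraction <= 1,
            multi_transcript_fraction >= 0, multi_transcript_fraction <= 1,
            all(promoter_at >= 0 & promoter_at <= 1),
            background_at >= 0, background_at <= 1,
            all(motif_insert_prob >= 0 & motif_insert_prob <= 1),
            dnase_base_rate >= 0,
            inherits(motif_pwm, "motif_model"))
  # every slot must hold a gene plus promoter + intergenic clearance
  min_slot <- gene_length_range[2] + promoter_width + 1300
  if (gene_slot < min_slot) {
    stop("gene_slot too small for the configured gene lengths; ",
         "need at least ", min_slot, " bp")
  }
  need <- n_genes[labels] * gene_slot
  if (is.null(region_size)) {
    region_size <- need
  } else {
    region_size <- region_size[labels]
    if (any(region_size < need)) {
      bad <- labels[which(region_size < need)[1]]
      stop("region ", bad, " too small for ", n_genes[bad],
           " genes; suggested minimum ", need[bad], " bp")
    }
  }
  probs <- as.matrix(factors[labels])
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(list(
    seed = seed, n_genes = n_genes[labels], gene_slot = gene_slot,
    region_size = region_size, probe_spacing = probe_spacing,
    gene_length_range = gene_length_range, max_exons = max_exons,
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    inactive_fraction = inactive_fraction,
    multi_transcript_fraction = multi_transcript_fraction,
    n_silent_hp1a_targets = n_silent_hp1a_targets,
    h_p = h_p, h_b = h_b, sigma = sigma, bump_shape = bump_shape,
    gaussian_sd = gaussian_sd, genotype_map = genotype_map,
    hp2_height = hp2_height, factors = factors,
    promoter_at = promoter_at[labels], background_at = background_at,
    motif_pwm = motif_pwm, motif_insert_prob = motif_insert_prob[labels],
    dnase_base_rate = dnase_base_rate,
    dnase_promoter_mult = dnase_promoter_mult[labels],
    dnase_body_mult = dnase_body_mult[labels],
    promoter_width = promoter_width), class = "synthetic_config")
}

#' Genotype-by-region response map of the generator
#'
#' Encodes which enrichment components survive in each mutant: gene-body
#' enrichment of HP1a and H3K9me2/3 is lost in the mutant of the region's
#' methyltransferase (Su(var)3-9 for the pericentromeric blocks, Setdb1 for
#' chromosome 4 and region 2L:31), and additionally on chromosome 4 in Pof
#' mutants; HP1a promoter peaks persist in every genotype; H3K9me tracks
#' never carry promoter peaks; G9a loss changes nothing; euchromatin never
#' carries enrichment.
#'
#' @return Tibble with columns `genotype`, `antibody`, `region`,
#'   `body_retained`, `promoter_retained`.
#' @export
default_genotype_map <- function() {
  grid <- tidyr::expand_grid(genotype = GENOTYPES, antibody = ANTIBODIES,
                             region = setdiff(REGION_LABELS, "excluded"))
  grid |>
    mutate(
      het = .data$region %in% c("chr4", "r2L31", "pericentromeric"),
      hkmt = dplyr::case_when(
        .data$region == "pericentromeric" ~ "Su(var)3-9",
        .data$region %in% c("chr4", "r2L31") ~ "Setdb1",
        TRUE ~ NA_character_),
      body_retained = .data$het &
        !(.data$genotype == .data$hkmt & !is.na(.data$hkmt)) &
        !(.data$genotype == "Pof" & .data$region == "chr4"),
      promoter_retained = .data$het & .data$antibody == "HP1a"
    ) |>
    select("genotype", "antibody", "region", "body_retained",
           "promoter_retained")
}

#' Default chromatin-factor table of the generator
#'
#' A small panel of promoter-binding factors with region-specific Bernoulli
#' binding probabilities: co-factors concentrated on chromosome 4 and the
#' other HP1a-enriched regions (HP2-like), broadly binding promoter factors,
#' and factors depleted from heterochromatin.
#'
#' @return Tibble with columns `name`, `chr4`, `r2L31`, `pericentromeric`,
#'   `euchromatic`.
#' @export
default_factor_table <- function() {
  tibble(
    name = c("HP2", "Chromator", "BEAF-32", "Trx", "E(bx)", "CP190",
             "dMi-2", "Su(Hw)", "MRG15", "JIL-1"),
    chr4 = c(0.95, 0.70, 0.60, 0.55, 0.55, 0.40, 0.35, 0.20, 0.30, 0.25),
    r2L31 = c(0.85, 0.65, 0.55, 0.50, 0.50, 0.40, 0.35, 0.20, 0.30, 0.25),
    pericentromeric = c(0.85, 0.60, 0.50, 0.45, 0.50, 0.40, 0.35, 0.20,
                        0.30, 0.25),
    euchromatic = c(0.05, 0.60, 0.55, 0.45, 0.40, 0.45, 0.40, 0.25, 0.35,
                    0.30))
}

#' Default planted promoter motif (A/T rich, 8 bp)
#'
#' @param pseudocount Probability floor applied off-consensus.
#' @return A [motif_model()].
#' @export
default_motif_pwm <- function(pseudocount = 0.04) {
  consensus <- c("A", "A", "T", "A", "A", "T", "T", "A")
  m <- matrix(pseudocount, nrow = length(consensus), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(consensus)) m[i, consensus[i]] <- 1 - 3 * pseudocount
  motif_model(m)
}

# Stable sub-seed derivation so each generated object has its own stream
# while everything follows from one user seed. Result is < 2^31.
derive_seed <- function(seed, tag) {
  h <- 0
  for (c in utf8ToInt(tag)) h <- (h * 31 + c) %% 1000003
  as.integer(((abs(seed) %% 1000003) * 1009 + h) %% 2147483647)
}

#' Generate a synthetic genome: sequence, annotation, regions
#'
#' Lays out non-overlapping genes in four region blocks (a chromosome-4-like
#' chromosome; a pericentromeric block, interior 2L:31-like block and
#' euchromatin on a 2L-like chromosome), draws transcript structures and
#' expression, and synthesizes sequence with region-specific promoter A/T
#' composition and planted motif instances. A configurable number of
#' chromosome-4 genes are silenced (expression 0) yet remain HP1a targets
#' in every genotype.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_genome` list: `sequences` (named character),
#'   `annotation` (tibble, see [annotation]), `regions` (tibble),
#'   `chrom_sizes` (named numeric), `gene_regions` (tibble `gene_id`,
#'   `region`), `silent_targets` (gene ids), `promoters` (tibble `gene_id`,
#'   `chrom`, `strand`, `p_start`, `p_end` - the generator's injected
#'   ground truth), `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "genome"))
  slot <- config$gene_slot
  labels <- names(config$n_genes)

  # region layout: chr4 alone; p2L + euchromatin + interior r2L31 on chr2L
  ne <- config$n_genes[["euchromatic"]]
  ne1 <- ceiling(ne / 2); ne2 <- ne - ne1
  blocks <- tibble(
    chrom = c("chr4", "chr2L", "chr2L", "chr2L", "chr2L"),
    region = c("chr4", "pericentromeric", "euchromatic", "r2L31",
               "euchromatic"),
    n = c(config$n_genes[["chr4"]], config$n_genes[["pericentromeric"]],
          ne1, config$n_genes[["r2L31"]], ne2))
  blocks$size <- blocks$n * slot
  extra <- config$region_size - config$n_genes[labels] * slot
  blocks$size <- blocks$size + vapply(seq_len(nrow(blocks)), function(i) {
    lab <- blocks$region[i]
    share <- extra[[lab]]
    if (lab == "euchromatic") share <- floor(share / 2)
    share
  }, numeric(1))
  blocks <- blocks[blocks$n > 0 | blocks$size > 0, ]
  blocks <- blocks |> group_by(.data$chrom) |>
    mutate(start = cumsum(dplyr::lag(.data$size, default = 0)),
           end = .data$start + .data$size) |>
    ungroup()
  chrom_sizes <- blocks |> group_by(.data$chrom) |>
    summarise(size = max(.data$end) + 1000, .groups = "drop")
  chrom_sizes <- setNames(chrom_sizes$size, chrom_sizes$chrom)

  genes <- list()
  counter <- setNames(rep(0L, length(labels)), labels)
  for (i in seq_len(nrow(blocks))) {
    bl <- blocks[i, ]
    if (bl$n == 0) next
    for (j in seq_len(bl$n)) {
      counter[[bl$region]] <- counter[[bl$region]] + 1L
      slot_start <- bl$start + (j - 1) * slot
      len <- round(runif(1, config$gene_length_range[1],
                         config$gene_length_range[2]))
      start <- slot_start + 1400
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("%s_g%03d", gsub("[()]", "", bl$region),
                     counter[[bl$region]])
      genes[[length(genes) + 1]] <- tibble(
        gene_id = gid, chrom = bl$chrom, region = bl$region,
        strand = strand, start = start, end = start + len)
    }
  }
  genes <- bind_rows(genes)

  # expression and silenced HP1a targets (middle of chromosome 4)
  n <- nrow(genes)
  active <- runif(n) >= config$inactive_fraction
  silent <- character()
  if (config$n_silent_hp1a_targets > 0) {
    chr4_idx <- which(genes$region == "chr4")
    if (length(chr4_idx) >= config$n_silent_hp1a_targets) {
      mid <- chr4_idx[floor(length(chr4_idx) / 2) +
                        seq_len(config$n_silent_hp1a_targets) -
                        config$n_silent_hp1a_targets %/% 2]
      active[mid] <- FALSE
      silent <- genes$gene_id[mid]
    }
  }
  expr <- ifelse(active,
                 round(rlnorm(n, config$expression_meanlog,
                              config$expression_sdlog), 3), 0)

  ann <- list()
  for (i in seq_len(n)) {
    g <- genes[i, ]
    exons <- draw_exons(g$start, g$end, config$max_exons)
    ann[[length(ann) + 1]] <- tibble(
      gene_id = g$gene_id, transcript_id = paste0(g$gene_id, ".t1"),
      chrom = g$chrom, strand = g$strand, span_start = g$start,
      span_end = g$end, expression = expr[i], exons = list(exons))
    if (runif(1) < config$multi_transcript_fraction &&
        g$end - g$start >= 600) {
      s2 <- g$start + 200
      ann[[length(ann) + 1]] <- tibble(
        gene_id = g$gene_id, transcript_id = paste0(g$gene_id, ".t2"),
        chrom = g$chrom, strand = g$strand, span_start = s2,
        span_end = g$end, expression = round(expr[i] * 0.3, 3),
        exons = list(data.frame(start = s2, end = g$end)))
    }
  }
  ann <- bind_rows(ann) |>
    arrange(.data$chrom, .data$span_start, .data$gene_id,
            .data$transcript_id)
  validate_annotation(ann)

  promoters <- genes |>
    mutate(p_start = ifelse(.data$strand == "+",
                            .data$start - config$promoter_width, .data$end),
           p_end = ifelse(.data$strand == "+", .data$start,
                          .data$end + config$promoter_width)) |>
    select("gene_id", "chrom", "strand", "p_start", "p_end")

  sequences <- draw_sequences(genes, promoters, chrom_sizes, config)

  regions <- blocks |>
    select("chrom", "start", "end", "region") |>
    arrange(.data$chrom, .data$start)

  structure(list(sequences = sequences, annotation = ann, regions = regions,
                 chrom_sizes = chrom_sizes,
                 gene_regions = genes[c("gene_id", "region")],
                 silent_targets = silent, promoters = promoters,
                 config = config),
            class = "synthetic_genome")
}

# Exon/intron structure: k exons and k-1 introns with a 30 bp floor per
# segment, proportions drawn from exponential weights.
draw_exons <- function(start, end, max_exons) {
  len <- end - start
  k <- if (len < 400) 1L else sample.int(max_exons, 1)
  nseg <- 2L * k - 1L
  if (nseg == 1L) return(data.frame(start = start, end = end))
  w <- rexp(nseg)
  seg <- floor((len - 30 * nseg) * w / sum(w)) + 30
  seg[nseg] <- len - sum(seg[-nseg])
  bounds <- start + cumsum(c(0, seg))
  idx <- seq(1, nseg, by = 2)
  data.frame(start = bounds[idx], end = bounds[idx + 1])
}

draw_sequences <- function(genes, promoters, chrom_sizes, config) {
  bases <- c("A", "C", "G", "T")
  at_probs <- function(at) c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  seqs <- list()
  for (ch in names(chrom_sizes)) {
    s <- sample(bases, chrom_sizes[[ch]], replace = TRUE,
                prob = at_probs(config$background_at))
    idx <- which(genes$chrom == ch)
    for (i in idx) {
      p <- promoters[promoters$gene_id == genes$gene_id[i], ]
      at <- config$promoter_at[[genes$region[i]]]
      w <- (p$p_start + 1):p$p_end     # 1-based
      s[w] <- sample(bases, length(w), replace = TRUE, prob = at_probs(at))
      if (runif(1) < config$motif_insert_prob[[genes$region[i]]]) {
        pwm <- config$motif_pwm$prob
        inst <- vapply(seq_len(nrow(pwm)), function(r)
          sample(bases, 1, prob = pwm[r, ]), character(1))
        off <- sample.int(length(w) - length(inst) + 1, 1)
        s[w[off + seq_along(inst) - 1]] <- inst
      }
    }
    seqs[[ch]] <- paste(s, collapse = "")
  }
  unlist(seqs)
}

#' Generate a synthetic ChIP enrichment track
#'
#' Produces the probe-level log2 enrichment of one (genotype, antibody)
#' combination: i.i.d. Gaussian baseline noise, plus the promoter peak
#' (height `h_p`, HP1a only) at each active-gene promoter where the
#' genotype map retains it, plus gene-body enrichment (`h_b`) over exonic
#' probes of active genes where retained. Silenced HP1a-target genes
#' receive both HP1a components in every genotype; H3K9me tracks never
#' receive promoter peaks. Effects are additive in log2 units.
#'
#' @param genome A [generate_genome()] result.
#' @param genotype One of `"wildtype"`, `"Su(var)3-9"`, `"Setdb1"`,
#'   `"G9a"`, `"Pof"`.
#' @param antibody One of `"HP1a"`, `"H3K9me2"`, `"H3K9me3"`.
#' @return A probe track on the genome-wide grid.
#' @export
generate_chip_track <- function(genome, genotype = "wildtype",
                                antibody = "HP1a") {
  stopifnot(inherits(genome, "synthetic_genome"))
  config <- genome$config
  if (!genotype %in% GENOTYPES) stop("unknown genotype: ", genotype)
  if (!antibody %in% ANTIBODIES) stop("unknown antibody: ", antibody)
  set.seed(derive_seed(config$seed, paste("chip", genotype, antibody)))
  trk <- probe_grid(genome$chrom_sizes, config$probe_spacing)
  trk$value <- if (config$sigma > 0) rnorm(nrow(trk), 0, config$sigma) else 0

  gm <- config$genotype_map
  flags <- gm[gm$genotype == genotype & gm$antibody == antibody, ]
  flag_of <- function(region, what) {
    row <- flags[flags$region == region, ]
    if (nrow(row) == 0) FALSE else row[[what]][1]
  }
  sel <- ann_main(genome)
  by_chrom <- split(seq_len(nrow(trk)), trk$chrom)

  add_interval <- function(chrom, a, b, amount, shape = "flat",
                           center = NULL) {
    idx <- by_chrom[[chrom]]
    if (is.null(idx)) return()
    pos <- trk$pos[idx]
    rng <- probe_range(pos, a, b)
    if (rng[1] > rng[2]) return()
    hit <- idx[rng[1]:rng[2]]
    if (shape == "flat") {
      trk$value[hit] <<- trk$value[hit] + amount
    } else {
      d <- trk$pos[hit] - center
      trk$value[hit] <<- trk$value[hit] +
        amount * exp(-d^2 / (2 * config$gaussian_sd^2))
    }
  }

  for (i in seq_len(nrow(sel))) {
    g <- sel[i, ]
    silent_target <- g$gene_id %in% genome$silent_targets
    is_active <- g$expression > 0
    prom_on <- (antibody == "HP1a") &&
      ((is_active && flag_of(g$region, "promoter_retained")) ||
         (silent_target && g$region == "chr4"))
    body_on <- (is_active && flag_of(g$region, "body_retained")) ||
      (silent_target && antibody == "HP1a" && g$region == "chr4")
    if (prom_on) {
      p <- genome$promoters[genome$promoters$gene_id == g$gene_id, ]
      if (config$bump_shape == "flat") {
        add_interval(g$chrom, p$p_start, p$p_end, config$h_p)
      } else {
        ctr <- (p$p_start + p$p_end) / 2
        add_interval(g$chrom, p$p_start - 3 * config$gaussian_sd,
                     p$p_end + 3 * config$gaussian_sd, config$h_p,
                     shape = "gaussian", center = ctr)
      }
    }
    if (body_on) {
      e <- g$exons[[1]]
      for (k in seq_len(nrow(e))) {
        add_interval(g$chrom, e$start[k], e$end[k], config$h_b)
      }
    }
  }
  trk
}

# Selected transcript (max expression) of each gene, with region label.
ann_main <- function(genome) {
  sel <- select_transcripts(genome$annotation)
  left_join(sel, genome$gene_regions, by = "gene_id")
}

probe_grid <- function(chrom_sizes, spacing) {
  parts <- lapply(sort(names(chrom_sizes)), function(ch) {
    pos <- seq(spacing %/% 2, chrom_sizes[[ch]] - 1, by = spacing)
    tibble(chrom = ch, pos = as.numeric(pos), value = 0)
  })
  bind_rows(parts)
}

#' Generate auxiliary synthetic tracks: HP2, factor intervals, DNase counts
#'
#' HP2 is a probe track with a Gaussian peak (sd 150 bp) co-centered with
#' every wild-type HP1a promoter peak. Each chromatin factor gets one
#' 200 bp promoter-overlapping interval per promoter with its
#' region-specific Bernoulli probability. DNase cleavage counts are
#' per-base Poisson over each gene's territory (promoter plus gene span),
#' with the promoter rate elevated and the chromosome-4 body rate lowered
#' relative to euchromatin.
#'
#' @param genome A [generate_genome()] result.
#' @param which Subset of `c("hp2", "factors", "dnase")` to generate
#'   (default all three).
#' @return A list with elements `hp2` (probe track), `factors` (named list
#'   of interval tibbles) and `dnase` (per-base count track); omitted
#'   components are `NULL`.
#' @export
generate_aux_tracks <- function(genome, which = c("hp2", "factors", "dnase")) {
  stopifnot(inherits(genome, "synthetic_genome"))
  which <- match.arg(which, several.ok = TRUE)
  config <- genome$config
  sel <- ann_main(genome)
  prom <- left_join(genome$promoters, genome$gene_regions, by = "gene_id")
  prom <- left_join(prom, sel[c("gene_id", "expression")], by = "gene_id")
  prom$center <- floor((prom$p_start + prom$p_end) / 2)
  het <- c("chr4", "r2L31", "pericentromeric")
  prom$hp1a_peak <- (prom$expression > 0 & prom$region %in% het) |
    prom$gene_id %in% genome$silent_targets

  hp2 <- NULL
  if ("hp2" %in% which) {
    set.seed(derive_seed(config$seed, "hp2"))
    hp2 <- probe_grid(genome$chrom_sizes, config$probe_spacing)
    hp2$value <- if (config$sigma > 0) rnorm(nrow(hp2), 0, config$sigma) else 0
    by_chrom <- split(seq_len(nrow(hp2)), hp2$chrom)
    for (i in base::which(prom$hp1a_peak)) {
      idx <- by_chrom[[prom$chrom[i]]]
      pos <- hp2$pos[idx]
      rng <- probe_range(pos, prom$center[i] - 600, prom$center[i] + 600)
      if (rng[1] > rng[2]) next
      hit <- idx[rng[1]:rng[2]]
      d <- hp2$pos[hit] - prom$center[i]
      hp2$value[hit] <- hp2$value[hit] +
        config$hp2_height * exp(-d^2 / (2 * 150^2))
    }
  }

  factors <- NULL
  if ("factors" %in% which) {
    set.seed(derive_seed(config$seed, "factors"))
    factors <- list()
    for (f in seq_len(nrow(config$factors))) {
      nm <- config$factors$name[f]
      p <- unlist(config$factors[f, names(config$n_genes)])
      bound <- runif(nrow(prom)) < p[prom$region]
      factors[[nm]] <- tibble(chrom = prom$chrom[bound],
                              start = prom$center[bound] - 100,
                              end = prom$center[bound] + 100,
                              name = nm) |>
        arrange(.data$chrom, .data$start)
    }
  }

  dnase <- NULL
  if ("dnase" %in% which) {
    set.seed(derive_seed(config$seed, "dnase"))
    parts <- list()
    for (i in seq_len(nrow(sel))) {
      g <- sel[i, ]
      p <- prom[prom$gene_id == g$gene_id, ]
      lo <- min(p$p_start, g$span_start)
      hi <- max(p$p_end, g$span_end)
      pos <- lo:(hi - 1)
      rate <- rep(config$dnase_base_rate, length(pos))
      in_prom <- pos >= p$p_start & pos < p$p_end
      in_body <- pos >= g$span_start & pos < g$span_end
      rate[in_body] <- config$dnase_base_rate *
        config$dnase_body_mult[[g$region]]
      rate[in_prom] <- config$dnase_base_rate *
        config$dnase_promoter_mult[[g$region]]
      parts[[i]] <- tibble(chrom = g$chrom, pos = as.numeric(pos),
                           value = as.numeric(rpois(length(pos), rate)))
    }
    dnase <- arrange(bind_rows(parts), .data$chrom, .data$pos)
  }

  list(hp2 = hp2, factors = factors, dnase = dnase)
}
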