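#' Configuration for the synthetic benchmark dataset
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' two sample groups of H3K27ac landscapes in which the case group carries
#' 20 shared super-enhancer loci enriched in planted GGAA microsatellites,
#' a fully interconnected 3-TF core regulatory circuit planted in case
#' samples only, and a "hegemonic" driver TF whose motif is planted in the
#' circuit TFs' super-enhancers while its own super-enhancer receives no
#' motif at all — so the driver acquires out-edges but never a self-loop,
#' and is excluded from every clique by construction. Loops connect TF
#' promoters to microsatellite-bound anchors at configured hop distances;
#' the expression matrix and dependency table are consistent with the
#' planted truth.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical files.
#' @param n_case,n_control Samples per group (default 10 and 10).
#' @param chrom_length Chromosome length in bp (two chromosomes; default
#'   2 Mb, enough to keep planted loci separated by more than the ROSE
#'   stitch distance).
#' @param n_genes,n_tfs Total genes and how many are TFs (60 / 12).
#' @param se_msat_per_kb Planted GGAA run density inside case
#'   super-enhancer constituents (default 1 per kb).
#' @param bg_msat_per_kb Background GGAA run density elsewhere (default
#'   0.1 per kb, i.e. a 10x enrichment in case SEs).
#' @param n_se_per_sample Planted super-enhancer loci per sample
#'   (default 20).
#' @param se_height,enh_height Log-normal median peak heights for SE
#'   constituents and typical enhancers (20 and 2).
#' @param jitter_sd Peak-boundary jitter in bp (default 100).
#' @param expr_noise_sd Gaussian noise on log2 expression (default 0.4).
#' @param loop_hops Named integer vector of planted hop distances from TF
#'   promoters to microsatellite anchors; a hop of 6 is unreachable at the
#'   default chain depth of 5.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 42L, n_case = 10L, n_control = 10L,
                         chrom_length = 2000000L, n_genes = 60L, n_tfs = 12L,
                         se_msat_per_kb = 1.0, bg_msat_per_kb = 0.1,
                         n_se_per_sample = 20L, se_height = 20, enh_height = 2,
                         jitter_sd = 100, expr_noise_sd = 0.4,
                         loop_hops = c(TF01 = 1L, TF02 = 2L, TF03 = 3L,
                                       TF04 = 5L, TF05 = 6L)) {
  stopifnot(n_tfs >= 7L, n_genes >= 56L, n_se_per_sample >= 5L)
  structure(list(seed = as.integer(seed), n_case = n_case, n_control = n_control,
                 chrom_length = as.integer(chrom_length), n_genes = n_genes,
                 n_tfs = n_tfs, se_msat_per_kb = se_msat_per_kb,
                 bg_msat_per_kb = bg_msat_per_kb,
                 n_se_per_sample = n_se_per_sample, se_height = se_height,
                 enh_height = enh_height, jitter_sd = jitter_sd,
                 expr_noise_sd = expr_noise_sd, loop_hops = loop_hops),
            class = "synth_config")
}

# deterministic gene layout: genes alternate between the two chromosomes,
# one locus every 60 kb; each locus hosts the TSS, three SE constituent
# slots downstream, and a standalone enhancer slot 30 kb downstream
synth_gene_layout <- function(cfg) {
  i <- seq_len(cfg$n_genes)
  gene <- c(sprintf("TF%02d", seq_len(cfg$n_tfs)),
            sprintf("GENE%02d", (cfg$n_tfs + 1L):cfg$n_genes))
  chrom <- paste0("chr", (i - 1L) %% 2L + 1L)
  locus <- (i + 1L) %/% 2L
  tss <- 20000L + (locus - 1L) * 60000L
  stopifnot(max(tss) + 35000L < cfg$chrom_length)
  tibble(gene = gene, chrom = chrom, tss = tss, is_tf = i <= cfg$n_tfs,
         locus = locus)
}

# constituent intervals of a locus SE cluster (BED half-open, rel. to tss)
CONSTIT_OFFSETS <- c(2000L, 6000L, 10000L)
CONSTIT_WIDTH <- 1500L
ENH_OFFSET <- 30000L
ENH_WIDTH <- 1000L
# features are planted only in the central zone of each constituent so that
# boundary jitter cannot move them out of the peak
ZONE_OFFSET <- 400L
ZONE_WIDTH <- 700L

synth_roles <- function(cfg) {
  genes <- synth_gene_layout(cfg)
  n_other <- cfg$n_se_per_sample - 4L
  pool_n <- cfg$n_se_per_sample + 4L  # control loci pool; samples draw subsets
  list(
    genes = genes,
    crc_tfs = c("TF01", "TF02", "TF03"),
    driver = "TF04",
    control_se_tfs = c("TF05", "TF06", "TF07"),
    case_se_genes = c("TF01", "TF02", "TF03", "TF04",
                      genes$gene[13:(12L + n_other)]),
    control_se_pool = c("TF05", "TF06", "TF07",
                        genes$gene[(13L + n_other):(12L + n_other + pool_n)])
  )
}

# enhancer loci used as chain intermediates; always present in case samples
CHAIN_ENH_LOCI <- list(chr1 = c(5L, 6L, 8L, 9L, 10L, 11L, 12L),
                       chr2 = c(5L, 7L, 8L, 9L, 10L))

#' Generate the full synthetic dataset
#'
#' Writes a complete dataset directory — genome FASTA, per-sample
#' narrowPeak + bedGraph H3K27ac files, fusion-TF (ETS) narrowPeak files
#' and loops (cases only), a JASPAR motif file, gene annotation, expression
#' matrix, dependency table, a sample sheet, and a JSON truth manifest
#' sufficient to recompute every expected intermediate.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
simulate_dataset <- function(cfg = synth_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed, kind = "Mersenne-Twister")

  roles <- synth_roles(cfg)
  genes <- roles$genes

  gen <- synth_genome(cfg, roles)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(gen$chroms)), file.path(out_dir, "genome.fa"))
  write_jaspar(gen$motifs, file.path(out_dir, "motifs.jaspar"))
  write.table(genes[, c("gene", "chrom", "tss", "is_tf")],
              file.path(out_dir, "annotation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  samples <- tibble(
    sample_id = c(sprintf("case%02d", seq_len(cfg$n_case)),
                  sprintf("ctrl%02d", seq_len(cfg$n_control))),
    group = rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
  )
  chip <- synth_chip_samples(cfg, roles, gen, samples, out_dir)
  loops <- synth_loops(cfg, roles, gen, samples, out_dir)
  ed <- synth_expression_dependency(cfg, roles, samples, out_dir)

  sheet <- tibble(
    sample_id = samples$sample_id,
    group = samples$group,
    peaks = paste0(samples$sample_id, "_h3k27ac.narrowPeak"),
    signal = paste0(samples$sample_id, "_h3k27ac.bedGraph"),
    ets_peaks = ifelse(samples$group == "case",
                       paste0(samples$sample_id, "_ets.narrowPeak"), NA),
    loops = ifelse(samples$group == "case",
                   paste0(samples$sample_id, "_loops.bedpe"), NA)
  )
  write.table(sheet, file.path(out_dir, "sample_sheet.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")

  manifest <- list(
    seed = cfg$seed,
    samples = samples,
    crc_tfs = roles$crc_tfs,
    driver = roles$driver,
    control_se_tfs = roles$control_se_tfs,
    case_se_genes = roles$case_se_genes,
    control_se_pool = roles$control_se_pool,
    n_se_per_sample = cfg$n_se_per_sample,
    msat_records = gen$msat_records,
    motif_plantings = gen$motif_plantings,
    loop_hops = as.list(cfg$loop_hops),
    expected_chain_hops = lapply(cfg$loop_hops, function(h) if (h > 5L) NA_integer_ else h),
    expected_specificity_candidates = roles$crc_tfs,
    expected_selected_mtfs = roles$crc_tfs,
    expected_dependency_genes = ed$expected_dependency_genes,
    expected_case_specific_tfs = c(roles$crc_tfs, roles$driver),
    expression_design = ed$design,
    files = list(genome = "genome.fa", motifs = "motifs.jaspar",
                 annotation = "annotation.tsv", expression = "expression.tsv",
                 dependency = "dependency.csv", sample_sheet = "sample_sheet.tsv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# ---- genome with planted microsatellites and motifs ------------------------

synth_genome <- function(cfg, roles) {
  genes <- roles$genes
  chroms <- list(
    chr1 = random_dna(cfg$chrom_length),
    chr2 = random_dna(cfg$chrom_length)
  )
  # distinct 10-bp consensus motifs per TF, none containing a GGAA/TTCC pair
  tf_names <- genes$gene[genes$is_tf]
  consensus <- character(0)
  while (length(consensus) < length(tf_names)) {
    cand <- random_dna(10L)
    if (cand %in% consensus) next
    if (grepl("GGAA|TTCC", cand)) next
    consensus <- c(consensus, cand)
  }
  names(consensus) <- tf_names
  motifs <- lapply(tf_names, function(tf) {
    ch <- strsplit(consensus[[tf]], "")[[1]]
    counts <- matrix(1, 4, length(ch), dimnames = list(c("A", "C", "G", "T"), NULL))
    counts[cbind(match(ch, c("A", "C", "G", "T")), seq_along(ch))] <- 97
    list(motif_id = paste0("SYN", sub("TF", "", tf)), tf_name = tf,
         counts = counts, pseudocount = 1,
         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  })
  names(motifs) <- tf_names

  msat_records <- list()
  motif_plantings <- list()

  # features per planted SE locus: the CRC TF loci additionally receive two
  # copies of each circuit TF motif and of the driver motif
  for (g in roles$case_se_genes) {
    gi <- which(genes$gene == g)
    feature_seqs <- character()
    feature_kind <- character()
    if (g %in% roles$crc_tfs) {
      for (src in c(roles$crc_tfs, roles$driver)) {
        feature_seqs <- c(feature_seqs, rep(consensus[[src]], 2L))
        feature_kind <- c(feature_kind, rep(paste0("motif:", src), 2L))
      }
    }
    n_msat <- max(1L, rpois(1, cfg$se_msat_per_kb * 3 * CONSTIT_WIDTH / 1000))
    for (m in seq_len(n_msat)) {
      n_copies <- 4L + sample(0:6, 1)
      feature_seqs <- c(feature_seqs, strrep("GGAA", n_copies))
      feature_kind <- c(feature_kind, paste0("msat:", n_copies))
    }
    placed <- plant_locus_features(chroms[[genes$chrom[gi]]], genes$tss[gi],
                                   feature_seqs)
    chroms[[genes$chrom[gi]]] <- placed$sequence
    for (f in seq_along(feature_seqs)) {
      rec <- list(gene = g, chrom = genes$chrom[gi],
                  start = placed$starts[f],
                  end = placed$starts[f] + nchar(feature_seqs[f]))
      if (startsWith(feature_kind[f], "msat")) {
        rec$n_copies <- as.integer(sub("msat:", "", feature_kind[f]))
        msat_records[[length(msat_records) + 1L]] <- rec
      } else {
        rec$source_tf <- sub("motif:", "", feature_kind[f])
        motif_plantings[[length(motif_plantings) + 1L]] <- rec
      }
    }
  }

  # control SE constituents and standalone enhancer slots receive explicit
  # background-rate GGAA runs, density-matched per region-kilobase, so that
  # control super-enhancers and typical enhancers share the same expected
  # microsatellite density (only case SEs are enriched)
  span_kb <- (CONSTIT_OFFSETS[3] + CONSTIT_WIDTH - CONSTIT_OFFSETS[1]) / 1000
  for (g in roles$control_se_pool) {
    gi <- which(genes$gene == g)
    cc <- genes$chrom[gi]
    for (o in CONSTIT_OFFSETS) {
      zp <- plant_zone_runs(chroms[[cc]], genes$tss[gi] + o + ZONE_OFFSET,
                            ZONE_WIDTH, cfg$bg_msat_per_kb * span_kb / 3)
      chroms[[cc]] <- zp$sequence
      for (rec in zp$records) {
        rec$gene <- NA_character_; rec$chrom <- cc
        msat_records[[length(msat_records) + 1L]] <- rec
      }
    }
  }
  for (ci in seq_len(nrow(genes))) {
    cc <- genes$chrom[ci]
    zp <- plant_zone_runs(chroms[[cc]], genes$tss[ci] + ENH_OFFSET + 150L,
                          ENH_WIDTH - 300L, cfg$bg_msat_per_kb * ENH_WIDTH / 1000)
    chroms[[cc]] <- zp$sequence
    for (rec in zp$records) {
      rec$gene <- NA_character_; rec$chrom <- cc
      msat_records[[length(msat_records) + 1L]] <- rec
    }
  }

  # sparse background GGAA runs scattered outside all planted zones, at the
  # same per-kb rate over the area actually available for placement, so the
  # background field density matches the control/enhancer planting rate
  se_loci <- genes[genes$gene %in% c(roles$case_se_genes, roles$control_se_pool), ]
  forbidden <- bind_rows(
    tibble(chrom = se_loci$chrom, start = se_loci$tss, end = se_loci$tss + 13000L),
    tibble(chrom = genes$chrom, start = genes$tss + ENH_OFFSET - 100L,
           end = genes$tss + ENH_OFFSET + ENH_WIDTH + 100L)
  )
  allowed_kb <- (2 * cfg$chrom_length - sum(forbidden$end - forbidden$start)) / 1000
  n_bg <- rpois(1, cfg$bg_msat_per_kb * allowed_kb)
  bg_placed <- 0L
  attempts <- 0L
  while (bg_placed < n_bg && attempts < n_bg * 20L) {
    attempts <- attempts + 1L
    cc <- sample(names(chroms), 1)
    n_copies <- 4L + sample(0:4, 1)
    run <- strrep("GGAA", n_copies)
    pos <- sample.int(cfg$chrom_length - nchar(run) - 100L, 1)
    fb <- forbidden[forbidden$chrom == cc, ]
    if (any(pos < fb$end + 50L & pos + nchar(run) > fb$start - 50L)) next
    prior <- keep(msat_records, ~ .x$chrom == cc)
    if (length(prior) &&
        any(map_lgl(prior, ~ pos < .x$end + 20L && pos + nchar(run) > .x$start - 20L))) next
    substr(chroms[[cc]], pos + 1L, pos + nchar(run)) <- run
    msat_records[[length(msat_records) + 1L]] <-
      list(gene = NA_character_, chrom = cc, start = pos,
           end = pos + nchar(run), n_copies = n_copies)
    bg_placed <- bg_placed + 1L
  }
  if (bg_placed < n_bg) {
    stop("could not place all background microsatellites (collisions)", call. = FALSE)
  }

  list(chroms = chroms, motifs = motifs, consensus = consensus,
       msat_records = msat_records, motif_plantings = motif_plantings)
}

# place features sequentially in the central zones of a locus's three
# constituents (round-robin), separated by random spacers; errors if a zone
# overflows
plant_locus_features <- function(chrom_seq, tss, feature_seqs) {
  zones <- lapply(CONSTIT_OFFSETS, function(o) {
    c(tss + o + ZONE_OFFSET, tss + o + ZONE_OFFSET + ZONE_WIDTH)
  })
  cursors <- vapply(zones, `[`, numeric(1), 1)
  starts <- integer(length(feature_seqs))
  for (f in seq_along(feature_seqs)) {
    z <- (f - 1L) %% 3L + 1L
    gap <- sample(10:40, 1)
    pos <- cursors[z] + gap
    if (pos + nchar(feature_seqs[f]) > zones[[z]][2]) {
      stop("planting zone overflow at locus near ", tss, call. = FALSE)
    }
    substr(chrom_seq, pos + 1L, pos + nchar(feature_seqs[f])) <- feature_seqs[f]
    starts[f] <- as.integer(pos)
    cursors[z] <- pos + nchar(feature_seqs[f])
  }
  list(sequence = chrom_seq, starts = starts)
}

# plant Poisson(lambda) GGAA runs sequentially inside one zone
plant_zone_runs <- function(chrom_seq, zone_start, zone_len, lambda) {
  n <- rpois(1, lambda)
  records <- list()
  cursor <- zone_start
  for (r in seq_len(n)) {
    n_copies <- 4L + sample(0:4, 1)
    run <- strrep("GGAA", n_copies)
    cursor <- cursor + sample(10:40, 1)
    if (cursor + nchar(run) > zone_start + zone_len) break
    substr(chrom_seq, cursor + 1L, cursor + nchar(run)) <- run
    records[[length(records) + 1L]] <- list(start = as.integer(cursor),
                                            end = as.integer(cursor + nchar(run)),
                                            n_copies = n_copies)
    cursor <- cursor + nchar(run)
  }
  list(sequence = chrom_seq, records = records)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- per-sample ChIP peaks and signal --------------------------------------

synth_chip_samples <- function(cfg, roles, gen, samples, out_dir) {
  genes <- roles$genes
  # shared enhancer slots are kept only where chains need them (cases);
  # all other typical enhancers are private per-sample windows drawn from
  # the background field, so per-sample microsatellite densities are
  # independent draws rather than one shared realization
  chain_rows <- which((genes$chrom == "chr1" & genes$locus %in% CHAIN_ENH_LOCI$chr1) |
                        (genes$chrom == "chr2" & genes$locus %in% CHAIN_ENH_LOCI$chr2))
  pool_genes <- setdiff(roles$control_se_pool, roles$control_se_tfs)
  n_private <- 20L
  # windows that private enhancers must avoid: any gene locus (its SE
  # cluster plus a stitch-distance margin) and the decoy-loop desert
  desert <- max(genes$tss) + 50000L
  private_forbidden <- bind_rows(
    tibble(chrom = genes$chrom, start = genes$tss - 13000L, end = genes$tss + 25000L),
    tibble(chrom = genes$chrom, start = genes$tss + ENH_OFFSET - 500L,
           end = genes$tss + ENH_OFFSET + ENH_WIDTH + 500L),
    tibble(chrom = "chr1", start = desert - 2000L, end = desert + 16000L)
  )
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    if (samples$group[si] == "case") {
      se_genes <- roles$case_se_genes
      enh_loci <- genes[chain_rows, ]
    } else {
      se_genes <- c(roles$control_se_tfs,
                    sort(sample(pool_genes, cfg$n_se_per_sample - 3L)))
      enh_loci <- genes[integer(), ]
    }
    pk <- list()
    for (g in se_genes) {
      gi <- which(genes$gene == g)
      for (o in CONSTIT_OFFSETS) {
        s0 <- genes$tss[gi] + o + as.integer(round(rnorm(1, 0, cfg$jitter_sd)))
        e0 <- genes$tss[gi] + o + CONSTIT_WIDTH + as.integer(round(rnorm(1, 0, cfg$jitter_sd)))
        h <- rlnorm(1, log(cfg$se_height), 0.3)
        pk[[length(pk) + 1L]] <- tibble(chrom = genes$chrom[gi], start = s0,
                                        end = max(e0, s0 + 200L), height = h)
      }
    }
    for (j in seq_len(nrow(enh_loci))) {
      s0 <- enh_loci$tss[j] + ENH_OFFSET + as.integer(round(rnorm(1, 0, cfg$jitter_sd)))
      e0 <- s0 + ENH_WIDTH + as.integer(round(rnorm(1, 0, cfg$jitter_sd)))
      h <- rlnorm(1, log(cfg$enh_height), 0.25)
      pk[[length(pk) + 1L]] <- tibble(chrom = enh_loci$chrom[j], start = s0,
                                      end = max(e0, s0 + 200L), height = h)
    }
    placed <- tibble(chrom = character(), start = integer(), end = integer())
    tries <- 0L
    while (nrow(placed) < n_private && tries < 2000L) {
      tries <- tries + 1L
      cc <- sample(paste0("chr", 1:2), 1)
      pos <- sample.int(cfg$chrom_length - 2000L, 1)
      fb <- private_forbidden[private_forbidden$chrom == cc, ]
      if (any(pos < fb$end & pos + ENH_WIDTH > fb$start)) next
      pv <- placed[placed$chrom == cc, ]
      # keep private windows a stitch distance apart so each stays its own
      # typical enhancer
      if (nrow(pv) && any(pos < pv$end + 13000L & pos + ENH_WIDTH > pv$start - 13000L)) next
      placed <- bind_rows(placed, tibble(chrom = cc, start = as.integer(pos),
                                         end = as.integer(pos + ENH_WIDTH)))
    }
    if (nrow(placed) < n_private) stop("could not place private enhancers", call. = FALSE)
    for (j in seq_len(nrow(placed))) {
      h <- rlnorm(1, log(cfg$enh_height), 0.25)
      pk[[length(pk) + 1L]] <- tibble(chrom = placed$chrom[j], start = placed$start[j],
                                      end = placed$end[j], height = h)
    }
    pk <- bind_rows(pk)
    pk <- pk[order(pk$chrom, pk$start), ]
    peaks <- region_tbl(pk$chrom, pk$start, pk$end,
                        name = sprintf("%s_peak%04d", sid, seq_len(nrow(pk))),
                        score = round(pk$height, 3),
                        summit = as.integer((pk$end - pk$start) %/% 2L))
    write_regions(peaks, file.path(out_dir, paste0(sid, "_h3k27ac.narrowPeak")),
                  format = "narrowPeak")
    write_signal(tibble(chrom = pk$chrom, start = pk$start, end = pk$end,
                        value = round(pk$height, 4)),
                 file.path(out_dir, paste0(sid, "_h3k27ac.bedGraph")))
    if (samples$group[si] == "case") {
      ms <- keep(gen$msat_records, ~ !is.na(.x$gene) && .x$gene %in% roles$case_se_genes)
      ets <- tibble(
        chrom = map_chr(ms, "chrom"),
        start = map_int(ms, ~ as.integer(.x$start) - 150L),
        end = map_int(ms, ~ as.integer(.x$end) + 150L)
      )
      ets <- merge_intervals(ets)
      ets <- region_tbl(ets$chrom, ets$start, ets$end,
                        name = sprintf("ets_%04d", seq_len(nrow(ets))),
                        score = 100,
                        summit = as.integer((ets$end - ets$start) %/% 2L))
      write_regions(ets, file.path(out_dir, paste0(sid, "_ets.narrowPeak")),
                    format = "narrowPeak")
    }
  }
  invisible(NULL)
}

merge_intervals <- function(x) {
  x <- x[order(x$chrom, x$start), ]
  hits <- overlap_pairs(x, x)
  hits <- hits[hits$query_idx < hits$subject_idx, , drop = FALSE]
  comp <- union_find(nrow(x), hits$query_idx, hits$subject_idx)
  groups <- unname(split(seq_len(nrow(x)), comp))
  out <- tibble(
    chrom = map_chr(groups, ~ x$chrom[.x[1]]),
    start = map_int(groups, ~ min(x$start[.x])),
    end = map_int(groups, ~ max(x$end[.x]))
  )
  out[order(out$chrom, out$start), ]
}

# ---- loops: planted promoter-to-microsatellite chains ----------------------

synth_loops <- function(cfg, roles, gen, samples, out_dir) {
  genes <- roles$genes
  # the first planted microsatellite of a locus (the forced one)
  locus_msat <- function(g) {
    ms <- keep(gen$msat_records, ~ !is.na(.x$gene) && .x$gene == g)[[1]]
    tibble(chrom = ms$chrom, start = as.integer(ms$start) - 200L,
           end = as.integer(ms$end) + 200L)
  }
  prom_anchor <- function(g) {
    gi <- which(genes$gene == g)
    tibble(chrom = genes$chrom[gi], start = genes$tss[gi] - 400L,
           end = genes$tss[gi] + 400L)
  }
  enh_anchor <- function(chrom, j) {
    g <- genes[genes$chrom == chrom & genes$locus == j, ][1, ]
    tibble(chrom = chrom, start = g$tss + ENH_OFFSET, end = g$tss + ENH_OFFSET + ENH_WIDTH)
  }
  # intermediate enhancer loci reserved per chain (disjoint within a chrom)
  intermediates <- list(
    TF01 = list(), TF02 = list(enh_anchor("chr2", 5L)),
    TF03 = list(enh_anchor("chr1", 5L), enh_anchor("chr1", 6L)),
    TF04 = list(enh_anchor("chr2", 7L), enh_anchor("chr2", 8L),
                enh_anchor("chr2", 9L), enh_anchor("chr2", 10L)),
    TF05 = list(enh_anchor("chr1", 8L), enh_anchor("chr1", 9L),
                enh_anchor("chr1", 10L), enh_anchor("chr1", 11L),
                enh_anchor("chr1", 12L))
  )
  targets <- list(TF01 = "TF01", TF02 = "TF02", TF03 = "TF03", TF04 = "TF04",
                  TF05 = genes$gene[13])  # TF05's chain ends at a case SE locus
  loops <- list()
  for (tf in names(cfg$loop_hops)) {
    chain <- c(list(prom_anchor(tf)), intermediates[[tf]],
               list(locus_msat(targets[[tf]])))
    stopifnot(length(chain) == cfg$loop_hops[[tf]] + 1L)
    for (k in seq_len(length(chain) - 1L)) {
      a <- chain[[k]]; b <- chain[[k + 1L]]
      loops[[length(loops) + 1L]] <- tibble(
        chrom_a = a$chrom, start_a = a$start, end_a = a$end,
        chrom_b = b$chrom, start_b = b$start, end_b = b$end,
        name = sprintf("%s_hop%d", tf, k), count = 10)
    }
  }
  # decoy loops between unannotated ("other") anchors in the gene desert
  desert <- max(genes$tss) + 50000L
  for (d in 0:2) {
    loops[[length(loops) + 1L]] <- tibble(
      chrom_a = "chr1", start_a = desert + d * 5000L, end_a = desert + d * 5000L + 800L,
      chrom_b = "chr1", start_b = desert + d * 5000L + 2000L,
      end_b = desert + d * 5000L + 2800L,
      name = sprintf("decoy%d", d), count = 3)
  }
  loop_tbl <- bind_rows(loops)
  for (si in which(samples$group == "case")) {
    write_bedpe(loop_tbl, file.path(out_dir,
                                    paste0(samples$sample_id[si], "_loops.bedpe")))
  }
  invisible(loop_tbl)
}

# ---- expression matrix and dependency table --------------------------------

synth_expression_dependency <- function(cfg, roles, samples, out_dir) {
  genes <- roles$genes
  is_case <- samples$group == "case"
  design <- list(high_case = 8, high = 7, base = 5, low = 0.2)
  mu <- matrix(design$base, cfg$n_genes, nrow(samples),
               dimnames = list(genes$gene, samples$sample_id))
  crc_plus <- c(roles$crc_tfs, roles$driver)
  mu[crc_plus, is_case] <- design$high_case
  mu[crc_plus, !is_case] <- design$low
  case_other <- setdiff(roles$case_se_genes, crc_plus)
  mu[case_other, is_case] <- design$high
  ctrl_genes <- roles$control_se_pool
  mu[ctrl_genes, !is_case] <- design$high
  mu[ctrl_genes, is_case] <- design$low
  expr <- mu + matrix(rnorm(length(mu), 0, cfg$expr_noise_sd), nrow(mu))
  expr <- round(expr, 4)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, file.path(out_dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  dep <- tibble(
    gene = c(roles$driver, roles$crc_tfs, genes$gene[13], genes$gene[14],
             roles$control_se_pool[4], genes$gene[cfg$n_genes - 1L],
             "TF08", roles$control_se_tfs[1]),
    lineage = "case",
    t_statistic = c(-12, -3.2, -3.0, -2.8, -2.1, -1.9, -1.4, -0.9, 1.1, 0.6),
    gene_effect = c(-2.5, -0.7, -0.65, -0.6, -0.5, -0.45, -0.3, -0.2, 0.1, 0.05),
    adj_p = c(1e-12, 1e-4, 2e-4, 5e-4, 0.003, 0.006, 0.02, 0.08, 0.6, 0.8)
  )
  dep <- bind_rows(dep, tibble(gene = c("PHOX2B", "MYOD1"), lineage = "other",
                               t_statistic = c(-8, -7), gene_effect = c(-1.8, -1.6),
                               adj_p = c(1e-9, 1e-8)))
  write.table(dep[, c("gene", "lineage", "gene_effect", "t_statistic", "adj_p")],
              file.path(out_dir, "dependency.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  list(design = design,
       expected_dependency_genes = sort(dep$gene[dep$lineage == "case" &
                                                   dep$t_statistic < 0]))
}

# ---- lightweight microsatellite enrichment simulator -----------------------

#' Simulate a paired super-enhancer vs enhancer microsatellite panel
#'
#' A fast region-level simulator used for power and type-I-error studies of
#' the paired enrichment test: per sample, `n_regions` super-enhancer and
#' `n_regions` typical-enhancer sequences are drawn with GGAA runs planted
#' at the given per-kb Poisson rates, scanned with [find_repeats()], and
#' summarized as per-sample mean densities.
#'
#' @param n_samples Samples (pairs) to simulate.
#' @param n_regions Regions per class per sample (default 20).
#' @param region_len Region length in bp (default 2000).
#' @param se_rate_per_kb,enh_rate_per_kb Planted GGAA run rates (default
#'   1.0 vs 0.1, the 10x enrichment of the main dataset; equal rates give
#'   a null panel).
#' @return Tibble with `sample`, `se_mean`, `enh_mean` (mean runs per kb).
#' @export
simulate_msat_panel <- function(n_samples = 10L, n_regions = 20L,
                                region_len = 2000L, se_rate_per_kb = 1.0,
                                enh_rate_per_kb = 0.1) {
  cls <- ggaa_classes()
  region_mean <- function(rate) {
    counts <- vapply(seq_len(n_regions), function(i) {
      s <- random_dna(region_len)
      n_runs <- rpois(1, rate * region_len / 1000)
      pos <- 10L
      for (r in seq_len(n_runs)) {
        run <- strrep("GGAA", 4L + sample(0:4, 1))
        pos <- pos + sample(20:60, 1)
        if (pos + nchar(run) + 10L > region_len) break
        substr(s, pos + 1L, pos + nchar(run)) <- run
        pos <- pos + nchar(run)
      }
      nrow(find_repeats(s, cls))
    }, integer(1))
    mean(counts * 1000 / region_len)
  }
  tibble(
    sample = sprintf("sim%02d", seq_len(n_samples)),
    se_mean = vapply(seq_len(n_samples), function(i) region_mean(se_rate_per_kb), numeric(1)),
    enh_mean = vapply(seq_len(n_samples), function(i) region_mean(enh_rate_per_kb), numeric(1))
  )
}
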