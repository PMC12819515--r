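#' Default pipeline parameters
#'
#' All numeric constants of the analysis surfaced in one place: ROSE
#' stitching distance (12.5 kb) and optional TSS exclusion (+/- 2.5 kb),
#' the top-500 super-enhancer truncation, the 50\% consensus merge, GGAA
#' run threshold (4 copies), top-10 cliques, the >=50\% case / <30\% control
#' specificity filter, chain depth 5, the 2-of-3 selection rule, and the
#' top-100 colocalization window.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    stitch_distance = 12500,
    tss_exclude = FALSE,
    tss_exclusion_bp = 2500,
    top_n_se = 500,
    consensus_min_overlap = 0.5,
    consensus_mode = "of_smaller",
    ggaa_min_repeats = 4L,
    ggaa_mode = "rotation_rc",
    crc_top_k = 10,
    activity_threshold = 1,
    score_fraction = 0.85,
    case_min = 0.5,
    control_max = 0.3,
    promoter_window = 2500,
    chain_max_depth = 5,
    min_criteria = 2,
    coloc_top_n = 100,
    dependency_lineage = "case",
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  p[names(over)] <- over
  p
}

#' Run the integrative super-enhancer / circuitry analysis end to end
#'
#' Orchestrates every stage on a dataset directory (as produced by
#' [simulate_dataset()], or assembled from real data in the same layout):
#' per-sample super-enhancer calling and normalization, the cross-sample
#' consensus matrix with PCA, microsatellite density statistics with the
#' paired enrichment test, per-sample circuitry inference with the
#' cross-entity specificity filter, promoter-enhancer chain traversal,
#' dependency integration and the 2-of-3 master-TF selection. Stage
#' outputs are written as TSV/JSON under `out_dir` and returned invisibly
#' as a list.
#'
#' The dataset directory must contain `sample_sheet.tsv` (columns
#' `sample_id`, `group`, `peaks`, `signal`, optional `control_signal`,
#' `ets_peaks`, `loops`; paths relative to the directory), `genome.fa`,
#' `annotation.tsv`, `motifs.jaspar`, `expression.tsv`, `dependency.csv`.
#'
#' @param dataset_dir Dataset directory.
#' @param out_dir Output directory for stage outputs.
#' @param params Parameter list from [pipeline_params()].
#' @return Invisibly, a list with elements `profiles`, `consensus`, `pca`,
#'   `msat`, `crc`, `chains`, `selection`, `dependency`, `params`.
#' @export
run_pipeline <- function(dataset_dir, out_dir = file.path(dataset_dir, "results"),
                         params = pipeline_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message("[secircuitry] ", ...)

  sheet <- read.table(file.path(dataset_dir, "sample_sheet.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE, na.strings = c("", "NA"))
  stopifnot(all(c("sample_id", "group", "peaks", "signal") %in% names(sheet)))
  case_ids <- sheet$sample_id[sheet$group == "case"]
  control_ids <- sheet$sample_id[sheet$group == "control"]
  genome <- read_genome(file.path(dataset_dir, "genome.fa"))
  genes <- read_gene_models(file.path(dataset_dir, "annotation.tsv"))
  motif_file <- read_jaspar(file.path(dataset_dir, "motifs.jaspar"))
  expr <- read_expression(file.path(dataset_dir, "expression.tsv"))
  dep <- read_dependency(file.path(dataset_dir, "dependency.csv"))
  # group motif matrices by the TF they belong to
  motifs_by_tf <- split(motif_file, map_chr(motif_file, "tf_name"))
  ggaa <- ggaa_classes(mode = if (params$ggaa_mode == "literal") "literal" else "rotation_rc",
                       min_repeats = params$ggaa_min_repeats)

  tss_excl <- NULL
  if (isTRUE(params$tss_exclude)) {
    tss_excl <- region_tbl(genes$chrom, pmax(0L, genes$tss - params$tss_exclusion_bp),
                           genes$tss + params$tss_exclusion_bp + 1L)
  }

  # ---- stage 1: per-sample super-enhancer calling --------------------------
  msg("calling super-enhancers for ", nrow(sheet), " samples")
  profiles <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    peaks <- read_regions(file.path(dataset_dir, sheet$peaks[i]),
                          format = "narrowPeak", sample_id = sid)
    treatment <- read_signal(file.path(dataset_dir, sheet$signal[i]))
    control <- NULL
    if ("control_signal" %in% names(sheet) && !is.na(sheet$control_signal[i])) {
      control <- read_signal(file.path(dataset_dir, sheet$control_signal[i]))
    }
    stitched <- stitch_peaks(peaks, params$stitch_distance, tss_excl)
    scored <- score_regions(stitched, treatment, control)
    prof <- call_superenhancers(scored, sample_id = sid)
    profiles[[sid]] <- normalize_profile(prof, top_n = params$top_n_se)
    se_out <- profiles[[sid]]$regions
    write.table(
      data.frame(chrom = se_out$chrom, start = se_out$start, end = se_out$end,
                 n_constituents = se_out$n_constituents, rank = se_out$rank,
                 net_signal = se_out$net_signal,
                 normalized_intensity = se_out$normalized_intensity,
                 is_super = as.integer(se_out$is_super)),
      file.path(out_dir, paste0(sid, "_se_calls.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- stage 2: consensus matrix + PCA + rank curves -----------------------
  msg("building consensus matrix")
  consensus <- build_consensus(profiles, min_overlap = params$consensus_min_overlap,
                               mode = params$consensus_mode)
  cm <- data.frame(consensus$regions, consensus$values, check.names = FALSE)
  write.table(cm, file.path(out_dir, "consensus_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pca <- pca_profiles(consensus, n_components = 2)
  write.table(as.data.frame(pca$scores), file.path(out_dir, "pca_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  curves <- list(case = se_rank_curve(consensus, case_ids),
                 control = se_rank_curve(consensus, control_ids))
  write.table(as.data.frame(curves$case), file.path(out_dir, "se_rank_curve_case.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- stage 3: microsatellite statistics ----------------------------------
  msg("scanning microsatellites")
  se_regions_of <- function(p) {
    r <- p$regions[p$regions$is_super, c("chrom", "start", "end")]
    sort_regions(r)
  }
  enh_regions_of <- function(p) {
    r <- p$regions[!p$regions$is_super, c("chrom", "start", "end")]
    sort_regions(r)
  }
  msat_stats <- bind_rows(lapply(names(profiles), function(sid) {
    se <- count_msats_in_regions(se_regions_of(profiles[[sid]]), genome, ggaa)
    enh <- count_msats_in_regions(enh_regions_of(profiles[[sid]]), genome, ggaa)
    tibble(sample_id = sid,
           group = sheet$group[match(sid, sheet$sample_id)],
           se_mean = mean(se$msat_per_kb),
           enh_mean = mean(enh$msat_per_kb),
           se_with_msat = sum(se$msat_count > 0), n_se = nrow(se),
           enh_with_msat = sum(enh$msat_count > 0), n_enh = nrow(enh))
  }))
  write.table(as.data.frame(msat_stats), file.path(out_dir, "msat_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- list(
    case = with(msat_stats[msat_stats$group == "case", ],
                paired_enrichment_test(se_mean, enh_mean)),
    control = with(msat_stats[msat_stats$group == "control", ],
                   paired_enrichment_test(se_mean, enh_mean))
  )
  frac <- list(
    se_pct = with(msat_stats[msat_stats$group == "case", ],
                  100 * sum(se_with_msat) / sum(n_se)),
    enhancer_pct = with(msat_stats[msat_stats$group == "case", ],
                        100 * sum(enh_with_msat) / sum(n_enh))
  )
  jsonlite::write_json(list(enrichment = enr, fraction_with_msat = frac),
                       file.path(out_dir, "enrichment_test.json"),
                       auto_unbox = TRUE, digits = NA)

  # ---- stage 4: fusion-TF microsatellite peaks -----------------------------
  ets_msat <- list()
  for (i in which(!is.na(sheet$ets_peaks %||% rep(NA, nrow(sheet))))) {
    sid <- sheet$sample_id[i]
    ets <- read_regions(file.path(dataset_dir, sheet$ets_peaks[i]),
                        format = "narrowPeak", sample_id = sid)
    flags <- flag_msat_peaks(ets, genome, mode = params$ggaa_mode,
                             min_repeats = params$ggaa_min_repeats)
    ets_msat[[sid]] <- ets[flags, , drop = FALSE]
  }

  # ---- stage 5: circuitry inference + specificity --------------------------
  msg("inferring regulatory circuitry")
  assignments <- list()
  cliques <- list()
  for (sid in names(profiles)) {
    act <- active_genes(expr, sid, params$activity_threshold)
    ses <- profiles[[sid]]$regions[profiles[[sid]]$regions$is_super, , drop = FALSE]
    asg <- assign_se_to_gene(ses, genes[genes$gene %in% act, ])
    assignments[[sid]] <- asg
    tf_rows <- which(!is.na(asg$assigned_gene) &
                       asg$assigned_gene %in% genes$gene[genes$is_tf])
    tf_seqs <- list()
    for (r in tf_rows) {
      tf <- asg$assigned_gene[r]
      seqs <- region_sequences(asg$constituents[[r]], genome)
      tf_seqs[[tf]] <- c(tf_seqs[[tf]], seqs)
    }
    net <- build_tf_network(tf_seqs, motifs_by_tf, params$score_fraction)
    cliques[[sid]] <- find_crc_cliques(net, top_k = params$crc_top_k)
  }
  membership <- crc_membership(cliques)
  write.table(data.frame(tf = rownames(membership), membership + 0L,
                         check.names = FALSE),
              file.path(out_dir, "crc_membership.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  spec_res <- specificity_filter(membership, case_ids, control_ids,
                                 case_min = params$case_min,
                                 control_max = params$control_max)
  write.table(as.data.frame(spec_res), file.path(out_dir, "specificity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  candidates <- spec_res$tf[spec_res$is_candidate]

  # ---- stage 6: promoter-enhancer chains -----------------------------------
  msg("traversing promoter-enhancer chains")
  anchor_graphs <- list()
  has_loops <- "loops" %in% names(sheet)
  for (i in which(!is.na(sheet$loops %||% rep(NA, nrow(sheet))))) {
    sid <- sheet$sample_id[i]
    loops <- read_bedpe(file.path(dataset_dir, sheet$loops[i]))
    peaks <- profiles[[sid]]$regions[, c("chrom", "start", "end")]
    anchor_graphs[[sid]] <- build_anchor_graph(
      loops, genes, h3k27ac_peaks = peaks,
      ets_msat_peaks = ets_msat[[sid]] %||% region_tbl(character(), integer(), integer()),
      promoter_window = params$promoter_window)
  }
  all_tfs <- genes$gene[genes$is_tf]
  chains <- if (length(anchor_graphs)) {
    chain_table(anchor_graphs, all_tfs, max_depth = params$chain_max_depth)
  } else tibble(tf = all_tfs)
  write.table(as.data.frame(chains), file.path(out_dir, "chain_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- stage 7: dependency integration + selection -------------------------
  msg("integrating dependencies and selecting master TFs")
  dep_genes <- dependency_filter(dep, params$dependency_lineage)
  se_genes_by_sample <- lapply(assignments[case_ids], function(a) {
    a$assigned_gene[!is.na(a$assigned_gene)]
  })
  overlap <- se_dependency_overlap(dep_genes, se_genes_by_sample)
  # per-TF criterion flags, evaluated over case samples
  msat_counts_for <- function(tf) {
    vapply(case_ids, function(sid) {
      a <- assignments[[sid]]
      r <- which(a$assigned_gene == tf)
      if (length(r) == 0L) return(NA_real_)
      se_span <- a[r, c("chrom", "start", "end")]
      ets <- ets_msat[[sid]]
      if (is.null(ets) || nrow(ets) == 0L) return(0)
      sum(count_overlaps(se_span, ets))
    }, numeric(1))
  }
  criteria_tfs <- if (length(candidates)) candidates else character()
  flags <- bind_rows(lapply(criteria_tfs, function(tf) {
    tibble(
      tf = tf,
      msat_in_se = suppressMessages(msat_in_se_criterion(msat_counts_for(tf))),
      specific_expression = tf %in% rownames(expr) &&
        expression_specificity(expr, tf, case_ids, control_ids),
      depmap_dependency = tf %in% dep_genes
    )
  }))
  selection <- if (nrow(flags)) select_mtfs(flags, min_criteria = params$min_criteria)
               else tibble(tf = character(), selected = logical())
  write.table(as.data.frame(selection), file.path(out_dir, "criteria.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dep_case <- dep[dep$lineage == params$dependency_lineage, ]
  top_dep <- dep_case$gene[order(dep_case$t_statistic)][1]
  selection_report <- list(
    candidates = candidates,
    selected_mtfs = selection$tf[selection$selected],
    top_dependency = top_dep,
    top_dependency_in_crc = top_dep %in% rownames(membership) &&
      any(membership[top_dep, case_ids])
  )
  jsonlite::write_json(
    c(selection_report,
      list(dependency_overlap = overlap[c("n_dependency_genes", "n_se_associated",
                                          "fraction")])),
    file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)

  run_manifest <- list(package_version = as.character(utils::packageVersion("secircuitry")),
                       r_version = as.character(getRversion()),
                       params = params, n_samples = nrow(sheet))
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    profiles = profiles, consensus = consensus, pca = pca, curves = curves,
    msat = list(stats = msat_stats, enrichment = enr, fraction = frac),
    crc = list(cliques = cliques, membership = membership,
               specificity = spec_res, candidates = candidates),
    chains = chains, assignments = assignments,
    selection = c(selection_report, list(table = selection, overlap = overlap)),
    dependency = list(genes = dep_genes, table = dep),
    params = params
  ))
}
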