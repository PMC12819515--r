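#' Read a CRISPR dependency table
#'
#' Comma-separated with header columns `gene`, `lineage`, `gene_effect`,
#' `t_statistic`, `adj_p` (DepMap-style lineage-enrichment export: gene
#' effect is the Chronos fitness score, the T-statistic compares the
#' lineage against all other models).
#'
#' @param path CSV file.
#' @return Tibble with the five columns above.
#' @export
read_dependency <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("gene", "lineage", "gene_effect", "t_statistic", "adj_p")
  if (!all(need %in% names(df))) {
    stop(path, ": dependency table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$adj_p < 0 | df$adj_p > 1, na.rm = TRUE)) {
    stop(path, ": adj_p outside [0, 1]", call. = FALSE)
  }
  as_tibble(df[, need])
}

#' Lineage dependency genes (negative T-statistic)
#'
#' Genes whose knockout effect is stronger in the lineage of interest than
#' in other models: negative T-statistic, deduplicated, sorted.
#'
#' @param dep Dependency tibble from [read_dependency()].
#' @param lineage Lineage label to filter on.
#' @return Sorted character vector of gene symbols.
#' @export
dependency_filter <- function(dep, lineage) {
  if (nrow(dep) == 0L) return(character())
  if (!lineage %in% dep$lineage) stop("unknown lineage: ", lineage, call. = FALSE)
  sort(unique(dep$gene[dep$lineage == lineage & dep$t_statistic < 0]))
}

#' Overlap between dependency genes and super-enhancer-associated genes
#'
#' A dependency gene counts as SE-associated when it is the assigned gene
#' of at least one super-enhancer in at least one sample.
#'
#' @param dep_genes Character vector of dependency genes (non-empty).
#' @param se_assigned_genes Character vector (or list of per-sample
#'   vectors) of SE-assigned genes.
#' @return List with `n_dependency_genes`, `n_se_associated`, `fraction`,
#'   `genes` (the intersecting symbols).
#' @export
se_dependency_overlap <- function(dep_genes, se_assigned_genes) {
  if (length(dep_genes) == 0L) stop("empty dependency gene list", call. = FALSE)
  se_genes <- unique(unlist(se_assigned_genes))
  inter <- sort(intersect(dep_genes, se_genes))
  list(
    n_dependency_genes = length(unique(dep_genes)),
    n_se_associated = length(inter),
    fraction = length(inter) / length(unique(dep_genes)),
    genes = inter
  )
}

#' Case-specific expression criterion
#'
#' TRUE when the median case expression is at least the 95th percentile of
#' the control expression plus `margin` — a conservative operationalization
#' of "expression specific to the entity across datasets".
#'
#' @param expr Expression matrix (genes x samples).
#' @param gene Gene symbol (must be a row).
#' @param case_ids,control_ids Non-empty sample vectors.
#' @param margin Additional log2 margin required (default 0).
#' @return Logical scalar.
#' @export
expression_specificity <- function(expr, gene, case_ids, control_ids, margin = 0) {
  if (!gene %in% rownames(expr)) stop("gene absent from expression matrix: ",
                                      gene, call. = FALSE)
  if (length(case_ids) == 0L || length(control_ids) == 0L) {
    stop("case and control groups must be non-empty", call. = FALSE)
  }
  case_med <- median(expr[gene, case_ids])
  ctrl_q95 <- quantile(expr[gene, control_ids], 0.95, names = FALSE)
  case_med >= ctrl_q95 + margin
}

#' Microsatellite-in-super-enhancer criterion
#'
#' Given per-sample counts of flagged fusion-TF microsatellite peaks inside
#' the TF's associated super-enhancer (`NA` where the TF has no SE in a
#' sample), the criterion is met when at least one peak is present in at
#' least half of the evaluable samples. With no evaluable sample the
#' criterion is FALSE.
#'
#' @param counts Numeric vector of per-sample peak counts; `NA` allowed.
#' @return Logical scalar.
#' @export
msat_in_se_criterion <- function(counts) {
  ev <- counts[!is.na(counts)]
  if (length(ev) == 0L) {
    message("no sample with an associated super-enhancer; criterion FALSE")
    return(FALSE)
  }
  mean(ev >= 1) >= 0.5
}

#' Select master transcription factors by multi-evidence integration
#'
#' A candidate is selected when it fulfils at least `min_criteria` of the
#' three criteria: a fusion-TF microsatellite peak in its super-enhancer,
#' case-specific expression, and a CRISPR dependency. Output order is
#' deterministic: selected TFs first, then alphabetical.
#'
#' @param flags Tibble with columns `tf`, `msat_in_se`,
#'   `specific_expression`, `depmap_dependency` (all logical, no missing).
#' @param min_criteria Minimum criteria met (default 2).
#' @return Tibble with `tf`, the three flags, `n_criteria`, `selected`.
#' @export
select_mtfs <- function(flags, min_criteria = 2) {
  need <- c("tf", "msat_in_se", "specific_expression", "depmap_dependency")
  if (!all(need %in% names(flags))) {
    stop("flags needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  fl <- flags[, need]
  if (any(is.na(fl$msat_in_se) | is.na(fl$specific_expression) |
            is.na(fl$depmap_dependency))) {
    stop("criterion flags must not be missing", call. = FALSE)
  }
  fl$n_criteria <- fl$msat_in_se + fl$specific_expression + fl$depmap_dependency
  fl$selected <- fl$n_criteria >= min_criteria
  fl[order(!fl$selected, fl$tf), , drop = FALSE]
}

#' Transcription-factor colocalization in the top super-enhancers
#'
#' For each of the `top_n` highest-intensity super-enhancers, counts how
#' many of the supplied TF peak sets have at least one peak overlapping it,
#' and summarizes the distribution of co-bound TF numbers.
#'
#' @param ses Region tibble of super-enhancers with an intensity column
#'   (`net_signal` or `mean_intensity`).
#' @param tf_peak_sets Named list of region tibbles, one per TF.
#' @param top_n Number of top super-enhancers considered (default 100).
#' @return List with `histogram` (named counts over 0..n_tfs co-bound
#'   TFs), `fraction_all` (share of top SEs bound by every TF), and
#'   `per_se` (tibble of SEs with `n_cobound`).
#' @export
colocalization_top_se <- function(ses, tf_peak_sets, top_n = 100) {
  stopifnot(length(tf_peak_sets) >= 1L)
  int_col <- intersect(c("net_signal", "mean_intensity"), names(ses))[1]
  if (is.na(int_col)) stop("ses needs a net_signal or mean_intensity column",
                           call. = FALSE)
  if (top_n > nrow(ses)) stop("top_n exceeds the number of super-enhancers",
                              call. = FALSE)
  top <- ses[order(-ses[[int_col]]), , drop = FALSE]
  top <- top[seq_len(top_n), , drop = FALSE]
  bound <- vapply(tf_peak_sets, function(pk) count_overlaps(top, pk) > 0L,
                  logical(top_n))
  if (top_n == 1L) bound <- matrix(bound, nrow = 1L)
  n_cobound <- rowSums(bound)
  hist <- table(factor(n_cobound, levels = 0:length(tf_peak_sets)))
  top$n_cobound <- as.integer(n_cobound)
  list(
    histogram = setNames(as.integer(hist), names(hist)),
    fraction_all = mean(n_cobound == length(tf_peak_sets)),
    per_se = top
  )
}
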