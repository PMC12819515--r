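#' Build the promoter/enhancer anchor graph from chromatin loops
#'
#' Loop ends (HiChIP anchors) that overlap by at least 1 bp are merged into
#' anchors (single linkage; the anchor is the union span). Each anchor is
#' labelled `promoter` when it overlaps a window of +/- `promoter_window`
#' around any TSS (and records those genes), else `enhancer` when it
#' overlaps an H3K27ac peak, else `other`. An anchor is `msat_bound` when
#' it overlaps a fusion-TF peak flagged as a microsatellite peak
#' ([flag_msat_peaks()]).
#'
#' @param loops Loop tibble from [read_bedpe()].
#' @param genes Gene-model tibble ([read_gene_models()]).
#' @param h3k27ac_peaks Region tibble of H3K27ac peaks.
#' @param ets_msat_peaks Region tibble of fusion-TF peaks already flagged
#'   as microsatellite-bound.
#' @param promoter_window Half-width of the promoter window in bp
#'   (default 2500).
#' @param min_count Minimum loop support; loops below it are dropped
#'   (default 1, i.e. all loops kept).
#' @return List with `anchors` (tibble: `anchor_id`, `chrom`, `start`,
#'   `end`, `label`, `genes` list-column, `msat_bound`) and `graph`
#'   (undirected `igraph`, vertices named by `anchor_id`, edge attribute
#'   `support`).
#' @export
build_anchor_graph <- function(loops, genes, h3k27ac_peaks, ets_msat_peaks,
                               promoter_window = 2500, min_count = 1) {
  loops <- loops[loops$count >= min_count, , drop = FALSE]
  ends <- bind_rows(
    tibble(chrom = loops$chrom_a, start = loops$start_a, end = loops$end_a),
    tibble(chrom = loops$chrom_b, start = loops$start_b, end = loops$end_b)
  )
  n_loops <- nrow(loops)
  if (n_loops == 0L) {
    anchors <- tibble(anchor_id = integer(), chrom = character(),
                      start = integer(), end = integer(), label = character(),
                      genes = list(), msat_bound = logical())
    return(list(anchors = anchors,
                graph = igraph::make_empty_graph(0, directed = FALSE)))
  }
  hits <- overlap_pairs(ends, ends)
  hits <- hits[hits$query_idx < hits$subject_idx, , drop = FALSE]
  comp <- union_find(nrow(ends), hits$query_idx, hits$subject_idx)
  groups <- unname(split(seq_len(nrow(ends)), comp))
  anchors <- tibble(
    chrom = map_chr(groups, ~ ends$chrom[.x[1]]),
    start = map_int(groups, ~ min(ends$start[.x])),
    end = map_int(groups, ~ max(ends$end[.x]))
  )
  ord <- order(anchors$chrom, anchors$start, anchors$end)
  anchors <- anchors[ord, ]
  anchors$anchor_id <- seq_len(nrow(anchors))
  # map every loop end to its merged anchor
  end_anchor <- integer(nrow(ends))
  for (gi in seq_along(groups)) end_anchor[groups[[gi]]] <- gi
  end_anchor <- match(end_anchor, ord)  # reindex after sorting
  # annotate anchors
  prom_windows <- tibble(chrom = genes$chrom,
                         start = pmax(0L, genes$tss - as.integer(promoter_window)),
                         end = genes$tss + as.integer(promoter_window) + 1L)
  ph <- overlap_pairs(anchors, prom_windows)
  gene_lists <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) gene_lists[[i]] <- character()
  if (nrow(ph) > 0L) {
    for (k in seq_len(nrow(ph))) {
      gene_lists[[ph$query_idx[k]]] <-
        sort(unique(c(gene_lists[[ph$query_idx[k]]], genes$gene[ph$subject_idx[k]])))
    }
  }
  anchors$genes <- gene_lists
  is_prom <- lengths(gene_lists) > 0L
  is_enh <- count_overlaps(anchors, h3k27ac_peaks) > 0L
  anchors$label <- ifelse(is_prom, "promoter", ifelse(is_enh, "enhancer", "other"))
  anchors$msat_bound <- count_overlaps(anchors, ets_msat_peaks) > 0L
  anchors <- anchors[, c("anchor_id", "chrom", "start", "end", "label",
                         "genes", "msat_bound")]
  # edges: one per loop between the two merged anchors; support summed
  e_from <- end_anchor[seq_len(n_loops)]
  e_to <- end_anchor[n_loops + seq_len(n_loops)]
  el <- tibble(from = pmin(e_from, e_to), to = pmax(e_from, e_to),
               support = loops$count)
  el <- el[el$from != el$to, , drop = FALSE]  # self-loop = anchors merged
  el <- summarise(group_by(el, .data$from, .data$to),
                  support = sum(.data$support), .groups = "drop")
  g <- igraph::make_empty_graph(nrow(anchors), directed = FALSE)
  igraph::V(g)$name <- as.character(anchors$anchor_id)
  if (nrow(el) > 0L) {
    g <- igraph::add_edges(g, rbind(as.character(el$from), as.character(el$to)),
                           support = el$support)
  }
  list(anchors = anchors, graph = g)
}

#' Search promoter-enhancer chains from a TF promoter
#'
#' Breadth-first traversal from the TF's promoter anchor through
#' promoter/enhancer anchors only (anchors labelled `other` are not
#' traversable). Reports the smallest hop index (1-based, counted in
#' interactions) of a microsatellite-bound fusion-TF anchor within
#' `max_depth` hops, plus one shortest witness path; ties between
#' equally-near anchors are broken toward the smaller genomic coordinate.
#' The starting promoter anchor itself (hop 0) is not counted.
#'
#' @param anchor_graph Output of [build_anchor_graph()].
#' @param tf Gene symbol; must have a promoter anchor.
#' @param max_depth Maximum hops considered (default 5, "within the first
#'   five interactions").
#' @return List with `tf`, `first_msat_hop` (`NA` when none within
#'   `max_depth`) and `path` (anchor tibble from promoter to the hit,
#'   or `NULL`).
#' @export
chain_search <- function(anchor_graph, tf, max_depth = 5) {
  anchors <- anchor_graph$anchors
  g <- anchor_graph$graph
  prom_idx <- which(map_lgl(anchors$genes, ~ tf %in% .x))
  if (length(prom_idx) == 0L) {
    stop("no promoter anchor for TF ", tf, call. = FALSE)
  }
  start_idx <- prom_idx[order(anchors$chrom[prom_idx], anchors$start[prom_idx])][1]
  traversable <- anchors$label %in% c("promoter", "enhancer")
  # BFS with deterministic neighbor order (genomic coordinate)
  depth <- rep(NA_integer_, nrow(anchors))
  parent <- rep(NA_integer_, nrow(anchors))
  depth[start_idx] <- 0L
  frontier <- start_idx
  found <- NA_integer_
  adj <- igraph::as_adj_list(g, mode = "all")
  d <- 0L
  while (length(frontier) > 0L && d < max_depth && is.na(found)) {
    d <- d + 1L
    nxt <- integer()
    for (v in frontier) {
      nb <- as.integer(igraph::V(g)$name[adj[[v]]])
      nb <- nb[order(anchors$chrom[nb], anchors$start[nb])]
      for (u in nb) {
        if (!is.na(depth[u]) || !traversable[u]) next
        depth[u] <- d
        parent[u] <- v
        nxt <- c(nxt, u)
      }
    }
    cand <- nxt[anchors$msat_bound[nxt]]
    if (length(cand) > 0L) {
      found <- cand[order(anchors$chrom[cand], anchors$start[cand])][1]
    }
    frontier <- nxt
  }
  if (is.na(found)) {
    return(list(tf = tf, first_msat_hop = NA_integer_, path = NULL))
  }
  path_idx <- found
  while (!is.na(parent[path_idx[1]])) path_idx <- c(parent[path_idx[1]], path_idx)
  list(tf = tf, first_msat_hop = depth[found],
       path = anchors[path_idx, , drop = FALSE])
}

#' First-microsatellite-hop table across samples
#'
#' For each TF and each sample's anchor graph, the hop index of the first
#' microsatellite-bound anchor reachable from the TF promoter (`NA` when
#' none within `max_depth`, or when the TF has no promoter anchor in that
#' sample).
#'
#' @param anchor_graphs Named list: sample -> output of
#'   [build_anchor_graph()].
#' @param tfs TF symbols (rows of the output).
#' @param max_depth Maximum hops (default 5).
#' @return Tibble with `tf` and one integer column per sample.
#' @export
chain_table <- function(anchor_graphs, tfs, max_depth = 5) {
  out <- tibble(tf = tfs)
  for (s in names(anchor_graphs)) {
    out[[s]] <- map_int(tfs, function(tf) {
      res <- tryCatch(chain_search(anchor_graphs[[s]], tf, max_depth),
                      error = function(e) list(first_msat_hop = NA_integer_))
      res$first_msat_hop
    })
  }
  out
}
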