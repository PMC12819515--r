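#' Read an expression matrix
#'
#' Tab-separated file with gene identifiers in the first column and one
#' column per sample; values are log2-transformed abundances. Duplicate
#' gene identifiers are rejected.
#'
#' @param path TSV file.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stop(path, ": duplicate gene identifiers", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a gene/TSS annotation table
#'
#' Tab-separated with columns `gene`, `chrom`, `tss` (0-based position) and
#' `is_tf` (0/1 or TRUE/FALSE), e.g. derived from a GTF plus a
#' transcription-factor list.
#'
#' @param path TSV file with a header.
#' @return Tibble with `gene`, `chrom`, `tss`, `is_tf`.
#' @export
read_gene_models <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "is_tf")
  if (!all(need %in% names(df))) {
    stop(path, ": annotation needs columns gene, chrom, tss, is_tf", call. = FALSE)
  }
  if (anyDuplicated(df$gene)) stop(path, ": duplicate gene symbols", call. = FALSE)
  tibble(gene = df$gene, chrom = as.character(df$chrom),
         tss = as.integer(df$tss), is_tf = as.logical(df$is_tf))
}

#' Genes active in a sample
#'
#' A gene is considered active when its (log2) expression in the sample is
#' at least `threshold`. Used to restrict super-enhancer-to-gene assignment
#' to expressed genes.
#'
#' @param expr Expression matrix (genes x samples).
#' @param sample Sample (column) name.
#' @param threshold Activity threshold on the log2 scale (default 1).
#' @return Character vector of active gene symbols.
#' @export
active_genes <- function(expr, sample, threshold = 1) {
  if (!sample %in% colnames(expr)) stop("unknown sample: ", sample, call. = FALSE)
  rownames(expr)[expr[, sample] >= threshold]
}

#' Assign super-enhancers to their closest active gene
#'
#' Each super-enhancer is annotated with the active gene whose TSS is
#' nearest to the SE interval (distance 0 when the TSS falls inside it).
#' Ties are broken by the smaller TSS coordinate, then alphabetically.
#' Super-enhancers on chromosomes without any active gene are left
#' unassigned (`NA`).
#'
#' @param ses Region tibble of super-enhancers.
#' @param genes Gene-model tibble ([read_gene_models()]) restricted to
#'   active genes.
#' @return `ses` with added `assigned_gene` and `tss_distance` columns.
#' @export
assign_se_to_gene <- function(ses, genes) {
  ses$assigned_gene <- NA_character_
  ses$tss_distance <- NA_integer_
  if (nrow(ses) == 0L || nrow(genes) == 0L) return(ses)
  for (i in seq_len(nrow(ses))) {
    g <- genes[genes$chrom == ses$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    d <- tss_distance(ses$start[i], ses$end[i], g$tss)
    best <- order(d, g$tss, g$gene)[1]
    ses$assigned_gene[i] <- g$gene[best]
    ses$tss_distance[i] <- d[best]
  }
  ses
}

# distance from a half-open interval to TSS points: 0 if inside
tss_distance <- function(start, end, tss) {
  ifelse(tss >= start & tss < end, 0L,
         ifelse(tss < start, start - tss, tss - (end - 1L)))
}

#' Scan a sequence with a position weight matrix
#'
#' Counts are converted to pseudocounted frequencies
#' `(counts + pseudocount * background) / (column_sum + pseudocount)` and
#' scored as log2 odds against the background. Both strands are scanned;
#' positions scoring at least `score_fraction` of the maximum attainable
#' score are reported. Positions covering a non-ACGT base never match.
#'
#' @param sequence Uppercase DNA string.
#' @param motif Motif list (see [read_jaspar()]).
#' @param score_fraction Fraction of the maximal log-odds score required
#'   for a hit (default 0.85).
#' @return Tibble with `start` (1-based position on the forward strand),
#'   `strand`, `score`.
#' @export
pwm_scan <- function(sequence, motif, score_fraction = 0.85) {
  stopifnot(score_fraction > 0, score_fraction <= 1)
  pwm <- motif_log_odds(motif)
  w <- ncol(pwm)
  L <- nchar(sequence)
  empty <- tibble(start = integer(), strand = character(), score = numeric())
  if (L < w) return(empty)
  max_score <- sum(apply(pwm, 2, max))
  thr <- score_fraction * max_score
  fwd <- scan_one_strand(sequence, pwm)
  rev <- scan_one_strand(revcomp(sequence), pwm)
  hits_f <- which(!is.na(fwd) & fwd >= thr)
  hits_r <- which(!is.na(rev) & rev >= thr)
  out <- tibble(
    start = c(hits_f, L - w + 2L - hits_r),
    strand = c(rep("+", length(hits_f)), rep("-", length(hits_r))),
    score = c(fwd[hits_f], rev[hits_r])
  )
  arrange(out, .data$start, .data$strand)
}

motif_log_odds <- function(motif) {
  counts <- motif$counts
  bg <- motif$background
  cs <- colSums(counts) + motif$pseudocount
  # counts is 4 x L (column-major), so the length-4 background recycles
  # down each column and cs is expanded to match
  freq <- (counts + motif$pseudocount * bg) / rep(cs, each = 4L)
  log2(freq / bg)
}

scan_one_strand <- function(sequence, pwm) {
  w <- ncol(pwm)
  L <- nchar(sequence)
  codes <- match(strsplit(sequence, "")[[1]], c("A", "C", "G", "T"))
  n <- L - w + 1L
  score <- numeric(n)
  for (j in seq_len(w)) {
    score <- score + pwm[cbind(codes[j:(j + n - 1L)], j)]
  }
  score
}

#' Build the directed motif-support network of one sample
#'
#' Nodes are the sample's super-enhancer-assigned active transcription
#' factors. A directed edge i -> j exists when at least one PWM hit of any
#' motif of TF i falls within the super-enhancer constituents assigned to
#' TF j; the edge weight is the total hit count. TFs without a motif are
#' excluded (with a message).
#'
#' @param tf_constituent_seqs Named list: TF symbol -> character vector of
#'   constituent-peak sequences of the super-enhancer assigned to that TF.
#' @param motifs Named list: TF symbol -> list of motif objects (a TF may
#'   have several matrices; any hit counts).
#' @param score_fraction Passed to [pwm_scan()].
#' @return A directed weighted `igraph` graph (self-loops allowed).
#' @export
build_tf_network <- function(tf_constituent_seqs, motifs, score_fraction = 0.85) {
  tfs <- names(tf_constituent_seqs)
  no_motif <- tfs[!tfs %in% names(motifs)]
  if (length(no_motif)) {
    message("excluding TF(s) without motif: ", paste(no_motif, collapse = ", "))
    tfs <- setdiff(tfs, no_motif)
  }
  edges <- list()
  for (i in tfs) {
    mats <- motifs[[i]]
    if (!is.null(mats$counts)) mats <- list(mats)  # single motif supplied bare
    for (j in tfs) {
      n_hits <- 0L
      for (m in mats) {
        for (s in tf_constituent_seqs[[j]]) {
          n_hits <- n_hits + nrow(pwm_scan(s, m, score_fraction))
        }
      }
      if (n_hits > 0L) {
        edges[[length(edges) + 1L]] <- tibble(from = i, to = j, weight = n_hits)
      }
    }
  }
  el <- bind_rows(edges)
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(tfs), name = tfs)
  if (nrow(el) > 0L) {
    g <- igraph::add_edges(g, rbind(el$from, el$to), weight = el$weight)
  }
  g
}

#' Enumerate autoregulatory transcription-factor cliques
#'
#' A core regulatory circuit is a set of TFs in which every member binds
#' its own super-enhancer (self-edge) and every ordered pair is connected
#' (full interconnection). Equivalently: maximal cliques of the undirected
#' graph whose vertices are the self-looped TFs and whose edges are the
#' bidirectional pairs. A node without a self-edge — such as a "hegemonic"
#' driver that regulates the others without reciprocal regulation — can
#' never appear in any clique.
#'
#' Cliques are scored by the mean, over members, of the total inbound
#' motif-hit weight from within the clique (self-edges included), ranked by
#' score, then size, then alphabetically, and the top `top_k` are retained.
#'
#' @param net Directed weighted `igraph` from [build_tf_network()].
#' @param top_k Number of top-ranked cliques retained (default 10).
#' @return Tibble with `rank`, `tfs` (list-column of sorted symbols),
#'   `size`, `score`.
#' @export
find_crc_cliques <- function(net, top_k = 10) {
  empty <- tibble(rank = integer(), tfs = list(), size = integer(),
                  score = numeric())
  if (igraph::vcount(net) == 0L) return(empty)
  adj <- directed_adjacency(net)
  selfed <- rownames(adj)[diag(adj) > 0]
  if (length(selfed) == 0L) return(empty)
  sub <- adj[selfed, selfed, drop = FALSE]
  und <- (sub > 0) & (t(sub) > 0)
  diag(und) <- FALSE
  gu <- igraph::graph_from_adjacency_matrix(und, mode = "undirected")
  cl <- igraph::max_cliques(gu, min = 1)
  tf_sets <- lapply(cl, function(v) sort(igraph::V(gu)$name[v]))
  score <- vapply(tf_sets, function(tfs) {
    block <- sub[tfs, tfs, drop = FALSE]
    mean(colSums(block))
  }, numeric(1))
  size <- lengths(tf_sets)
  key <- vapply(tf_sets, paste, character(1), collapse = ",")
  ord <- order(-score, -size, key)
  out <- tibble(tfs = tf_sets[ord], size = size[ord], score = score[ord])
  out <- head(out, top_k)
  out$rank <- seq_len(nrow(out))
  out[, c("rank", "tfs", "size", "score")]
}

directed_adjacency <- function(net) {
  nm <- igraph::V(net)$name
  adj <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  if (igraph::ecount(net) > 0L) {
    el <- igraph::as_edgelist(net)
    w <- igraph::E(net)$weight
    if (is.null(w)) w <- rep(1, nrow(el))
    for (k in seq_len(nrow(el))) {
      adj[el[k, 1], el[k, 2]] <- adj[el[k, 1], el[k, 2]] + w[k]
    }
  }
  adj
}

#' Core-regulatory-circuit membership matrix
#'
#' A TF is present in a sample when it appears in any of that sample's
#' top-k cliques.
#'
#' @param clique_lists Named list: sample -> clique tibble from
#'   [find_crc_cliques()].
#' @return Logical matrix, TF x sample.
#' @export
crc_membership <- function(clique_lists) {
  samples <- names(clique_lists)
  tfs <- sort(unique(unlist(lapply(clique_lists, function(cl) unlist(cl$tfs)))))
  m <- matrix(FALSE, length(tfs), length(samples), dimnames = list(tfs, samples))
  for (s in samples) {
    present <- unique(unlist(clique_lists[[s]]$tfs))
    m[present, s] <- TRUE
  }
  m
}

#' Cross-entity specificity filter for CRC transcription factors
#'
#' Retains TFs present in the circuitry of at least `case_min` of the case
#' samples while present in fewer than `control_max` of the controls (the
#' ">= 50% of cases, < 30% of controls" rule).
#'
#' @param membership Logical TF x sample matrix from [crc_membership()].
#' @param case_ids,control_ids Disjoint, non-empty sample vectors.
#' @param case_min Minimum case fraction (default 0.5).
#' @param control_max Exclusive maximum control fraction (default 0.3).
#' @return Tibble with `tf`, `case_fraction`, `control_fraction`,
#'   `is_candidate`.
#' @export
specificity_filter <- function(membership, case_ids, control_ids,
                               case_min = 0.5, control_max = 0.3) {
  if (length(case_ids) == 0L || length(control_ids) == 0L) {
    stop("case and control groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(case_ids, control_ids))) {
    stop("case and control groups overlap", call. = FALSE)
  }
  missing <- setdiff(c(case_ids, control_ids), colnames(membership))
  if (length(missing)) {
    stop("sample(s) absent from membership matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  case_frac <- rowMeans(membership[, case_ids, drop = FALSE])
  ctrl_frac <- rowMeans(membership[, control_ids, drop = FALSE])
  tibble(
    tf = rownames(membership),
    case_fraction = unname(case_frac),
    control_fraction = unname(ctrl_frac),
    is_candidate = unname(case_frac >= case_min & ctrl_frac < control_max)
  )
}
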