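# Independent brute-force oracles used to verify the implementation.
# Each oracle recomputes the quantity by a different route (regex, per-base
# summation, exhaustive enumeration) and must stay independent of the
# package's own algorithms.

rotations_of <- function(u) {
  k <- nchar(u)
  d <- paste0(u, u)
  unique(vapply(seq_len(k), function(i) substr(d, i, i + k - 1L), character(1)))
}

# regex brute force: maximal matches of (rotation){r,} for every rotation,
# overlapping matches grouped; per group the longest match (earliest start
# on ties) defines the hit
oracle_repeat_hits <- function(seq, classes) {
  out <- list()
  for (ci in seq_len(nrow(classes))) {
    k <- classes$k[ci]
    r <- classes$min_repeats[ci]
    ms <- list()
    for (rot in rotations_of(classes$unit[ci])) {
      g <- gregexpr(sprintf("(?:%s){%d,}", rot, r), seq, perl = TRUE)[[1]]
      if (g[1] != -1L) {
        ms[[rot]] <- data.frame(start = as.integer(g) - 1L,
                                len = attr(g, "match.length"))
      }
    }
    if (!length(ms)) next
    mm <- do.call(rbind, ms)
    mm <- mm[order(mm$start), , drop = FALSE]
    grp <- cumsum(c(1L, utils::tail(mm$start, -1) >= utils::head(mm$start + mm$len, -1)))
    for (gi in split(seq_len(nrow(mm)), grp)) {
      sub <- mm[gi, , drop = FALSE]
      cp <- sub$len %/% k
      best <- max(cp)
      st <- min(sub$start[cp == best])
      out[[length(out) + 1L]] <- data.frame(start = st, end = st + k * best,
                                            unit = classes$unit[ci], k = k,
                                            n_repeats = best)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), unit = character(),
                      k = integer(), n_repeats = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$k), , drop = FALSE]
}

hit_key <- function(d) sort(paste(d$start, d$end, d$unit, d$n_repeats))

# O(n^2) gap merging by repeated pairwise passes until fixpoint; returns
# the partition of peak indices
oracle_stitch_partition <- function(peaks, dist) {
  n <- nrow(peaks)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] == comp[j]) next
      if (peaks$chrom[i] != peaks$chrom[j]) next
      gap <- max(peaks$start[i], peaks$start[j]) - min(peaks$end[i], peaks$end[j])
      if (gap <= dist) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(seq_len(n), comp), sort))
}

partition_key <- function(groups) {
  sort(vapply(groups, function(g) paste(sort(g), collapse = ","), character(1)))
}

# per-base signal summation
oracle_signal_sum <- function(region, track) {
  total <- 0
  tr <- track[track$chrom == region$chrom, , drop = FALSE]
  for (b in seq(region$start, region$end - 1L)) {
    hit <- which(tr$start <= b & tr$end > b)
    if (length(hit)) total <- total + tr$value[hit[1]]
  }
  total
}

# independent slope scan for the tangent cutoff (explicit loop)
oracle_cutoff_index <- function(s) {
  n <- length(s)
  if (max(s) == min(s)) return(NA_integer_)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  for (i in seq_len(n)) {
    lo <- max(1L, i - 1L)
    hi <- min(n, i + 1L)
    if ((y[hi] - y[lo]) / (x[hi] - x[lo]) > 1) return(i)
  }
  NA_integer_
}

# exhaustive enumeration of maximal fully-interconnected autoregulatory
# sets from a directed logical adjacency matrix
oracle_cliques <- function(adj) {
  n <- nrow(adj)
  ok <- function(idx) {
    all(diag(adj)[idx]) &&
      all(adj[idx, idx, drop = FALSE] & t(adj[idx, idx, drop = FALSE]))
  }
  valid <- list()
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (ok(idx)) valid[[length(valid) + 1L]] <- idx
  }
  maximal <- keep_maximal(valid)
  sort(vapply(maximal, function(idx) paste(rownames(adj)[idx], collapse = ","),
              character(1)))
}

keep_maximal <- function(sets) {
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && keep[i] && all(sets[[i]] %in% sets[[j]]) &&
        length(sets[[j]]) > length(sets[[i]])) keep[i] <- FALSE
  }
  sets[keep]
}

# exhaustive simple-path search for the minimal hop to a microsatellite
# anchor (traversable anchors only), or NA beyond max_depth
oracle_min_hop <- function(adj_list, traversable, msat, start, max_depth) {
  best <- Inf
  recurse <- function(v, depth, visited) {
    if (depth >= max_depth) return()
    for (u in adj_list[[v]]) {
      if (u %in% visited || !traversable[u]) next
      if (msat[u]) best <<- min(best, depth + 1L)
      recurse(u, depth + 1L, c(visited, u))
    }
  }
  recurse(start, 0L, start)
  if (is.finite(best)) as.integer(best) else NA_integer_
}

adj_list_from_edges <- function(n, edges) {
  adj <- replicate(n, integer(), simplify = FALSE)
  for (k in seq_len(nrow(edges))) {
    adj[[edges$from[k]]] <- sort(unique(c(adj[[edges$from[k]]], edges$to[k])))
    adj[[edges$to[k]]] <- sort(unique(c(adj[[edges$to[k]]], edges$from[k])))
  }
  adj
}

# build an anchor-graph object directly (for graph-level tests)
make_anchor_graph <- function(anchors, edges) {
  g <- igraph::make_empty_graph(nrow(anchors), directed = FALSE)
  igraph::V(g)$name <- as.character(anchors$anchor_id)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(as.character(edges$from), as.character(edges$to)),
                           support = 1)
  }
  list(anchors = anchors, graph = g)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

toy_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}
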