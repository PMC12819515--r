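#' Stitch enhancer peaks into candidate super-enhancer regions
#'
#' ROSE-style stitching: peaks on the same chromosome whose gap is at most
#' `stitch_distance` are merged into one stitched region. Peaks fully
#' contained in a TSS-exclusion region (e.g. +/- 2.5 kb around promoters)
#' are dropped before stitching, mirroring the ROSE `-t` option.
#'
#' @param peaks Region tibble of (H3K27ac) peaks.
#' @param stitch_distance Maximum gap in bp bridged by stitching
#'   (ROSE default 12500).
#' @param tss_exclusion Optional region tibble; peaks fully inside any of
#'   these regions are removed before stitching.
#' @return Tibble with columns `chrom`, `start`, `end`, `n_constituents`
#'   and a list-column `constituents` holding the member peaks.
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500, tss_exclusion = NULL) {
  stopifnot(stitch_distance >= 0)
  peaks <- sort_regions(peaks)
  if (!is.null(tss_exclusion) && nrow(peaks) > 0L && nrow(tss_exclusion) > 0L) {
    hits <- overlap_pairs(peaks, tss_exclusion)
    if (nrow(hits) > 0L) {
      contained <- hits$overlap_bp == (peaks$end[hits$query_idx] - peaks$start[hits$query_idx])
      drop <- unique(hits$query_idx[contained])
      if (length(drop)) peaks <- peaks[-drop, , drop = FALSE]
    }
  }
  if (nrow(peaks) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_constituents = integer(), constituents = list()))
  }
  # single left-to-right sweep per chromosome; peaks are sorted
  grp <- integer(nrow(peaks))
  g <- 0L
  cur_chrom <- ""
  cur_end <- -Inf
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != cur_chrom || peaks$start[i] - cur_end > stitch_distance) {
      g <- g + 1L
      cur_chrom <- peaks$chrom[i]
      cur_end <- peaks$end[i]
    } else {
      cur_end <- max(cur_end, peaks$end[i])
    }
    grp[i] <- g
  }
  idx <- unname(split(seq_len(nrow(peaks)), grp))
  tibble(
    chrom = map_chr(idx, ~ peaks$chrom[.x[1]]),
    start = map_int(idx, ~ min(peaks$start[.x])),
    end = map_int(idx, ~ max(peaks$end[.x])),
    n_constituents = lengths(idx),
    constituents = map(idx, ~ peaks[.x, , drop = FALSE])
  )
}

#' Score stitched regions by input-subtracted coverage
#'
#' The net signal of a stitched region is the treatment coverage summed over
#' the region minus the control (input DNA) coverage summed over the same
#' region, floored at 0 — negative enrichment after input subtraction is
#' treated as noise.
#'
#' @param stitched Output of [stitch_peaks()].
#' @param treatment Signal tibble (see [read_signal()]).
#' @param control Optional input signal tibble.
#' @return `stitched` with an added `net_signal` column.
#' @export
score_regions <- function(stitched, treatment, control = NULL) {
  t_sum <- signal_sum(stitched, treatment)
  c_sum <- if (is.null(control)) 0 else signal_sum(stitched, control)
  stitched$net_signal <- pmax(t_sum - c_sum, 0)
  stitched
}

# per-region sum of (coverage value x overlapped bases)
signal_sum <- function(regions, track) {
  if (nrow(regions) == 0L) return(numeric())
  if (nrow(track) == 0L) return(numeric(nrow(regions)))
  hits <- overlap_pairs(regions, track)
  out <- numeric(nrow(regions))
  if (nrow(hits) > 0L) {
    contrib <- hits$overlap_bp * track$value[hits$subject_idx]
    agg <- tapply(contrib, hits$query_idx, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Call super-enhancers by the tangent cutoff on the ranked signal curve
#'
#' Regions are ranked ascending by net signal; both the rank axis and the
#' signal axis are min-max scaled to `[0, 1]`. The cutoff is the signal at
#' the first rank (scanning ascending) where the discrete slope of the
#' scaled curve exceeds 1 — the point where the curve rises faster than the
#' diagonal, i.e. the ROSE tangent geometry. Regions with net signal
#' strictly above the cutoff are flagged super-enhancers; ties at the
#' cutoff remain typical enhancers. A flat curve (all signals equal) yields
#' no super-enhancers.
#'
#' The discrete slope is a central difference; the endpoints use one-sided
#' differences.
#'
#' @param scored Output of [score_regions()] (needs `net_signal`).
#' @param sample_id Optional sample label.
#' @return A `ranked_profile`: list with `sample_id`, `regions` (the scored
#'   tibble sorted ascending by `net_signal`, plus `rank`, `is_super` and a
#'   `normalized_intensity` placeholder) and `cutoff_signal`.
#' @export
call_superenhancers <- function(scored, sample_id = NULL) {
  if (nrow(scored) < 2L) stop("insufficient regions: need at least 2", call. = FALSE)
  if (any(!is.finite(scored$net_signal))) stop("non-finite net_signal", call. = FALSE)
  ord <- order(scored$net_signal, scored$chrom, scored$start)
  regions <- scored[ord, , drop = FALSE]
  s <- regions$net_signal
  cut_idx <- tangent_cutoff_index(s)
  cutoff <- if (is.na(cut_idx)) Inf else s[cut_idx]
  regions$rank <- seq_len(nrow(regions))
  regions$is_super <- regions$net_signal > cutoff
  regions$normalized_intensity <- NA_real_
  structure(list(sample_id = sample_id %||% attr(scored, "sample_id"),
                 regions = regions, cutoff_signal = cutoff),
            class = "ranked_profile")
}

# index (ascending rank) of the first point whose scaled-curve slope
# exceeds 1, or NA if the slope never does (flat/degenerate curve)
tangent_cutoff_index <- function(s) {
  n <- length(s)
  rng <- max(s) - min(s)
  if (rng <= 0) return(NA_integer_)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / rng
  slope <- numeric(n)
  slope[1] <- (y[2] - y[1]) / (x[2] - x[1])
  slope[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    slope[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  idx <- which(slope > 1)
  if (length(idx) == 0L) NA_integer_ else idx[1]
}

#' Normalize a ranked profile and retain the strongest super-enhancers
#'
#' Normalized intensity is net signal divided by the sample's maximum net
#' signal, so each sample's strongest region scores 1. Super-enhancers
#' beyond the strongest `top_n` are demoted to typical enhancers.
#' Idempotent.
#'
#' @param profile A `ranked_profile` from [call_superenhancers()].
#' @param top_n Number of super-enhancers retained per sample (default 500).
#' @return The profile with `normalized_intensity` filled in and `is_super`
#'   truncated to the top `top_n`.
#' @export
normalize_profile <- function(profile, top_n = 500) {
  r <- profile$regions
  mx <- max(r$net_signal)
  if (mx <= 0) {
    warning("maximum net signal is 0; all normalized intensities set to 0",
            call. = FALSE)
    r$normalized_intensity <- 0
  } else {
    r$normalized_intensity <- r$net_signal / mx
  }
  n_se <- sum(r$is_super)
  if (n_se > top_n) {
    # regions are sorted ascending; keep only the strongest top_n
    se_idx <- which(r$is_super)
    demote <- head(se_idx, n_se - top_n)
    r$is_super[demote] <- FALSE
  }
  profile$regions <- r
  profile
}

#' Merge super-enhancers across samples into a consensus matrix
#'
#' Super-enhancers from all profiles are merged transitively whenever a
#' pair overlaps by at least `min_overlap` of the smaller region
#' (`mode = "of_smaller"`, the default) or of both regions
#' (`mode = "reciprocal"`). Each consensus region is the union span of its
#' members. The value matrix holds, per consensus region and sample, the
#' normalized intensity of that sample's best-overlapping super-enhancer,
#' or 0 where the sample has none.
#'
#' @param profiles List of normalized `ranked_profile` objects.
#' @param min_overlap Minimum overlap fraction (default 0.5).
#' @param mode `"of_smaller"` or `"reciprocal"`.
#' @return List with `regions` (consensus tibble), `samples`, and `values`
#'   (consensus x sample matrix of normalized intensities).
#' @export
build_consensus <- function(profiles, min_overlap = 0.5,
                            mode = c("of_smaller", "reciprocal")) {
  mode <- match.arg(mode)
  stopifnot(length(profiles) >= 1L)
  samples <- map_chr(profiles, function(p) p$sample_id %||% NA_character_)
  if (any(is.na(samples))) samples <- paste0("sample_", seq_along(profiles))
  ses <- bind_rows(lapply(seq_along(profiles), function(i) {
    r <- profiles[[i]]$regions
    r <- r[r$is_super, c("chrom", "start", "end", "normalized_intensity")]
    r$sample <- samples[i]
    r
  }))
  if (nrow(ses) == 0L) {
    return(list(regions = tibble(chrom = character(), start = integer(),
                                 end = integer()),
                samples = samples,
                values = matrix(0, 0, length(samples),
                                dimnames = list(NULL, samples))))
  }
  hits <- overlap_pairs(ses, ses)
  hits <- hits[hits$query_idx < hits$subject_idx, , drop = FALSE]
  if (nrow(hits) > 0L) {
    wq <- ses$end[hits$query_idx] - ses$start[hits$query_idx]
    ws <- ses$end[hits$subject_idx] - ses$start[hits$subject_idx]
    frac <- switch(mode,
      of_smaller = hits$overlap_bp / pmin(wq, ws),
      reciprocal = pmin(hits$overlap_bp / wq, hits$overlap_bp / ws)
    )
    hits <- hits[frac >= min_overlap, , drop = FALSE]
  }
  comp <- union_find(nrow(ses), hits$query_idx, hits$subject_idx)
  groups <- unname(split(seq_len(nrow(ses)), comp))
  regions <- tibble(
    chrom = map_chr(groups, ~ ses$chrom[.x[1]]),
    start = map_int(groups, ~ min(ses$start[.x])),
    end = map_int(groups, ~ max(ses$end[.x]))
  )
  ord <- order(regions$chrom, regions$start, regions$end)
  regions <- regions[ord, ]
  groups <- groups[ord]
  values <- matrix(0, nrow(regions), length(samples),
                   dimnames = list(NULL, samples))
  for (gi in seq_along(groups)) {
    members <- ses[groups[[gi]], ]
    # per sample, keep the member with the largest overlap with the
    # consensus span (the best-overlapping SE)
    for (s in unique(members$sample)) {
      ms <- members[members$sample == s, ]
      ov <- pmin(ms$end, regions$end[gi]) - pmax(ms$start, regions$start[gi])
      values[gi, s] <- ms$normalized_intensity[which.max(ov)]
    }
  }
  list(regions = regions, samples = samples, values = values)
}

union_find <- function(n, a, b) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

#' Principal components of the consensus super-enhancer matrix
#'
#' Samples are the observations, consensus regions the variables; values
#' are mean-centered (not scaled). Component signs are fixed so that each
#' component's largest-magnitude loading is positive, making the scores
#' deterministic.
#'
#' @param consensus Output of [build_consensus()].
#' @param n_components Number of components to return.
#' @return List with `scores` (tibble: sample plus `PC1..PCk`),
#'   `loadings`, and `var_explained` (fraction per component).
#' @export
pca_profiles <- function(consensus, n_components = 2) {
  m <- t(consensus$values)  # samples x regions
  if (nrow(m) < 2L) stop("need at least 2 samples for PCA", call. = FALSE)
  if (n_components > min(dim(m))) {
    stop("n_components exceeds matrix dimensions", call. = FALSE)
  }
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$x))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  sc <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    flip <- sign(rot[which.max(abs(rot[, j])), j])
    if (flip < 0) {
      rot[, j] <- -rot[, j]
      sc[, j] <- -sc[, j]
    }
  }
  scores <- as_tibble(sc)
  scores <- mutate(scores, sample = consensus$samples, .before = 1)
  var_expl <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, loadings = rot, var_explained = var_expl[seq_len(k)])
}

#' Super-enhancer rank curve for a sample group
#'
#' For each consensus region, the mean normalized intensity over the chosen
#' samples; regions are ranked ascending by that mean, giving the familiar
#' hockey-stick curve.
#'
#' @param consensus Output of [build_consensus()].
#' @param samples Samples to average over (default: all).
#' @return Tibble with `rank`, `chrom`, `start`, `end`, `mean_intensity`,
#'   sorted ascending by `mean_intensity`.
#' @export
se_rank_curve <- function(consensus, samples = NULL) {
  samples <- samples %||% consensus$samples
  missing <- setdiff(samples, consensus$samples)
  if (length(missing)) stop("unknown sample(s): ", paste(missing, collapse = ", "),
                            call. = FALSE)
  mm <- consensus$values[, samples, drop = FALSE]
  mu <- rowMeans(mm)
  out <- consensus$regions
  out$mean_intensity <- mu
  out <- out[order(out$mean_intensity), ]
  out$rank <- seq_len(nrow(out))
  out[, c("rank", "chrom", "start", "end", "mean_intensity")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
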