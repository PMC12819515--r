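#' Enumerate canonical tandem-repeat classes
#'
#' The agnostic microsatellite scan considers every possible repeat unit of
#' length 3 or 4. Units that are rotations of one another describe the same
#' tandem repeat (a GGAA run is equally a GAAG, AAGG or AGGA run), so units
#' are grouped into rotational equivalence classes and represented by their
#' lexicographically minimal rotation. Homopolymer units (AAAA, ...) are
#' excluded: a run of AAAA is a poly-A tract, not a period-4 microsatellite.
#' This yields 66 classes for 4-mers and 20 for 3-mers. Each class records
#' the canonical unit of its reverse complement (`rc_partner`), which may be
#' the class itself.
#'
#' @param k_specs List of `c(unit_length, min_repeats)` pairs; defaults to
#'   4-mers repeated at least 4 times and 3-mers repeated at least 5 times.
#' @return Tibble with columns `unit` (canonical), `k`, `min_repeats`,
#'   `rc_partner`.
#' @export
enumerate_repeat_classes <- function(k_specs = list(c(4L, 4L), c(3L, 5L))) {
  bind_rows(lapply(k_specs, function(spec) {
    k <- spec[1]; min_rep <- spec[2]
    units <- all_kmers(k)
    units <- units[!is_homopolymer(units)]
    canon <- vapply(units, canonical_rotation, character(1))
    canon <- sort(unique(canon))
    tibble(
      unit = canon,
      k = k,
      min_repeats = as.integer(min_rep),
      rc_partner = vapply(canon, function(u) canonical_rotation(revcomp(u)),
                          character(1), USE.NAMES = FALSE)
    )
  }))
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}

is_homopolymer <- function(units) {
  vapply(units, function(u) {
    ch <- strsplit(u, "")[[1]]
    all(ch == ch[1])
  }, logical(1))
}

#' Canonical rotation of a repeat unit
#'
#' Lexicographically minimal rotation; GGAA, GAAG, AAGG and AGGA all map to
#' AAGG.
#'
#' @param unit Repeat unit (uppercase).
#' @return The minimal rotation.
#' @export
canonical_rotation <- function(unit) {
  k <- nchar(unit)
  doubled <- paste0(unit, unit)
  rots <- vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L), character(1))
  min(rots)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Maximal period-k tracts of a sequence. A tract is a maximal interval on
# which s[i] == s[i + k]; its repeat unit is its first k bases. Positions
# outside {A,C,G,T} (N etc.) never satisfy the period test, so tracts break
# at N. Returns 0-based tract starts, tract lengths and units.
scan_tracts <- function(sequence, k) {
  L <- nchar(sequence)
  empty <- list(start = integer(), tract_len = integer(), unit = character())
  if (L < 2L * k) return(empty)
  r <- charToRaw(sequence)
  acgt <- charToRaw("ACGT")
  valid <- r %in% acgt
  i1 <- seq_len(L - k)
  eq <- (r[i1] == r[i1 + k]) & valid[i1] & valid[i1 + k]
  runs <- rle(eq)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= k  # at least 2 full copies
  if (!any(keep)) return(empty)
  st <- starts[keep]
  m <- runs$lengths[keep]
  list(
    start = st - 1L,                       # 0-based
    tract_len = m + k,
    unit = substring(sequence, st, st + k - 1L)
  )
}

#' Find maximal microsatellite runs in a sequence
#'
#' Detects all maximal runs in which any rotation of a repeat unit occurs
#' tandemly at least `min_repeats` times. A run is reported once, as the
#' longest whole-unit stretch starting at the earliest possible phase; a
#' 7-copy run is a single hit with `n_repeats = 7`, not four overlapping
#' hits. Runs are broken at non-ACGT bases.
#'
#' @param sequence Uppercase DNA string (ACGTN).
#' @param classes Repeat-class tibble from [enumerate_repeat_classes()]
#'   (possibly filtered to the classes of interest).
#' @return Tibble with `start` (0-based), `end` (exclusive), `unit`
#'   (canonical class unit), `k`, `n_repeats`.
#' @export
find_repeats <- function(sequence, classes = enumerate_repeat_classes()) {
  start <- end <- n_rep_all <- k_all <- integer()
  unit_all <- character()
  for (k in unique(classes$k)) {
    cls <- classes[classes$k == k, ]
    tr <- scan_tracts(sequence, k)
    if (length(tr$start) == 0L) next
    canon <- vapply(tr$unit, canonical_rotation, character(1), USE.NAMES = FALSE)
    idx <- match(canon, cls$unit)
    n_rep <- tr$tract_len %/% k
    keep <- !is.na(idx) & n_rep >= cls$min_repeats[ifelse(is.na(idx), 1L, idx)]
    if (!any(keep)) next
    start <- c(start, tr$start[keep])
    end <- c(end, tr$start[keep] + k * n_rep[keep])
    unit_all <- c(unit_all, canon[keep])
    k_all <- c(k_all, rep(k, sum(keep)))
    n_rep_all <- c(n_rep_all, n_rep[keep])
  }
  ord <- order(start, k_all)
  tibble(start = start[ord], end = end[ord], unit = unit_all[ord],
         k = k_all[ord], n_repeats = n_rep_all[ord])
}

#' The GGAA microsatellite classes
#'
#' The rotational class of GGAA (canonical AAGG) and, in
#' `"rotation_rc"` mode, also that of its reverse complement TTCC
#' (canonical CCTT) — ETS-type elements occur on both strands of the
#' reference genome. `min_repeats` defaults to 4 consecutive copies.
#'
#' @param mode `"rotation_rc"` (default) or `"literal"`.
#' @param min_repeats Minimum tandem copies (default 4).
#' @return Repeat-class tibble usable with [find_repeats()].
#' @export
ggaa_classes <- function(mode = c("rotation_rc", "literal"), min_repeats = 4L) {
  mode <- match.arg(mode)
  fwd <- canonical_rotation("GGAA")
  units <- if (mode == "rotation_rc") c(fwd, canonical_rotation(revcomp("GGAA"))) else fwd
  tibble(
    unit = unique(units),
    k = 4L,
    min_repeats = as.integer(min_repeats),
    rc_partner = vapply(unique(units), function(u) canonical_rotation(revcomp(u)),
                        character(1), USE.NAMES = FALSE)
  )
}

#' Count microsatellites in genomic regions
#'
#' Per-region raw hit counts and length-normalized counts (hits per kb),
#' the quantity summarized per sample as "the mean of the normalized number
#' of microsatellites per region".
#'
#' @param regions Region tibble.
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param classes Repeat-class tibble (default: the GGAA classes).
#' @return `regions` with added `msat_count` and `msat_per_kb` columns.
#' @export
count_msats_in_regions <- function(regions, genome, classes = ggaa_classes()) {
  seqs <- region_sequences(regions, genome)
  counts <- vapply(seqs, function(s) nrow(find_repeats(s, classes)), integer(1),
                   USE.NAMES = FALSE)
  regions$msat_count <- counts
  regions$msat_per_kb <- counts * 1000 / (regions$end - regions$start)
  regions
}

#' Flag ETS fusion peaks containing a GGAA microsatellite
#'
#' A peak is an "mSat peak" if its sequence contains at least `min_repeats`
#' consecutive copies of GGAA. In `"rotation_rc"` mode (default) any
#' rotation of GGAA or TTCC counts; in `"literal"` mode the run must
#' contain `min_repeats` whole copies of literal GGAA.
#'
#' @param ets_peaks Region tibble of fusion-TF ChIP peaks.
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param mode `"rotation_rc"` or `"literal"`.
#' @param min_repeats Minimum tandem copies (default 4).
#' @return Logical vector, one flag per peak.
#' @export
flag_msat_peaks <- function(ets_peaks, genome, mode = c("rotation_rc", "literal"),
                            min_repeats = 4L) {
  mode <- match.arg(mode)
  if (nrow(ets_peaks) == 0L) return(logical())
  seqs <- region_sequences(ets_peaks, genome)
  cls <- ggaa_classes(mode = "rotation_rc", min_repeats = min_repeats)
  vapply(seqs, function(s) {
    hits <- find_repeats(s, cls)
    if (nrow(hits) == 0L) return(FALSE)
    if (mode == "rotation_rc") return(TRUE)
    # literal: within a hit tract, count whole copies of literal GGAA
    any(vapply(seq_len(nrow(hits)), function(i) {
      tract <- substr(s, hits$start[i] + 1L, hits$end[i])
      literal_copies(tract, "GGAA") >= min_repeats
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

# max whole tandem copies of a literal unit within a pure periodic tract
literal_copies <- function(tract, unit) {
  k <- nchar(unit)
  best <- 0L
  for (o in 0:(k - 1L)) {
    if (nchar(tract) - o < k) break
    if (substr(tract, o + 1L, o + k) == unit) {
      best <- max(best, (nchar(tract) - o) %/% k)
    }
  }
  best
}

#' Paired Wilcoxon test for microsatellite enrichment in super-enhancers
#'
#' Two-sided Wilcoxon signed-rank test on per-sample paired means
#' (super-enhancer mean density vs typical-enhancer mean density).
#' Zero differences are dropped before ranking; the exact null
#' distribution is used when the remaining differences are tie-free.
#'
#' @param se_means Per-sample mean normalized microsatellite counts in
#'   super-enhancers.
#' @param enhancer_means Per-sample means in typical enhancers, same
#'   sample order.
#' @return List with `statistic` (V), `p_value`, `n_pairs` (non-zero
#'   differences used).
#' @export
paired_enrichment_test <- function(se_means, enhancer_means) {
  if (length(se_means) != length(enhancer_means)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (length(se_means) < 5L) stop("insufficient pairs: need at least 5", call. = FALSE)
  d <- se_means - enhancer_means
  d <- d[d != 0]
  if (length(d) < 5L) stop("insufficient pairs: fewer than 5 non-zero differences",
                           call. = FALSE)
  exact <- !any(duplicated(abs(d)))
  wt <- suppressWarnings(wilcox.test(d, alternative = "two.sided", exact = exact,
                                     correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n_pairs = length(d))
}

#' Percentage of regions containing a microsatellite
#'
#' @param regions Region tibble.
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param classes Repeat-class tibble (default: the GGAA classes).
#' @return Percentage in `[0, 100]` of regions with at least one hit.
#' @export
fraction_with_msat <- function(regions, genome, classes = ggaa_classes()) {
  if (nrow(regions) == 0L) stop("empty region set", call. = FALSE)
  x <- count_msats_in_regions(regions, genome, classes)
  100 * sum(x$msat_count > 0) / nrow(x)
}
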