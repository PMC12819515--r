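#' Genomic region tables
#'
#' Throughout the package a set of genomic regions is an ordinary tibble with
#' at least the columns `chrom` (character), `start` and `end` (integers,
#' 0-based half-open BED convention). Optional columns are `name`, `score`,
#' `strand` (one of `+`, `-`, `.`) and `summit` (narrowPeak column 10: offset
#' of the peak summit from `start`, or `NA`). `region_tbl()` builds and
#' validates such a table; every reader in the package returns one.
#'
#' Coordinates are validated (`0 <= start < end`; `summit` in
#' `[0, end - start)`) and rows are sorted by `(chrom, start, end)`.
#' Strand is carried but ignored by all interval arithmetic: H3K27ac
#' enrichment and chromatin loops are unstranded. Chromosome names are passed
#' through verbatim; no "chr" prefix normalization is attempted, so naming
#' mismatches between inputs surface as zero overlaps rather than silent
#' renames.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param name Optional character labels.
#' @param score Optional numeric scores.
#' @param strand Optional strand (`+`, `-` or `.`).
#' @param summit Optional integer summit offsets from `start`.
#' @return A tibble sorted by `(chrom, start, end)`.
#' @export
#' @examples
#' region_tbl("chr1", c(100L, 5000L), c(200L, 6000L))
region_tbl <- function(chrom, start, end, name = NA_character_,
                       score = NA_real_, strand = ".", summit = NA_integer_) {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand),
    summit = as.integer(summit)
  )
  validate_regions(x)
}

validate_regions <- function(x, context = "region table") {
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    stop(context, ": missing chromosome name", call. = FALSE)
  }
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    stop(context, ": missing coordinates", call. = FALSE)
  }
  bad <- which(x$start < 0L | x$start >= x$end)
  if (length(bad)) {
    stop(sprintf("%s: invalid interval at row %d (start=%d, end=%d); need 0 <= start < end",
                 context, bad[1], x$start[bad[1]], x$end[bad[1]]), call. = FALSE)
  }
  if ("strand" %in% names(x)) {
    ok <- x$strand %in% c("+", "-", ".")
    if (!all(ok)) stop(context, ": strand must be one of '+', '-', '.'", call. = FALSE)
  }
  if ("summit" %in% names(x)) {
    s <- x$summit
    bad <- which(!is.na(s) & (s < 0L | s >= (x$end - x$start)))
    if (length(bad)) {
      stop(sprintf("%s: summit out of range at row %d", context, bad[1]), call. = FALSE)
    }
  }
  sort_regions(x)
}

sort_regions <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Overlap fraction between two intervals
#'
#' Fraction of one region covered by its intersection with the other,
#' the comparison behind "super-enhancers overlapping by at least 50\%
#' were merged". Regions on different chromosomes overlap by 0.
#'
#' @param a,b Single-row region tibbles (or lists with `chrom`, `start`, `end`).
#' @param mode `"of_a"`: intersection length / length of `a`;
#'   `"of_smaller"`: intersection length / length of the smaller region
#'   (symmetric; this is the default used for consensus merging).
#' @return A fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b, mode = c("of_smaller", "of_a")) {
  mode <- match.arg(mode)
  if (a$chrom[1] != b$chrom[1]) return(0)
  inter <- min(a$end[1], b$end[1]) - max(a$start[1], b$start[1])
  if (inter <= 0) return(0)
  denom <- switch(mode,
    of_a = a$end[1] - a$start[1],
    of_smaller = min(a$end[1] - a$start[1], b$end[1] - b$start[1])
  )
  inter / denom
}

# Overlap join: rows (query_idx, subject_idx, overlap_bp) for every
# overlapping pair between two region tables. IRanges does the sweep;
# BED half-open intervals are shifted to 1-based closed.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(tibble(query_idx = integer(), subject_idx = integer(), overlap_bp = integer()))
  }
  common <- intersect(unique(query$chrom), unique(subject$chrom))
  if (length(common) == 0L) {
    warning("no shared chromosome names between region sets", call. = FALSE)
  }
  out <- vector("list", length(common))
  for (i in seq_along(common)) {
    cc <- common[i]
    qi <- which(query$chrom == cc)
    si <- which(subject$chrom == cc)
    qr <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    sr <- IRanges::IRanges(subject$start[si] + 1L, subject$end[si])
    hits <- IRanges::findOverlaps(qr, sr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(qr[qh], sr[sh]))
    out[[i]] <- tibble(query_idx = qi[qh], subject_idx = si[sh], overlap_bp = ov)
  }
  if (length(out) == 0L) {
    return(tibble(query_idx = integer(), subject_idx = integer(), overlap_bp = integer()))
  }
  bind_rows(out)
}

# number of subject regions overlapping each query region
count_overlaps <- function(query, subject) {
  hits <- overlap_pairs(query, subject)
  tab <- tabulate(hits$query_idx, nbins = nrow(query))
  tab
}
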