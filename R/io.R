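#' Read genomic regions from BED-family files
#'
#' Parses BED3, BED6, ENCODE narrowPeak (10 columns) or broadPeak (9 columns)
#' into a region tibble (see [region_tbl()]). Track and comment lines
#' (`track`, `browser`, `#`) are skipped. The narrowPeak summit (column 10)
#' is captured in the `summit` column; `-1` (no summit called) becomes `NA`.
#'
#' @param path File path.
#' @param format One of `"bed3"`, `"bed6"`, `"narrowPeak"`, `"broadPeak"`.
#' @param sample_id Optional sample label attached as the `sample_id` attribute.
#' @return Region tibble sorted by `(chrom, start, end)`.
#' @export
read_regions <- function(path, format = c("bed6", "bed3", "narrowPeak", "broadPeak"),
                         sample_id = NULL) {
  format <- match.arg(format)
  ncol_needed <- switch(format, bed3 = 3L, bed6 = 6L, broadPeak = 9L, narrowPeak = 10L)
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    out <- region_tbl(character(), integer(), integer())
    attr(out, "sample_id") <- sample_id
    return(out)
  }
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < ncol_needed)
  if (length(bad)) {
    stop(sprintf("%s: line %d has %d fields, %s needs %d",
                 path, lines$lineno[bad[1]], nf[bad[1]], format, ncol_needed),
         call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, function(f) f[seq_len(ncol_needed)]))
  start <- parse_int(m[, 2], path, lines$lineno, "start")
  end <- parse_int(m[, 3], path, lines$lineno, "end")
  bad <- which(start >= end | start < 0L)
  if (length(bad)) {
    stop(sprintf("%s: line %d: invalid interval [%d, %d)",
                 path, lines$lineno[bad[1]], start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  name <- if (ncol_needed >= 4L) m[, 4] else NA_character_
  score <- if (ncol_needed >= 5L) suppressWarnings(as.numeric(m[, 5])) else NA_real_
  strand <- if (ncol_needed >= 6L) ifelse(m[, 6] %in% c("+", "-"), m[, 6], ".") else "."
  summit <- NA_integer_
  if (format == "narrowPeak") {
    summit <- parse_int(m[, 10], path, lines$lineno, "summit")
    summit[summit < 0L] <- NA_integer_
  }
  out <- region_tbl(m[, 1], start, end, name = name, score = score,
                    strand = strand, summit = summit)
  attr(out, "sample_id") <- sample_id
  out
}

#' Write genomic regions to a BED-family file
#'
#' Inverse of [read_regions()] for the fields each dialect carries.
#'
#' @param x Region tibble.
#' @param path Output path.
#' @param format Output dialect (see [read_regions()]).
#' @export
write_regions <- function(x, path, format = c("bed6", "bed3", "narrowPeak", "broadPeak")) {
  format <- match.arg(format)
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
  score <- if ("score" %in% names(x)) ifelse(is.na(x$score), 0, x$score) else 0
  strand <- if ("strand" %in% names(x)) x$strand else "."
  summit <- if ("summit" %in% names(x)) ifelse(is.na(x$summit), -1L, x$summit) else -1L
  df <- switch(format,
    bed3 = data.frame(x$chrom, x$start, x$end),
    bed6 = data.frame(x$chrom, x$start, x$end, name, score, strand),
    broadPeak = data.frame(x$chrom, x$start, x$end, name, score, strand,
                           score, -1, -1),
    narrowPeak = data.frame(x$chrom, x$start, x$end, name, score, strand,
                            score, -1, -1, summit)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' A signal track is a tibble with columns `chrom`, `start`, `end` (BED
#' half-open) and `value` (non-negative coverage). Within a chromosome,
#' intervals must be sorted and non-overlapping (abutting is fine);
#' overlapping intervals or negative values are rejected.
#'
#' @param path 4-column bedGraph file.
#' @return Signal tibble sorted by `(chrom, start, end)`.
#' @export
read_signal <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines$text) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  value = numeric()))
  }
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad)) {
    stop(sprintf("%s: line %d has %d fields, bedGraph needs 4",
                 path, lines$lineno[bad[1]], nf[bad[1]]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:4]))
  x <- tibble(
    chrom = m[, 1],
    start = parse_int(m[, 2], path, lines$lineno, "start"),
    end = parse_int(m[, 3], path, lines$lineno, "end"),
    value = suppressWarnings(as.numeric(m[, 4]))
  )
  if (any(is.na(x$value))) {
    stop(path, ": non-numeric bedGraph value", call. = FALSE)
  }
  if (any(x$value < 0)) {
    stop(path, ": negative bedGraph value", call. = FALSE)
  }
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  for (cc in unique(x$chrom)) {
    xi <- x[x$chrom == cc, ]
    if (nrow(xi) > 1L && any(xi$start[-1] < xi$end[-nrow(xi)])) {
      stop(sprintf("%s: overlapping bedGraph intervals on %s", path, cc),
           call. = FALSE)
    }
  }
  x
}

#' Write a bedGraph coverage track
#' @param x Signal tibble (`chrom`, `start`, `end`, `value`).
#' @param path Output path.
#' @export
write_signal <- function(x, path) {
  write.table(data.frame(x$chrom, x$start, x$end, x$value), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromatin loops from a BEDPE file
#'
#' Each loop joins two anchors (HiChIP interaction ends). Anchor order is
#' preserved as written. The loop support `count` is taken from the BEDPE
#' score column (column 8) when present; a 7-column file with a numeric
#' seventh field is read as `chromA startA endA chromB startB endB score`;
#' otherwise the count defaults to 1.
#'
#' @param path BEDPE file (>= 6 columns).
#' @return Tibble with columns `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`, `name`, `count`.
#' @export
read_bedpe <- function(path) {
  lines <- read_data_lines(path)
  empty <- tibble(chrom_a = character(), start_a = integer(), end_a = integer(),
                  chrom_b = character(), start_b = integer(), end_b = integer(),
                  name = character(), count = numeric())
  if (length(lines$text) == 0L) return(empty)
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  if (length(bad)) {
    stop(sprintf("%s: line %d has %d fields, BEDPE needs at least 6",
                 path, lines$lineno[bad[1]], nf[bad[1]]), call. = FALSE)
  }
  get_col <- function(j) map_chr(fields, function(f) if (length(f) >= j) f[j] else NA_character_)
  name <- get_col(7L)
  score <- get_col(8L)
  count <- rep(1, length(fields))
  has8 <- !is.na(score)
  count[has8] <- suppressWarnings(as.numeric(score[has8]))
  seven <- !has8 & !is.na(name) & !is.na(suppressWarnings(as.numeric(name)))
  count[seven] <- as.numeric(name[seven])
  name[seven] <- NA_character_
  if (any(is.na(count))) stop(path, ": non-numeric BEDPE score", call. = FALSE)
  out <- tibble(
    chrom_a = get_col(1L),
    start_a = parse_int(get_col(2L), path, lines$lineno, "startA"),
    end_a = parse_int(get_col(3L), path, lines$lineno, "endA"),
    chrom_b = get_col(4L),
    start_b = parse_int(get_col(5L), path, lines$lineno, "startB"),
    end_b = parse_int(get_col(6L), path, lines$lineno, "endB"),
    name = name,
    count = count
  )
  bad <- which(out$start_a >= out$end_a | out$start_b >= out$end_b |
                 out$start_a < 0L | out$start_b < 0L)
  if (length(bad)) {
    stop(sprintf("%s: line %d: invalid anchor coordinates", path,
                 lines$lineno[bad[1]]), call. = FALSE)
  }
  out
}

#' Write chromatin loops to a BEDPE file
#' @param x Loop tibble as returned by [read_bedpe()].
#' @param path Output path.
#' @export
write_bedpe <- function(x, path) {
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
  df <- data.frame(x$chrom_a, x$start_a, x$end_a, x$chrom_b, x$start_b,
                   x$end_b, name, x$count)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Parses the JASPAR 2016+ PFM text format: a `>ID NAME` header followed by
#' four count rows `A [ ... ]`, `C [ ... ]`, `G [ ... ]`, `T [ ... ]`.
#' When the header carries no name, the TF name defaults to the motif ID.
#'
#' @param path JASPAR PFM text file.
#' @param pseudocount Pseudocount used later when converting counts to
#'   log-odds (stored on the motif; default 1).
#' @param background Background base frequencies (A, C, G, T); must sum to 1.
#' @return A named list of motifs; each motif is a list with `motif_id`,
#'   `tf_name`, `counts` (4 x L matrix, rows A/C/G/T), `pseudocount`,
#'   `background`.
#' @export
read_jaspar <- function(path, pseudocount = 1,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (abs(sum(background) - 1) > 1e-9) {
    stop("background frequencies must sum to 1", call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  headers <- grep("^>", raw)
  if (length(headers) == 0L) stop(path, ": no JASPAR '>' header found", call. = FALSE)
  motifs <- list()
  for (i in seq_along(headers)) {
    h <- headers[i]
    last <- if (i < length(headers)) headers[i + 1] - 1L else length(raw)
    block <- raw[(h + 1L):last]
    if (length(block) < 4L) {
      stop(sprintf("%s: motif at line %d has fewer than 4 count rows", path, h),
           call. = FALSE)
    }
    header <- sub("^>\\s*", "", raw[h])
    parts <- strsplit(trimws(header), "\\s+")[[1]]
    motif_id <- parts[1]
    tf_name <- if (length(parts) >= 2L) paste(parts[-1], collapse = " ") else motif_id
    rows <- lapply(block[1:4], function(line) {
      body <- sub("^[ACGTacgt]?\\s*\\[?", "", line)
      body <- sub("\\]\\s*$", "", body)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
      if (any(is.na(vals))) {
        stop(sprintf("%s: non-numeric count in motif %s", path, motif_id),
             call. = FALSE)
      }
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop(sprintf("%s: motif %s has count rows of unequal length", path, motif_id),
           call. = FALSE)
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) {
      stop(sprintf("%s: negative count in motif %s", path, motif_id), call. = FALSE)
    }
    if (ncol(counts) < 1L || any(colSums(counts) <= 0)) {
      stop(sprintf("%s: motif %s has an empty column", path, motif_id), call. = FALSE)
    }
    motifs[[motif_id]] <- list(motif_id = motif_id, tf_name = tf_name,
                               counts = counts, pseudocount = pseudocount,
                               background = background)
  }
  motifs
}

#' Write motifs in JASPAR text format
#' @param motifs List of motifs as returned by [read_jaspar()].
#' @param path Output path.
#' @export
write_jaspar <- function(motifs, path) {
  out <- character()
  for (m in motifs) {
    out <- c(out, paste0(">", m$motif_id, " ", m$tf_name))
    for (b in c("A", "C", "G", "T")) {
      out <- c(out, paste0(b, "  [ ", paste(m$counts[b, ], collapse = " "), " ]"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# -- shared line-oriented parsing helpers ------------------------------------

read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  lineno <- seq_along(raw)
  keep <- nzchar(raw) & !grepl("^(#|track\\b|browser\\b)", raw)
  list(text = raw[keep], lineno = lineno[keep])
}

parse_int <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v))
  if (length(bad)) {
    stop(sprintf("%s: line %d: malformed %s field '%s'",
                 path, lineno[bad[1]], what, x[bad[1]]), call. = FALSE)
  }
  v
}
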