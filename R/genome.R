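#' Load a genome FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that keeps only the
#' first whitespace-delimited token of each header as the chromosome name
#' and uppercases the sequence.
#'
#' @param path FASTA file.
#' @return A named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

#' Extract region sequences from a genome
#'
#' @param regions Region tibble (BED half-open coordinates).
#' @param genome Named `DNAStringSet` (or path to a FASTA file).
#' @return Character vector of uppercase sequences, one per region.
#' @export
region_sequences <- function(regions, genome) {
  if (is.character(genome) && length(genome) == 1L) genome <- read_genome(genome)
  if (nrow(regions) == 0L) return(character())
  missing <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing)) {
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lens <- Biostrings::width(genome)[match(regions$chrom, names(genome))]
  bad <- which(regions$end > lens)
  if (length(bad)) {
    stop(sprintf("region %s:%d-%d extends beyond chromosome end (%d)",
                 regions$chrom[bad[1]], regions$start[bad[1]],
                 regions$end[bad[1]], lens[bad[1]]), call. = FALSE)
  }
  vapply(seq_len(nrow(regions)), function(i) {
    as.character(Biostrings::subseq(genome[[regions$chrom[i]]],
                                    regions$start[i] + 1L, regions$end[i]))
  }, character(1))
}
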