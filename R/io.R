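# File format helpers. FASTA/FASTQ go through Biostrings; BED, bedgraph
# and the sample sheet are simple tab-delimited tables written with readr.

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Tibble with columns name, seq, qual.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("name", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    abort("sequence and quality lengths differ")
  }
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$name
  Biostrings::writeXStringSet(
    dna, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ path (Phred+33).
#' @return Tibble (name, seq, qual).
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  tibble::tibble(
    name = names(dna),
    seq = unname(as.character(dna)),
    qual = unname(as.character(S4Vectors::mcols(dna)$qualities))
  )
}

#' Write contig sequences to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write intervals as BED6
#'
#' Intervals are written as 0-based half-open, matching the package's
#' internal convention and BED's native one.
#'
#' @param x Tibble with columns contig, start, end, strand and optionally
#'   a name column (`name_col`).
#' @param path Output path.
#' @param name_col Column used for the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path, name_col = "site_id") {
  nm <- if (name_col %in% names(x)) x[[name_col]] else "."
  bed <- tibble::tibble(
    contig = x$contig, start = x$start, end = x$end,
    name = nm, score = 0L, strand = x$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 file of intervals
#'
#' @param path BED6 path.
#' @return Tibble (contig, start, end, name, score, strand).
#' @export
read_bed6 <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("contig", "start", "end", "name", "score", "strand"),
    col_types = "ciicic", progress = FALSE
  )
}

#' Write a sample sheet
#'
#' @param barcode_map Named character vector, sample -> 4-nt barcode.
#' @param path Output path (2-column TSV: sample, barcode).
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(barcode_map, path) {
  readr::write_tsv(
    tibble::tibble(sample = names(barcode_map), barcode = unname(barcode_map)),
    path
  )
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path 2-column TSV (sample, barcode).
#' @return Tibble (sample, barcode).
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}
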