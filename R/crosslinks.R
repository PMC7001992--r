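#' Extract single-nucleotide crosslink events from alignments
#'
#' The crosslinked nucleotide is the position immediately upstream, in
#' transcript orientation, of the read's 5' mapping position: `start - 1`
#' for plus-strand alignments and `end` (one base 3'-ward in genome
#' coordinates of the rightmost aligned base) for minus-strand
#' alignments. Events falling outside contig bounds are dropped and
#' counted.
#'
#' @param alignments Deduplicated alignment tibble.
#' @param genome [Biostrings::DNAStringSet] or named integer vector of
#'   contig lengths, used for bounds checking.
#' @return Crosslink track tibble (contig, strand, pos, count) with
#'   0-based positions, sorted; attribute `dropped_out_of_bounds` counts
#'   discarded events.
#' @examples
#' aln <- tibble::tibble(name = "r1", contig = "c", strand = "+",
#'                       start = 100L, end = 130L)
#' extract_crosslinks(aln, c(c = 200L))
#' @export
extract_crosslinks <- function(alignments, genome) {
  lens <- if (inherits(genome, "DNAStringSet")) {
    setNames(Biostrings::width(genome), names(genome))
  } else genome
  pos <- ifelse(alignments$strand == "+",
                alignments$start - 1L, alignments$end)
  in_bounds <- pos >= 0L & pos < lens[alignments$contig]
  dropped <- sum(!in_bounds)
  track <- tibble::tibble(
    contig = alignments$contig[in_bounds],
    strand = alignments$strand[in_bounds],
    pos = as.integer(pos[in_bounds])
  ) |>
    dplyr::count(.data$contig, .data$strand, .data$pos, name = "count") |>
    dplyr::arrange(.data$contig, .data$strand, .data$pos)
  attr(track, "dropped_out_of_bounds") <- dropped
  track
}

#' Write one strand of a crosslink track as bedgraph
#'
#' Adjacent positions with equal counts are merged into one line;
#' intervals are 0-based half-open and counts are integers.
#'
#' @param track Crosslink track tibble (contig, strand, pos, count).
#' @param path Output path.
#' @param strand Strand to export (`"+"` or `"-"`); bedgraph has no
#'   strand column, so one file is written per strand.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, strand = "+") {
  t1 <- track[track$strand == strand, , drop = FALSE]
  if (nrow(t1) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  t1 <- dplyr::arrange(t1, .data$contig, .data$pos)
  new_run <- c(TRUE, t1$contig[-1] != t1$contig[-nrow(t1)] |
                 t1$pos[-1] != t1$pos[-nrow(t1)] + 1L |
                 t1$count[-1] != t1$count[-nrow(t1)])
  run <- cumsum(new_run)
  runs <- t1 |>
    dplyr::mutate(run = run) |>
    dplyr::group_by(run) |>
    dplyr::summarise(
      contig = dplyr::first(.data$contig),
      start = min(.data$pos),
      end = max(.data$pos) + 1L,
      count = dplyr::first(.data$count),
      .groups = "drop"
    ) |>
    dplyr::select("contig", "start", "end", "count")
  readr::write_tsv(runs, path, col_names = FALSE)
  invisible(path)
}

#' Read a bedgraph file back into a crosslink track
#'
#' @param path bedgraph path (4 columns, 0-based half-open).
#' @param strand Strand label to assign to the track.
#' @return Crosslink track tibble (contig, strand, pos, count).
#' @export
read_bedgraph <- function(path, strand = "+") {
  bg <- readr::read_tsv(path, col_names = c("contig", "start", "end", "count"),
                        col_types = "ciii", progress = FALSE)
  if (nrow(bg) == 0) {
    return(tibble::tibble(contig = character(), strand = character(),
                          pos = integer(), count = integer()))
  }
  n <- bg$end - bg$start
  tibble::tibble(
    contig = rep(bg$contig, n),
    strand = strand,
    pos = unlist(lapply(seq_len(nrow(bg)),
                        function(i) seq(bg$start[i], bg$end[i] - 1L))),
    count = rep(bg$count, n)
  ) |>
    dplyr::arrange(.data$contig, .data$pos)
}
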