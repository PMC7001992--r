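#' Naive exact aligner for synthetic references
#'
#' Desk-scale stand-in for an external genome aligner: an ungapped
#' Hamming-distance scan of both strands allowing up to `max_mismatch`
#' mismatches, with no 5' soft-clipping by construction. A read is
#' `unique` iff exactly one hit attains the minimal mismatch count; the
#' reported alignment is the first best hit in (plus strand, position)
#' order. Internally the contigs are concatenated with 100-nt N spacers
#' so each strand needs a single scan; since N mismatches every base, no
#' alignment within the mismatch budget can cross a contig boundary, and
#' any hit not fully inside a contig is discarded.
#'
#' @param reads Tibble (name, seq, qual) of barcode-relocated reads.
#' @param genome [Biostrings::DNAStringSet] of contigs.
#' @param max_mismatch Maximum Hamming mismatches per alignment.
#' @return Alignment tibble (name, contig, strand, start, end,
#'   n_mismatches, n_best_hits, unique, spliced, mapq, seq,
#'   rand_barcode); coordinates 0-based half-open. Unmapped reads are
#'   omitted and counted in the `align_counts` attribute.
#' @export
align_naive <- function(reads, genome, max_mismatch = 2L) {
  spacer <- 100L
  contig_names <- names(genome)
  widths <- Biostrings::width(genome)
  offsets <- cumsum(c(0L, head(widths + spacer, -1)))
  subject <- Biostrings::DNAString(
    paste(as.character(genome), collapse = strrep("N", spacer))
  )

  useq <- unique(reads$seq)
  hits_by_seq <- lapply(useq, function(s) {
    if (nchar(s) == 0) return(NULL)
    scan_one(s, subject, max_mismatch, contig_names, widths, offsets)
  })
  names(hits_by_seq) <- useq

  rows <- vector("list", nrow(reads))
  n_unmapped <- 0L
  for (i in seq_len(nrow(reads))) {
    h <- hits_by_seq[[reads$seq[i]]]
    if (is.null(h)) { n_unmapped <- n_unmapped + 1L; next }
    rows[[i]] <- dplyr::mutate(h, name = reads$name[i], seq = reads$seq[i])
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      name = character(), contig = character(), strand = character(),
      start = integer(), end = integer(), n_mismatches = integer(),
      n_best_hits = integer(), unique = logical(), spliced = logical(),
      mapq = integer(), seq = character()
    )
  } else {
    out <- dplyr::relocate(out, "name")
  }
  out$rand_barcode <- parse_rand_barcode(out$name)
  attr(out, "align_counts") <- c(
    input = nrow(reads), mapped = nrow(out), unmapped = n_unmapped
  )
  out
}

# Best-hit summary for one read sequence against the spacer-joined
# subject; returns a one-row tibble or NULL if unmapped.
scan_one <- function(s, subject, max_mismatch, contig_names, widths, offsets) {
  pat <- Biostrings::DNAString(s)
  collect <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, subject,
                                  max.mismatch = max_mismatch,
                                  with.indels = FALSE, fixed = TRUE)
    if (length(m) == 0) return(NULL)
    st <- Biostrings::start(m) - 1L            # 0-based in joined coords
    en <- st + nchar(s)
    idx <- findInterval(st, offsets)
    ok <- st >= offsets[idx] & en <= offsets[idx] + widths[idx]
    if (!any(ok)) return(NULL)
    mism <- vapply(which(ok), function(j) {
      as.integer(Biostrings::neditStartingAt(
        pattern, subject, starting.at = st[j] + 1L, fixed = TRUE))
    }, integer(1))
    tibble::tibble(
      contig = contig_names[idx[ok]], strand = strand,
      start = st[ok] - offsets[idx[ok]], end = en[ok] - offsets[idx[ok]],
      n_mismatches = mism
    )
  }
  hits <- dplyr::bind_rows(
    collect(pat, "+"),
    collect(Biostrings::reverseComplement(pat), "-")
  )
  if (nrow(hits) == 0) return(NULL)
  best <- min(hits$n_mismatches)
  bh <- hits[hits$n_mismatches == best, , drop = FALSE]
  dplyr::mutate(
    bh[1, ],
    n_best_hits = nrow(bh),
    unique = nrow(bh) == 1,
    spliced = FALSE,
    mapq = ifelse(nrow(bh) == 1, 60L, 0L)
  )
}

#' Keep unique, unspliced alignments
#'
#' Retains alignments flagged unique and unspliced. Records lacking
#' uniqueness evidence (`unique` is `NA`, e.g. ingested from a file
#' without the configured tag) are dropped with a warning.
#'
#' @param alignments Alignment tibble with `unique` and `spliced`
#'   columns.
#' @return Filtered alignment tibble with a `filter_counts` attribute.
#' @export
filter_alignments <- function(alignments) {
  no_evidence <- is.na(alignments$unique)
  if (any(no_evidence)) {
    warn(sprintf("%d alignment(s) lack uniqueness evidence and were dropped",
                 sum(no_evidence)))
  }
  keep <- !no_evidence & alignments$unique & !alignments$spliced
  out <- alignments[keep, , drop = FALSE]
  attr(out, "filter_counts") <- c(
    input = nrow(alignments), kept = sum(keep),
    multimapped = sum(!no_evidence & !alignments$unique),
    spliced = sum(!no_evidence & alignments$unique & alignments$spliced),
    no_evidence = sum(no_evidence)
  )
  out
}

#' Collapse PCR duplicates using random barcodes
#'
#' Reads whose 5' ends map to the same genomic position (and strand) are
#' duplicate candidates; among candidates sharing the same random
#' barcode exactly one read is retained (technical duplicates removed),
#' while candidates with differing random barcodes are all kept
#' (biological duplicates). The 5' end is the alignment start on the
#' plus strand and the last aligned base on the minus strand. Ties
#' within a duplicate class are broken by keeping the lexicographically
#' smallest read name, so the result is independent of input order.
#'
#' @param alignments Alignment tibble; each row must carry a parseable
#'   `rand_barcode`.
#' @return Deduplicated alignment tibble, sorted by (contig, strand,
#'   5' position, barcode).
#' @export
deduplicate <- function(alignments) {
  if (nrow(alignments) == 0) return(alignments)
  rb <- alignments$rand_barcode
  if (is.null(rb) || anyNA(rb)) {
    bad <- if (is.null(rb)) alignments$name else alignments$name[is.na(rb)]
    abort(paste0("missing random barcode for read(s): ",
                 paste(head(bad, 3), collapse = ", ")))
  }
  out <- alignments |>
    dplyr::mutate(
      five_prime = ifelse(.data$strand == "+", .data$start, .data$end - 1L)
    ) |>
    dplyr::group_by(.data$contig, .data$strand, .data$five_prime,
                    .data$rand_barcode) |>
    dplyr::slice_min(.data$name, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$contig, .data$strand, .data$five_prime,
                   .data$rand_barcode)
  dplyr::select(out, -"five_prime")
}
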