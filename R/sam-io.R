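# SAM serialization of alignment tibbles. Reading goes through Rsamtools
# (SAM is converted to BAM on the fly); writing emits minimal records
# with NM and NH tags so the file round-trips through this module.

#' Write alignments as SAM
#'
#' @param alignments Alignment tibble from [align_naive()] (or the same
#'   shape); needs name, contig, strand, start, end, mapq, n_mismatches,
#'   n_best_hits and optionally seq.
#' @param genome [Biostrings::DNAStringSet] or named integer vector of
#'   contig lengths, used for the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  lens <- if (inherits(genome, "DNAStringSet")) {
    setNames(Biostrings::width(genome), names(genome))
  } else genome
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens))
  )
  a <- alignments
  width <- a$end - a$start
  seq <- if ("seq" %in% names(a)) {
    ifelse(a$strand == "-", vapply(a$seq, reverse_complement, character(1),
                                   USE.NAMES = FALSE), a$seq)
  } else strrep("N", width)
  records <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d\tNH:i:%d",
    a$name, ifelse(a$strand == "-", 16L, 0L), a$contig, a$start + 1L,
    a$mapq, width, seq, a$n_mismatches, a$n_best_hits
  )
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read alignments from SAM/BAM
#'
#' Ingests externally produced alignments into the pipeline's tibble
#' representation. An alignment is `spliced` iff its CIGAR contains a
#' skipped-region (`N`) operation. Uniqueness evidence is taken from the
#' `NH` tag when present (`NH == 1`), otherwise from
#' `MAPQ >= mapq_min`; records with neither get `unique = NA` and are
#' dropped later by [filter_alignments()] with a warning.
#'
#' @param path SAM or BAM file.
#' @param mapq_min Mapping-quality threshold accepted as uniqueness
#'   evidence when no `NH` tag is present.
#' @return Alignment tibble (name, contig, strand, start, end,
#'   n_mismatches, n_best_hits, unique, spliced, mapq, seq,
#'   rand_barcode), 0-based half-open.
#' @export
read_sam <- function(path, mapq_min = 60L) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "seq"),
    tag = c("NH", "NM"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  ref_width <- cigar_ref_width(x$cigar)
  nh <- x$tag$NH
  nm <- x$tag$NM
  n <- length(x$qname)
  if (is.null(nh)) nh <- rep(NA_integer_, n)
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  mapq <- as.integer(x$mapq)
  unique <- ifelse(!is.na(nh), nh == 1L,
                   ifelse(!is.na(mapq) & mapq != 255L, mapq >= mapq_min, NA))
  name <- x$qname
  tibble::tibble(
    name = name,
    contig = as.character(x$rname),
    strand = as.character(x$strand),
    start = x$pos - 1L,
    end = x$pos - 1L + ref_width,
    n_mismatches = nm,
    n_best_hits = nh,
    unique = unique,
    spliced = grepl("N", x$cigar, fixed = TRUE),
    mapq = mapq,
    seq = as.character(x$seq),
    rand_barcode = parse_rand_barcode(name)
  )
}

# Reference-consumed width of CIGAR strings (ops M, D, N, =, X).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}
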