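#' Composite-barcode layout
#'
#' Describes the 9-nt read prefix of the library design: a 4-nt
#' experimental (sample) barcode at read positions 4-7 and a 5-nt random
#' barcode (UMI) split across positions 1-3 and 8-9, together with the
#' quality thresholds applied to each part: at most one experimental
#' position may fall below Phred 20, and no random position may fall
#' below Phred 17.
#'
#' @param experimental_positions 1-based read positions of the
#'   experimental barcode.
#' @param random_positions 1-based read positions of the random barcode,
#'   in the order they are concatenated.
#' @param exp_phred_min,exp_max_failures Experimental-barcode rule: drop
#'   the read when more than `exp_max_failures` positions score below
#'   `exp_phred_min`.
#' @param rand_phred_min Random-barcode rule: drop the read when any
#'   position scores below this.
#' @return A `barcode_layout` list.
#' @export
barcode_layout <- function(experimental_positions = 4:7,
                           random_positions = c(1:3, 8:9),
                           exp_phred_min = 20L,
                           exp_max_failures = 1L,
                           rand_phred_min = 17L) {
  if (length(intersect(experimental_positions, random_positions)) > 0) {
    abort("barcode position sets must be disjoint")
  }
  structure(
    list(
      experimental_positions = as.integer(experimental_positions),
      random_positions = as.integer(random_positions),
      total_prefix = max(experimental_positions, random_positions),
      exp_phred_min = as.integer(exp_phred_min),
      exp_max_failures = as.integer(exp_max_failures),
      rand_phred_min = as.integer(rand_phred_min)
    ),
    class = "barcode_layout"
  )
}

# Phred matrix over the given 1-based positions; reads must be long enough.
prefix_phred <- function(qual, positions) {
  vapply(positions, function(p) phred_at(qual, p), integer(length(qual)))
}

#' Filter reads on barcode-region base quality
#'
#' A read is dropped when more than `exp_max_failures` experimental-
#' barcode positions score below `exp_phred_min`, or when any
#' random-barcode position scores below `rand_phred_min`. Reads shorter
#' than the prefix are dropped with reason `short_prefix`.
#'
#' @param reads Tibble (name, seq, qual).
#' @param layout A [barcode_layout()].
#' @param keep_all If `TRUE`, return every read with `qc_keep` and
#'   `qc_reason` columns instead of filtering.
#' @return Filtered read tibble (default), with a `qc_counts` attribute
#'   tallying drop reasons; or the annotated full tibble if
#'   `keep_all = TRUE`.
#' @export
filter_barcode_quality <- function(reads, layout = barcode_layout(),
                                   keep_all = FALSE) {
  n <- nrow(reads)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)

  long_enough <- nchar(reads$qual) >= layout$total_prefix
  keep[!long_enough] <- FALSE
  reason[!long_enough] <- "short_prefix"

  if (any(long_enough)) {
    q <- reads$qual[long_enough]
    expm <- prefix_phred(q, layout$experimental_positions)
    randm <- prefix_phred(q, layout$random_positions)
    if (length(q) == 1) { expm <- rbind(expm); randm <- rbind(randm) }
    exp_fail <- rowSums(expm < layout$exp_phred_min) > layout$exp_max_failures
    rand_fail <- rowSums(randm < layout$rand_phred_min) > 0
    r <- rep(NA_character_, length(q))
    r[rand_fail] <- "rand_barcode_quality"
    r[exp_fail & !rand_fail] <- "exp_barcode_quality"
    keep[long_enough] <- !(exp_fail | rand_fail)
    reason[long_enough] <- r
  }

  if (keep_all) {
    return(dplyr::mutate(reads, qc_keep = keep, qc_reason = reason))
  }
  out <- reads[keep, , drop = FALSE]
  attr(out, "qc_counts") <- c(
    input = n, kept = sum(keep),
    table(factor(reason, levels = c("short_prefix", "exp_barcode_quality",
                                    "rand_barcode_quality")))
  )
  out
}

#' Demultiplex reads on the experimental barcode
#'
#' Assigns each read to the sample whose 4-nt barcode exactly equals the
#' read's experimental-barcode positions; no mismatches are tolerated, so
#' an `N` or miscalled base leaves the read unassigned.
#'
#' @param reads Tibble (name, seq, qual).
#' @param sample_sheet Named character vector (sample -> barcode) or
#'   tibble with columns sample, barcode.
#' @param layout A [barcode_layout()].
#' @param keep_all If `TRUE`, return every read with a `sample` column
#'   (`NA` = unassigned) instead of discarding unassigned reads.
#' @return Read tibble with a `sample` column; unassigned reads are
#'   discarded (and counted in the `demux_counts` attribute) unless
#'   `keep_all = TRUE`.
#' @export
demultiplex <- function(reads, sample_sheet, layout = barcode_layout(),
                        keep_all = FALSE) {
  sheet <- as_sample_sheet(sample_sheet)
  if (anyDuplicated(sheet$barcode)) {
    abort("sample sheet contains duplicate barcodes")
  }
  obs <- observed_barcode(reads$seq, layout$experimental_positions)
  sample <- sheet$sample[match(obs, sheet$barcode)]
  if (keep_all) {
    return(dplyr::mutate(reads, sample = sample))
  }
  out <- dplyr::mutate(reads, sample = sample)[!is.na(sample), , drop = FALSE]
  attr(out, "demux_counts") <- c(
    input = nrow(reads), assigned = sum(!is.na(sample)),
    unassigned = sum(is.na(sample))
  )
  out
}

as_sample_sheet <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("sample", "barcode") %in% names(x)))
    tibble::as_tibble(x[c("sample", "barcode")])
  } else {
    tibble::tibble(sample = names(x), barcode = unname(x))
  }
}

observed_barcode <- function(seq, positions) {
  parts <- lapply(positions, function(p) substr(seq, p, p))
  do.call(paste0, parts)
}

#' Trim the 3' adapter from read ends
#'
#' Removes the longest 3'-terminal read suffix that matches a prefix of
#' the adapter with a mismatch fraction of at most `max_error_rate` and
#' an overlap of at least `min_overlap` nucleotides; qualities are
#' trimmed in lockstep. The search is anchored at the read end (the
#' library reads into the 3' adapter); internal occurrences are not
#' searched.
#'
#' @param reads Tibble (name, seq, qual).
#' @param adapter Adapter sequence (non-empty).
#' @param max_error_rate Maximum mismatch fraction within the overlap.
#' @param min_overlap Minimum overlap in nt.
#' @return Read tibble with trimmed seq and qual.
#' @export
trim_adapter <- function(reads, adapter, max_error_rate = 0.1,
                         min_overlap = 1L) {
  if (!is.character(adapter) || nchar(adapter) == 0) {
    abort("`adapter` must be a non-empty string")
  }
  araw <- charToRaw(adapter)
  eps <- sqrt(.Machine$double.eps)
  trim_len <- vapply(reads$seq, function(s) {
    rraw <- charToRaw(s)
    n <- length(rraw)
    for (L in seq(min(n, length(araw)), min_overlap)) {
      if (L < 1) break
      mism <- sum(rraw[(n - L + 1):n] != araw[1:L])
      if (mism / L <= max_error_rate + eps) return(L)
    }
    0L
  }, integer(1), USE.NAMES = FALSE)
  keep_len <- nchar(reads$seq) - trim_len
  dplyr::mutate(reads,
    seq = substr(.data$seq, 1, keep_len),
    qual = substr(.data$qual, 1, keep_len)
  )
}

#' Move the barcode prefix into the read name
#'
#' Removes the 9-nt composite prefix and appends both barcode strings to
#' the read name as parseable fields (`__exp=XXXX__rand=XXXXX`); the
#' random barcode is reconstructed by concatenating its positions in
#' layout order. The fields survive FASTQ and SAM round trips (no
#' whitespace).
#'
#' @param reads Tibble (name, seq, qual); every read must span the prefix.
#' @param layout A [barcode_layout()].
#' @return Read tibble with prefix-free seq/qual, amended names, and
#'   `exp_barcode` / `rand_barcode` columns.
#' @export
relocate_barcode <- function(reads, layout = barcode_layout()) {
  if (any(nchar(reads$seq) < layout$total_prefix)) {
    abort("reads shorter than the barcode prefix must be dropped upstream")
  }
  exp_bc <- observed_barcode(reads$seq, layout$experimental_positions)
  rand_bc <- observed_barcode(reads$seq, layout$random_positions)
  k <- layout$total_prefix
  dplyr::mutate(reads,
    name = paste0(.data$name, "__exp=", exp_bc, "__rand=", rand_bc),
    seq = substr(.data$seq, k + 1L, nchar(.data$seq)),
    qual = substr(.data$qual, k + 1L, nchar(.data$qual)),
    exp_barcode = exp_bc,
    rand_barcode = rand_bc
  )
}

# Extract the random-barcode field from amended read names.
parse_rand_barcode <- function(name) {
  m <- regmatches(name, regexpr("__rand=[ACGTN]+", name))
  out <- rep(NA_character_, length(name))
  hit <- grepl("__rand=[ACGTN]+", name)
  out[hit] <- sub("^__rand=", "", m)
  out
}

#' Remove short inserts
#'
#' Retains reads whose barcode-free insert is at least `min_len`
#' nucleotides; "shorter than 15 nt" is read strictly, so a 15-nt insert
#' is kept.
#'
#' @param reads Tibble (name, seq, qual).
#' @param min_len Minimum insert length in nt.
#' @return Filtered read tibble.
#' @export
length_filter <- function(reads, min_len = 15L) {
  reads[nchar(reads$seq) >= min_len, , drop = FALSE]
}

#' Run the full read-preprocessing pipeline
#'
#' Applies, in order: barcode-region quality filtering, exact-match
#' demultiplexing, 3' adapter trimming, barcode relocation into the read
#' name, and the minimum-insert-length filter.
#'
#' @param reads Tibble (name, seq, qual).
#' @param sample_sheet Named vector or tibble (sample, barcode).
#' @param adapter 3' adapter sequence.
#' @param layout A [barcode_layout()].
#' @param min_len Minimum insert length (nt).
#' @return Tibble of preprocessed reads with `sample`, `exp_barcode` and
#'   `rand_barcode` columns; a `preprocess_log` attribute records
#'   per-stage read counts.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 2, barcode_map = c(s1 = "ACGT"))
#' sim <- simulate_iclip_reads(cfg, generate_reference(cfg))
#' pp <- preprocess_reads(sim$reads, cfg$barcode_map, cfg$adapter_seq)
#' attr(pp, "preprocess_log")
#' @export
preprocess_reads <- function(reads, sample_sheet, adapter,
                             layout = barcode_layout(), min_len = 15L) {
  log <- list(input = nrow(reads))
  out <- filter_barcode_quality(reads, layout)
  log$after_quality_filter <- nrow(out)
  out <- demultiplex(out, sample_sheet, layout)
  log$after_demultiplex <- nrow(out)
  out <- trim_adapter(out, adapter)
  out <- relocate_barcode(out, layout)
  out <- length_filter(out, min_len)
  log$after_length_filter <- nrow(out)
  attr(out, "preprocess_log") <- log
  out
}
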