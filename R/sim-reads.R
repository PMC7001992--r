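#' Simulate multiplexed iCLIP reads with ground truth
#'
#' Draws crosslinked molecules per sample and gene under a truncation
#' model: crosslink events arise Poisson-distributed at `signal_rate` per
#' nucleotide inside true binding sites and `background_rate` per exonic
#' nucleotide elsewhere. Reverse transcription truncates at the
#' crosslinked nucleotide, so the cDNA insert starts one nucleotide
#' downstream (in transcript orientation) of the crosslink. Each molecule
#' receives a random 5-nt barcode and `1 + Poisson(duplication_rate)` PCR
#' copies; every copy becomes one read laid out as
#' `rand[1:3] + experimental barcode + rand[4:5] + insert + adapter`,
#' truncated to `read_length`. Base qualities follow a two-state model:
#' Phred 38, or Phred 10-19 with probability `corruption_prob` per
#' position.
#'
#' @param config A [sim_config()].
#' @param reference A [generate_reference()] result built from the same
#'   config.
#' @return List with elements:
#'   * `reads`: tibble (name, seq, qual); read names are
#'     `m<molecule>/<copy>` so every read traces to one molecule row,
#'   * `molecules`: ground-truth tibble (molecule, sample, gene_id,
#'     contig, strand, xl_pos, random_barcode, n_copies, in_site),
#'     where `xl_pos` is the 0-based genomic position of the crosslinked
#'     nucleotide.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 2,
#'                   barcode_map = c(s1 = "ACGT"), duplication_rate = 0)
#' ref <- generate_reference(cfg)
#' sim <- simulate_iclip_reads(cfg, ref)
#' nrow(sim$reads) == nrow(sim$molecules)
#' @export
simulate_iclip_reads <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"),
            inherits(reference, "sim_reference"))
  if (length(config$barcode_map) == 0) {
    abort("`barcode_map` must contain at least one sample")
  }
  with_seed(config$seed, {
    mols <- draw_molecules(config, reference)
    reads <- emit_reads(config, reference, mols)
    list(reads = reads, molecules = mols)
  })
}

draw_molecules <- function(config, reference) {
  out <- list()
  contig_len <- setNames(Biostrings::width(reference$genome),
                         names(reference$genome))
  for (sample_name in names(config$barcode_map)) {
    for (g in seq_len(nrow(reference$genes))) {
      gene <- reference$genes[g, ]
      exons <- dplyr::filter(reference$exons, .data$gene_id == gene$gene_id)
      sites <- dplyr::filter(reference$sites, .data$gene_id == gene$gene_id)
      exonic <- unlist(lapply(seq_len(nrow(exons)), function(k) {
        seq(exons$start[k], exons$end[k] - 1L)
      }))
      in_site <- positions_in_intervals(exonic, sites)
      rate <- ifelse(in_site, config$signal_rate, config$background_rate)
      n_events <- rpois(length(exonic), rate)
      idx <- rep(seq_along(exonic), n_events)
      if (length(idx) == 0) next
      out[[length(out) + 1]] <- tibble::tibble(
        sample = sample_name,
        gene_id = gene$gene_id,
        contig = gene$contig,
        strand = gene$strand,
        xl_pos = exonic[idx],
        in_site = in_site[idx]
      )
    }
  }
  mols <- dplyr::bind_rows(out)
  if (nrow(mols) == 0) {
    return(tibble::tibble(
      molecule = integer(), sample = character(), gene_id = character(),
      contig = character(), strand = character(), xl_pos = integer(),
      random_barcode = character(), n_copies = integer(), in_site = logical()
    ))
  }
  mols$molecule <- seq_len(nrow(mols))
  mols$random_barcode <- vapply(seq_len(nrow(mols)),
                                function(i) random_dna(5), character(1))
  mols$n_copies <- 1L + rpois(nrow(mols), config$duplication_rate)
  dplyr::relocate(mols, "molecule")
}

emit_reads <- function(config, reference, mols) {
  if (nrow(mols) == 0) {
    return(tibble::tibble(name = character(), seq = character(),
                          qual = character()))
  }
  contig_len <- setNames(Biostrings::width(reference$genome),
                         names(reference$genome))
  ins_len <- resample(
    seq(config$insert_length_range[1], config$insert_length_range[2]),
    nrow(mols), replace = TRUE
  )
  inserts <- character(nrow(mols))
  for (i in seq_len(nrow(mols))) {
    m <- mols[i, ]
    len <- contig_len[[m$contig]]
    if (m$strand == "+") {
      s <- m$xl_pos + 1L
      e <- min(s + ins_len[i], len)
      if (e <= s) { inserts[i] <- ""; next }
      inserts[i] <- as.character(Biostrings::subseq(
        reference$genome[[m$contig]], start = s + 1L, end = e))
    } else {
      e <- m$xl_pos               # half-open end (crosslink excluded)
      s <- max(e - ins_len[i], 0L)
      if (e <= s) { inserts[i] <- ""; next }
      inserts[i] <- reverse_complement(as.character(Biostrings::subseq(
        reference$genome[[m$contig]], start = s + 1L, end = e)))
    }
  }

  exp_bc <- config$barcode_map[mols$sample]
  prefix <- paste0(
    substr(mols$random_barcode, 1, 3), exp_bc,
    substr(mols$random_barcode, 4, 5)
  )
  full <- substr(paste0(prefix, inserts, config$adapter_seq),
                 1, config$read_length)

  copy_of <- rep(seq_len(nrow(mols)), mols$n_copies)
  copy_no <- sequence(mols$n_copies)
  seqs <- full[copy_of]
  quals <- vapply(nchar(seqs), sim_quality_string,
                  character(1), corruption_prob = config$corruption_prob)
  tibble::tibble(
    name = sprintf("m%d/%d", mols$molecule[copy_of], copy_no),
    seq = seqs,
    qual = quals
  )
}

# Two-state quality model: high state Phred 38, corrupted state uniform
# on 10..19 with probability `corruption_prob` per position.
sim_quality_string <- function(n, corruption_prob) {
  if (n == 0) return("")
  bad <- runif(n) < corruption_prob
  scores <- ifelse(bad, resample(10:19, n, replace = TRUE), 38L)
  intToUtf8(scores + 33L)
}
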