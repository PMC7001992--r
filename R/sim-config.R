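#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' emulate the experimental design the pipeline was written for: a
#' multiplexed iCLIP library of 75-nt single-end reads carrying a 9-nt
#' composite barcode (4-nt experimental barcode at read positions 4-7,
#' 5-nt random barcode at positions 1-3 and 8-9), with six bait replicates
#' and one control sample, crosslink-truncated reads piling up at binding
#' sites ten-fold over the exonic background, and PCR amplification
#' producing on average one extra copy per molecule.
#'
#' @param seed Integer seed; a fixed seed makes every generated artifact
#'   byte-identical across runs.
#' @param n_genes Number of simulated genes (one per contig).
#' @param exon_count_range Integer pair, inclusive range of exons per gene.
#' @param exon_length_range Integer pair, inclusive range of exon lengths
#'   (nt). The last exon is drawn at least `utr3_length` long so the
#'   annotated 3'UTR fits inside it.
#' @param utr3_length 3'UTR length in nt, annotated at the 3' end of the
#'   terminal exon.
#' @param n_true_sites_per_gene True binding sites planted per gene.
#' @param site_width Width of each true site (nt).
#' @param signal_rate Expected crosslink events per site nucleotide.
#' @param background_rate Expected crosslink events per exonic nucleotide
#'   outside sites. The default signal:background ratio of 10 is the
#'   regime the site-recovery checks are calibrated to.
#' @param duplication_rate Mean number of *extra* PCR copies per molecule
#'   (copies = 1 + Poisson(`duplication_rate`)), so 0 means no duplication.
#' @param read_length Sequenced read length in nt (default 75).
#' @param insert_length_range Integer pair, range of cDNA insert lengths
#'   (nt) between barcode prefix and adapter.
#' @param barcode_map Named character vector, sample name -> 4-nt
#'   experimental barcode.
#' @param adapter_seq 3' adapter sequence appended to reads. The library
#'   adapter is not dictated by the assay; the default is a common
#'   single-end sequencing adapter prefix and is fully configurable.
#' @param corruption_prob Per-position probability that a base quality is
#'   drawn from the corrupted state (Phred 10-19) instead of the high
#'   state (Phred 38); exercises both barcode QC rules.
#' @param padding Flanking non-genic sequence per contig (nt).
#' @param intron_length_range Integer pair, range of intron lengths (nt).
#' @param ribosomal_genes Number of genes flagged ribosomal (excluded from
#'   SOB scoring downstream).
#' @param lfq Sub-configuration from [lfq_config()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_reference()], [simulate_iclip_reads()],
#'   [simulate_lfq_matrix()]
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 12L,
                       exon_count_range = c(1L, 3L),
                       exon_length_range = c(350L, 600L),
                       utr3_length = 300L,
                       n_true_sites_per_gene = 2L,
                       site_width = 9L,
                       signal_rate = 1.0,
                       background_rate = 0.1,
                       duplication_rate = 1.0,
                       read_length = 75L,
                       insert_length_range = c(20L, 40L),
                       barcode_map = default_barcode_map(),
                       adapter_seq = "AGATCGGAAGAGC",
                       corruption_prob = 0,
                       padding = 150L,
                       intron_length_range = c(60L, 150L),
                       ribosomal_genes = 0L,
                       lfq = lfq_config()) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    exon_count_range = as.integer(exon_count_range),
    exon_length_range = as.integer(exon_length_range),
    utr3_length = as.integer(utr3_length),
    n_true_sites_per_gene = as.integer(n_true_sites_per_gene),
    site_width = as.integer(site_width),
    signal_rate = signal_rate, background_rate = background_rate,
    duplication_rate = duplication_rate,
    read_length = as.integer(read_length),
    insert_length_range = as.integer(insert_length_range),
    barcode_map = barcode_map, adapter_seq = adapter_seq,
    corruption_prob = corruption_prob, padding = as.integer(padding),
    intron_length_range = as.integer(intron_length_range),
    ribosomal_genes = as.integer(ribosomal_genes),
    lfq = lfq
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' LFQ simulation sub-configuration
#'
#' Parameters for the synthetic label-free quantification (LFQ)
#' protein-group matrix: two conditions (bait IP vs control) with three
#' replicates each, a minority of truly enriched proteins at a known log2
#' fold change, and missing-not-at-random dropout whose probability
#' decreases logistically with log2 abundance (left censoring).
#'
#' @param n_proteins Protein groups with real quantifications.
#' @param n_contaminants Rows flagged as contaminants.
#' @param n_reverse Rows flagged as reverse (decoy) hits.
#' @param n_only_by_site Rows flagged "only identified by site".
#' @param n_enriched Truly enriched proteins among `n_proteins`.
#' @param true_log2fc True log2 fold change of enriched proteins
#'   (IP over control).
#' @param replicates Replicates per condition.
#' @param base_mean,base_sd Mean and SD of per-protein baseline log2
#'   abundance (typical MaxQuant LFQ intensities span roughly 2^22-2^32).
#' @param noise_sd Replicate-level measurement SD on the log2 scale.
#' @param missing_mid Log2 abundance at which dropout probability is 0.5;
#'   the default sits two baseline SDs below the typical abundance,
#'   modelling a detection limit that censors only the left tail.
#' @param missing_scale Logistic scale of the dropout curve (log2 units);
#'   dropout probability is `plogis((missing_mid - x) / missing_scale)`.
#'   The default is sharp, as a limit of detection is on the log scale:
#'   dropout is concentrated in the left abundance tail, matching the
#'   left-censoring assumption behind low-value imputation.
#' @param low_peptide_frac Fraction of background (non-enriched) rows
#'   given peptide counts failing the two-peptide/one-unique filter, to
#'   exercise it; spiked enriched proteins always carry full evidence so
#'   the enrichment ground truth stays the recovery target.
#'
#' @return An object of class `lfq_config`.
#' @export
lfq_config <- function(n_proteins = 500L,
                       n_contaminants = 20L,
                       n_reverse = 10L,
                       n_only_by_site = 5L,
                       n_enriched = 25L,
                       true_log2fc = 3,
                       replicates = 3L,
                       base_mean = 25,
                       base_sd = 2,
                       noise_sd = 0.3,
                       missing_mid = 21,
                       missing_scale = 0.5,
                       low_peptide_frac = 0.05) {
  if (n_enriched > n_proteins) {
    abort("`n_enriched` must not exceed `n_proteins`")
  }
  if (replicates < 1) abort("`replicates` must be >= 1")
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      n_contaminants = as.integer(n_contaminants),
      n_reverse = as.integer(n_reverse),
      n_only_by_site = as.integer(n_only_by_site),
      n_enriched = as.integer(n_enriched),
      true_log2fc = true_log2fc, replicates = as.integer(replicates),
      base_mean = base_mean, base_sd = base_sd, noise_sd = noise_sd,
      missing_mid = missing_mid, missing_scale = missing_scale,
      low_peptide_frac = low_peptide_frac
    ),
    class = "lfq_config"
  )
}

#' Default experimental barcode map
#'
#' Six bait replicates plus one control sample, mirroring the multiplexed
#' library design the pipeline targets. Barcodes are distinct 4-mers.
#'
#' @return Named character vector sample -> 4-nt barcode.
#' @export
default_barcode_map <- function() {
  c(
    bait_rep1 = "ACGT", bait_rep2 = "CGTA", bait_rep3 = "GTAC",
    bait_rep4 = "TACG", bait_rep5 = "AACC", bait_rep6 = "GGTT",
    ctrl_rep1 = "CCAA"
  )
}

validate_sim_config <- function(cfg) {
  rates <- c(cfg$signal_rate, cfg$background_rate, cfg$duplication_rate,
             cfg$corruption_prob)
  if (any(rates < 0)) abort("all rates must be >= 0")
  if (cfg$site_width > cfg$exon_length_range[1]) {
    abort("`site_width` exceeds the shortest possible exon")
  }
  if (cfg$utr3_length > cfg$exon_length_range[2]) {
    abort("`utr3_length` exceeds the longest possible exon")
  }
  bc <- cfg$barcode_map
  if (length(bc) > 0) {
    if (anyDuplicated(bc)) abort("experimental barcodes must be distinct")
    if (any(nchar(bc) != 4) || any(grepl("[^ACGT]", bc))) {
      abort("experimental barcodes must be 4-nt ACGT strings")
    }
    if (is.null(names(bc)) || any(names(bc) == "")) {
      abort("`barcode_map` must be a named vector (sample -> barcode)")
    }
  }
  if (!grepl("^[ACGT]+$", cfg$adapter_seq)) {
    abort("`adapter_seq` must be a non-empty ACGT string")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " genes:", x$n_genes,
      " sites/gene:", x$n_true_sites_per_gene, "\n")
  cat("  signal rate:", x$signal_rate, "/site-nt  background rate:",
      x$background_rate, "/exon-nt\n")
  cat("  samples:", paste(names(x$barcode_map), collapse = ", "), "\n")
  invisible(x)
}
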