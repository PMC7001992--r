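# Small simulation setups shared across tests.

tiny_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, n_genes = 3,
               barcode_map = c(s1 = "ACGT", s2 = "CGTA"), ...)
  if (!"n_true_sites_per_gene" %in% names(args)) {
    args$n_true_sites_per_gene <- 2
  }
  do.call(sim_config, args)
}

# Make a quality string of given Phred scores.
qual_string <- function(scores) intToUtf8(scores + 33L)

# A read tibble from raw vectors.
read_tbl <- function(seq, qual = strrep("I", nchar(seq)),
                     name = sprintf("r%d", seq_along(seq))) {
  tibble::tibble(name = name, seq = seq, qual = qual)
}

# Build a crosslink track tibble quickly.
track_tbl <- function(contig, strand, pos, count) {
  tibble::tibble(contig = contig, strand = strand,
                 pos = as.integer(pos), count = as.integer(count))
}

# Ground-truth track: one event per distinct (position, barcode) class of
# the molecule table for one sample (what a perfect pipeline recovers).
truth_track <- function(molecules, samples = unique(molecules$sample)) {
  m <- molecules[molecules$sample %in% samples, ]
  m <- unique(m[c("contig", "strand", "xl_pos", "random_barcode")])
  agg <- dplyr::count(m, contig, strand, xl_pos, name = "count")
  agg <- dplyr::rename(agg, pos = "xl_pos")
  dplyr::arrange(agg, contig, strand, pos)
}
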