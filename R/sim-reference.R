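#' Generate a synthetic genome, gene models and true binding sites
#'
#' Builds one random contig per gene: flanking padding, exons separated by
#' introns, a 3'UTR annotated at the transcript 3' end of the terminal
#' exon, and `n_true_sites_per_gene` binding-site intervals planted fully
#' inside exons. All coordinates are 0-based half-open genomic intervals.
#' Output is byte-identical for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_reference` with elements:
#'   * `genome`: [Biostrings::DNAStringSet] of contig sequences,
#'   * `genes`: tibble (gene_id, contig, strand, start, end, utr3_start,
#'     utr3_end, ribosomal),
#'   * `exons`: tibble (gene_id, contig, strand, start, end),
#'   * `sites`: tibble (site_id, gene_id, contig, strand, start, end) —
#'     the ground-truth binding sites.
#' @examples
#' ref <- generate_reference(sim_config(seed = 1, n_genes = 2))
#' ref$genes
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genes <- list(); exons <- list(); sites <- list(); seqs <- character(0)
    for (i in seq_len(config$n_genes)) {
      g <- build_gene(config, i)
      genes[[i]] <- g$gene
      exons[[i]] <- g$exons
      sites[[i]] <- g$sites
      seqs[g$gene$contig] <- g$seq
    }
    out <- list(
      genome = Biostrings::DNAStringSet(seqs),
      genes = dplyr::bind_rows(genes),
      exons = dplyr::bind_rows(exons),
      sites = dplyr::bind_rows(sites)
    )
    if (nrow(out$sites) > 0) {
      out$sites$site_id <- sprintf("site_%03d", seq_len(nrow(out$sites)))
      out$sites <- dplyr::relocate(out$sites, "site_id")
    } else {
      out$sites <- tibble::tibble(
        site_id = character(), gene_id = character(), contig = character(),
        strand = character(), start = integer(), end = integer()
      )
    }
    structure(out, class = "sim_reference")
  })
}

build_gene <- function(config, i) {
  gene_id <- sprintf("gene_%03d", i)
  contig <- sprintf("chr_%03d", i)
  strand <- resample(c("+", "-"), 1)
  n_exon <- resample(seq(config$exon_count_range[1], config$exon_count_range[2]), 1)
  exon_len <- resample(
    seq(config$exon_length_range[1], config$exon_length_range[2]),
    n_exon, replace = TRUE
  )
  # terminal exon (transcript orientation) must hold the annotated 3'UTR
  term <- if (strand == "+") n_exon else 1L
  exon_len[term] <- max(exon_len[term], config$utr3_length)
  intron_len <- if (n_exon > 1) {
    resample(seq(config$intron_length_range[1], config$intron_length_range[2]),
             n_exon - 1, replace = TRUE)
  } else integer(0)

  starts <- integer(n_exon)
  pos <- config$padding
  for (k in seq_len(n_exon)) {
    starts[k] <- pos
    pos <- pos + exon_len[k]
    if (k < n_exon) pos <- pos + intron_len[k]
  }
  ends <- starts + exon_len
  contig_len <- pos + config$padding
  seq <- random_dna(contig_len)

  utr3 <- if (strand == "+") {
    c(ends[n_exon] - config$utr3_length, ends[n_exon])
  } else {
    c(starts[1], starts[1] + config$utr3_length)
  }

  sites <- plant_sites(config, exon_starts = starts, exon_ends = ends)
  n_sites <- nrow(sites)
  gene <- tibble::tibble(
    gene_id = gene_id, contig = contig, strand = strand,
    start = starts[1], end = ends[n_exon],
    utr3_start = utr3[1], utr3_end = utr3[2],
    ribosomal = i <= config$ribosomal_genes
  )
  exons <- tibble::tibble(
    gene_id = gene_id, contig = contig, strand = strand,
    start = starts, end = ends
  )
  if (n_sites > 0) {
    sites <- dplyr::mutate(sites, gene_id = gene_id, contig = contig,
                           strand = strand, .before = 1)
  } else {
    sites <- tibble::tibble(gene_id = character(), contig = character(),
                            strand = character(), start = integer(),
                            end = integer())
  }
  list(gene = gene, exons = exons, sites = sites, seq = seq)
}

# Sample disjoint site intervals fully inside single exons.
plant_sites <- function(config, exon_starts, exon_ends) {
  n <- config$n_true_sites_per_gene
  w <- config$site_width
  if (n == 0) return(tibble::tibble(start = integer(), end = integer()))
  # candidate start positions: any exonic position with the site fitting
  cand <- unlist(lapply(seq_along(exon_starts), function(k) {
    if (exon_ends[k] - exon_starts[k] >= w) {
      seq(exon_starts[k], exon_ends[k] - w)
    } else integer(0)
  }))
  if (length(cand) == 0) abort("`site_width` larger than every exon")
  for (attempt in 1:50) {
    st <- sort(resample(cand, min(n, length(cand))))
    if (all(diff(st) >= w)) {
      return(tibble::tibble(start = as.integer(st), end = as.integer(st + w)))
    }
  }
  # fall back to a greedy disjoint subset of the last draw
  keep <- st[c(TRUE, diff(st) >= w)]
  tibble::tibble(start = as.integer(keep), end = as.integer(keep + w))
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("<sim_reference> ", length(x$genome), " contigs, ",
      nrow(x$genes), " genes, ", nrow(x$sites), " true sites\n", sep = "")
  invisible(x)
}
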