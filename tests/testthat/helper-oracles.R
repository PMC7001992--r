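# Independent brute-force oracles used to freeze expected values.

# Barcode-QC decision computed directly from the stated rule on a vector
# of nine Phred scores.
oracle_barcode_qc <- function(phred9, exp_pos = 4:7, rand_pos = c(1:3, 8:9),
                              exp_min = 20, exp_max_fail = 1, rand_min = 17) {
  exp_fails <- sum(phred9[exp_pos] < exp_min)
  rand_fails <- sum(phred9[rand_pos] < rand_min)
  !(exp_fails > exp_max_fail || rand_fails > 0)
}

# Benjamini-Hochberg adjustment from the definition:
# adj_(i) = min_{j >= i} min(1, n * p_(j) / j) on sorted p-values.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    adj_sorted[i] <- min(1, min(n * ps[i:n] / (i:n)))
  }
  adj <- numeric(n)
  adj[o] <- adj_sorted
  adj
}

# Longest 3'-anchored adapter overlap by brute force over all suffix
# lengths.
oracle_trim_length <- function(seq, adapter, rate = 0.1, min_overlap = 1) {
  n <- nchar(seq)
  best <- 0L
  for (L in seq_len(min(n, nchar(adapter)))) {
    if (L < min_overlap) next
    suffix <- substr(seq, n - L + 1, n)
    prefix <- substr(adapter, 1, L)
    mism <- sum(strsplit(suffix, "")[[1]] != strsplit(prefix, "")[[1]])
    if (mism / L <= rate + 1e-12) best <- L
  }
  best
}

# SOB by exhaustive enumeration of every exonic nucleotide of a gene.
oracle_sob <- function(track, reference, sites, flank = 5,
                       min_background = 10, past_site = 10,
                       no_site_utr3 = 500) {
  res <- list()
  for (g in seq_len(nrow(reference$genes))) {
    gene <- reference$genes[g, ]
    gsites <- sites[!is.na(sites$gene_id) & sites$gene_id == gene$gene_id, ]
    if (nrow(gsites) == 0) next
    exons <- reference$exons[reference$exons$gene_id == gene$gene_id, ]
    exonic <- sort(unique(unlist(
      mapply(function(s, e) seq(s, e - 1), exons$start, exons$end,
             SIMPLIFY = FALSE)
    )))
    # 3'UTR truncation
    utr_sites <- gsites[gsites$start < gene$utr3_end &
                          gsites$end > gene$utr3_start, ]
    if (gene$strand == "+") {
      cut <- if (nrow(utr_sites) > 0) {
        min(gene$utr3_end, max(utr_sites$end) + past_site)
      } else min(gene$utr3_end, gene$utr3_start + no_site_utr3)
      exonic <- exonic[exonic < cut]
    } else {
      cut <- if (nrow(utr_sites) > 0) {
        max(gene$utr3_start, min(utr_sites$start) - past_site)
      } else max(gene$utr3_start, gene$utr3_end - no_site_utr3)
      exonic <- exonic[exonic >= cut]
    }
    count_at <- function(p) {
      i <- track$contig == gene$contig & track$strand == gene$strand &
        track$pos == p
      if (any(i)) sum(track$count[i]) else 0
    }
    in_any <- function(p, st, en) any(p >= st & p < en)
    bg <- 0
    for (p in exonic) {
      if (!in_any(p, gsites$start - flank, gsites$end + flank)) {
        bg <- bg + count_at(p)
      }
    }
    rate <- bg / length(exonic)
    for (i in seq_len(nrow(gsites))) {
      site_events <- sum(vapply(seq(gsites$start[i], gsites$end[i] - 1),
                                count_at, numeric(1)))
      excluded <- isTRUE(gene$ribosomal) || bg < min_background
      res[[length(res) + 1]] <- tibble::tibble(
        site_id = gsites$site_id[i],
        sob = if (excluded) NA_real_ else site_events / rate,
        excluded = excluded
      )
    }
  }
  dplyr::bind_rows(res)
}

# Ungapped Hamming scan of both strands of a small genome.
oracle_align <- function(seq, genome, max_mismatch = 2) {
  hits <- list()
  for (ct in names(genome)) {
    subject <- as.character(genome[[ct]])
    L <- nchar(seq)
    n <- nchar(subject)
    if (L > n) next
    sv <- strsplit(subject, "")[[1]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") seq else {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
      }
      qv <- strsplit(q, "")[[1]]
      for (s in 0:(n - L)) {
        mism <- sum(sv[(s + 1):(s + L)] != qv)
        if (mism <= max_mismatch) {
          hits[[length(hits) + 1]] <- tibble::tibble(
            contig = ct, strand = strand, start = s, end = s + L,
            n_mismatches = mism
          )
        }
      }
    }
  }
  dplyr::bind_rows(hits)
}
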