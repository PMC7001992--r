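#' Positional 2-mer profile around binding-site midpoints
#'
#' Centers each site at its midpoint (for even widths, the lower-median
#' position), extends a symmetric window `window` nt up- and downstream
#' in transcript orientation, and reports for every offset the mean
#' occurrence of each homopolymeric 2-mer (AA, CC, GG, TT) read on the
#' gene's sense strand. Sites whose window (plus the trailing base of
#' the 2-mer) falls off the contig are dropped with a warning. Intended
#' for sites restricted to 3'UTRs (see [sites_in_utr3()]).
#'
#' @param sites Site tibble (contig, strand, start, end).
#' @param genome [Biostrings::DNAStringSet].
#' @param window Half-window in nt (offsets `-window .. +window`).
#' @param dimers 2-mers to profile; `"all"` expands to all 16
#'   dinucleotides (their positional means sum to 1).
#' @return Tibble (offset, dimer, occurrence) of class `dimer_profile`;
#'   occurrence is a mean over sites, in `[0, 1]`. The number of sites
#'   used is attached as attribute `n_sites`.
#' @export
dimer_profile <- function(sites, genome, window = 100L,
                          dimers = c("AA", "CC", "GG", "TT")) {
  if (identical(dimers, "all")) {
    bases <- c("A", "C", "G", "T")
    dimers <- as.vector(outer(bases, bases, paste0))
  }
  offsets <- seq(-window, window)
  empty <- tibble::tibble(offset = integer(), dimer = character(),
                          occurrence = numeric())
  if (nrow(sites) == 0) {
    warn("no sites supplied; returning an empty profile")
    return(structure(empty, class = c("dimer_profile", class(empty)),
                     n_sites = 0L))
  }

  lens <- setNames(Biostrings::width(genome), names(genome))
  width <- sites$end - sites$start
  mid <- sites$start + (width - 1L) %/% 2L
  ok <- ifelse(
    sites$strand == "+",
    mid - window >= 0L & mid + window + 2L <= lens[sites$contig],
    mid - window - 1L >= 0L & mid + window + 1L <= lens[sites$contig]
  )
  if (any(!ok)) {
    warn(sprintf("%d site window(s) clipped at contig ends were dropped",
                 sum(!ok)))
  }
  s <- sites[ok, , drop = FALSE]
  mid <- mid[ok]
  if (nrow(s) == 0) {
    return(structure(empty, class = c("dimer_profile", class(empty)),
                     n_sites = 0L))
  }

  # sense-strand window string; transcript offset p's 2-mer starts at
  # string index p + window + 1 for both strands
  win <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    if (s$strand[i] == "+") {
      win[i] <- as.character(Biostrings::subseq(
        genome[[s$contig[i]]], start = mid[i] - window + 1L,
        end = mid[i] + window + 2L))
    } else {
      win[i] <- reverse_complement(as.character(Biostrings::subseq(
        genome[[s$contig[i]]], start = mid[i] - window,
        end = mid[i] + window + 1L)))
    }
  }

  rows <- lapply(seq_along(offsets), function(k) {
    mer <- substr(win, k, k + 1L)
    occ <- vapply(dimers, function(d) mean(mer == d), numeric(1))
    tibble::tibble(offset = offsets[k], dimer = dimers,
                   occurrence = unname(occ))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("dimer_profile", class(out)),
            n_sites = nrow(s))
}
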