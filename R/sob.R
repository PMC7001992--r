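#' Effective gene extent with 3'UTR truncation
#'
#' Returns the merged exonic intervals of a gene after restricting its
#' 3'UTR: when the gene has a binding site overlapping the 3'UTR, the
#' UTR is clipped 10 nt past the 3'-most such site (in transcript
#' orientation); otherwise it is clipped 500 nt from the UTR start.
#' Clipping never lengthens an annotated UTR.
#'
#' @param gene One-row tibble from the `genes` table (gene_id, contig,
#'   strand, start, end, utr3_start, utr3_end).
#' @param exons Exon tibble for this gene (start, end).
#' @param sites Site tibble for this gene (may be empty).
#' @param past_site nt of 3'UTR kept past the last site.
#' @param no_site_utr3 nt of 3'UTR kept when no site overlaps it.
#' @return List with `intervals` (tibble start/end, merged, 0-based
#'   half-open) and `length` (total nt).
#' @export
effective_gene_extent <- function(gene, exons, sites,
                                  past_site = 10L, no_site_utr3 = 500L) {
  merged <- merge_intervals(exons$start, exons$end)
  utr_sites <- sites[sites$start < gene$utr3_end &
                       sites$end > gene$utr3_start, , drop = FALSE]
  if (gene$strand == "+") {
    cut <- if (nrow(utr_sites) > 0) {
      min(gene$utr3_end, max(utr_sites$end) + past_site)
    } else {
      min(gene$utr3_end, gene$utr3_start + no_site_utr3)
    }
    allowed <- tibble::tibble(start = 0L, end = as.integer(cut))
  } else {
    cut <- if (nrow(utr_sites) > 0) {
      max(gene$utr3_start, min(utr_sites$start) - past_site)
    } else {
      max(gene$utr3_start, gene$utr3_end - no_site_utr3)
    }
    allowed <- tibble::tibble(start = as.integer(cut),
                              end = as.integer(max(exons$end)))
  }
  intervals <- intersect_intervals(merged, allowed)
  list(intervals = intervals, length = interval_width(intervals))
}

#' Signal-over-background (SOB) per binding site, one replicate
#'
#' For each gene, the background rate is the number of crosslink events
#' inside the gene's effective exonic extent but outside every binding
#' site extended by `flank` nt to either side, divided by the merged
#' effective exon length (events per nt). A site's SOB is its crosslink
#' event count divided by that per-nucleotide background rate (units:
#' nt). Sites of ribosomal genes, and of genes with fewer than
#' `min_background` background events, are excluded with a reason.
#'
#' @param track Crosslink track tibble for one replicate.
#' @param reference A [generate_reference()] result (or list with
#'   `genes` and `exons` tables of the same shape).
#' @param sites Site tibble with `site_id` and `gene_id` columns.
#' @param flank nt added to each side of every site when excluding
#'   events from the background sum (the denominator stays the merged
#'   exon length).
#' @param min_background Minimum background events for a gene's sites to
#'   receive SOB values.
#' @param per_width If `TRUE`, additionally divide each SOB by the site
#'   width, making it a density ratio; the default reports the site
#'   event count over the background density.
#' @return Tibble (site_id, gene_id, contig, strand, start, end,
#'   site_events, background_events, background_rate, sob, excluded,
#'   reason).
#' @export
compute_sob <- function(track, reference, sites, flank = 5L,
                        min_background = 10L, per_width = FALSE) {
  stopifnot(all(c("site_id", "gene_id") %in% names(sites)))
  genes <- reference$genes
  out <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    gsites <- sites[!is.na(sites$gene_id) & sites$gene_id == gene$gene_id, ,
                    drop = FALSE]
    if (nrow(gsites) == 0) next
    gexons <- reference$exons[reference$exons$gene_id == gene$gene_id, ,
                              drop = FALSE]
    ext <- effective_gene_extent(gene, gexons, gsites)
    if (ext$length == 0) abort(paste0("zero merged length for ", gene$gene_id))
    gtrack <- track[track$contig == gene$contig &
                      track$strand == gene$strand, , drop = FALSE]
    flanked <- merge_intervals(pmax(gsites$start - flank, 0L),
                               gsites$end + flank)
    in_extent <- positions_in_intervals(gtrack$pos, ext$intervals)
    in_flanked <- positions_in_intervals(gtrack$pos, flanked)
    bg_events <- sum(gtrack$count[in_extent & !in_flanked])
    bg_rate <- bg_events / ext$length

    site_events <- vapply(seq_len(nrow(gsites)), function(i) {
      sum(gtrack$count[gtrack$pos >= gsites$start[i] &
                         gtrack$pos < gsites$end[i]])
    }, numeric(1))

    excluded <- FALSE; reason <- NA_character_
    if (isTRUE(gene$ribosomal)) {
      excluded <- TRUE; reason <- "ribosomal"
    } else if (bg_events < min_background) {
      excluded <- TRUE; reason <- "low_background"
    }
    sob <- if (excluded) rep(NA_real_, nrow(gsites)) else site_events / bg_rate
    if (!excluded && per_width) sob <- sob / (gsites$end - gsites$start)
    out[[g]] <- tibble::tibble(
      site_id = gsites$site_id, gene_id = gene$gene_id,
      contig = gene$contig, strand = gene$strand,
      start = gsites$start, end = gsites$end,
      site_events = site_events, background_events = bg_events,
      background_rate = bg_rate, sob = sob,
      excluded = excluded, reason = reason
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(
      site_id = character(), gene_id = character(), contig = character(),
      strand = character(), start = integer(), end = integer(),
      site_events = numeric(), background_events = numeric(),
      background_rate = numeric(), sob = numeric(), excluded = logical(),
      reason = character()
    )
  }
  res
}

#' Average per-replicate SOB values
#'
#' SOB is computed separately for each replicate and then averaged with
#' the arithmetic mean over the replicates where the site's gene passed
#' the exclusion rules; a site with no defined replicate stays excluded.
#'
#' @param sob_list Named list of per-replicate [compute_sob()] tibbles.
#' @return Tibble with one row per site: coordinates, one `sob_<rep>`
#'   column per replicate, `mean_sob`, `n_defined`, `excluded`,
#'   `reason`.
#' @examples
#' r1 <- tibble::tibble(site_id = "s", gene_id = "g", contig = "c",
#'                      strand = "+", start = 0L, end = 9L,
#'                      site_events = 4, background_events = 12,
#'                      background_rate = 0.01, sob = 2,
#'                      excluded = FALSE, reason = NA_character_)
#' r2 <- dplyr::mutate(r1, sob = 4)
#' average_sob(list(rep1 = r1, rep2 = r2))$mean_sob
#' @export
average_sob <- function(sob_list) {
  stopifnot(length(sob_list) >= 1)
  if (is.null(names(sob_list))) {
    names(sob_list) <- sprintf("rep%d", seq_along(sob_list))
  }
  keys <- c("site_id", "gene_id", "contig", "strand", "start", "end")
  base <- sob_list[[1]][keys]
  sob_mat <- matrix(
    unlist(lapply(sob_list, function(x) x$sob[match(base$site_id, x$site_id)])),
    nrow = nrow(base), dimnames = list(NULL, names(sob_list))
  )
  reasons <- matrix(
    unlist(lapply(sob_list,
                  function(x) x$reason[match(base$site_id, x$site_id)])),
    nrow = nrow(base), dimnames = list(NULL, names(sob_list))
  )

  n_defined <- rowSums(!is.na(sob_mat))
  mean_sob <- ifelse(n_defined > 0, rowMeans(sob_mat, na.rm = TRUE), NA_real_)
  excluded <- n_defined == 0
  reason <- apply(reasons, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) NA_character_ else r[1]
  })
  reason[!excluded] <- NA_character_

  out <- dplyr::bind_cols(
    base,
    tibble::as_tibble(setNames(as.data.frame(sob_mat),
                               paste0("sob_", names(sob_list))))
  )
  dplyr::mutate(out, mean_sob = mean_sob, n_defined = n_defined,
                excluded = excluded, reason = reason)
}

#' Full SOB table across replicates
#'
#' Convenience wrapper: runs [compute_sob()] on each replicate track and
#' averages with [average_sob()].
#'
#' @param tracks Named list of crosslink track tibbles, one per
#'   replicate.
#' @param reference A [generate_reference()] result.
#' @param sites Site tibble with `site_id` and `gene_id`.
#' @param ... Passed to [compute_sob()].
#' @return See [average_sob()].
#' @export
sob_table <- function(tracks, reference, sites, ...) {
  per_rep <- lapply(tracks, compute_sob, reference = reference,
                    sites = sites, ...)
  average_sob(per_rep)
}
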