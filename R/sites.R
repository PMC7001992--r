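#' Call binding sites from a crosslink track
#'
#' Minimal plumbing peak caller: maximal runs of positions whose
#' crosslink count reaches `min_count`, merging runs separated by at
#' most `merge_gap` sub-threshold positions. With `merge_gap = 0` runs
#' split at every below-threshold position.
#'
#' @param track Crosslink track tibble (contig, strand, pos, count).
#' @param min_count Minimum per-position event count.
#' @param merge_gap Maximum gap (nt) bridged between runs.
#' @return Site tibble (contig, strand, start, end), 0-based half-open.
#' @examples
#' track <- tibble::tibble(contig = "c", strand = "+",
#'                         pos = c(10L, 11L, 20L), count = 5L)
#' call_sites(track, min_count = 3, merge_gap = 2)
#' @export
call_sites <- function(track, min_count = 2L, merge_gap = 0L) {
  if (nrow(track) == 0) {
    abort("`track` is empty")
  }
  hot <- track[track$count >= min_count, , drop = FALSE]
  if (nrow(hot) == 0) {
    return(tibble::tibble(contig = character(), strand = character(),
                          start = integer(), end = integer()))
  }
  hot |>
    dplyr::arrange(.data$contig, .data$strand, .data$pos) |>
    dplyr::group_by(.data$contig, .data$strand) |>
    dplyr::mutate(run = cumsum(c(TRUE, diff(.data$pos) > merge_gap + 1L))) |>
    dplyr::group_by(.data$contig, .data$strand, .data$run) |>
    dplyr::summarise(start = min(.data$pos), end = max(.data$pos) + 1L,
                     .groups = "drop") |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$contig, .data$strand, .data$start)
}

#' Assign sites to genes by exonic overlap
#'
#' A site is assigned to the gene on the same contig and strand whose
#' exon span contains it; sites overlapping no gene get `NA`.
#'
#' @param sites Site tibble (contig, strand, start, end).
#' @param reference A [generate_reference()] result, or any list with
#'   `genes` shaped the same way.
#' @return `sites` with `gene_id` (and `site_id` if absent) columns.
#' @export
assign_sites_to_genes <- function(sites, reference) {
  genes <- reference$genes
  gene_id <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    hit <- genes$contig == sites$contig[i] &
      genes$strand == sites$strand[i] &
      genes$start <= sites$start[i] & sites$end[i] <= genes$end
    if (any(hit)) gene_id[i] <- genes$gene_id[which(hit)[1]]
  }
  out <- dplyr::mutate(sites, gene_id = gene_id)
  if (!"site_id" %in% names(out) && nrow(out) > 0) {
    out$site_id <- sprintf("site_%03d", seq_len(nrow(out)))
  }
  dplyr::relocate(out, dplyr::any_of(c("site_id", "gene_id")))
}

#' Restrict sites to those overlapping their gene's 3'UTR
#'
#' @param sites Site tibble with `gene_id`.
#' @param reference A [generate_reference()] result (supplies `genes`
#'   with utr3_start/utr3_end).
#' @return The subset of `sites` overlapping the annotated 3'UTR.
#' @export
sites_in_utr3 <- function(sites, reference) {
  g <- reference$genes[, c("gene_id", "utr3_start", "utr3_end")]
  dplyr::inner_join(sites, g, by = "gene_id") |>
    dplyr::filter(.data$start < .data$utr3_end,
                  .data$end > .data$utr3_start) |>
    dplyr::select(-"utr3_start", -"utr3_end")
}
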