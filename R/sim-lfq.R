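#' Simulate a label-free protein-groups matrix with ground truth
#'
#' Emulates the statistical structure of a MaxQuant protein-groups table
#' for a two-condition IP experiment (bait vs control, `replicates` runs
#' each): per-protein baseline log2 abundances, a known subset of truly
#' enriched proteins at `true_log2fc`, contaminant/reverse/only-by-site
#' flag rows, peptide and unique-peptide counts, and
#' missing-not-at-random dropout where the probability of a missing value
#' decreases logistically with log2 abundance (left censoring). Masking
#' only removes values; retained intensities are untouched.
#'
#' @param config A [sim_config()] (only `config$seed` and `config$lfq`
#'   are used).
#' @return List with elements:
#'   * `table`: tibble with columns id, contaminant, reverse,
#'     only_by_site, peptides, unique_peptides, and one raw intensity
#'     column per replicate (`ip_1..`, `ctrl_1..`; `NA` = missing),
#'   * `design`: tibble (column, condition) mapping intensity columns to
#'     conditions,
#'   * `truth`: tibble (id, enriched, true_ctrl_mean, true_ip_mean) on
#'     the log2 scale.
#' @examples
#' sim <- simulate_lfq_matrix(sim_config(seed = 1))
#' sum(sim$truth$enriched)
#' @export
simulate_lfq_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lfq <- config$lfq
  with_seed(config$seed, {
    n <- lfq$n_proteins
    ids <- sprintf("P%04d", seq_len(n))
    enriched <- seq_len(n) <= lfq$n_enriched
    ctrl_mean <- rnorm(n, lfq$base_mean, lfq$base_sd)
    ip_mean <- ctrl_mean + ifelse(enriched, lfq$true_log2fc, 0)

    flag_rows <- function(prefix, k) {
      if (k == 0) return(NULL)
      tibble::tibble(
        id = sprintf("%s%03d", prefix, seq_len(k)),
        mean = rnorm(k, lfq$base_mean, lfq$base_sd)
      )
    }
    con <- flag_rows("CON__", lfq$n_contaminants)
    rev <- flag_rows("REV__", lfq$n_reverse)
    obs <- flag_rows("SITE__", lfq$n_only_by_site)

    all_ids <- c(ids, con$id, rev$id, obs$id)
    n_all <- length(all_ids)
    ctrl_all <- c(ctrl_mean, con$mean, rev$mean, obs$mean)
    ip_all <- c(ip_mean, con$mean, rev$mean, obs$mean)

    reps <- lfq$replicates
    cols_ip <- sprintf("ip_%d", seq_len(reps))
    cols_ctrl <- sprintf("ctrl_%d", seq_len(reps))
    vals <- matrix(NA_real_, n_all, 2 * reps,
                   dimnames = list(NULL, c(cols_ip, cols_ctrl)))
    for (r in seq_len(reps)) {
      vals[, cols_ip[r]] <- ip_all + rnorm(n_all, 0, lfq$noise_sd)
      vals[, cols_ctrl[r]] <- ctrl_all + rnorm(n_all, 0, lfq$noise_sd)
    }
    # MNAR mask: dropout probability decreasing in log2 abundance
    p_miss <- stats::plogis((lfq$missing_mid - vals) / lfq$missing_scale)
    mask <- matrix(runif(length(vals)) < p_miss, n_all, 2 * reps)
    intensities <- 2^vals
    intensities[mask] <- NA_real_

    peptides <- 2L + rpois(n_all, 2)
    unique_peptides <- pmax(1L, peptides - rpois(n_all, 1))
    enriched_all <- c(enriched, rep(FALSE, n_all - n))
    low <- runif(n_all) < lfq$low_peptide_frac & !enriched_all
    peptides[low] <- 1L
    unique_peptides[low] <- 1L

    tab <- tibble::tibble(
      id = all_ids,
      contaminant = startsWith(all_ids, "CON__"),
      reverse = startsWith(all_ids, "REV__"),
      only_by_site = startsWith(all_ids, "SITE__"),
      peptides = peptides,
      unique_peptides = unique_peptides
    )
    tab <- dplyr::bind_cols(tab, tibble::as_tibble(intensities))
    design <- tibble::tibble(
      column = c(cols_ip, cols_ctrl),
      condition = rep(c("ip", "ctrl"), each = reps)
    )
    truth <- tibble::tibble(
      id = ids, enriched = enriched,
      true_ctrl_mean = ctrl_mean, true_ip_mean = ip_mean
    )
    list(table = tab, design = design, truth = truth)
  })
}
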