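#' Percentage from an event/total count pair
#'
#' `100 * events / total`, rounded half-up to the requested number of
#' decimals (the convention of printed phenotype tables). Vectorised.
#'
#' @param events Non-negative event counts.
#' @param total Positive totals; `events <= total`.
#' @param decimals Decimal places to round to.
#' @return Numeric vector of percentages.
#' @examples
#' percent_of(40, 1222)   # 3.3
#' percent_of(620, 2058)  # 30.1
#' @export
percent_of <- function(events, total, decimals = 1L) {
  if (any(total <= 0)) abort("`total` must be positive")
  if (any(events < 0) || any(events > total)) {
    abort("`events` must lie in [0, total]")
  }
  round_half_up(100 * events / total, decimals)
}

#' Hatching table from egg counts
#'
#' Adds unhatched counts and hatching percentages to a table of
#' (genotype, eggs laid, hatched) rows. Rows with zero eggs laid are
#' reported as 0.0% and flagged with `zero_total = TRUE`.
#'
#' @param counts Tibble with columns genotype, laid, hatched.
#' @param decimals Decimal places of the percentage column.
#' @return Tibble (genotype, laid, hatched, unhatched, hatching_pct,
#'   zero_total).
#' @examples
#' hatching_table(tibble::tibble(genotype = "rescue",
#'                               laid = 2120, hatched = 1690))
#' @export
hatching_table <- function(counts, decimals = 1L) {
  stopifnot(all(c("genotype", "laid", "hatched") %in% names(counts)))
  bad <- counts$hatched > counts$laid
  if (any(bad)) {
    abort(paste0("hatched exceeds laid for row(s): ",
                 paste(counts$genotype[bad], collapse = ", ")))
  }
  dplyr::mutate(counts,
    unhatched = .data$laid - .data$hatched,
    hatching_pct = ifelse(.data$laid > 0,
                          round_half_up(100 * .data$hatched / .data$laid,
                                        decimals),
                          0),
    zero_total = .data$laid == 0
  )
}

#' One-sample t-test against a null mean
#'
#' Tests whether replicate fold enrichments differ from a null value
#' (1 = no enrichment over control). Degenerate inputs with zero
#' variance are returned with `NA` statistics and `degenerate = TRUE`.
#'
#' @param values Numeric replicate values (n >= 2, finite).
#' @param null_mean Null hypothesis mean.
#' @return One-row tibble (estimate, t, df, p_value, degenerate).
#' @examples
#' one_sample_t(c(1.5, 2.0, 2.5), null_mean = 1)
#' @export
one_sample_t <- function(values, null_mean = 1) {
  if (length(values) < 2 || any(!is.finite(values))) {
    abort("`values` must hold >= 2 finite replicates")
  }
  if (sd(values) == 0) {
    # no spread: values identical to the null carry no evidence (t = 0,
    # p = 1); identical values away from the null leave t undefined
    if (values[1] == null_mean) {
      return(tibble::tibble(estimate = null_mean, t = 0,
                            df = length(values) - 1L, p_value = 1,
                            degenerate = FALSE))
    }
    return(tibble::tibble(estimate = mean(values), t = NA_real_,
                          df = length(values) - 1L, p_value = NA_real_,
                          degenerate = TRUE))
  }
  tt <- t.test(values, mu = null_mean)
  tibble::tibble(
    estimate = unname(tt$estimate), t = unname(tt$statistic),
    df = unname(tt$parameter), p_value = tt$p.value, degenerate = FALSE
  )
}

#' Per-group one-sample t-tests for fold enrichments
#'
#' Runs [one_sample_t()] within each group (e.g. per transcript in an
#' RNA-immunoprecipitation experiment). No multiple-testing correction
#' is applied unless requested via `adjust`.
#'
#' @param data Tibble of replicate measurements.
#' @param group Column (tidy-select) identifying the groups.
#' @param value Column holding the fold-enrichment values.
#' @param null_mean Null hypothesis mean.
#' @param adjust `p.adjust` method applied across groups (default
#'   `"none"`).
#' @return Tibble with one row per group: group label, n, estimate, t,
#'   df, p_value (and `p_adj` if `adjust != "none"`), degenerate.
#' @export
fold_enrichment_tests <- function(data, group, value, null_mean = 1,
                                  adjust = "none") {
  out <- data |>
    dplyr::group_by({{ group }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      res = list(one_sample_t(dplyr::pick({{ value }})[[1]],
                              null_mean = null_mean)),
      .groups = "drop"
    ) |>
    tidyr::unnest("res")
  if (adjust != "none") {
    out <- dplyr::mutate(out, p_adj = p.adjust(.data$p_value, method = adjust))
  }
  out
}
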