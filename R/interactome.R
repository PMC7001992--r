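#' Filter protein groups on flags and peptide evidence
#'
#' Removes rows flagged as contaminant, reverse (decoy) or "only
#' identified by site", and rows with insufficient peptide evidence. The
#' default requires at least two peptides and at least one unique
#' peptide (the conventional reading); `literal = TRUE` instead removes
#' only rows failing both thresholds.
#'
#' @param table Protein-groups tibble with logical columns contaminant,
#'   reverse, only_by_site and integer columns peptides,
#'   unique_peptides.
#' @param min_peptides,min_unique Peptide-evidence thresholds.
#' @param literal Use the weaker both-fail reading of the peptide rule.
#' @return Filtered tibble with a `filter_counts` attribute.
#' @export
filter_protein_groups <- function(table, min_peptides = 2L, min_unique = 1L,
                                  literal = FALSE) {
  flagged <- table$contaminant | table$reverse | table$only_by_site
  pep_ok <- if (literal) {
    !(table$peptides < min_peptides & table$unique_peptides < min_unique)
  } else {
    table$peptides >= min_peptides & table$unique_peptides >= min_unique
  }
  keep <- !flagged & pep_ok
  out <- table[keep, , drop = FALSE]
  attr(out, "filter_counts") <- c(
    input = nrow(table), kept = sum(keep), flagged = sum(flagged),
    low_evidence = sum(!flagged & !pep_ok)
  )
  out
}

#' Log2-transform intensity columns
#'
#' @param table Protein-groups tibble.
#' @param design Tibble (column, condition) naming the intensity columns.
#' @return `table` with the intensity columns replaced by their log2.
#' @export
log_transform_lfq <- function(table, design) {
  dplyr::mutate(table,
                dplyr::across(dplyr::all_of(design$column), log2))
}

#' Impute missing values from a left tail
#'
#' Replaces each missing log-scale value by `m * u`, where `m` is the
#' lowest measured value in the table and `u` is a Beta-distributed draw
#' rescaled to `[0.001, 0.015]` — i.e. imputed values lie between 0.1%
#' and 1.5% of the lowest measured value, far below the measured range,
#' encoding the assumption that missingness reflects abundances under
#' the detection limit. Measured cells are never altered. The default
#' Beta(1, 1) is uniform on the interval; the shape, the interval and
#' per-column operation are configurable.
#'
#' @param table Log-transformed protein-groups tibble (missing = `NA`).
#' @param design Tibble (column, condition).
#' @param seed Integer seed; identical seeds give identical imputations.
#' @param shape Length-2 Beta shape parameters.
#' @param range Imputation interval as fractions of the lowest measured
#'   value.
#' @param per_column If `TRUE`, use each column's own minimum.
#' @return Completed tibble; the original missingness mask is attached
#'   as attribute `measured_mask` (logical matrix, `TRUE` = measured).
#' @export
impute_missing <- function(table, design, seed, shape = c(1, 1),
                           range = c(0.001, 0.015), per_column = FALSE) {
  cols <- design$column
  vals <- as.matrix(table[cols])
  if (all(is.na(vals))) abort("all intensity values are missing")
  mask <- !is.na(vals)
  out <- with_seed(seed, {
    n_miss <- sum(!mask)
    u <- range[1] + rbeta(n_miss, shape[1], shape[2]) * diff(range)
    if (per_column) {
      mins <- apply(vals, 2, min, na.rm = TRUE)
      m <- rep(mins, each = nrow(vals))[!mask]
    } else {
      m <- min(vals, na.rm = TRUE)
    }
    vals[!mask] <- m * u
    vals
  })
  table[cols] <- tibble::as_tibble(out)
  attr(table, "measured_mask") <- mask
  table
}

#' Keep protein groups measured in enough replicates
#'
#' Retains rows with measured (pre-imputation) values in at least
#' `min_replicates` replicates of at least one condition. Evaluated on
#' the original missingness mask so that imputation cannot defeat the
#' filter.
#'
#' @param table Protein-groups tibble (imputed or not).
#' @param design Tibble (column, condition).
#' @param min_replicates Required measured replicates per condition.
#' @param mask Logical matrix of measured cells; defaults to the
#'   `measured_mask` attribute left by [impute_missing()], or to the
#'   `NA` pattern of the intensity columns.
#' @return Filtered tibble (mask attribute subset accordingly).
#' @export
presence_filter <- function(table, design, min_replicates = 2L, mask = NULL) {
  if (is.null(mask)) mask <- attr(table, "measured_mask")
  if (is.null(mask)) mask <- !is.na(as.matrix(table[design$column]))
  keep <- rep(FALSE, nrow(table))
  for (cond in unique(design$condition)) {
    cols <- design$column[design$condition == cond]
    keep <- keep | rowSums(mask[, cols, drop = FALSE]) >= min_replicates
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "measured_mask") <- mask[keep, , drop = FALSE]
  out
}

#' Empirical-Bayes moderated two-sample test
#'
#' Compares two conditions on log2 intensities. Each row's pooled
#' residual variance is shrunk toward a prior variance `s0^2` with prior
#' degrees of freedom `d0`, both estimated from the observed
#' distribution of log residual variances by moment matching (the
#' digamma/trigamma equations are inverted numerically). The moderated
#' statistic is `t = dmean / (s_post * sqrt(1/n1 + 1/n2))` with
#' `s_post^2 = (d0 s0^2 + d s^2) / (d0 + d)` on `d0 + d` degrees of
#' freedom; two-sided p-values are BH-adjusted across rows. Forcing
#' `prior_df = 0` recovers the ordinary pooled t-test; `prior_df = Inf`
#' replaces every row variance by `s0^2`.
#'
#' @param table Complete log2 protein-groups tibble (see
#'   [impute_missing()]).
#' @param design Tibble (column, condition) with exactly two conditions.
#' @param contrast Character pair `c(test, reference)`; log2 fold change
#'   is test minus reference. Defaults to the design's condition order.
#' @param prior_df Force the prior degrees of freedom instead of
#'   estimating them (`NULL` = estimate).
#' @param prior_var Force the prior variance (`NULL` = estimate).
#' @return Object of class `moderated_fit`: list with `results` (tibble:
#'   id, log2fc, s2, s2_post, t, df_total, p_value, fdr), `prior_df`,
#'   `prior_var`, `design`, `contrast`.
#' @export
moderated_test <- function(table, design, contrast = NULL,
                           prior_df = NULL, prior_var = NULL) {
  conds <- unique(design$condition)
  if (length(conds) != 2) abort("`design` must contain exactly two conditions")
  if (is.null(contrast)) contrast <- conds
  stopifnot(all(contrast %in% conds))
  c1 <- design$column[design$condition == contrast[1]]
  c2 <- design$column[design$condition == contrast[2]]
  n1 <- length(c1); n2 <- length(c2)
  if (n1 < 2 || n2 < 2) abort("need >= 2 replicates per condition")

  m <- as.matrix(table[c(c1, c2)])
  x1 <- m[, c1, drop = FALSE]
  x2 <- m[, c2, drop = FALSE]
  mean1 <- rowMeans(x1); mean2 <- rowMeans(x2)
  rss <- rowSums((x1 - mean1)^2) + rowSums((x2 - mean2)^2)
  df <- n1 + n2 - 2
  s2 <- rss / df

  bad <- !is.finite(s2) | s2 <= 0
  if (any(bad)) {
    warn(sprintf("%d row(s) with zero residual variance were excluded",
                 sum(bad)))
  }
  fit_rows <- which(!bad)
  prior <- fit_variance_prior(s2[fit_rows], df,
                              prior_df = prior_df, prior_var = prior_var)
  d0 <- prior$df; s02 <- prior$var

  s2_post <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else {
    (d0 * s02 + df * s2) / (d0 + df)
  }
  df_total <- d0 + df
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  log2fc <- mean1 - mean2
  tstat <- log2fc / se
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[bad] <- NA_real_
  tstat[bad] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  fdr[!bad] <- p.adjust(p[!bad], method = "BH")

  results <- tibble::tibble(
    id = if ("id" %in% names(table)) table$id else as.character(seq_along(p)),
    log2fc = log2fc, s2 = s2, s2_post = s2_post,
    t = tstat, df_total = df_total, p_value = p, fdr = fdr
  )
  structure(
    list(results = results[!bad, , drop = FALSE], prior_df = d0,
         prior_var = s02, design = design, contrast = contrast,
         n_excluded = sum(bad)),
    class = "moderated_fit"
  )
}

# Moment-matching estimate of the scaled inverse-chi-square prior on row
# variances: equate mean and variance of log(s^2) with the theoretical
# moments of log F(df, d0) scaled by s0^2, via digamma/trigamma.
fit_variance_prior <- function(s2, df, prior_df = NULL, prior_var = NULL) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  if (is.null(prior_df)) {
    n <- length(z)
    rhs <- mean((e - emean)^2 * n / (n - 1)) - trigamma(df / 2)
    prior_df <- if (rhs <= 0) Inf else 2 * trigamma_inverse(rhs)
  }
  if (is.null(prior_var)) {
    prior_var <- if (is.infinite(prior_df) || prior_df == 0) {
      # d0 = 0 gives the prior zero weight; report the location estimate
      exp(emean)
    } else {
      exp(emean + digamma(prior_df / 2) - log(prior_df / 2))
    }
  }
  list(df = prior_df, var = prior_var)
}

# Solve trigamma(x) = y for x > 0 by Newton iteration.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Classify significantly changed protein groups
#'
#' A row is significant when its BH-adjusted FDR is at most `fdr_max`
#' and its log2 fold change (enrichment of the test condition over the
#' reference) is at least `lfc_min`.
#'
#' @param fit A `moderated_fit` or its `results` tibble.
#' @param fdr_max FDR ceiling.
#' @param lfc_min Minimum log2 fold change.
#' @return The results tibble with a `significant` column.
#' @export
classify_hits <- function(fit, fdr_max = 0.05, lfc_min = 2) {
  results <- if (inherits(fit, "moderated_fit")) fit$results else fit
  dplyr::mutate(results,
                significant = .data$fdr <= fdr_max & .data$log2fc >= lfc_min)
}

#' Run the complete interactome analysis
#'
#' Flag/peptide filtering, log2 transform, left-tail beta imputation,
#' replicate-presence filtering (on the original missingness mask),
#' moderated differential test and significance classification.
#'
#' @param table Raw protein-groups tibble (intensities, `NA` = missing).
#' @param design Tibble (column, condition), two conditions.
#' @param seed Seed for the imputation draws.
#' @param contrast Passed to [moderated_test()].
#' @param fdr_max,lfc_min Passed to [classify_hits()].
#' @param ... Passed to [filter_protein_groups()].
#' @return A `moderated_fit` whose `results` carry a `significant`
#'   column.
#' @examples
#' sim <- simulate_lfq_matrix(sim_config(seed = 1))
#' fit <- interactome_analysis(sim$table, sim$design, seed = 7,
#'                             contrast = c("ip", "ctrl"))
#' glance(fit)
#' @export
interactome_analysis <- function(table, design, seed, contrast = NULL,
                                 fdr_max = 0.05, lfc_min = 2, ...) {
  x <- filter_protein_groups(table, ...)
  x <- log_transform_lfq(x, design)
  x <- impute_missing(x, design, seed = seed)
  x <- presence_filter(x, design)
  fit <- moderated_test(x, design, contrast = contrast)
  fit$results <- classify_hits(fit, fdr_max = fdr_max, lfc_min = lfc_min)
  fit
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat("<moderated_fit> ", nrow(x$results), " protein groups; prior df = ",
      format(x$prior_df, digits = 4), ", prior variance = ",
      format(x$prior_var, digits = 4), "\n", sep = "")
  if ("significant" %in% names(x$results)) {
    cat("  significant:", sum(x$results$significant), "\n")
  }
  invisible(x)
}

#' @describeIn moderated_test Tidy per-protein results.
#' @param x A `moderated_fit`.
#' @param ... Unused.
#' @method tidy moderated_fit
#' @export
tidy.moderated_fit <- function(x, ...) {
  x$results
}

#' @describeIn moderated_test One-row model summary.
#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$results),
    prior_df = x$prior_df,
    prior_var = x$prior_var,
    n_significant = if ("significant" %in% names(x$results)) {
      sum(x$results$significant)
    } else NA_integer_,
    n_excluded = x$n_excluded
  )
}
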