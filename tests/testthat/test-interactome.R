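pg_row <- function(id, peptides = 3L, unique_peptides = 2L,
                   contaminant = FALSE, reverse = FALSE,
                   only_by_site = FALSE, ...) {
  tibble::tibble(id = id, contaminant = contaminant, reverse = reverse,
                 only_by_site = only_by_site, peptides = peptides,
                 unique_peptides = unique_peptides, ...)
}

design_3v3 <- tibble::tibble(
  column = c("ip_1", "ip_2", "ip_3", "ctrl_1", "ctrl_2", "ctrl_3"),
  condition = rep(c("ip", "ctrl"), each = 3)
)

test_that("protein-group filtering removes flags and weak peptide evidence", {
  tab <- dplyr::bind_rows(
    pg_row("keep", peptides = 3L, unique_peptides = 2L),
    pg_row("con", contaminant = TRUE),
    pg_row("rev", reverse = TRUE),
    pg_row("site", only_by_site = TRUE),
    pg_row("one_pep", peptides = 1L, unique_peptides = 1L),
    pg_row("two_pep_no_unique", peptides = 2L, unique_peptides = 0L)
  )
  kept <- filter_protein_groups(tab)
  expect_equal(kept$id, "keep")
  # the literal both-fail reading only removes rows failing both rules
  kept_lit <- filter_protein_groups(tab, literal = TRUE)
  expect_setequal(kept_lit$id, c("keep", "one_pep", "two_pep_no_unique"))
})

test_that("imputed values respect the stated bounds and leave data untouched", {
  tab <- pg_row(sprintf("p%d", 1:40))
  set.seed(1)
  vals <- matrix(rnorm(240, 25, 2), 40, 6,
                 dimnames = list(NULL, design_3v3$column))
  vals[sample(240, 60)] <- NA
  tab <- dplyr::bind_cols(tab, tibble::as_tibble(vals))
  imp <- impute_missing(tab, design_3v3, seed = 9)
  out <- as.matrix(imp[design_3v3$column])
  m <- min(vals, na.rm = TRUE)
  measured <- !is.na(vals)
  expect_identical(out[measured], vals[measured])
  expect_true(all(out[!measured] >= 0.001 * m - 1e-12))
  expect_true(all(out[!measured] <= 0.015 * m + 1e-12))
  # deterministic under the seed
  imp2 <- impute_missing(tab, design_3v3, seed = 9)
  expect_identical(imp, imp2, ignore_attr = TRUE)
  # a complete table passes through unchanged
  full <- tab
  full[design_3v3$column] <- tibble::as_tibble(
    matrix(5, 40, 6, dimnames = list(NULL, design_3v3$column)))
  expect_equal(as.matrix(impute_missing(full, design_3v3, 1)[design_3v3$column]),
               as.matrix(full[design_3v3$column]))
  # an all-missing table is an error
  empty <- tab
  empty[design_3v3$column] <- NA_real_
  expect_error(impute_missing(empty, design_3v3, 1), "missing")
})

test_that("the presence filter uses the pre-imputation missingness mask", {
  tab <- pg_row(c("a", "b", "c"))
  vals <- rbind(
    c(10, 11, NA, NA, NA, NA),  # 2/3 in ip, 0/3 in ctrl -> keep
    c(10, NA, NA, 11, NA, NA),  # 1 per condition -> drop
    c(10, 11, 12, 10, 11, 12)   # complete -> keep
  )
  colnames(vals) <- design_3v3$column
  tab <- dplyr::bind_cols(tab, tibble::as_tibble(vals))
  kept <- presence_filter(tab, design_3v3)
  expect_setequal(kept$id, c("a", "c"))
  # after imputation the mask decides, not the completed values
  imp <- impute_missing(tab, design_3v3, seed = 3)
  kept2 <- presence_filter(imp, design_3v3)
  expect_setequal(kept2$id, c("a", "c"))
})

make_complete_matrix <- function(n, seed, delta = 0) {
  set.seed(seed)
  vals <- matrix(rnorm(6 * n, 20, 1), n, 6,
                 dimnames = list(NULL, design_3v3$column))
  vals[, 1:3] <- vals[, 1:3] + delta
  dplyr::bind_cols(pg_row(sprintf("p%03d", 1:n)), tibble::as_tibble(vals))
}

test_that("forcing the prior df recovers the two classical limiting cases", {
  tab <- make_complete_matrix(60, seed = 2)
  fit0 <- moderated_test(tab, design_3v3, contrast = c("ip", "ctrl"),
                         prior_df = 0)
  m <- as.matrix(tab[design_3v3$column])
  ordinary_t <- apply(m, 1, function(r) {
    t.test(r[1:3], r[4:6], var.equal = TRUE)$statistic
  })
  expect_equal(fit0$results$t, unname(ordinary_t), tolerance = 1e-10)

  fit_inf <- moderated_test(tab, design_3v3, contrast = c("ip", "ctrl"),
                            prior_df = Inf)
  expect_true(all(fit_inf$results$s2_post == fit_inf$prior_var))
  # and the statistic is the s0-scaled mean difference
  s0 <- sqrt(fit_inf$prior_var)
  d <- rowMeans(m[, 1:3]) - rowMeans(m[, 4:6])
  expect_equal(fit_inf$results$t, d / (s0 * sqrt(2 / 3)), tolerance = 1e-10)
})

test_that("the moderated t lies between the two limiting statistics", {
  tab <- make_complete_matrix(80, seed = 4)
  fit <- moderated_test(tab, design_3v3, contrast = c("ip", "ctrl"))
  fit0 <- moderated_test(tab, design_3v3, contrast = c("ip", "ctrl"),
                         prior_df = 0)
  fit_inf <- moderated_test(tab, design_3v3, contrast = c("ip", "ctrl"),
                            prior_df = Inf, prior_var = fit$prior_var)
  lo <- pmin(abs(fit0$results$t), abs(fit_inf$results$t))
  hi <- pmax(abs(fit0$results$t), abs(fit_inf$results$t))
  expect_true(all(abs(fit$results$t) >= lo - 1e-12))
  expect_true(all(abs(fit$results$t) <= hi + 1e-12))
})

test_that("moderated statistics agree with an independent reference implementation", {
  skip_if_not_installed("limma")
  tab <- make_complete_matrix(120, seed = 6, delta = 0.5)
  fit <- moderated_test(tab, design_3v3, contrast = c("ip", "ctrl"))
  m <- as.matrix(tab[design_3v3$column])
  dm <- cbind(intercept = 1, ip = rep(c(1, 0), each = 3))
  lf <- limma::eBayes(limma::lmFit(m, dm))
  expect_equal(fit$prior_df, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior_var, lf$s2.prior, tolerance = 1e-6)
  expect_equal(fit$results$t, unname(lf$t[, "ip"]), tolerance = 1e-6)
  expect_equal(fit$results$p_value, unname(lf$p.value[, "ip"]),
               tolerance = 1e-6)
})

test_that("BH adjustment equals the brute-force definition on small instances", {
  set.seed(8)
  for (i in 1:5) {
    n <- sample(3:20, 1)
    tab <- make_complete_matrix(n, seed = 100 + i, delta = runif(1))
    fit <- moderated_test(tab, design_3v3, contrast = c("ip", "ctrl"))
    expect_equal(fit$results$fdr, oracle_bh(fit$results$p_value),
                 tolerance = 1e-12)
    # monotone in the raw p-values
    o <- order(fit$results$p_value)
    expect_true(all(diff(fit$results$fdr[o]) >= -1e-12))
    expect_true(all(fit$results$fdr >= fit$results$p_value - 1e-12))
  }
})

test_that("significance needs both the FDR and the fold-change threshold", {
  res <- tibble::tibble(
    id = c("a", "b", "c"),
    log2fc = c(2.5, 1.9, 5),
    fdr = c(0.04, 0.04, 0.06)
  )
  got <- classify_hits(res)
  expect_identical(got$significant, c(TRUE, FALSE, FALSE))
})

test_that("null data give nominal type-I error and spiked data are recovered", {
  # null: no condition difference
  tab <- make_complete_matrix(200, seed = 12)
  fit <- moderated_test(tab, design_3v3, contrast = c("ip", "ctrl"))
  frac <- mean(fit$results$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200))

  # spiked matrix at the generator defaults
  sim <- simulate_lfq_matrix(sim_config(seed = 23))
  fit2 <- interactome_analysis(sim$table, sim$design, seed = 24,
                               contrast = c("ip", "ctrl"))
  hits <- fit2$results$id[fit2$results$significant]
  truth <- sim$truth$id[sim$truth$enriched]
  expect_gte(mean(truth %in% hits), 0.9)
  expect_lte(mean(!hits %in% truth), 0.1)
})

test_that("tidy and glance expose the fit in broom style", {
  sim <- simulate_lfq_matrix(sim_config(seed = 31))
  fit <- interactome_analysis(sim$table, sim$design, seed = 32,
                              contrast = c("ip", "ctrl"))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("id", "log2fc", "t", "p_value", "fdr", "significant")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_proteins, nrow(td))
  expect_s3_class(autoplot(fit), "ggplot")
})
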