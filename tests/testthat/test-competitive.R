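make_stats <- function(n, z, seed = NULL) {
  tibble::tibble(gene_id = sprintf("g%04d", seq_len(n)), z = z,
                 length = 1000, n_snps = 5L)
}

test_that("constant z-scores give a zero beta and p of one half", {
  stats <- make_stats(50, rep(1.3, 50))
  fit <- competitive_test(stats, stats$gene_id[1:10], covariates = FALSE)
  expect_equal(fit$result$beta, 0)
  expect_equal(fit$result$p, 0.5)
  expect_equal(fit$result$status, "no_variance")
})

test_that("a planted mean shift in member genes is recovered within 2 SE", {
  withr::with_seed(61, {
    z <- rnorm(1000)
    members <- sprintf("g%04d", 1:150)
    z[1:150] <- z[1:150] + 0.5
    fit <- competitive_test(make_stats(1000, z), members,
                            covariates = FALSE)
    expect_lt(abs(fit$result$beta - 0.5), 2 * fit$result$se)
    expect_lt(fit$result$p, 0.05)
  })
})

test_that("degenerate designs are explicit errors", {
  stats <- make_stats(20, rnorm(20))
  expect_error(competitive_test(stats, character()),
               class = "convergene_degenerate_error")
  expect_error(competitive_test(stats, stats$gene_id),
               class = "convergene_degenerate_error")
  expect_error(
    competitive_test(stats, stats$gene_id[1:5], covariates = FALSE,
                     condition_on = list(self = stats$gene_id[1:5])),
    class = "convergene_collinear_error"
  )
})

test_that("conditioning on a disjoint null set leaves beta nearly unchanged", {
  withr::with_seed(62, {
    diffs <- replicate(30, {
      z <- rnorm(400)
      members <- sprintf("g%04d", 1:60)
      null_set <- sprintf("g%04d", 201:260)
      z[1:60] <- z[1:60] + 0.4
      stats <- make_stats(400, z)
      b0 <- competitive_test(stats, members, covariates = FALSE)$result
      b1 <- competitive_test(stats, members, covariates = FALSE,
                             condition_on = list(nul = null_set))$result
      c(b1$beta - b0$beta, b0$se)
    })
    # mean paired shift is small relative to the sampling SE
    expect_lt(abs(mean(diffs[1, ])), mean(diffs[2, ]) / 2)
  })
})

test_that("gene-level covariates are accepted and reported", {
  withr::with_seed(63, {
    stats <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:300),
      z = rnorm(300),
      length = round(runif(300, 2e3, 2e5)),
      n_snps = sample(2:20, 300, replace = TRUE)
    )
    fit <- competitive_test(stats, stats$gene_id[1:50])
    expect_equal(fit$result$status, "ok")
    td <- tidy(fit)
    expect_true(all(c("member", "gene_length", "log_length",
                      "n_snps", "log_n_snps") %in% td$term))
  })
})

test_that("batch competitive runs capture per-set failures without aborting", {
  cfg <- small_sim(seed = 64)
  g <- sim_gene_table(cfg)
  sim <- sim_gwas(g, cfg)
  coll <- dplyr::bind_rows(
    tibble::tibble(set = "ok_set", category = "human_cell",
                   gene_id = g$gene_id[1:40]),
    tibble::tibble(set = "tiny", category = "synaptic",
                   gene_id = g$gene_id[1:3])
  )
  res <- run_common(qc_gwas(sim$sumstats), sim$ld, g, coll,
                    min_set_size = 10)
  expect_equal(nrow(res), 2)
  expect_equal(res$status[res$set == "ok_set"], "ok")
  expect_equal(res$status[res$set == "tiny"], "skipped_small")
  # determinism of the batch
  res2 <- run_common(qc_gwas(sim$sumstats), sim$ld, g, coll,
                     min_set_size = 10)
  expect_identical(res, res2)
  # empty collection gives an empty result table
  empty <- coll[0, ]
  expect_equal(nrow(run_common(qc_gwas(sim$sumstats), sim$ld, g, empty)), 0)
})

test_that("GLS with an identity gene correlation reproduces OLS", {
  withr::with_seed(65, {
    stats <- tibble::tibble(gene_id = sprintf("g%03d", 1:120),
                            z = rnorm(120))
    stats$z[1:30] <- stats$z[1:30] + 0.4
    members <- stats$gene_id[1:30]
    ols <- competitive_test(stats, members, covariates = FALSE)$result
    gls <- competitive_test(stats, members, covariates = FALSE,
                            gene_corr = diag(120))$result
    expect_equal(gls$beta, ols$beta, tolerance = 1e-10)
    expect_equal(gls$se, ols$se, tolerance = 1e-10)
    expect_equal(gls$p, ols$p, tolerance = 1e-10)
    expect_error(
      competitive_test(stats, members, covariates = FALSE,
                       gene_corr = diag(10)),
      "square"
    )
  })
})
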