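base_covars <- function(n) {
  df <- tibble::tibble(sex = 0L)
  df <- df[rep(1, n), ]
  for (k in 1:10) df[[paste0("PC", k)]] <- 0
  df
}

test_that("a 2x2 collapse recovers the closed-form log odds ratio", {
  # 30/1000 case carriers vs 10/1000 control carriers, binary burden:
  # beta = log((30/970) / (10/990)) = 1.11886...
  df <- dplyr::bind_cols(
    tibble::tibble(
      case = rep(c(1L, 0L), each = 1000),
      score = c(rep(1L, 30), rep(0L, 970), rep(1L, 10), rep(0L, 990))
    ),
    base_covars(2000)
  )
  fit <- burden_regression(df, "collapse")
  expect_equal(fit$result$beta, log((30 / 970) / (10 / 990)),
               tolerance = 1e-6)
  expect_equal(fit$result$n_carriers, 40L)
})

test_that("the logistic fit matches an independent IRLS oracle", {
  withr::with_seed(81, {
    for (rep in 1:5) {
      n <- 400
      df <- tibble::tibble(
        case = rbinom(n, 1, 0.5),
        score = rpois(n, 1),
        sex = rbinom(n, 1, 0.5)
      )
      for (k in 1:10) df[[paste0("PC", k)]] <- rnorm(n)
      fit <- burden_regression(df, "fuzz")
      X <- cbind(1, as.matrix(df[c("score", "sex", paste0("PC", 1:10))]))
      oracle <- oracle_irls_logistic(X, df$case)
      expect_equal(fit$result$beta, oracle$beta[2], tolerance = 1e-6)
      expect_equal(fit$result$se, oracle$se[2], tolerance = 1e-6)
    }
  })
})

test_that("degenerate burden designs raise explicit errors", {
  df <- dplyr::bind_cols(
    tibble::tibble(case = rep(c(1L, 0L), 50), score = 1L),
    base_covars(100)
  )
  expect_error(burden_regression(df, "const"),
               class = "convergene_degenerate_error")
  df2 <- df
  df2$score <- rep(0:1, 50)
  df2$case <- 1L
  expect_error(burden_regression(df2, "one_class"),
               class = "convergene_degenerate_error")
})

test_that("separation falls back to a flagged Firth fit", {
  withr::with_seed(82, {
    n <- 200
    df <- dplyr::bind_cols(
      tibble::tibble(case = rep(c(1L, 0L), each = n / 2),
                     score = c(rep(1L, 20), rep(0L, n / 2 - 20),
                               rep(0L, n / 2))),
      base_covars(n)
    )
    # every carrier is a case: ML estimate diverges
    fit <- burden_regression(df, "sep")
    expect_equal(fit$result$status, "firth")
    expect_true(is.finite(fit$result$beta) && fit$result$beta > 0)
    expect_true(is.finite(fit$result$se) && fit$result$se > 0)
  })
})

test_that("constant conditioning burdens are dropped, identical ones error", {
  withr::with_seed(83, {
    n <- 300
    df <- tibble::tibble(
      case = rbinom(n, 1, 0.5),
      score = rpois(n, 1),
      sex = rbinom(n, 1, 0.5)
    )
    for (k in 1:10) df[[paste0("PC", k)]] <- rnorm(n)
    df$cond_empty <- 0L
    df$cond_self <- df$score
    plain <- burden_regression(df, "s")$result
    expect_warning(
      dropped <- burden_regression(df, "s",
                                   condition_cols = "cond_empty")$result,
      "constant"
    )
    expect_equal(dropped$beta, plain$beta, tolerance = 1e-12)
    expect_error(
      burden_regression(df, "s", condition_cols = "cond_self"),
      class = "convergene_collinear_error"
    )
  })
})

test_that("synonymous burden shows nominal type-I error across cohorts", {
  cfg_base <- list(n_genes = 150, n_cases = 150, n_controls = 150,
                   mu_ptv = 3e-3, mu_syn = 1.5e-2, burden_logor = 0.4)
  withr::with_seed(84, {
    rejected <- vapply(1:500, function(i) {
      cfg <- do.call(sim_config, c(cfg_base, list(seed = 10000 + i)))
      g <- sim_gene_table(cfg)
      cohort <- sim_exome_cohort(g, cfg, causal_sets = g$gene_id[1:50])
      sc <- burden_score(cohort, g$gene_id[1:50], "rare", "synonymous")
      df <- dplyr::inner_join(cohort$individuals, sc,
                              by = "individual_id")
      tryCatch(burden_regression(df, "syn")$result$p < 0.05,
               error = function(e) NA)
    }, logical(1))
    rate <- mean(rejected, na.rm = TRUE)
    n_ok <- sum(!is.na(rejected))
    band <- 3 * sqrt(0.05 * 0.95 / n_ok)
    expect_lt(abs(rate - 0.05), band)
  })
})

test_that("batch rare runs pair PTV with synonymous controls per class", {
  cfg <- small_sim(seed = 85)
  g <- sim_gene_table(cfg)
  coll <- dplyr::bind_rows(
    tibble::tibble(set = "setA", category = "human_cell",
                   gene_id = g$gene_id[1:100]),
    tibble::tibble(set = "PI", category = "PI",
                   gene_id = g$gene_id[50:150])
  )
  cohort <- sim_exome_cohort(g, cfg, causal_sets = coll)
  res <- run_rare(cohort, coll, classes = c("urv", "rare_excl"),
                  min_set_size = 5)
  expect_setequal(unique(res$variant_class),
                  c("urv_ptv", "urv_syn", "rare_excl_ptv",
                    "rare_excl_syn"))
  expect_equal(nrow(res), 2 * 4) # 2 sets x 4 class-consequence pairs
  expect_identical(res, run_rare(cohort, coll,
                                 classes = c("urv", "rare_excl"),
                                 min_set_size = 5))
  expect_error(run_rare(exome_cohort(cohort$individuals[0, ],
                                     cohort$variants[0, ],
                                     cohort$carriers[0, ], 1),
                        coll),
               "empty")
})

test_that("conditional fits report a variance-inflation diagnostic", {
  withr::with_seed(86, {
    n <- 400
    df <- tibble::tibble(
      case = rbinom(n, 1, 0.5),
      score = rpois(n, 1),
      sex = rbinom(n, 1, 0.5)
    )
    for (k in 1:10) df[[paste0("PC", k)]] <- rnorm(n)
    # nested conditioning burden: focal score plus extra alleles
    df$cond_pi <- df$score + rpois(n, 0.5)
    fit <- burden_regression(df, "s", condition_cols = "cond_pi")$result
    expect_true(is.finite(fit$vif) && fit$vif > 1)
    plain <- burden_regression(df, "s")$result
    expect_true(is.na(plain$vif))
  })
})

test_that("the exclusion hook removes individuals before QC", {
  cfg <- small_sim(seed = 87)
  g <- sim_gene_table(cfg)
  coll <- tibble::tibble(set = "setA", category = "human_cell",
                         gene_id = g$gene_id[1:100])
  cohort <- sim_exome_cohort(g, cfg)
  drop_ids <- cohort$individuals$individual_id[1:50]
  res <- run_rare(cohort, coll, classes = "urv", min_set_size = 5,
                  exclude_individuals = drop_ids)
  expect_equal(nrow(res), 2)
  res_all <- run_rare(cohort, coll, classes = "urv", min_set_size = 5)
  expect_false(identical(res$beta, res_all$beta))
})
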