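test_that("BH step-up matches the hand-computed example", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.9)
  # largest i with p_(i) <= 0.05 i / 5 is i = 4
  expect_equal(bh_fdr(p), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 6)), rep(FALSE, 6))
  expect_equal(bh_fdr(numeric()), logical())
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("BH matches an exhaustive step-up oracle on fuzzed lists", {
  withr::with_seed(91, {
    for (i in 1:100) {
      m <- sample(1:20, 1)
      p <- runif(m)^sample(1:3, 1) # skew some lists toward small values
      q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
      expect_equal(bh_fdr(p, q), oracle_bh(p, q))
    }
  })
})

test_that("BH rejections are monotone in q and empty at q = 0", {
  withr::with_seed(92, {
    p <- runif(15)^2
    prev <- rep(FALSE, 15)
    for (q in c(0, 0.01, 0.05, 0.1, 0.5, 1)) {
      cur <- bh_fdr(p, q)
      if (q == 0) expect_false(any(cur))
      expect_true(all(prev <= cur))
      prev <- cur
    }
  })
})

test_that("FDR flags are assigned per variant-class family", {
  res <- tibble::tibble(
    set = rep(c("a", "b", "c"), 2),
    variant_class = rep(c("common", "urv_ptv"), each = 3),
    p = c(0.001, 0.5, 0.9, 0.01, 0.02, 0.6),
    conditioned_on = "",
    status = "ok",
    beta = 0.1, se = 0.1
  )
  res$conditioned_on[3] <- "PI" # conditional row: excluded from the family
  out <- add_fdr(res, q = 0.05)
  expect_true(is.na(out$fdr_significant[3]))
  expect_equal(out$fdr_significant[out$variant_class == "common" &
                                     out$set == "a"], TRUE)
  expect_equal(out$fdr_significant[out$variant_class == "urv_ptv"],
               bh_fdr(c(0.01, 0.02, 0.6)))
})

make_results <- function(beta, se, p, class = "common") {
  tibble::tibble(
    set = sprintf("s%02d", seq_along(beta)),
    category = "human_cell", variant_class = class,
    n_genes = 100L, beta = beta, se = se, p = p,
    conditioned_on = "", status = "ok"
  )
}

test_that("weighted correlation equals unweighted under equal weights", {
  withr::with_seed(93, {
    beta_a <- rnorm(20)
    beta_b <- 0.5 * beta_a + rnorm(20, 0, 0.2)
    a <- make_results(beta_a, rep(0.1, 20), runif(20, 0.01, 0.9))
    b <- make_results(beta_b, rep(0.3, 20), runif(20, 0.01, 0.9),
                      "urv_ptv")
    cv <- correlate_enrichment(a, b)
    expect_equal(cv$weighted_correlation,
                 cor(beta_a, beta_b), tolerance = 1e-12)
    expect_equal(cv$correlation, cor(beta_a, beta_b), tolerance = 1e-12)
  })
})

test_that("perfect linear relation gives correlation one", {
  beta_a <- c(-0.2, 0.1, 0.4, 0.7)
  a <- make_results(beta_a, c(0.1, 0.2, 0.3, 0.4), rep(0.5, 4))
  b <- make_results(2 * beta_a, c(0.4, 0.3, 0.2, 0.1), rep(0.5, 4),
                    "urv_ptv")
  cv <- correlate_enrichment(a, b)
  expect_equal(cv$correlation, 1, tolerance = 1e-12)
  expect_equal(cv$weighted_correlation, 1, tolerance = 1e-12)
})

test_that("weighted estimate matches the hand moment formula and is scale-free", {
  x <- c(1, 2, 3)
  y <- c(1, 3, 2)
  w <- c(4, 1, 1)
  a <- make_results(x, 1 / w, rep(0.5, 3)) # se_a * se_b = 1/w
  b <- make_results(y, rep(1, 3), rep(0.5, 3), "urv_ptv")
  cv <- correlate_enrichment(a, b)
  expect_equal(cv$weighted_correlation, oracle_weighted_pearson(x, y, w),
               tolerance = 1e-12)
  # rescaling every weight by a positive constant leaves it unchanged
  a2 <- make_results(x, 10 / w, rep(0.5, 3))
  cv2 <- correlate_enrichment(a2, b)
  expect_equal(cv2$weighted_correlation, cv$weighted_correlation,
               tolerance = 1e-12)
})

test_that("spearman uses rank correlation for the plain estimate", {
  withr::with_seed(94, {
    beta_a <- rnorm(15)
    beta_b <- beta_a^3 + rnorm(15, 0, 0.01) # monotone, nonlinear
    a <- make_results(beta_a, rep(0.1, 15), runif(15))
    b <- make_results(beta_b, rep(0.1, 15), runif(15), "urv_ptv")
    cv <- correlate_enrichment(a, b, method = "spearman")
    expect_equal(cv$correlation, cor(beta_a, beta_b, method = "spearman"),
                 tolerance = 1e-12)
    expect_gt(cv$correlation, 0.99)
  })
})

test_that("identical result tables give correlation 1 and full overlap", {
  withr::with_seed(95, {
    a <- make_results(rnorm(12), runif(12, 0.05, 0.2),
                      c(1e-5, 1e-4, runif(10, 0.2, 0.9)))
    b <- a
    b$variant_class <- "urv_ptv"
    cv <- correlate_enrichment(a, b)
    expect_equal(cv$correlation, 1, tolerance = 1e-12)
    sig <- add_fdr(a)$fdr_significant
    expect_setequal(cv$overlap_sets, a$set[which(sig)])
    expect_gt(length(cv$overlap_sets), 0)
  })
})

test_that("too few shared sets and mismatched collections are errors", {
  a <- make_results(c(0.1, 0.2), c(0.1, 0.1), c(0.5, 0.5))
  b <- make_results(c(0.1, 0.2), c(0.1, 0.1), c(0.5, 0.5), "urv_ptv")
  expect_error(correlate_enrichment(a, b), "fewer than 3")
  a4 <- make_results(rnorm(4), rep(0.1, 4), rep(0.5, 4))
  b4 <- make_results(rnorm(4), rep(0.1, 4), rep(0.5, 4), "urv_ptv")
  b4$set[4] <- "other"
  expect_error(convergence_report(a4, b4), "unmatched")
})

test_that("global-null convergence centres on zero over replicates", {
  withr::with_seed(96, {
    ests <- replicate(500, {
      a <- make_results(rnorm(15), runif(15, 0.05, 0.2),
                        runif(15, 0.2, 1))
      b <- make_results(rnorm(15), runif(15, 0.05, 0.2),
                        runif(15, 0.2, 1), "urv_ptv")
      correlate_enrichment(a, b)$correlation
    })
    mc_se <- sd(ests) / sqrt(length(ests))
    expect_lt(abs(mean(ests)), 2 * mc_se)
  })
})
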