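test_that("summary-statistic QC removes duplicates and low-INFO records", {
  ss <- tibble::tibble(
    snp = c("rs1", "rs1", "rs2", "rs3", "rs4"),
    chrom = "chr1", bp = 1:5,
    p = c(0.5, 0.4, 0.3, 0.2, 0.1),
    info = c(0.9, 0.9, 0.79, 0.80, 1.0),
    n = 100L
  )
  out <- qc_gwas(ss)
  expect_setequal(out$snp, c("rs3", "rs4")) # rs1 both copies, rs2 INFO<0.8
  log <- attr(out, "qc_log")
  expect_equal(log$removed_duplicate, 2)
  expect_equal(log$removed_low_info, 1)

  clean <- ss[4:5, ]
  expect_equal(qc_gwas(clean)$snp, clean$snp)
  expect_warning(qc_gwas(ss[ss$info < 0.5, ]), "no SNPs")
})

test_that("SNPs map to genes by closed-interval containment", {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gOv"),
    chrom = c("chr1", "chr2", "chr1"),
    start = c(100L, 100L, 150L),
    stop = c(200L, 200L, 250L)
  )
  ss <- tibble::tibble(
    snp = c("s_start", "s_stop", "s_after", "s_before", "s_overlap",
            "s_chr2"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    bp = c(100L, 200L, 201L, 99L, 180L, 150L),
    p = 0.5, info = 1, n = 10L
  )
  ann <- annotate_snps(ss, genes)
  expect_true(all(c("s_start", "s_stop") %in%
                    ann$snp[ann$gene_id == "gA"]))
  expect_false("s_after" %in% ann$snp[ann$gene_id == "gA"])
  expect_false("s_before" %in% ann$snp)
  # a SNP inside two overlapping genes is assigned to both
  expect_setequal(ann$gene_id[ann$snp == "s_overlap"], c("gA", "gOv"))
  expect_equal(ann$gene_id[ann$snp == "s_chr2"], "gB")
  # window extends the interval
  ann_w <- annotate_snps(ss, genes, window = 1)
  expect_true("s_after" %in% ann_w$snp[ann_w$gene_id == "gA"])
})

test_that("gene p-value reduces to closed forms", {
  # single SNP: identity
  one <- gene_pvalue(0.01, matrix(1))
  expect_equal(one$p_gene, 0.01, tolerance = 1e-12)
  # two independent SNPs with chi-square 1 each: chi^2_2 tail at 2 = e^-1
  p1 <- 2 * pnorm(-1)
  two <- gene_pvalue(c(p1, p1), diag(2))
  expect_equal(two$t_stat, 2, tolerance = 1e-12)
  expect_equal(two$p_gene, exp(-1), tolerance = 1e-12)
})

test_that("identity-LD gene p-values equal the exact chi-square tail", {
  withr::with_seed(41, {
    for (k in c(1, 2, 4, 6)) {
      ps <- runif(k, 1e-6, 0.99)
      got <- gene_pvalue(ps, diag(k))
      t_exp <- sum(qchisq(ps, 1, lower.tail = FALSE))
      p_exp <- pchisq(t_exp, df = k, lower.tail = FALSE)
      expect_equal(got$p_gene, p_exp, tolerance = 1e-10)
      expect_equal(got$method, "exact")
    }
  })
})

test_that("correlated-LD gene p-values match a Monte-Carlo oracle", {
  cases <- list(
    list(k = 3, R = {m <- matrix(0.5, 3, 3); diag(m) <- 1; m}, seed = 1),
    list(k = 4, R = random_corr(4, 51), seed = 2),
    list(k = 6, R = random_corr(6, 52), seed = 3)
  )
  withr::with_seed(42, {
    for (cs in cases) {
      ps <- runif(cs$k, 0.01, 0.9)
      got <- gene_pvalue(ps, cs$R)
      lambda <- eigen(cs$R, symmetric = TRUE, only.values = TRUE)$values
      mc <- oracle_mc_tail(got$t_stat, lambda, n = 1e6, seed = cs$seed)
      mc_se <- sqrt(mc * (1 - mc) / 1e6)
      expect_lt(abs(got$p_gene - mc), 3 * mc_se)
      expect_equal(got$method, "imhof")
    }
  })
})

test_that("gene z is strictly decreasing in the gene p-value", {
  R <- random_corr(4, 53)
  withr::with_seed(43, {
    res <- purrr::map_dfr(1:15, ~ gene_pvalue(runif(4), R))
  })
  ord <- order(res$p_gene)
  expect_true(all(diff(res$z[ord]) < 0))
})

test_that("invalid inputs to the gene statistic are rejected", {
  expect_error(gene_pvalue(numeric(), matrix(1)), "at least one")
  expect_error(gene_pvalue(0, matrix(1)), "clamp")
  expect_error(gene_pvalue(c(0.5, 0.5), matrix(1)), "dim")
  bad <- matrix(c(1, 2, 2, 1), 2) # |r| > 1: not PSD
  expect_error(gene_pvalue(c(0.5, 0.5), bad), "positive semidefinite")
})

test_that("gene p-values are uniform under the global null", {
  cfg <- sim_config(n_genes = 5000, ld_block_size = 5, ld_rho = 0.5,
                    tau2_null = 0, tau2_enriched = 0, seed = 44)
  g <- sim_gene_table(cfg)
  sim <- sim_gwas(g, cfg)
  gs <- gene_stats(sim$sumstats, sim$ld, g)
  expect_equal(nrow(gs), 5000)
  ks <- suppressWarnings(ks.test(gs$p_gene, "punif"))
  expect_gt(ks$p.value, 0.01)
})
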