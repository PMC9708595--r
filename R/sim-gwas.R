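#' Simulate GWAS summary statistics with block LD
#'
#' Each gene owns one independent LD block of `ld_block_size` SNPs with an
#' AR(1) correlation matrix `R` (`R[i, j] = ld_rho^|i - j|`). Per-SNP joint
#' effects `b` are drawn independently with variance `tau2_enriched` when the
#' gene belongs to an enriched set and `tau2_null` otherwise, and the SNP
#' z-scores follow the standard summary-statistic model
#' `z ~ MVN(R b sqrt(N), R)`. Two-sided p-values, INFO scores and optional
#' QC hazards (duplicate records, low-INFO records) complete the table.
#'
#' @param genes Gene table from [sim_gene_table()].
#' @param cfg A [sim_config()]; uses `ld_block_size`, `ld_rho`, `gwas_n`,
#'   `tau2_null`, `tau2_enriched`, `dup_snp_frac`, `low_info_frac`, `seed`.
#' @param enriched_sets Optional set membership: a long gene-set tibble with
#'   columns `set`, `gene_id` (members of sets named in
#'   `cfg$enriched_set_names` are enriched) or a plain character vector of
#'   enriched gene ids.
#' @return A list with components `sumstats` (tibble: `snp`, `chrom`, `bp`,
#'   `p`, `info`, `n`) and `ld` (tibble: `gene_id`, `snps` list-column,
#'   `R` list-column of correlation matrices).
#' @examples
#' cfg <- sim_config(n_genes = 20, ld_block_size = 4, seed = 1)
#' g <- sim_gene_table(cfg)
#' sim <- sim_gwas(g, cfg)
#' head(sim$sumstats)
#' @export
sim_gwas <- function(genes, cfg, enriched_sets = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_cols(genes, c("gene_id", "chrom", "start", "stop"), "gene table")
  m <- as.integer(cfg$ld_block_size)
  if (m < 1) abort_input("`ld_block_size` must be >= 1")
  if (cfg$ld_rho >= 1) {
    abort_input("`ld_rho` must be < 1 for a positive-definite LD block")
  }
  enriched_genes <- resolve_enriched_genes(enriched_sets, cfg)
  G <- nrow(genes)
  R <- ar1_corr(m, cfg$ld_rho)
  U <- chol(R)

  with_seed(sub_seed(cfg$seed, 23L), {
    tau2 <- if_else(genes$gene_id %in% enriched_genes,
                    cfg$tau2_enriched, cfg$tau2_null)
    B <- matrix(rnorm(m * G, 0, sqrt(rep(tau2, each = m))), nrow = m)
    E <- matrix(rnorm(m * G), nrow = m)
    Z <- sqrt(cfg$gwas_n) * (R %*% B) + crossprod(U, E)

    bp <- purrr::map2(genes$start, genes$stop, function(a, b) {
      as.integer(round(seq(a, b, length.out = m)))
    })
    snp_ids <- purrr::map(genes$gene_id, function(g) {
      sprintf("%s_snp%02d", g, seq_len(m))
    })
    ss <- tibble(
      snp = unlist(snp_ids),
      chrom = rep(genes$chrom, each = m),
      bp = unlist(bp),
      p = clamp_p(2 * pnorm(-abs(as.vector(Z)))),
      info = runif(m * G, 0.8, 1),
      n = as.integer(cfg$gwas_n)
    )
    if (cfg$low_info_frac > 0) {
      lo <- runif(nrow(ss)) < cfg$low_info_frac
      ss$info[lo] <- runif(sum(lo), 0, 0.8 - 1e-9)
    }
    if (cfg$dup_snp_frac > 0) {
      dup <- ss[runif(nrow(ss)) < cfg$dup_snp_frac, ]
      ss <- bind_rows(ss, dup) %>% arrange(.data$chrom, .data$bp, .data$snp)
    }
    ld <- tibble(
      gene_id = genes$gene_id,
      snps = snp_ids,
      R = rep(list(R), G)
    )
    list(sumstats = ss, ld = ld)
  })
}

resolve_enriched_genes <- function(enriched_sets, cfg) {
  if (is.null(enriched_sets)) return(character())
  if (is.character(enriched_sets)) return(unique(enriched_sets))
  assert_cols(enriched_sets, c("set", "gene_id"), "enriched_sets")
  enriched_sets %>%
    filter(.data$set %in% cfg$enriched_set_names) %>%
    pull("gene_id") %>%
    unique()
}

# AR(1) correlation matrix rho^|i-j|.
ar1_corr <- function(m, rho) {
  if (rho < 0 || rho >= 1) abort_input("AR(1) rho must be in [0, 1)")
  outer(seq_len(m), seq_len(m), function(i, j) rho^abs(i - j))
}
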