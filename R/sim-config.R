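#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator into a validated
#' list. The defaults describe the study conditions the pipeline is designed
#' around: a GWAS of 105,318 individuals, 14 human and 24 mouse brain cell
#' types with the top 1600 genes selected per type, 35 synaptic gene-sets of
#' 50+ genes, an exome cohort of 4625 cases and 5966 controls, and a combined
#' cohort + reference panel of 188,023 individuals for singleton calling.
#'
#' @param n_genes Number of genes in the synthetic genome. The default of
#'   12,000 makes the top-1600 cell-type selection roughly 15% of the
#'   qualifying brain-expressed genes, the proportion the selection is
#'   designed around.
#' @param n_cell_types_human,n_cell_types_mouse Numbers of cell types in the
#'   human and mouse expression matrices.
#' @param markers_per_type Planted marker genes per cell type (elevated
#'   expression specificity in that type only).
#' @param synaptic_set_sizes Integer vector of raw synaptic gene-set sizes.
#' @param ld_block_size SNPs per gene; each gene owns one independent LD
#'   block.
#' @param ld_rho AR(1) correlation between adjacent SNPs within a block,
#'   in `[0, 1)`.
#' @param gwas_n GWAS sample size used to scale simulated SNP z-scores.
#' @param tau2_null,tau2_enriched Per-SNP effect-size variance outside and
#'   inside enriched gene-sets.
#' @param enriched_set_names Names of the gene-sets whose member genes get
#'   `tau2_enriched` in the GWAS simulation (and the planted burden effect in
#'   the exome simulation unless overridden).
#' @param n_cases,n_controls Exome cohort case/control totals.
#' @param mu_ptv,mu_syn Per-gene, per-individual expected counts of
#'   qualifying protein-truncating and synonymous alleles.
#' @param burden_logor Planted per-allele log-odds of case status for
#'   qualifying PTVs in causal gene-sets.
#' @param ref_panel_n Reference-panel individuals added to the cohort when
#'   forming the allele-frequency denominator (cohort + panel = 188,023 under
#'   the defaults).
#' @param singleton_frac Fraction of simulated variants whose reference-panel
#'   allele count is forced to zero, so that true singletons exist.
#' @param ref_ac_rate Poisson rate for the reference-panel allele count of
#'   non-singleton variants.
#' @param variant_recur_prob Probability that a simulated allele joins an
#'   existing variant of its gene rather than founding a new site.
#' @param pli_p_hi Mixture weight of the high (constrained) pLI component.
#' @param pli_shape_lo,pli_shape_hi Beta shape pairs `c(a, b)` for the low
#'   and high pLI mixture components.
#' @param frac_unexpressed Fraction of genes simulated as not brain-expressed
#'   (near-zero expression in all cell types).
#' @param homology_coverage Fraction of human genes with a mouse homologue.
#' @param homology_ambiguous_frac Fraction of mapped mouse genes given a
#'   second human target (exercises the many-to-many drop policy).
#' @param dup_snp_frac,low_info_frac Fractions of GWAS records duplicated or
#'   assigned INFO below 0.8, to exercise summary-statistic QC.
#' @param seed Integer seed; identical configurations produce identical
#'   outputs.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 7)
#' cfg$gwas_n
#' @export
sim_config <- function(n_genes = 12000,
                       n_cell_types_human = 14,
                       n_cell_types_mouse = 24,
                       markers_per_type = 100,
                       synaptic_set_sizes = seq(50L, 220L, by = 5L),
                       ld_block_size = 10,
                       ld_rho = 0.6,
                       gwas_n = 105318,
                       tau2_null = 1e-6,
                       tau2_enriched = 5e-6,
                       enriched_set_names = "PI",
                       n_cases = 4625,
                       n_controls = 5966,
                       mu_ptv = 7.5e-5,
                       mu_syn = 4e-4,
                       burden_logor = 0.3,
                       ref_panel_n = 188023 - n_cases - n_controls,
                       singleton_frac = 0.5,
                       ref_ac_rate = 3,
                       variant_recur_prob = 0.3,
                       pli_p_hi = 0.15,
                       pli_shape_lo = c(0.5, 8),
                       pli_shape_hi = c(8, 0.5),
                       frac_unexpressed = 0.1,
                       homology_coverage = 0.9,
                       homology_ambiguous_frac = 0.02,
                       dup_snp_frac = 0,
                       low_info_frac = 0,
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes,
    n_cell_types_human = n_cell_types_human,
    n_cell_types_mouse = n_cell_types_mouse,
    markers_per_type = markers_per_type,
    synaptic_set_sizes = as.integer(synaptic_set_sizes),
    ld_block_size = ld_block_size,
    ld_rho = ld_rho,
    gwas_n = gwas_n,
    tau2_null = tau2_null,
    tau2_enriched = tau2_enriched,
    enriched_set_names = enriched_set_names,
    n_cases = n_cases,
    n_controls = n_controls,
    mu_ptv = mu_ptv,
    mu_syn = mu_syn,
    burden_logor = burden_logor,
    ref_panel_n = ref_panel_n,
    singleton_frac = singleton_frac,
    ref_ac_rate = ref_ac_rate,
    variant_recur_prob = variant_recur_prob,
    pli_p_hi = pli_p_hi,
    pli_shape_lo = pli_shape_lo,
    pli_shape_hi = pli_shape_hi,
    frac_unexpressed = frac_unexpressed,
    homology_coverage = homology_coverage,
    homology_ambiguous_frac = homology_ambiguous_frac,
    dup_snp_frac = dup_snp_frac,
    low_info_frac = low_info_frac,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_genes", "n_cell_types_human", "n_cell_types_mouse",
              "markers_per_type", "ld_block_size", "gwas_n", "n_cases",
              "n_controls", "ref_panel_n")
  for (nm in counts) {
    assert_scalar_number(cfg[[nm]], nm, lower = 0)
  }
  assert_scalar_number(cfg$ld_rho, "ld_rho", lower = 0, upper = 1,
                       allow_boundary = c(TRUE, FALSE))
  for (nm in c("tau2_null", "tau2_enriched", "mu_ptv", "mu_syn",
               "ref_ac_rate")) {
    assert_scalar_number(cfg[[nm]], nm, lower = 0)
  }
  for (nm in c("singleton_frac", "variant_recur_prob", "pli_p_hi",
               "frac_unexpressed", "homology_coverage",
               "homology_ambiguous_frac", "dup_snp_frac", "low_info_frac")) {
    assert_scalar_number(cfg[[nm]], nm, lower = 0, upper = 1)
  }
  if (length(cfg$synaptic_set_sizes) > 0 &&
      any(cfg$synaptic_set_sizes < 0)) {
    abort_input("`synaptic_set_sizes` must be nonnegative")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genes: %d | GWAS N: %d | cohort: %d/%d (+%d panel)\n",
              x$n_genes, x$gwas_n, x$n_cases, x$n_controls, x$ref_panel_n))
  cat(sprintf("  cell types: %d human, %d mouse | synaptic sets: %d\n",
              x$n_cell_types_human, x$n_cell_types_mouse,
              length(x$synaptic_set_sizes)))
  cat(sprintf("  LD: %d SNPs/gene, rho = %.2f | tau2: %g null / %g enriched\n",
              x$ld_block_size, x$ld_rho, x$tau2_null, x$tau2_enriched))
  cat(sprintf("  burden log-OR: %g | seed: %d\n", x$burden_logor, x$seed))
  invisible(x)
}
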