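#' Classify variants by allele frequency
#'
#' The total allele count pools the in-sample and reference-panel counts;
#' the allele frequency denominator is `2 * panel_total_n` chromosomes
#' (cohort plus panel combined). Flags: `singleton` (total AC exactly 1,
#' the ultra-rare class), `rare_incl` (AF strictly below `af_max`,
#' singletons included) and `rare_excl` (AF below `af_max` and total AC at
#' least 2, i.e. rare excluding singletons).
#'
#' @param variants Tibble with `ac_sample`, `ac_ref` (and typically
#'   `variant_id`, `gene_id`, `consequence`).
#' @param panel_total_n Combined cohort + reference-panel individuals.
#' @param af_max Rare-variant frequency threshold, default 0.001.
#' @return The input with added columns `ac_total`, `af`, `singleton`,
#'   `rare_incl`, `rare_excl`.
#' @examples
#' v <- tibble::tibble(ac_sample = c(1L, 2L, 900L), ac_ref = c(0L, 0L, 0L))
#' classify_variants(v, panel_total_n = 188023)
#' @export
classify_variants <- function(variants, panel_total_n, af_max = 0.001) {
  assert_cols(variants, c("ac_sample", "ac_ref"), "variants")
  assert_scalar_number(panel_total_n, "panel_total_n", lower = 1)
  if (nrow(variants) > 0 &&
      (any(variants$ac_sample < 0) || any(variants$ac_ref < 0))) {
    abort_input("allele counts must be nonnegative")
  }
  variants %>% mutate(
    ac_total = .data$ac_sample + .data$ac_ref,
    af = .data$ac_total / (2 * panel_total_n),
    singleton = .data$ac_total == 1L,
    # an unobserved allele (AC 0) belongs to no frequency class
    rare_incl = .data$af < af_max & .data$ac_total >= 1L,
    rare_excl = .data$af < af_max & .data$ac_total >= 2L
  )
}

# Frequency-class flag column used by a class label.
class_flag <- function(vclass) {
  switch(vclass,
         urv = "singleton",
         rare = "rare_incl",
         rare_excl = "rare_excl",
         abort_input(sprintf("unknown variant class '%s'", vclass)))
}

#' Median-absolute-deviation sample QC
#'
#' Excludes individuals whose synonymous qualifying-variant count deviates
#' from the cohort median by more than `k` median absolute deviations. The
#' MAD is unscaled (no normal-consistency factor) and "more than" is
#' strict, so a MAD of zero excludes any individual with a nonzero
#' deviation only when that deviation is positive.
#'
#' @param counts Numeric vector of per-individual synonymous counts.
#' @param k Deviation multiplier, default 4.
#' @return Logical keep-flags in input order.
#' @examples
#' sample_qc_mad(c(7, 8, 8, 9, 9, 10, 50))
#' @export
sample_qc_mad <- function(counts, k = 4) {
  if (length(counts) < 1) abort_input("at least one individual is required")
  med <- median(counts)
  mad_u <- median(abs(counts - med))
  abs(counts - med) <= k * mad_u
}

#' Per-individual burden scores for one gene-set and variant class
#'
#' Counts each QC-passing individual's qualifying alleles of the given
#' consequence and frequency class, inside the set and exome-wide. Gene ids
#' in the set but absent from the cohort are ignored (their count is
#' logged on the `"unknown_genes"` attribute).
#'
#' @param cohort An `exome_cohort`.
#' @param set_genes Character vector of member gene ids.
#' @param vclass Frequency class: `"urv"` (singletons), `"rare"`
#'   (AF < `af_max` incl. singletons) or `"rare_excl"` (AF < `af_max`,
#'   singletons excluded).
#' @param consequence `"PTV"` or `"synonymous"`.
#' @param af_max Rare-frequency threshold passed to [classify_variants()].
#' @param keep Optional character vector of individual ids to score
#'   (QC-passing subset); default all.
#' @return Tibble: `individual_id`, `score` (set burden), `exome_wide`.
#' @export
burden_score <- function(cohort, set_genes, vclass, consequence,
                         af_max = 0.001, keep = NULL) {
  stopifnot(inherits(cohort, "exome_cohort"))
  flag <- class_flag(vclass)
  cls <- classify_variants(cohort$variants, cohort$panel_total_n, af_max)
  qual <- cls %>%
    filter(.data$consequence == !!consequence, .data[[flag]])
  unknown <- setdiff(set_genes, cohort$variants$gene_id)
  ids <- keep %||% cohort$individuals$individual_id
  counts <- cohort$carriers %>%
    filter(.data$individual_id %in% ids) %>%
    inner_join(qual %>% select("variant_id", "gene_id"), by = "variant_id")
  exome <- counts %>%
    group_by(.data$individual_id) %>%
    summarise(exome_wide = sum(.data$dosage), .groups = "drop")
  in_set <- counts %>%
    filter(.data$gene_id %in% set_genes) %>%
    group_by(.data$individual_id) %>%
    summarise(score = sum(.data$dosage), .groups = "drop")
  out <- tibble(individual_id = ids) %>%
    left_join(in_set, by = "individual_id") %>%
    left_join(exome, by = "individual_id") %>%
    mutate(score = if_else(is.na(.data$score), 0L, as.integer(.data$score)),
           exome_wide = if_else(is.na(.data$exome_wide), 0L,
                                as.integer(.data$exome_wide)))
  attr(out, "unknown_genes") <- length(unknown)
  out
}

# Synonymous class counts per individual, used by the MAD filter.
syn_class_counts <- function(cohort, vclass, af_max = 0.001) {
  burden_score(cohort, character(), vclass, "synonymous",
               af_max = af_max)$exome_wide
}

#' QC-passing individuals for a frequency class
#'
#' Applies the synonymous-count MAD filter of [sample_qc_mad()] within the
#' given frequency class and returns the retained individual ids.
#'
#' @inheritParams burden_score
#' @param mad_k MAD multiplier, default 4.
#' @return Character vector of individual ids passing QC.
#' @export
qc_individuals <- function(cohort, vclass, mad_k = 4, af_max = 0.001) {
  keep <- sample_qc_mad(syn_class_counts(cohort, vclass, af_max), k = mad_k)
  cohort$individuals$individual_id[keep]
}
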