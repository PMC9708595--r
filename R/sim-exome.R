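#' Simulate a case-control exome cohort with a planted burden effect
#'
#' Individuals acquire qualifying protein-truncating (PTV) and synonymous
#' alleles as independent Poisson events across genes (`mu_ptv`, `mu_syn`
#' expected alleles per gene per individual). Alleles within a gene either
#' found a new variant site or recur at the most recently founded site
#' (probability `variant_recur_prob`), so in-sample allele counts of 1, 2,
#' ... arise. Each variant also gets a reference-panel allele count: a
#' fraction `singleton_frac` is forced to zero (true singleton candidates),
#' the rest Poisson(`ref_ac_rate`). Case status is assigned prospectively by
#' a logistic model whose linear predictor adds `burden_logor` per qualifying
#' PTV allele in the causal gene-sets plus small sex and principal-component
#' effects; the intercept targets a case fraction of
#' `n_cases / (n_cases + n_controls)`. Synonymous alleles never enter the
#' linear predictor, making them an exact negative control.
#'
#' @param genes Gene table from [sim_gene_table()].
#' @param cfg A [sim_config()].
#' @param causal_sets Gene-set membership carrying the planted burden effect:
#'   a long tibble (`set`, `gene_id`; sets named in
#'   `cfg$enriched_set_names` are causal) or a character vector of causal
#'   gene ids. `NULL` plants no effect.
#' @return An object of class `exome_cohort`: a list with `individuals`
#'   (tibble: `individual_id`, `case` 0/1, `sex` 0/1, `PC1`..`PC10`),
#'   `variants` (tibble: `variant_id`, `gene_id`, `consequence`
#'   `"PTV"`/`"synonymous"`, `ac_sample`, `ac_ref`), `carriers` (tibble:
#'   `variant_id`, `individual_id`, `dosage`), and `panel_total_n`.
#' @examples
#' cfg <- sim_config(n_genes = 50, n_cases = 40, n_controls = 40,
#'                   mu_ptv = 0.01, mu_syn = 0.02, seed = 2)
#' cohort <- sim_exome_cohort(sim_gene_table(cfg), cfg)
#' cohort
#' @export
sim_exome_cohort <- function(genes, cfg, causal_sets = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_cols(genes, "gene_id", "gene table")
  if (cfg$n_cases < 1 || cfg$n_controls < 1) {
    abort_input("`n_cases` and `n_controls` must both be >= 1")
  }
  if (cfg$mu_ptv < 0 || cfg$mu_syn < 0) {
    abort_input("per-gene mutation rates must be nonnegative")
  }
  n_ind <- as.integer(cfg$n_cases + cfg$n_controls)
  causal_genes <- resolve_enriched_genes(causal_sets, cfg)

  with_seed(sub_seed(cfg$seed, 37L), {
    ids <- sprintf("I%06d", seq_len(n_ind))
    pcs <- matrix(rnorm(n_ind * 10), ncol = 10,
                  dimnames = list(NULL, paste0("PC", 1:10)))
    individuals <- tibble(
      individual_id = ids,
      sex = rbinom(n_ind, 1, 0.5)
    ) %>% bind_cols(as_tibble(pcs))

    events <- bind_rows(
      sim_allele_events(genes$gene_id, n_ind, cfg$mu_ptv, "PTV"),
      sim_allele_events(genes$gene_id, n_ind, cfg$mu_syn, "synonymous")
    )

    if (nrow(events) > 0) {
      # allele -> variant assignment, per gene and consequence
      events <- events %>%
        group_by(.data$gene_id, .data$consequence) %>%
        mutate(variant_idx = cumsum(
          c(TRUE, runif(n() - 1L) >= cfg$variant_recur_prob)
        )) %>%
        ungroup() %>%
        mutate(variant_id = sprintf(
          "%s_%s_v%03d", .data$gene_id,
          if_else(.data$consequence == "PTV", "ptv", "syn"),
          .data$variant_idx
        ))
      carriers <- events %>%
        count(.data$variant_id, .data$individual_idx, name = "dosage") %>%
        mutate(dosage = pmin(.data$dosage, 2L),
               individual_id = ids[.data$individual_idx]) %>%
        select("variant_id", "individual_id", "dosage")
      variants <- events %>%
        distinct(.data$variant_id, .data$gene_id, .data$consequence) %>%
        inner_join(
          carriers %>%
            group_by(.data$variant_id) %>%
            summarise(ac_sample = sum(.data$dosage), .groups = "drop"),
          by = "variant_id"
        ) %>%
        arrange(.data$variant_id)
      singleton <- runif(nrow(variants)) < cfg$singleton_frac
      variants$ac_ref <- if_else(singleton, 0L,
                                 rpois(nrow(variants), cfg$ref_ac_rate))
    } else {
      carriers <- tibble(variant_id = character(),
                         individual_id = character(), dosage = integer())
      variants <- tibble(variant_id = character(), gene_id = character(),
                         consequence = character(), ac_sample = integer(),
                         ac_ref = integer())
    }

    causal_count <- integer(n_ind)
    if (nrow(events) > 0 && length(causal_genes) > 0) {
      cc <- events %>%
        filter(.data$consequence == "PTV",
               .data$gene_id %in% causal_genes) %>%
        count(.data$individual_idx)
      causal_count[cc$individual_idx] <- cc$n
    }
    alpha <- qlogis(cfg$n_cases / n_ind)
    lp <- alpha +
      cfg$burden_logor * (causal_count - mean(causal_count)) +
      0.1 * (individuals$sex - mean(individuals$sex)) +
      0.05 * pcs[, 1] + 0.05 * pcs[, 2]
    individuals <- individuals %>%
      mutate(case = rbinom(n_ind, 1, plogis(lp)), .after = "individual_id")

    structure(
      list(
        individuals = individuals,
        variants = variants,
        carriers = carriers,
        panel_total_n = n_ind + as.integer(cfg$ref_panel_n)
      ),
      class = "exome_cohort"
    )
  })
}

# Poisson allele events over an individuals x genes grid, via superposition:
# total ~ Pois(n_ind * n_genes * mu), each event lands uniformly.
sim_allele_events <- function(gene_ids, n_ind, mu, consequence) {
  if (mu == 0 || length(gene_ids) == 0 || n_ind == 0) {
    return(tibble(gene_id = character(), individual_idx = integer(),
                  consequence = character()))
  }
  total <- rpois(1L, n_ind * length(gene_ids) * mu)
  if (total == 0) {
    return(tibble(gene_id = character(), individual_idx = integer(),
                  consequence = character()))
  }
  tibble(
    gene_id = sample(gene_ids, total, replace = TRUE),
    individual_idx = sample.int(n_ind, total, replace = TRUE),
    consequence = consequence
  ) %>% arrange(.data$gene_id, .data$individual_idx)
}

#' @export
print.exome_cohort <- function(x, ...) {
  cat("<exome_cohort>\n")
  cat(sprintf("  individuals: %d (%d cases / %d controls)\n",
              nrow(x$individuals), sum(x$individuals$case),
              sum(1 - x$individuals$case)))
  cat(sprintf("  variants: %d (%d PTV, %d synonymous)\n",
              nrow(x$variants),
              sum(x$variants$consequence == "PTV"),
              sum(x$variants$consequence == "synonymous")))
  cat(sprintf("  panel total n: %d\n", x$panel_total_n))
  invisible(x)
}

#' @importFrom dplyr bind_cols
NULL
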