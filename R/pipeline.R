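#' Pipeline run configuration
#'
#' Validated bundle of simulation settings and analysis thresholds used by
#' [run_all()]. Unknown keys (e.g. in a YAML file read by
#' [read_run_config()]) are rejected rather than ignored.
#'
#' @param sim Named list of [sim_config()] overrides.
#' @param pli_threshold Constrained-gene pLI cutoff.
#' @param top_n Genes per cell-type set.
#' @param min_expr Expression floor for qualification and backgrounds.
#' @param min_synaptic Minimum synaptic set size.
#' @param info_min GWAS INFO threshold.
#' @param af_max Rare-variant frequency threshold.
#' @param mad_k MAD multiplier for exome sample QC.
#' @param fdr_q FDR level per variant-frequency family.
#' @param min_set_size Minimum scored genes for a testable set.
#' @param classes Rare frequency classes to analyse.
#' @param conditioning Run the conditional analyses.
#' @param strict Strict mode: fewer than `top_n` qualifying genes is an
#'   error instead of a warning.
#' @param write_inputs Also write the simulated inputs (GMT, sumstats,
#'   gene-loc, covariates, VCF) to `out_dir`.
#' @param out_dir Output directory for [run_all()] artifacts.
#' @param seed Optional integer overriding `sim$seed`.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = list(), pli_threshold = 0.9, top_n = 1600,
                       min_expr = 0.5, min_synaptic = 50, info_min = 0.8,
                       af_max = 0.001, mad_k = 4, fdr_q = 0.05,
                       min_set_size = 10,
                       classes = c("urv", "rare_excl"),
                       conditioning = TRUE, strict = FALSE,
                       write_inputs = FALSE, out_dir = NULL, seed = NULL) {
  assert_scalar_number(pli_threshold, "pli_threshold", 0, 1)
  assert_scalar_number(top_n, "top_n", lower = 0)
  assert_scalar_number(min_expr, "min_expr", lower = 0)
  assert_scalar_number(min_synaptic, "min_synaptic", lower = 0)
  assert_scalar_number(info_min, "info_min", 0, 1)
  assert_scalar_number(af_max, "af_max", 0, 1)
  assert_scalar_number(mad_k, "mad_k", lower = 0)
  assert_scalar_number(fdr_q, "fdr_q", 0, 1)
  assert_scalar_number(min_set_size, "min_set_size", lower = 0)
  bad <- setdiff(classes, c("urv", "rare", "rare_excl"))
  if (length(bad) > 0) {
    abort_input(sprintf("unknown rare class(es): %s",
                        paste(bad, collapse = ", ")))
  }
  structure(
    list(sim = sim, pli_threshold = pli_threshold, top_n = top_n,
         min_expr = min_expr, min_synaptic = min_synaptic,
         info_min = info_min, af_max = af_max, mad_k = mad_k,
         fdr_q = fdr_q, min_set_size = min_set_size, classes = classes,
         conditioning = isTRUE(conditioning), strict = isTRUE(strict),
         write_inputs = isTRUE(write_inputs), out_dir = out_dir,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file whose top-level keys match the arguments of
#'   `run_config()`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  vals <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), "")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0) {
    abort_input(sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' Build the full gene-set collection from its raw inputs
#'
#' Orchestrates [select_pi()], [cell_type_sets()], [map_homologs()],
#' [filter_synaptic()], [intersect_pi()] and [background_sets()] into one
#' assembled collection: constrained genes, human and mouse cell-type sets,
#' synaptic sets, all cell-type-by-PI intersections, and brain-expressed
#' background sets for conditioning.
#'
#' @param genes Gene table with `pli`.
#' @param expr_human,expr_mouse Wide expression tibbles (mouse over mouse
#'   gene ids).
#' @param homology Mouse-to-human homology tibble.
#' @param synaptic_raw Raw synaptic gene-set tibble.
#' @inheritParams run_config
#' @return Long gene-set tibble (see [assemble_collection()]).
#' @export
build_all_sets <- function(genes, expr_human, expr_mouse, homology,
                           synaptic_raw, pli_threshold = 0.9,
                           top_n = 1600, min_expr = 0.5,
                           min_synaptic = 50, strict = FALSE) {
  pi <- select_pi(genes, threshold = pli_threshold)
  human <- cell_type_sets(expr_human, n = top_n, min_expr = min_expr,
                          category = "human_cell", strict = strict)
  mouse_raw <- cell_type_sets(expr_mouse, n = top_n, min_expr = min_expr,
                              category = "mouse_cell", strict = strict)
  mouse <- map_homologs(mouse_raw, homology)
  synaptic <- filter_synaptic(synaptic_raw, min_size = min_synaptic)
  inter <- intersect_pi(bind_rows(human, mouse), pi)
  bg <- background_sets(expr_human, min_expr = min_expr)
  assemble_collection(pi, human, mouse, synaptic, inter, bg)
}

#' Simulate every pipeline input
#'
#' Generates the gene table, human and mouse expression matrices, homology
#' map, raw synaptic sets, the assembled collection, the GWAS summary
#' statistics with their LD reference (enrichment planted in
#' `cfg$enriched_set_names`), and the exome cohort with the planted burden
#' effect in the same sets.
#'
#' @param cfg A [sim_config()].
#' @param config A [run_config()] supplying thresholds.
#' @return Named list: `genes`, `expr_human`, `expr_mouse`, `homology`,
#'   `synaptic_raw`, `collection`, `gwas` (list `sumstats`, `ld`),
#'   `cohort`.
#' @export
simulate_inputs <- function(cfg, config = run_config()) {
  genes <- sim_gene_table(cfg)
  expr_human <- sim_expression(
    genes, cfg$n_cell_types_human, cfg$markers_per_type,
    seed = sub_seed(cfg$seed, 101L), cell_type_prefix = "hum",
    frac_unexpressed = cfg$frac_unexpressed
  )
  homology <- sim_homology(genes, coverage = cfg$homology_coverage,
                           seed = sub_seed(cfg$seed, 103L),
                           ambiguous_frac = cfg$homology_ambiguous_frac)
  expr_mouse <- sim_expression(
    unique(homology$mouse_id), cfg$n_cell_types_mouse,
    min(cfg$markers_per_type,
        length(unique(homology$mouse_id)) %/%
          max(1L, cfg$n_cell_types_mouse)),
    seed = sub_seed(cfg$seed, 105L), cell_type_prefix = "mus",
    frac_unexpressed = cfg$frac_unexpressed
  )
  synaptic_raw <- sim_synaptic_sets(genes, cfg$synaptic_set_sizes,
                                    seed = sub_seed(cfg$seed, 107L))
  collection <- build_all_sets(
    genes, expr_human, expr_mouse, homology, synaptic_raw,
    pli_threshold = config$pli_threshold, top_n = config$top_n,
    min_expr = config$min_expr, min_synaptic = config$min_synaptic,
    strict = config$strict
  )
  gwas <- sim_gwas(genes, cfg, enriched_sets = collection)
  cohort <- sim_exome_cohort(genes, cfg, causal_sets = collection)
  list(genes = genes, expr_human = expr_human, expr_mouse = expr_mouse,
       homology = homology, synaptic_raw = synaptic_raw,
       collection = collection, gwas = gwas, cohort = cohort)
}

#' Run the whole pipeline end to end
#'
#' Simulate (seeded) inputs, build the gene-set collection, run the
#' common-variant competitive analyses and the rare-variant burden
#' analyses (with conditional schemes when `conditioning` is on), apply
#' per-frequency FDR, compute the convergence report, and write all result
#' tables plus a manifest recording the configuration, seed and artifact
#' checksums. Identical configuration and seed reproduce identical
#' artifact checksums.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); overrides
#'   `config$out_dir`.
#' @return Invisibly, a list with `collection`, `common`, `rare`,
#'   `convergence`, `manifest` (path) and `artifacts` (named paths).
#' @export
run_all <- function(config = run_config(), out_dir = config$out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) abort_input("an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- config$sim
  if (!is.null(config$seed)) sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)

  inputs <- simulate_inputs(cfg, config)
  collection <- inputs$collection

  ss <- qc_gwas(inputs$gwas$sumstats, info_min = config$info_min)
  plan_common <- if (config$conditioning) {
    default_conditioning_plan(collection)
  } else NULL
  common <- run_common(ss, inputs$gwas$ld, inputs$genes, collection,
                       conditioning_plan = plan_common,
                       min_set_size = config$min_set_size) %>%
    add_fdr(q = config$fdr_q)

  plan_rare <- if (config$conditioning) {
    default_conditioning_plan(
      collection %>% filter(.data$category != "background")
    )
  } else NULL
  rare <- run_rare(inputs$cohort, collection, classes = config$classes,
                   conditioning_plan = plan_rare,
                   af_max = config$af_max, mad_k = config$mad_k,
                   min_set_size = config$min_set_size) %>%
    add_fdr(q = config$fdr_q)

  conv <- convergence_report(common, rare, q = config$fdr_q)

  paths <- c(
    genesets = file.path(out_dir, "genesets.gmt"),
    common = file.path(out_dir, "common_results.tsv"),
    rare = file.path(out_dir, "rare_results.tsv"),
    convergence = file.path(out_dir, "convergence.tsv"),
    overlap = file.path(out_dir, "overlap_sets.tsv")
  )
  write_gmt(collection, paths[["genesets"]])
  write_results(common, paths[["common"]])
  write_results(rare, paths[["rare"]])
  readr::write_tsv(conv %>% select(-"overlap_sets"),
                   paths[["convergence"]])
  overlap_tbl <- conv %>%
    filter(.data$method == "pearson") %>%
    select("pair", "overlap_sets") %>%
    tidyr::unnest_longer("overlap_sets", values_to = "set") %>%
    select(any_of(c("pair", "set")))
  readr::write_tsv(overlap_tbl, paths[["overlap"]])

  if (config$write_inputs) {
    write_gene_loc(inputs$genes, file.path(out_dir, "gene_loc.tsv"))
    write_sumstats(inputs$gwas$sumstats,
                   file.path(out_dir, "sumstats.tsv"))
    write_expression(inputs$expr_human,
                     file.path(out_dir, "expression_human.tsv"))
    write_expression(inputs$expr_mouse,
                     file.path(out_dir, "expression_mouse.tsv"))
    write_homology(inputs$homology, file.path(out_dir, "homology.tsv"))
    write_covariates(inputs$cohort$individuals,
                     file.path(out_dir, "covariates.tsv"))
    write_vcf_min(inputs$cohort, file.path(out_dir, "cohort.vcf"),
                  genes = inputs$genes)
  }

  manifest_path <- file.path(out_dir, "manifest.yaml")
  manifest <- list(
    package = "convergene",
    version = as.character(utils::packageVersion("convergene")),
    seed = cfg$seed,
    config = config_as_list(config),
    n_analysed_sets = n_analysed_sets(collection),
    checksums = as.list(tools::md5sum(unname(paths)))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  yaml::write_yaml(manifest, manifest_path)

  invisible(list(collection = collection, common = common, rare = rare,
                 convergence = conv, manifest = manifest_path,
                 artifacts = paths))
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$out_dir <- NULL
  out
}
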