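#' Minimal VCF writer and reader for the exome cohort
#'
#' The dialect is VCFv4.2 with required INFO keys `GENE` (gene id),
#' `CSQ_CLASS` (`PTV` or `SYN`) and `AC_REF` (reference-panel allele
#' count), and a single `GT` FORMAT field over the cohort samples
#' (`0/0`, `0/1`, `1/1`). Other INFO keys are ignored with a count.
#' Parsing is delegated to `vcfR`.
#'
#' @param cohort An `exome_cohort`.
#' @param path Output path.
#' @param genes Optional gene table used to place variants inside their
#'   gene; without it variants get synthetic sequential positions.
#' @return `write_vcf_min()`: the path, invisibly.
#' @export
write_vcf_min <- function(cohort, path, genes = NULL) {
  stopifnot(inherits(cohort, "exome_cohort"))
  ids <- cohort$individuals$individual_id
  v <- cohort$variants %>% arrange(.data$variant_id)
  if (!is.null(genes)) {
    v <- v %>% left_join(genes %>% select("gene_id", "chrom", "start"),
                         by = "gene_id") %>%
      group_by(.data$gene_id) %>%
      mutate(pos = .data$start + row_number() - 1L) %>%
      ungroup()
  } else {
    v <- v %>% mutate(chrom = "chr1", pos = row_number())
  }
  gt <- matrix("0/0", nrow = nrow(v), ncol = length(ids),
               dimnames = list(v$variant_id, ids))
  if (nrow(cohort$carriers) > 0) {
    idx <- cbind(match(cohort$carriers$variant_id, v$variant_id),
                 match(cohort$carriers$individual_id, ids))
    gt[idx] <- if_else(cohort$carriers$dosage >= 2, "1/1", "0/1")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    paste0("##INFO=<ID=CSQ_CLASS,Number=1,Type=String,",
           "Description=\"Consequence class (PTV or SYN)\">"),
    paste0("##INFO=<ID=AC_REF,Number=1,Type=Integer,",
           "Description=\"Reference panel allele count\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", ids), collapse = "\t")
  )
  info <- sprintf("GENE=%s;CSQ_CLASS=%s;AC_REF=%d", v$gene_id,
                  if_else(v$consequence == "PTV", "PTV", "SYN"), v$ac_ref)
  body <- paste(v$chrom, v$pos, v$variant_id, "A", "T", ".", "PASS",
                info, "GT", apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_vcf_min
#' @return `read_vcf_min()`: list with `variants` (tibble: `variant_id`,
#'   `gene_id`, `consequence`, `ac_sample`, `ac_ref`), `carriers` (tibble:
#'   `variant_id`, `individual_id`, `dosage`) and `sample_ids`.
#' @export
read_vcf_min <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  n_rec <- nrow(vcf@fix)
  if (is.null(n_rec) || n_rec == 0) {
    return(list(
      variants = tibble(variant_id = character(), gene_id = character(),
                        consequence = character(), ac_sample = integer(),
                        ac_ref = integer()),
      carriers = tibble(variant_id = character(),
                        individual_id = character(), dosage = integer()),
      sample_ids = character()
    ))
  }
  gene <- vcfR::extract.info(vcf, element = "GENE")
  csq <- vcfR::extract.info(vcf, element = "CSQ_CLASS")
  ac_ref <- vcfR::extract.info(vcf, element = "AC_REF", as.numeric = TRUE)
  for (nm in c("GENE", "CSQ_CLASS", "AC_REF")) {
    val <- switch(nm, GENE = gene, CSQ_CLASS = csq, AC_REF = ac_ref)
    if (any(is.na(val))) {
      abort_input(sprintf("VCF record missing required INFO key %s", nm),
                  class = "convergene_schema_error")
    }
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  ids <- colnames(gt_raw)
  dosage <- matrix(0L, nrow = n_rec, ncol = length(ids))
  dosage[gt_raw == "0/1" | gt_raw == "1/0" | gt_raw == "0|1" |
           gt_raw == "1|0"] <- 1L
  dosage[gt_raw == "1/1" | gt_raw == "1|1"] <- 2L
  variant_id <- vcf@fix[, "ID"]
  variants <- tibble(
    variant_id = variant_id,
    gene_id = gene,
    consequence = if_else(csq == "PTV", "PTV", "synonymous"),
    ac_sample = as.integer(rowSums(dosage)),
    ac_ref = as.integer(ac_ref)
  )
  carrier_idx <- which(dosage > 0, arr.ind = TRUE)
  carriers <- tibble(
    variant_id = variant_id[carrier_idx[, 1]],
    individual_id = ids[carrier_idx[, 2]],
    dosage = dosage[carrier_idx]
  ) %>% arrange(.data$variant_id, .data$individual_id)
  list(variants = variants, carriers = carriers, sample_ids = ids)
}

#' Assemble an exome cohort from parsed components
#'
#' Constructor used when reading a cohort back from a minimal VCF and a
#' covariate table.
#'
#' @param individuals Tibble: `individual_id`, `case`, `sex`,
#'   `PC1`..`PC10`.
#' @param variants,carriers Tibbles as produced by [read_vcf_min()].
#' @param panel_total_n Combined cohort + reference-panel individuals.
#' @return An `exome_cohort`.
#' @export
exome_cohort <- function(individuals, variants, carriers, panel_total_n) {
  assert_cols(individuals, c("individual_id", "case", "sex",
                             paste0("PC", 1:10)), "individuals")
  assert_cols(variants, c("variant_id", "gene_id", "consequence",
                          "ac_sample", "ac_ref"), "variants")
  assert_cols(carriers, c("variant_id", "individual_id", "dosage"),
              "carriers")
  if (anyDuplicated(individuals$individual_id)) {
    abort_input("individual ids must be unique")
  }
  if (panel_total_n < nrow(individuals)) {
    abort_input("`panel_total_n` must be at least the cohort size")
  }
  structure(
    list(individuals = as_tibble(individuals),
         variants = as_tibble(variants),
         carriers = as_tibble(carriers),
         panel_total_n = as.integer(panel_total_n)),
    class = "exome_cohort"
  )
}
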