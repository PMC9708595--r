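#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then members, tab-separated.
#' Duplicate members within a line are collapsed with a warning; duplicate
#' set names are an error; lines with fewer than three fields are a parse
#' error naming the line.
#'
#' @param path File path.
#' @param category Category assigned to all sets read (the GMT format does
#'   not carry one); the description field is used when it matches a known
#'   category label.
#' @return `read_gmt()`: long gene-set tibble (`set`, `category`,
#'   `gene_id`).
#' @export
read_gmt <- function(path, category = NULL) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(set = character(), category = character(),
                  gene_id = character()))
  }
  known <- c("PI", "human_cell", "mouse_cell", "synaptic", "intersection",
             "background")
  rows <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort_input(sprintf("GMT parse error at line %d: fewer than 3 fields",
                          i), class = "convergene_parse_error")
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      rlang::warn(sprintf("GMT line %d ('%s'): duplicate members collapsed",
                          i, fields[1]))
      members <- unique(members)
    }
    cat_i <- category %||%
      (if (fields[2] %in% known) fields[2] else "unknown")
    tibble(set = fields[1], category = cat_i, gene_id = members)
  })
  out <- bind_rows(rows)
  set_names <- unique(purrr::map_chr(rows, ~ .x$set[1]))
  if (length(set_names) < length(rows)) {
    abort_input("duplicate set names in GMT file")
  }
  out
}

#' @rdname read_gmt
#' @param collection Long gene-set tibble to write; the `category` is
#'   stored in the GMT description field.
#' @export
write_gmt <- function(collection, path) {
  assert_cols(collection, c("set", "category", "gene_id"), "collection")
  split_sets <- split(collection, factor(collection$set,
                                         levels = unique(collection$set)))
  lines <- purrr::map_chr(split_sets, function(df) {
    paste(c(df$set[1], df$category[1], df$gene_id), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

# Shared validated-TSV reader.
read_schema_tsv <- function(path, required, col_types, what) {
  if (!file.exists(path)) abort_input(sprintf("no such file: %s", path))
  df <- suppressWarnings(
    readr::read_tsv(path, col_types = col_types,
                    progress = FALSE, show_col_types = FALSE)
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_input(sprintf("%s file %s is missing column(s): %s", what, path,
                        paste(missing, collapse = ", ")),
                class = "convergene_schema_error")
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort_input(sprintf("%s file %s: unparsable value at row %d, column %d",
                        what, path, probs$row[1], probs$col[1]),
                class = "convergene_parse_error")
  }
  df
}

#' GWAS summary-statistic TSV
#'
#' Columns `SNP`, `CHR`, `BP`, `P`, `INFO`, `N` (1-based positions).
#'
#' @param path File path.
#' @return `read_sumstats()`: tibble with lower-case columns `snp`,
#'   `chrom`, `bp`, `p`, `info`, `n`.
#' @export
read_sumstats <- function(path) {
  df <- read_schema_tsv(path, c("SNP", "CHR", "BP", "P", "INFO", "N"),
                        readr::cols(SNP = "c", CHR = "c", BP = "i",
                                    P = "d", INFO = "d", N = "i"),
                        "sumstats")
  df %>% transmute(snp = .data$SNP, chrom = .data$CHR, bp = .data$BP,
                   p = .data$P, info = .data$INFO, n = .data$N)
}

#' @rdname read_sumstats
#' @param sumstats Tibble as returned by [sim_gwas()].
#' @export
write_sumstats <- function(sumstats, path) {
  assert_cols(sumstats, c("snp", "chrom", "bp", "p", "info", "n"),
              "sumstats")
  sumstats %>%
    transmute(SNP = .data$snp, CHR = .data$chrom, BP = .data$bp,
              P = .data$p, INFO = .data$info, N = .data$n) %>%
    readr::write_tsv(path)
  invisible(path)
}

#' Gene location TSV
#'
#' Columns `GENE`, `CHR`, `START`, `STOP` and optionally `PLI`
#' (1-based inclusive coordinates).
#'
#' @param path File path.
#' @return `read_gene_loc()`: tibble `gene_id`, `chrom`, `start`, `stop`
#'   (+ `pli` when present).
#' @export
read_gene_loc <- function(path) {
  df <- read_schema_tsv(path, c("GENE", "CHR", "START", "STOP"),
                        readr::cols(GENE = "c", CHR = "c", START = "i",
                                    STOP = "i", .default = "d"),
                        "gene location")
  out <- df %>% transmute(gene_id = .data$GENE, chrom = .data$CHR,
                          start = .data$START, stop = .data$STOP)
  if ("PLI" %in% names(df)) out$pli <- df$PLI
  out
}

#' @rdname read_gene_loc
#' @param genes Gene table.
#' @export
write_gene_loc <- function(genes, path) {
  assert_cols(genes, c("gene_id", "chrom", "start", "stop"), "gene table")
  out <- genes %>% transmute(GENE = .data$gene_id, CHR = .data$chrom,
                             START = .data$start, STOP = .data$stop)
  if ("pli" %in% names(genes)) out$PLI <- genes$pli
  readr::write_tsv(out, path)
  invisible(path)
}

#' Phenotype/covariate TSV
#'
#' Columns `IID`, `CASE`, `SEX`, `PC1`..`PC10`.
#'
#' @param path File path.
#' @return `read_covariates()`: tibble `individual_id`, `case`, `sex`,
#'   `PC1`..`PC10`.
#' @export
read_covariates <- function(path) {
  df <- read_schema_tsv(path, c("IID", "CASE", "SEX", paste0("PC", 1:10)),
                        readr::cols(IID = "c", CASE = "i", SEX = "i",
                                    .default = "d"),
                        "covariate")
  df %>%
    rename(individual_id = "IID", case = "CASE", sex = "SEX")
}

#' @rdname read_covariates
#' @param individuals Individuals tibble of an `exome_cohort`.
#' @export
write_covariates <- function(individuals, path) {
  assert_cols(individuals, c("individual_id", "case", "sex",
                             paste0("PC", 1:10)), "individuals")
  individuals %>%
    rename(IID = "individual_id", CASE = "case", SEX = "sex") %>%
    readr::write_tsv(path)
  invisible(path)
}

#' Expression matrix TSV
#'
#' `gene_id` column plus one column per cell type.
#'
#' @param path File path.
#' @return `read_expression()`: wide expression tibble.
#' @export
read_expression <- function(path) {
  df <- read_schema_tsv(path, "gene_id",
                        readr::cols(gene_id = "c", .default = "d"),
                        "expression")
  if (any(as.matrix(df[setdiff(names(df), "gene_id")]) < 0)) {
    abort_input("expression file contains negative values")
  }
  df
}

#' @rdname read_expression
#' @param expr Wide expression tibble.
#' @export
write_expression <- function(expr, path) {
  assert_cols(expr, "gene_id", "expression")
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Homology map TSV (two columns)
#'
#' @param path File path.
#' @return `read_homology()`: tibble `mouse_id`, `human_id`.
#' @export
read_homology <- function(path) {
  read_schema_tsv(path, c("mouse_id", "human_id"),
                  readr::cols(.default = "c"), "homology")
}

#' @rdname read_homology
#' @param map Homology tibble.
#' @export
write_homology <- function(map, path) {
  assert_cols(map, c("mouse_id", "human_id"), "homology map")
  readr::write_tsv(map, path)
  invisible(path)
}

#' Enrichment results TSV
#'
#' @param results Enrichment tibble.
#' @param path File path.
#' @return `read_results()`: the results tibble.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(results, path, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read_schema_tsv(path, c("set", "variant_class", "beta", "se", "p",
                          "conditioned_on", "status"),
                  readr::cols(set = "c", category = "c",
                              variant_class = "c", conditioned_on = "c",
                              status = "c", n_genes = "i",
                              fdr_significant = "l",
                              .default = "d"),
                  "results") %>%
    mutate(conditioned_on = if_else(is.na(.data$conditioned_on), "",
                                    .data$conditioned_on))
}
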