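#' Simulate a gene-by-cell-type mean expression matrix
#'
#' Emulates the cell-type-averaged single-cell/single-nucleus expression
#' input of cell-type gene-set construction. Baseline expression is
#' log-normal; a configurable fraction of genes is unexpressed (near zero in
#' every type); each cell type receives `markers_per_type` disjoint planted
#' marker genes whose expression in that type is multiplied by a fixed
#' fold-change, so they rank top by specificity.
#'
#' @param genes A gene table (tibble with `gene_id`) or a character vector of
#'   gene ids.
#' @param n_cell_types Number of cell-type columns.
#' @param markers_per_type Planted markers per type; must satisfy
#'   `markers_per_type * n_cell_types <= n_genes`.
#' @param seed Integer seed.
#' @param cell_type_prefix Prefix for generated cell-type labels.
#' @param marker_fold Fold-change applied to a marker in its own type.
#' @param frac_unexpressed Fraction of genes with near-zero expression
#'   everywhere.
#' @param noise_sd Log-normal noise standard deviation; `0` gives a
#'   deterministic expression surface given the marker assignment.
#' @return A wide tibble: `gene_id` plus one nonnegative column per cell
#'   type, with attributes `markers` (named list of planted marker ids per
#'   type).
#' @examples
#' ex <- sim_expression(sprintf("G%03d", 1:50), n_cell_types = 3,
#'                      markers_per_type = 5, seed = 1)
#' dim(ex)
#' @export
sim_expression <- function(genes, n_cell_types, markers_per_type, seed,
                           cell_type_prefix = "type",
                           marker_fold = 8,
                           frac_unexpressed = 0.1,
                           noise_sd = 0.5) {
  gene_ids <- if (is.character(genes)) genes else {
    assert_cols(genes, "gene_id", "gene table")
    genes$gene_id
  }
  n <- length(gene_ids)
  if (anyDuplicated(gene_ids)) abort_input("gene ids must be unique")
  if (markers_per_type * n_cell_types > n) {
    abort_input(sprintf(
      "cannot plant %d markers in each of %d cell types with only %d genes",
      markers_per_type, n_cell_types, n
    ), class = "convergene_config_error")
  }
  types <- sprintf("%s%02d", cell_type_prefix, seq_len(n_cell_types))
  with_seed(seed, {
    base <- exp(rnorm(n, mean = 1, sd = 1))
    base[runif(n) < frac_unexpressed] <- 0
    mat <- matrix(rep(base, n_cell_types), nrow = n)
    if (noise_sd > 0) {
      mat <- mat * exp(matrix(rnorm(n * n_cell_types, 0, noise_sd), nrow = n))
    }
    markers <- list()
    if (markers_per_type > 0 && n_cell_types > 0) {
      # markers drawn from expressed genes, disjoint across types
      pool <- sample(which(base > 0))
      if (length(pool) < markers_per_type * n_cell_types) {
        abort_input("not enough expressed genes to plant disjoint markers",
                    class = "convergene_config_error")
      }
      for (j in seq_len(n_cell_types)) {
        idx <- pool[seq.int((j - 1L) * markers_per_type + 1L,
                            j * markers_per_type)]
        mat[idx, j] <- mat[idx, j] * marker_fold
        markers[[types[j]]] <- gene_ids[idx]
      }
    } else {
      markers <- setNames(vector("list", n_cell_types), types)
    }
    out <- as_tibble(setNames(as.data.frame(mat), types)) %>%
      mutate(gene_id = gene_ids, .before = 1)
    attr(out, "markers") <- markers
    out
  })
}

# Wide expression tibble -> numeric matrix (genes in rows).
expr_matrix <- function(expr) {
  assert_cols(expr, "gene_id", "expression matrix")
  m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  if (any(m < 0)) abort_input("expression values must be nonnegative")
  m
}
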