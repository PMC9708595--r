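#' Gene-set construction
#'
#' Gene-sets are represented throughout the package as long tibbles with
#' columns `set` (name), `category` and `gene_id`; a collection is simply
#' the row-bound union with unique set names. Categories used by the
#' analysis are `"PI"` (constrained genes), `"human_cell"`, `"mouse_cell"`,
#' `"synaptic"`, `"intersection"` and `"background"` (conditioning-only
#' sets, never counted as analysed).
#'
#' @name genesets
NULL

#' Select constrained (PTV-intolerant) genes
#'
#' Genes whose pLI strictly exceeds the threshold; the boundary value is
#' excluded.
#'
#' @param genes Gene table with `gene_id` and `pli` in `[0, 1]`.
#' @param threshold pLI cutoff, default 0.9.
#' @param name Set name, default `"PI"`.
#' @return A one-set tibble (`set`, `category = "PI"`, `gene_id`).
#' @examples
#' g <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
#'                     pli = c(0.95, 0.90, 0.10))
#' select_pi(g)
#' @export
select_pi <- function(genes, threshold = 0.9, name = "PI") {
  assert_cols(genes, c("gene_id", "pli"), "gene table")
  if (nrow(genes) > 0 &&
      (any(!is.finite(genes$pli)) || any(genes$pli < 0 | genes$pli > 1))) {
    abort_input("`pli` must be a probability in [0, 1] for every gene")
  }
  genes %>%
    filter(.data$pli > threshold) %>%
    transmute(set = name, category = "PI", gene_id = .data$gene_id) %>%
    arrange(.data$gene_id)
}

#' Select the most specifically expressed genes of one cell type
#'
#' Genes below `min_expr` in the focal cell type are excluded; remaining
#' genes are ranked by expression specificity (expression in the focal type
#' divided by the mean over all cell types plus a small pseudocount) and the
#' top `n` are returned, ties broken lexicographically by gene id.
#'
#' @param expr Wide expression tibble (`gene_id` + one column per type).
#' @param cell_type Column name of the focal cell type.
#' @param n Number of genes to select (default 1600).
#' @param min_expr Minimum expression in the focal type.
#' @param pseudocount Added to the denominator of the specificity ratio.
#' @param category Category label for the resulting set.
#' @param strict If `TRUE`, fewer than `n` qualifying genes is an error;
#'   otherwise a warning is raised and all qualifying genes are returned.
#' @return A one-set tibble (`set = cell_type`, `category`, `gene_id`).
#' @export
select_top_expressed <- function(expr, cell_type, n = 1600,
                                 min_expr = 0.5, pseudocount = 0.01,
                                 category = "human_cell", strict = FALSE) {
  assert_cols(expr, c("gene_id", cell_type), "expression matrix")
  mat <- expr_matrix(expr)
  spec <- mat[, cell_type] / (rowMeans(mat) + pseudocount)
  qualifying <- tibble(
    gene_id = expr$gene_id,
    expr = mat[, cell_type],
    specificity = spec
  ) %>%
    filter(.data$expr >= min_expr) %>%
    arrange(desc(.data$specificity), .data$gene_id)
  if (nrow(qualifying) < n) {
    msg <- sprintf(
      "cell type '%s': only %d genes qualify (requested top %d)",
      cell_type, nrow(qualifying), n
    )
    if (strict) abort_input(msg) else rlang::warn(msg)
  }
  qualifying %>%
    head(n) %>%
    transmute(set = cell_type, category = category,
              gene_id = .data$gene_id) %>%
    arrange(.data$gene_id)
}

#' Build one top-expressed set per cell type
#'
#' Convenience wrapper applying [select_top_expressed()] to every cell-type
#' column of an expression matrix.
#'
#' @inheritParams select_top_expressed
#' @return A long gene-set tibble with one set per cell type.
#' @export
cell_type_sets <- function(expr, n = 1600, min_expr = 0.5,
                           pseudocount = 0.01, category = "human_cell",
                           strict = FALSE) {
  types <- setdiff(names(expr), "gene_id")
  purrr::map_dfr(types, function(ct) {
    select_top_expressed(expr, ct, n = n, min_expr = min_expr,
                         pseudocount = pseudocount, category = category,
                         strict = strict)
  })
}

#' Translate mouse gene-sets into human gene ids
#'
#' Members are translated through the homology map. Mouse genes without a
#' human homologue are dropped; mouse genes mapping to more than one human
#' gene are dropped entirely (many-to-many homology inflates sets);
#' duplicate human ids after translation are collapsed. Drop counts are
#' attached as the `"homology_log"` attribute.
#'
#' @param mouse_sets Long gene-set tibble whose `gene_id` are mouse ids.
#' @param map Homology tibble with `mouse_id`, `human_id`.
#' @return The translated long gene-set tibble (human `gene_id`).
#' @export
map_homologs <- function(mouse_sets, map) {
  assert_cols(mouse_sets, c("set", "category", "gene_id"), "mouse_sets")
  assert_cols(map, c("mouse_id", "human_id"), "homology map")
  ambiguous <- map %>%
    count(.data$mouse_id) %>%
    filter(.data$n > 1) %>%
    pull("mouse_id")
  usable <- map %>% filter(!.data$mouse_id %in% ambiguous)
  n_in <- nrow(mouse_sets)
  out <- mouse_sets %>%
    inner_join(usable, by = c(gene_id = "mouse_id")) %>%
    transmute(.data$set, .data$category, gene_id = .data$human_id) %>%
    distinct() %>%
    arrange(.data$set, .data$gene_id)
  n_ambiguous <- sum(mouse_sets$gene_id %in% ambiguous)
  attr(out, "homology_log") <- list(
    members_in = n_in,
    members_out = nrow(out),
    dropped_ambiguous = n_ambiguous,
    dropped_unmapped = n_in - n_ambiguous -
      sum(mouse_sets$gene_id %in% usable$mouse_id)
  )
  out
}

#' Retain synaptic gene-sets of sufficient size
#'
#' Keeps sets with `min_size` or more members (inclusive boundary) and
#' labels them `"synaptic"`.
#'
#' @param raw_sets Long gene-set tibble.
#' @param min_size Minimum member count, default 50.
#' @return The filtered long gene-set tibble.
#' @export
filter_synaptic <- function(raw_sets, min_size = 50) {
  assert_cols(raw_sets, c("set", "gene_id"), "raw_sets")
  keep <- raw_sets %>%
    count(.data$set) %>%
    filter(.data$n >= min_size) %>%
    pull("set")
  raw_sets %>%
    filter(.data$set %in% keep) %>%
    mutate(category = "synaptic") %>%
    select("set", "category", "gene_id")
}

#' Intersect cell-type sets with the constrained gene-set
#'
#' One intersection set per cell-type set, named `"<cell>_x_PI"`. Empty
#' intersections are retained (they surface downstream with a skipped
#' status rather than disappearing silently).
#'
#' @param cell_sets Long gene-set tibble of cell-type sets.
#' @param pi One-set tibble from [select_pi()].
#' @return Long gene-set tibble of category `"intersection"`.
#' @export
intersect_pi <- function(cell_sets, pi) {
  assert_cols(cell_sets, c("set", "gene_id"), "cell_sets")
  assert_cols(pi, "gene_id", "pi set")
  set_names <- unique(cell_sets$set)
  out <- purrr::map_dfr(set_names, function(s) {
    members <- intersect(
      cell_sets$gene_id[cell_sets$set == s], pi$gene_id
    )
    tibble(
      set = paste0(s, "_x_PI"),
      category = "intersection",
      gene_id = sort(members)
    )
  })
  # the long format cannot carry memberless rows; empty intersections are
  # listed on this attribute so downstream reporting can flag them
  empty <- setdiff(paste0(set_names, "_x_PI"), unique(out$set))
  if (length(empty) > 0) {
    rlang::warn(sprintf("empty intersection set(s): %s (low power)",
                        paste(empty, collapse = ", ")))
  }
  attr(out, "empty_sets") <- empty
  out
}

#' Brain-expressed background sets for conditional analyses
#'
#' Brain-expressed genes are those above `min_expr` in at least one cell
#' type; the top-fraction sets take the given fractions of brain-expressed
#' genes ranked by overall mean expression. Backgrounds are conditioning
#' covariates only and are never counted among the analysed sets.
#'
#' @param expr Wide human expression tibble.
#' @param fractions Fractions of brain-expressed genes to retain.
#' @param min_expr Expression threshold defining "expressed".
#' @return Long gene-set tibble of category `"background"` with sets
#'   `brain_all`, `brain_top50`, ... (names follow the fractions).
#' @export
background_sets <- function(expr, fractions = c(1, 0.5, 0.2, 0.1),
                            min_expr = 0.5) {
  mat <- expr_matrix(expr)
  expressed <- tibble(
    gene_id = expr$gene_id,
    mean_expr = rowMeans(mat)
  ) %>%
    filter(apply(mat, 1, max) > min_expr) %>%
    arrange(desc(.data$mean_expr), .data$gene_id)
  purrr::map_dfr(fractions, function(f) {
    assert_scalar_number(f, "fraction", lower = 0, upper = 1)
    nm <- if (f == 1) "brain_all" else sprintf("brain_top%d", round(100 * f))
    expressed %>%
      head(floor(f * nrow(expressed))) %>%
      transmute(set = nm, category = "background",
                gene_id = .data$gene_id) %>%
      arrange(.data$gene_id)
  })
}

#' Assemble the analysis gene-set collection
#'
#' Row-binds the constrained, cell-type, synaptic and intersection families
#' into the analysed collection and attaches the background sets for
#' conditioning. Duplicate set names are an error.
#'
#' @param pi,human_sets,mouse_sets,synaptic_sets,intersections Long
#'   gene-set tibbles (any may be empty or `NULL`).
#' @param background Optional background tibble from [background_sets()].
#' @return A long gene-set tibble containing all families, with the
#'   background rows carrying `category = "background"`.
#' @export
assemble_collection <- function(pi = NULL, human_sets = NULL,
                                mouse_sets = NULL, synaptic_sets = NULL,
                                intersections = NULL, background = NULL) {
  parts <- purrr::compact(list(pi, human_sets, mouse_sets, synaptic_sets,
                               intersections, background))
  empty <- tibble(set = character(), category = character(),
                  gene_id = character())
  if (length(parts) == 0) return(empty)
  collection <- bind_rows(parts)
  if (nrow(collection) == 0) return(empty)
  assert_cols(collection, c("set", "category", "gene_id"), "collection")
  names_by_cat <- collection %>% distinct(.data$set, .data$category)
  if (anyDuplicated(names_by_cat$set)) {
    dups <- names_by_cat$set[duplicated(names_by_cat$set)]
    abort_input(sprintf("duplicate set name(s) in collection: %s",
                        paste(unique(dups), collapse = ", ")))
  }
  collection %>% distinct() %>% arrange(.data$category, .data$set,
                                        .data$gene_id)
}

#' Count analysed sets in a collection
#'
#' Background sets condition other tests and are excluded from the count
#' (and from multiple-testing families).
#'
#' @param collection Long gene-set tibble.
#' @return Integer number of analysed sets.
#' @export
n_analysed_sets <- function(collection) {
  collection %>%
    filter(.data$category != "background") %>%
    summarise(n = n_distinct(.data$set)) %>%
    pull("n")
}

#' List the members of one set
#'
#' @param collection Long gene-set tibble.
#' @param name Set name.
#' @return Character vector of member gene ids.
#' @export
set_members <- function(collection, name) {
  collection$gene_id[collection$set == name]
}

#' @importFrom dplyr transmute
NULL
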