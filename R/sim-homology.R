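#' Simulate a mouse-to-human homology map
#'
#' Emulates a mouse/human homologue reference: roughly `coverage` of the
#' human genes receive a mouse counterpart, and a configurable fraction of
#' the mapped mouse genes are given a second human target so that the
#' many-to-many mapping policy of [map_homologs()] is exercised.
#'
#' @param genes Gene table or character vector of human gene ids.
#' @param coverage Fraction of human genes with a mouse homologue, in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @param ambiguous_frac Fraction of mapped mouse genes that also map to a
#'   second human gene.
#' @return A tibble with columns `mouse_id`, `human_id`; pairs unique.
#' @examples
#' sim_homology(c("G1", "G2", "G3"), coverage = 1, seed = 1)
#' @export
sim_homology <- function(genes, coverage, seed, ambiguous_frac = 0) {
  gene_ids <- if (is.character(genes)) genes else {
    assert_cols(genes, "gene_id", "gene table")
    genes$gene_id
  }
  assert_scalar_number(coverage, "coverage", lower = 0, upper = 1)
  assert_scalar_number(ambiguous_frac, "ambiguous_frac", lower = 0, upper = 1)
  with_seed(seed, {
    mapped <- gene_ids[runif(length(gene_ids)) < coverage]
    map <- tibble(
      mouse_id = paste0("m_", mapped),
      human_id = mapped
    )
    n_amb <- round(ambiguous_frac * nrow(map))
    if (n_amb > 0 && length(gene_ids) > 1) {
      amb_rows <- sample(nrow(map), n_amb)
      extra <- map[amb_rows, ]
      # second, different human target for the same mouse gene
      extra$human_id <- vapply(extra$human_id, function(h) {
        sample(setdiff(gene_ids, h), 1L)
      }, character(1))
      map <- bind_rows(map, extra)
    }
    distinct(map, .data$mouse_id, .data$human_id) %>%
      arrange(.data$mouse_id, .data$human_id)
  })
}

#' Simulate raw synaptic ontology gene-sets
#'
#' One named set per requested size, each drawn without replacement from the
#' gene universe, mimicking ontology-derived annotations of synaptic
#' location and function.
#'
#' @param genes Gene table or character vector of gene ids.
#' @param set_sizes Integer vector of set sizes.
#' @param seed Integer seed.
#' @return A long tibble with columns `set`, `category` (`"synaptic"`),
#'   `gene_id`; set sizes exactly as requested.
#' @examples
#' sim_synaptic_sets(sprintf("G%03d", 1:100), c(60, 49), seed = 1)
#' @export
sim_synaptic_sets <- function(genes, set_sizes, seed) {
  gene_ids <- if (is.character(genes)) genes else {
    assert_cols(genes, "gene_id", "gene table")
    genes$gene_id
  }
  if (length(set_sizes) == 0) {
    return(tibble(set = character(), category = character(),
                  gene_id = character()))
  }
  if (any(set_sizes > length(gene_ids))) {
    abort_input("a requested synaptic set size exceeds the gene universe")
  }
  with_seed(seed, {
    purrr::imap_dfr(as.integer(set_sizes), function(sz, i) {
      tibble(
        set = sprintf("synaptic_%02d", i),
        category = "synaptic",
        gene_id = sample(gene_ids, sz)
      )
    })
  })
}
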