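#' Simulate a gene location table with constraint scores
#'
#' Lays non-overlapping gene intervals on 22 synthetic autosomes and draws a
#' per-gene pLI (probability of loss-of-function intolerance) from a
#' two-component Beta mixture, so that the score distribution is bimodal and
#' a constrained (`pLI > 0.9`) subset exists, as in population constraint
#' references.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `stop`
#'   (1-based inclusive bp) and `pli`.
#' @examples
#' genes <- sim_gene_table(sim_config(n_genes = 100, seed = 1))
#' mean(genes$pli > 0.9)
#' @export
sim_gene_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  if (n < 1) {
    abort_input("`n_genes` must be >= 1 to simulate a gene table")
  }
  with_seed(sub_seed(cfg$seed, 11L), {
    n_chrom <- min(22L, n)
    chrom <- sprintf("chr%d", rep_len(seq_len(n_chrom), n))
    # widths 2-200 kb, separated by >= 1 kb gaps within each chromosome
    width <- as.integer(round(runif(n, 2e3, 2e5)))
    gap <- as.integer(round(runif(n, 1e3, 5e4)))
    df <- tibble(
      gene_id = sprintf("G%05d", seq_len(n)),
      chrom = chrom,
      width = width,
      gap = gap
    ) %>%
      group_by(.data$chrom) %>%
      mutate(
        start = cumsum(dplyr::lag(.data$width + .data$gap, default = 0)) + 1L,
        stop = .data$start + .data$width - 1L
      ) %>%
      ungroup()
    hi <- runif(n) < cfg$pli_p_hi
    pli <- numeric(n)
    pli[hi] <- rbeta(sum(hi), cfg$pli_shape_hi[1], cfg$pli_shape_hi[2])
    pli[!hi] <- rbeta(sum(!hi), cfg$pli_shape_lo[1], cfg$pli_shape_lo[2])
    df %>%
      mutate(pli = pli) %>%
      select("gene_id", "chrom", "start", "stop", "pli")
  })
}

# Theoretical P(pLI > thr) under the configured mixture; used by calibration
# checks rather than re-deriving it at call sites.
pli_tail_prob <- function(cfg, threshold = 0.9) {
  cfg$pli_p_hi *
    (1 - pbeta(threshold, cfg$pli_shape_hi[1], cfg$pli_shape_hi[2])) +
    (1 - cfg$pli_p_hi) *
    (1 - pbeta(threshold, cfg$pli_shape_lo[1], cfg$pli_shape_lo[2]))
}

#' @importFrom stats pbeta
NULL
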