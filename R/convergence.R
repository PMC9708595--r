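#' Benjamini-Hochberg FDR flags
#'
#' Step-up procedure at level `q`, returning rejection flags in input
#' order. Apply once per variant-frequency family (see [add_fdr()]).
#'
#' @param pvals Numeric p-values in `(0, 1]`.
#' @param q FDR level, default 0.05.
#' @return Logical vector of rejections.
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.04, 0.9))
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) return(logical())
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1)) {
    abort_input("p-values must lie in (0, 1]")
  }
  assert_scalar_number(q, "q", lower = 0, upper = 1)
  p.adjust(pvals, method = "BH") <= q
}

#' Flag FDR-significant enrichment results per frequency family
#'
#' Applies [bh_fdr()] separately within each `variant_class` family, over
#' the primary (unconditioned, status `"ok"`) rows of all analysed sets;
#' other rows get `NA`.
#'
#' @param results Enrichment tibble from [run_common()] or [run_rare()].
#' @param q FDR level.
#' @return `results` with an added logical `fdr_significant` column.
#' @export
add_fdr <- function(results, q = 0.05) {
  assert_cols(results, c("variant_class", "p", "conditioned_on", "status"),
              "results")
  results %>%
    group_by(.data$variant_class) %>%
    mutate(fdr_significant = {
      primary <- .data$conditioned_on == "" & .data$status %in%
        c("ok", "firth")
      flag <- rep(NA, n())
      if (any(primary)) flag[primary] <- bh_fdr(.data$p[primary], q = q)
      flag
    }) %>%
    ungroup()
}

# Weighted Pearson correlation with normalized weights.
weighted_pearson <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  cov <- sum(w * (x - mx) * (y - my))
  cov / sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

#' Correlate enrichment betas between two result tables
#'
#' Pairs the primary results of the two tables by set name and computes the
#' plain correlation of the betas (Pearson or Spearman) and the weighted
#' Pearson correlation with weights `1 / (se_a * se_b)` (precision of the
#' pair; invariant to rescaling all weights). Sets flagged FDR-significant
#' in both tables form the overlap list.
#'
#' @param results_a,results_b Enrichment tibbles (e.g. common-variant and
#'   ultra-rare results); if they lack an `fdr_significant` column it is
#'   added at `q`.
#' @param method `"pearson"` (default) or `"spearman"` for the plain
#'   estimate.
#' @param q FDR level used when flags must be added.
#' @return Object of class `convergence_result`: list with `pairs`
#'   (tibble: `set`, `beta_a`, `se_a`, `beta_b`, `se_b`, `weight`,
#'   `sig_both`), `correlation`, `weighted_correlation`, `method`,
#'   `overlap_sets`, `n_sets`.
#' @export
correlate_enrichment <- function(results_a, results_b,
                                 method = c("pearson", "spearman"),
                                 q = 0.05) {
  method <- match.arg(method)
  prep <- function(res) {
    assert_cols(res, c("set", "beta", "se", "p", "conditioned_on",
                       "status"), "results")
    if (!"fdr_significant" %in% names(res)) res <- add_fdr(res, q = q)
    res %>%
      filter(.data$conditioned_on == "",
             .data$status %in% c("ok", "firth")) %>%
      select("set", "beta", "se", "fdr_significant")
  }
  a <- prep(results_a)
  b <- prep(results_b)
  pairs <- inner_join(a, b, by = "set",
                      suffix = c("_a", "_b")) %>%
    rename(beta_a = "beta_a", beta_b = "beta_b")
  if (nrow(pairs) < 3) {
    abort_input("fewer than 3 shared sets with usable estimates")
  }
  if (any(pairs$se_a <= 0) || any(pairs$se_b <= 0)) {
    abort_input("standard errors must be positive")
  }
  pairs <- pairs %>%
    mutate(weight = 1 / (.data$se_a * .data$se_b),
           sig_both = .data$fdr_significant_a & .data$fdr_significant_b)
  plain <- cor(pairs$beta_a, pairs$beta_b, method = method)
  weighted <- weighted_pearson(pairs$beta_a, pairs$beta_b, pairs$weight)
  structure(
    list(
      pairs = pairs %>% select("set", "beta_a", "se_a", "beta_b", "se_b",
                               "weight", "sig_both"),
      correlation = plain,
      weighted_correlation = weighted,
      method = method,
      overlap_sets = sort(pairs$set[which(pairs$sig_both)]),
      n_sets = nrow(pairs)
    ),
    class = "convergence_result"
  )
}

#' @export
print.convergence_result <- function(x, ...) {
  cat("<convergence_result>\n")
  cat(sprintf("  %d paired sets | %s correlation: %.3f | weighted: %.3f\n",
              x$n_sets, x$method, x$correlation, x$weighted_correlation))
  cat(sprintf("  significant in both: %d set(s)\n", length(x$overlap_sets)))
  invisible(x)
}

#' Cross-frequency convergence report
#'
#' One convergence estimate per (common, rare-class) pair, each with both
#' Pearson and Spearman plain estimates, the weighted Pearson estimate and
#' the overlap of FDR-significant sets.
#'
#' @param common_results Common-variant enrichment tibble.
#' @param rare_results Rare-variant enrichment tibble with multiple
#'   `variant_class` values.
#' @param q FDR level.
#' @return Tibble: `pair`, `method`, `n_sets`, `correlation`,
#'   `weighted_correlation`, `n_overlap`, `overlap_sets` (list-column),
#'   with attribute `"details"` holding the `convergence_result` objects.
#' @export
convergence_report <- function(common_results, rare_results, q = 0.05) {
  common_sets <- unique(common_results$set)
  rare_sets <- unique(rare_results$set)
  if (!setequal(common_sets, rare_sets)) {
    missing <- c(setdiff(common_sets, rare_sets),
                 setdiff(rare_sets, common_sets))
    abort_input(sprintf(
      "result tables cover different collections; unmatched set(s): %s",
      paste(head(missing, 10), collapse = ", ")))
  }
  classes <- unique(rare_results$variant_class)
  details <- list()
  rows <- purrr::map_dfr(classes, function(vc) {
    rb <- rare_results %>% filter(.data$variant_class == vc)
    purrr::map_dfr(c("pearson", "spearman"), function(m) {
      cv <- correlate_enrichment(common_results, rb, method = m, q = q)
      details[[paste(vc, m, sep = ".")]] <<- cv
      tibble(
        pair = paste0("common_vs_", vc),
        method = m,
        n_sets = cv$n_sets,
        correlation = cv$correlation,
        weighted_correlation = cv$weighted_correlation,
        n_overlap = length(cv$overlap_sets),
        overlap_sets = list(cv$overlap_sets)
      )
    })
  })
  attr(rows, "details") <- details
  rows
}
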