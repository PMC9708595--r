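#' Competitive gene-set test on gene z-scores
#'
#' Linear regression of the gene z-scores on set membership, an intercept,
#' gene-level covariates (gene length, SNP count and their logs) and any
#' conditioning set indicators. The membership coefficient is the
#' enrichment beta; the reported p-value is one-sided for beta > 0 (the
#' competitive convention) unless `alternative = "two.sided"`.
#'
#' @param stats Gene-level tibble with `gene_id`, `z` and, when
#'   `covariates = TRUE`, `length` and `n_snps`.
#' @param members Character vector of member gene ids.
#' @param set_name Name recorded in the result.
#' @param condition_on Named list of character vectors: conditioning sets
#'   entered as additional membership indicators.
#' @param covariates Include the length/SNP-count covariates (default TRUE;
#'   turn off for pure z-score simulations).
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @param gene_corr Optional gene-gene correlation matrix (rows/columns in
#'   the order of `stats`): when supplied the regression is fitted by
#'   generalized least squares (whitening both sides with the inverse
#'   Cholesky factor), for data whose gene statistics are not independent.
#'   The default `NULL` uses ordinary least squares, valid when genes carry
#'   disjoint, independent LD blocks.
#' @return An object of class `competitive_fit` with elements `result`
#'   (one-row tibble: `set`, `n_genes`, `beta`, `se`, `p`,
#'   `conditioned_on`, `status`) and `fit` (the underlying `lm`).
#' @examples
#' stats <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
#'                         z = rnorm(40))
#' competitive_test(stats, sprintf("g%02d", 1:10), covariates = FALSE)
#' @export
competitive_test <- function(stats, members, set_name = "set",
                             condition_on = NULL, covariates = TRUE,
                             alternative = c("greater", "two.sided"),
                             gene_corr = NULL) {
  alternative <- match.arg(alternative)
  assert_cols(stats, c("gene_id", "z"), "gene statistics")
  if (any(!is.finite(stats$z))) {
    abort_input("gene z-scores must be finite")
  }
  member <- as.numeric(stats$gene_id %in% members)
  if (sum(member) < 2 || sum(1 - member) < 2) {
    abort_input(sprintf(
      "set '%s' needs >= 2 member and >= 2 non-member genes with statistics",
      set_name
    ), class = "convergene_degenerate_error")
  }
  df <- tibble(z = stats$z, member = member)
  if (covariates) {
    assert_cols(stats, c("length", "n_snps"), "gene statistics")
    df <- df %>% mutate(
      gene_length = stats$length,
      n_snps = stats$n_snps,
      log_length = log(stats$length),
      log_n_snps = log(stats$n_snps)
    )
  }
  cond_names <- character()
  for (nm in names(condition_on)) {
    ind <- as.numeric(stats$gene_id %in% condition_on[[nm]])
    if (identical(ind, member)) {
      abort_input(sprintf(
        "conditioning set '%s' is identical to the focal set '%s'",
        nm, set_name
      ), class = "convergene_collinear_error")
    }
    col <- paste0("cond_", make.names(nm))
    df[[col]] <- ind
    cond_names <- c(cond_names, nm)
  }
  if (!is.null(gene_corr)) {
    gene_corr <- as.matrix(gene_corr)
    if (!all(dim(gene_corr) == nrow(df))) {
      abort_input("`gene_corr` must be square with one row per gene")
    }
    # GLS by whitening: L^-1 y = L^-1 X b + e with gene_corr = L L^T
    Linv <- backsolve(chol(gene_corr), diag(nrow(df)), transpose = TRUE)
    X <- stats::model.matrix(~ ., data = df[setdiff(names(df), "z")])
    wy <- drop(Linv %*% df$z)
    wX <- Linv %*% X
    df <- as_tibble(setNames(as.data.frame(wX[, -1, drop = FALSE]),
                             colnames(X)[-1]))
    df$z <- wy
    df$.intercept <- wX[, 1]
    fit <- lm(z ~ 0 + ., data = df)
  } else {
    fit <- lm(z ~ ., data = df)
  }
  smry <- suppressWarnings(summary(fit))
  cf <- smry$coefficients
  if (!"member" %in% rownames(cf) || is.na(cf["member", "Std. Error"]) ||
      cf["member", "Std. Error"] == 0 ||
      smry$sigma < 1e-10 * (1 + max(abs(df$z)))) {
    # zero residual variance (e.g. all z equal): no evidence either way
    result <- tibble(
      set = set_name, n_genes = as.integer(sum(member)),
      beta = unname(coef(fit)["member"]) %||% 0,
      se = NA_real_, p = 0.5,
      conditioned_on = paste(cond_names, collapse = ";"),
      status = "no_variance"
    )
    result$beta[is.na(result$beta)] <- 0
    return(structure(list(result = result, fit = fit),
                     class = "competitive_fit"))
  }
  beta <- cf["member", "Estimate"]
  se <- cf["member", "Std. Error"]
  tval <- beta / se
  dfree <- fit$df.residual
  p <- if (alternative == "greater") {
    pt(tval, df = dfree, lower.tail = FALSE)
  } else {
    2 * pt(abs(tval), df = dfree, lower.tail = FALSE)
  }
  result <- tibble(
    set = set_name,
    n_genes = as.integer(sum(member)),
    beta = beta,
    se = se,
    p = clamp_p(p),
    conditioned_on = paste(cond_names, collapse = ";"),
    status = "ok"
  )
  structure(list(result = result, fit = fit), class = "competitive_fit")
}

#' @export
print.competitive_fit <- function(x, ...) {
  cat("<competitive_fit>\n")
  print(x$result)
  invisible(x)
}

#' Paper-style conditioning plan for a collection
#'
#' Brain cell-type, intersection and synaptic sets are conditioned on each
#' brain-expressed background set; intersection sets are additionally
#' conditioned on their parent cell-type set, on the constrained (PI) set,
#' and on both.
#'
#' @param collection Long gene-set tibble (with `background` rows for the
#'   background schemes to be generated).
#' @param pi_name Name of the constrained set.
#' @return Tibble with columns `set`, `scheme` and `condition_on`
#'   (list-column of conditioning set names).
#' @export
default_conditioning_plan <- function(collection, pi_name = "PI") {
  cats <- collection %>% distinct(.data$set, .data$category)
  backgrounds <- cats$set[cats$category == "background"]
  brainish <- cats %>%
    filter(.data$category %in% c("human_cell", "mouse_cell",
                                 "intersection"))
  plan_bg <- tidyr::expand_grid(set = brainish$set, bg = backgrounds) %>%
    mutate(scheme = paste0("cond_", .data$bg),
           condition_on = purrr::map(.data$bg, identity)) %>%
    select("set", "scheme", "condition_on")
  inter <- cats$set[cats$category == "intersection"]
  parent <- sub("_x_PI$", "", inter)
  plan_int <- bind_rows(
    tibble(set = inter, scheme = "cond_cell",
           condition_on = purrr::map(parent, identity)),
    tibble(set = inter, scheme = "cond_PI",
           condition_on = purrr::map(inter, function(...) pi_name)),
    tibble(set = inter, scheme = "cond_cell_PI",
           condition_on = purrr::map(parent, function(p) c(p, pi_name)))
  )
  bind_rows(plan_bg, plan_int) %>% arrange(.data$set, .data$scheme)
}

#' Run the competitive test over a whole collection
#'
#' One primary (unconditioned) result per analysed set, plus one result per
#' row of the conditioning plan. Per-set failures are captured in the
#' `status` column; the batch never aborts. Sets with fewer scored member
#' genes than `min_set_size` are reported with status `"skipped_small"`.
#'
#' @param gwas QC'd summary statistics (see [qc_gwas()]).
#' @param ld LD reference tibble (`gene_id`, `snps`, `R`).
#' @param genes Gene table.
#' @param collection Long gene-set tibble; background rows are used only
#'   for conditioning.
#' @param conditioning_plan Optional tibble from
#'   [default_conditioning_plan()]; `NULL` runs primary tests only.
#' @param min_set_size Minimum scored members for a testable set.
#' @return Enrichment tibble: `set`, `category`, `variant_class`
#'   (`"common"`), `n_genes`, `beta`, `se`, `p`, `conditioned_on`,
#'   `status`, one row per set x scheme, deterministic order.
#' @export
run_common <- function(gwas, ld, genes, collection,
                       conditioning_plan = NULL, min_set_size = 10) {
  empty_result <- tibble(
    set = character(), category = character(),
    variant_class = character(), n_genes = integer(), beta = numeric(),
    se = numeric(), p = numeric(), conditioned_on = character(),
    status = character()
  )
  analysed <- collection %>% filter(.data$category != "background")
  if (nrow(analysed) == 0) return(empty_result)
  stats <- gene_stats(gwas, ld, genes)
  cats <- analysed %>% distinct(.data$set, .data$category)
  schemes <- bind_rows(
    tibble(set = cats$set, scheme = "primary",
           condition_on = purrr::map(cats$set, function(...) character())),
    conditioning_plan
  )
  rows <- purrr::pmap(schemes, function(set, scheme, condition_on) {
    members <- set_members(collection, set)
    n_scored <- sum(stats$gene_id %in% members)
    cond <- setNames(
      purrr::map(condition_on, ~ set_members(collection, .x)),
      condition_on
    )
    if (n_scored < min_set_size) {
      return(tibble(set = set, n_genes = as.integer(n_scored),
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    conditioned_on = paste(condition_on, collapse = ";"),
                    status = "skipped_small"))
    }
    tryCatch(
      competitive_test(stats, members, set_name = set,
                       condition_on = cond)$result,
      error = function(e) {
        tibble(set = set, n_genes = as.integer(n_scored),
               beta = NA_real_, se = NA_real_, p = NA_real_,
               conditioned_on = paste(condition_on, collapse = ";"),
               status = paste0("error: ", conditionMessage(e)))
      }
    )
  })
  bind_rows(rows) %>%
    left_join(cats, by = "set") %>%
    mutate(variant_class = "common") %>%
    select("set", "category", "variant_class", "n_genes", "beta", "se",
           "p", "conditioned_on", "status") %>%
    arrange(.data$set, .data$conditioned_on)
}
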