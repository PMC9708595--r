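#' Logistic burden regression
#'
#' Fits `case ~ burden + sex + PC1..PC10` (plus the exome-wide class burden
#' when `adjust_exome_wide = TRUE`, and any conditioning burden columns) by
#' maximum likelihood. The burden coefficient is the per-allele log-odds of
#' case status; a Wald standard error and two-sided p-value are reported.
#' When the ML fit shows separation (non-convergence or exploding
#' estimates) a Firth-penalized fit is used instead and flagged in
#' `status`. Conditioning columns that are constant (e.g. an empty set's
#' all-zero burden) are dropped with a warning.
#'
#' @param data Tibble with columns `case` (0/1), `score`, `sex`,
#'   `PC1`..`PC10`, optionally `exome_wide` and conditioning columns.
#' @param set_name Name recorded in the result.
#' @param adjust_exome_wide Add the exome-wide class burden as covariate.
#' @param condition_cols Character vector of conditioning burden column
#'   names in `data`.
#' @return Object of class `burden_fit`: list with `result` (one-row
#'   tibble: `set`, `n_ind`, `n_carriers`, `beta`, `se`, `p`,
#'   `conditioned_on`, `vif` — the variance-inflation factor of the focal
#'   burden against the conditioning burdens, `NA` when unconditioned —
#'   and `status`) and `fit`.
#' @export
burden_regression <- function(data, set_name = "set",
                              adjust_exome_wide = FALSE,
                              condition_cols = character()) {
  assert_cols(data, c("case", "score", "sex", paste0("PC", 1:10)),
              "burden data")
  if (length(unique(data$case)) < 2) {
    abort_input("both cases and controls must be present",
                class = "convergene_degenerate_error")
  }
  if (length(unique(data$score)) < 2) {
    abort_input(sprintf("set '%s': burden score is constant", set_name),
                class = "convergene_degenerate_error")
  }
  covars <- c("sex", paste0("PC", 1:10))
  if (adjust_exome_wide) {
    assert_cols(data, "exome_wide", "burden data")
    covars <- c(covars, "exome_wide")
  }
  kept_cond <- character()
  for (cc in condition_cols) {
    assert_cols(data, cc, "burden data")
    if (length(unique(data[[cc]])) < 2) {
      rlang::warn(sprintf(
        "conditioning burden '%s' is constant; dropped", cc))
      next
    }
    if (isTRUE(all.equal(data[[cc]], data$score))) {
      abort_input(sprintf(
        "conditioning burden '%s' is identical to the focal burden", cc),
        class = "convergene_collinear_error")
    }
    covars <- c(covars, cc)
    kept_cond <- c(kept_cond, cc)
  }
  fml <- stats::reformulate(c("score", covars), response = "case")
  fit <- suppressWarnings(glm(fml, data = data, family = binomial()))
  status <- "ok"
  cf <- summary(fit)$coefficients
  separated <- !fit$converged || !"score" %in% rownames(cf) ||
    abs(cf["score", "Estimate"]) > 15 || cf["score", "Std. Error"] > 100
  if (separated) {
    fit <- firth_logistic(fml, data)
    cf <- fit$coefficients_table
    status <- "firth"
  }
  beta <- cf["score", 1]
  se <- cf["score", 2]
  if (!is.finite(se) || se <= 0) {
    abort_input(sprintf("set '%s': burden fit is degenerate", set_name),
                class = "convergene_degenerate_error")
  }
  p <- clamp_p(2 * pnorm(-abs(beta / se)))
  # collinearity diagnostic between the focal and conditioning burdens
  # (shared variants in nested sets inflate the focal variance)
  vif <- NA_real_
  if (length(kept_cond) > 0) {
    r2 <- summary(lm(stats::reformulate(kept_cond, response = "score"),
                     data = data))$r.squared
    vif <- 1 / max(1 - r2, 1e-12)
  }
  result <- tibble(
    set = set_name,
    n_ind = nrow(data),
    n_carriers = as.integer(sum(data$score > 0)),
    beta = beta, se = se, p = p,
    conditioned_on = paste(sub("^cond_", "", kept_cond), collapse = ";"),
    vif = vif,
    status = status
  )
  structure(list(result = result, fit = fit), class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, ...) {
  cat("<burden_fit>\n")
  print(x$result)
  invisible(x)
}

# Firth-penalized logistic regression by Newton-Raphson with the
# hat-diagonal score correction; returns an object exposing a
# glm-like coefficient table.
firth_logistic <- function(formula, data, max_iter = 100, tol = 1e-8) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  # drop non-identifiable columns (constant or aliased), as glm does
  qrX <- qr(X)
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  X <- X[, keep, drop = FALSE]
  beta <- rep(0, ncol(X))
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    inv <- solve(XtWX)
    h <- rowSums((XW %*% inv) * XW)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- inv %*% U
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- plogis(eta) * (1 - plogis(eta))
  vc <- solve(crossprod(X * sqrt(w)))
  tab <- cbind(Estimate = beta, `Std. Error` = sqrt(diag(vc)))
  rownames(tab) <- colnames(X)
  structure(list(coefficients = setNames(beta, colnames(X)),
                 coefficients_table = tab, vcov = vc,
                 converged = iter < max_iter),
            class = "firth_logistic")
}

#' Run burden regressions over a whole collection
#'
#' For each analysed set, each frequency class and each consequence (PTV
#' with its synonymous negative control), fits the covariate-adjusted
#' burden regression on the MAD-QC-passing individuals of that class.
#' Conditioning schemes (intersection sets on their parent cell set, the
#' constrained set, or both) add further rows. Per-set failures are
#' recorded in `status`; the batch continues.
#'
#' @param cohort An `exome_cohort`.
#' @param collection Long gene-set tibble.
#' @param classes Frequency classes to analyse (default `"urv"` and
#'   `"rare_excl"`).
#' @param conditioning_plan Optional tibble (`set`, `scheme`,
#'   `condition_on` list-column of set names); conditioning enters as
#'   additional burden-score covariates.
#' @param adjust_exome_wide Adjust for the exome-wide class burden.
#' @param af_max,mad_k QC thresholds.
#' @param min_set_size Minimum member genes present in the cohort for a
#'   testable set.
#' @param exclude_individuals Character vector of individual ids removed
#'   before any QC (hook for upstream phenotype exclusions).
#' @return Enrichment tibble: `set`, `category`, `variant_class` (e.g.
#'   `"urv_ptv"`, `"urv_syn"`), `n_genes`, `beta`, `se`, `p`,
#'   `conditioned_on`, `status`.
#' @export
run_rare <- function(cohort, collection, classes = c("urv", "rare_excl"),
                     conditioning_plan = NULL, adjust_exome_wide = TRUE,
                     af_max = 0.001, mad_k = 4, min_set_size = 10,
                     exclude_individuals = NULL) {
  stopifnot(inherits(cohort, "exome_cohort"))
  if (length(exclude_individuals) > 0) {
    cohort$individuals <- cohort$individuals %>%
      filter(!.data$individual_id %in% exclude_individuals)
  }
  if (nrow(cohort$individuals) == 0) {
    abort_input("empty cohort")
  }
  analysed <- collection %>% filter(.data$category != "background")
  if (nrow(analysed) == 0) {
    return(tibble(
      set = character(), category = character(),
      variant_class = character(), n_genes = integer(), beta = numeric(),
      se = numeric(), p = numeric(), conditioned_on = character(),
      status = character()
    ))
  }
  cats <- analysed %>% distinct(.data$set, .data$category)
  schemes <- bind_rows(
    tibble(set = cats$set, scheme = "primary",
           condition_on = purrr::map(cats$set, function(...) character())),
    conditioning_plan
  )
  consequences <- c(ptv = "PTV", syn = "synonymous")
  rows <- purrr::map_dfr(classes, function(vclass) {
    keep <- qc_individuals(cohort, vclass, mad_k = mad_k, af_max = af_max)
    covar <- cohort$individuals %>%
      filter(.data$individual_id %in% keep)
    purrr::map_dfr(names(consequences), function(csq_tag) {
      csq <- consequences[[csq_tag]]
      vc_label <- paste0(vclass, "_", csq_tag)
      score_cache <- new.env(parent = emptyenv())
      get_score <- function(nm) {
        if (is.null(score_cache[[nm]])) {
          score_cache[[nm]] <- burden_score(
            cohort, set_members(collection, nm), vclass, csq,
            af_max = af_max, keep = keep
          )
        }
        score_cache[[nm]]
      }
      purrr::pmap_dfr(schemes, function(set, scheme, condition_on) {
        n_present <- length(intersect(set_members(collection, set),
                                      unique(cohort$variants$gene_id)))
        base_row <- tibble(set = set, n_genes = as.integer(n_present),
                           beta = NA_real_, se = NA_real_, p = NA_real_,
                           conditioned_on = paste(condition_on,
                                                  collapse = ";"))
        if (n_present < min_set_size) {
          return(base_row %>% mutate(status = "skipped_small",
                                     variant_class = vc_label))
        }
        res <- tryCatch({
          sc <- get_score(set)
          df <- covar %>% inner_join(sc, by = "individual_id")
          cond_cols <- character()
          for (nm in condition_on) {
            col <- paste0("cond_", make.names(nm))
            df[[col]] <- get_score(nm)$score
            cond_cols <- c(cond_cols, col)
          }
          out <- burden_regression(
            df, set_name = set, adjust_exome_wide = adjust_exome_wide,
            condition_cols = cond_cols
          )$result
          out$conditioned_on <- paste(condition_on, collapse = ";")
          out %>% select(-"n_ind", -"n_carriers", -"vif") %>%
            mutate(n_genes = as.integer(n_present), .after = "set")
        }, error = function(e) {
          base_row %>% mutate(status = paste0("error: ",
                                              conditionMessage(e)))
        })
        res %>% mutate(variant_class = vc_label)
      })
    })
  })
  rows %>%
    left_join(cats, by = "set") %>%
    select("set", "category", "variant_class", "n_genes", "beta", "se",
           "p", "conditioned_on", "status") %>%
    arrange(.data$variant_class, .data$set, .data$conditioned_on)
}
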