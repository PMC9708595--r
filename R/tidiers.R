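#' Tidy methods for fitted objects
#'
#' `tidy()` returns the coefficient table of a fit as one row per term;
#' `glance()` returns one-row model-level summaries. Both follow the broom
#' conventions (`term`, `estimate`, `std.error`, `statistic`, `p.value`).
#'
#' @param x A `competitive_fit`, `burden_fit` or `convergence_result`.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy competitive_fit
#' @export
tidy.competitive_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std.error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "t value"]),
    p.value = unname(cf[, "Pr(>|t|)"])
  )
}

#' @rdname tidiers
#' @method glance competitive_fit
#' @export
glance.competitive_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    set = x$result$set,
    n_genes = x$result$n_genes,
    r.squared = s$r.squared,
    sigma = s$sigma,
    df.residual = x$fit$df.residual,
    status = x$result$status
  )
}

#' @rdname tidiers
#' @method tidy burden_fit
#' @export
tidy.burden_fit <- function(x, ...) {
  if (inherits(x$fit, "firth_logistic")) {
    tab <- x$fit$coefficients_table
    return(tibble(
      term = rownames(tab),
      estimate = unname(tab[, 1]),
      std.error = unname(tab[, 2]),
      statistic = unname(tab[, 1] / tab[, 2]),
      p.value = unname(2 * pnorm(-abs(tab[, 1] / tab[, 2])))
    ))
  }
  cf <- summary(x$fit)$coefficients
  tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std.error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "z value"]),
    p.value = unname(cf[, "Pr(>|z|)"])
  )
}

#' @rdname tidiers
#' @method glance burden_fit
#' @export
glance.burden_fit <- function(x, ...) {
  out <- tibble(
    set = x$result$set,
    n_ind = x$result$n_ind,
    n_carriers = x$result$n_carriers,
    status = x$result$status
  )
  if (!inherits(x$fit, "firth_logistic")) {
    out$deviance <- x$fit$deviance
    out$aic <- x$fit$aic
  }
  out
}

#' @rdname tidiers
#' @method tidy convergence_result
#' @export
tidy.convergence_result <- function(x, ...) {
  x$pairs
}

#' @rdname tidiers
#' @method glance convergence_result
#' @export
glance.convergence_result <- function(x, ...) {
  tibble(
    method = x$method,
    n_sets = x$n_sets,
    correlation = x$correlation,
    weighted_correlation = x$weighted_correlation,
    n_overlap = length(x$overlap_sets)
  )
}
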