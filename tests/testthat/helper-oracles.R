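# Independent oracles used to validate package computations. These are
# deliberately naive implementations that share no code with the package.

# Iteratively reweighted least squares for logistic regression.
oracle_irls_logistic <- function(X, y, tol = 1e-12, max_iter = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(crossprod(X, X * w), crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  vc <- solve(crossprod(X, X * w))
  list(beta = unname(beta), se = unname(sqrt(diag(vc))))
}

# Exhaustive Benjamini-Hochberg step-up: largest i with p_(i) <= i*q/m,
# reject the i smallest p-values.
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  if (m == 0) return(logical())
  ord <- order(p)
  sorted <- p[ord]
  k <- 0
  for (i in seq_len(m)) {
    if (sorted[i] <= i * q / m) k <- i
  }
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# Weighted Pearson correlation written out as explicit moment sums.
oracle_weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  sxy <- sum(w * (x - mx) * (y - my)) / sw
  sxx <- sum(w * (x - mx)^2) / sw
  syy <- sum(w * (y - my)^2) / sw
  sxy / sqrt(sxx * syy)
}

# Monte-Carlo tail of sum_i lambda_i chi^2_1.
oracle_mc_tail <- function(q, lambda, n = 1e6, seed = 99) {
  withr::with_seed(seed, {
    draws <- colSums(matrix(stats::rchisq(n * length(lambda), df = 1),
                            nrow = length(lambda)) * lambda)
    mean(draws > q)
  })
}

# Random correlation matrix with unit diagonal (k <= 6) built from a
# random factor structure.
random_corr <- function(k, seed) {
  withr::with_seed(seed, {
    A <- matrix(stats::rnorm(k * k), k)
    S <- crossprod(A) + diag(k) * 0.5
    D <- diag(1 / sqrt(diag(S)))
    D %*% S %*% D
  })
}

# Minimal hand-built exome cohort: explicit variants and carriers.
tiny_cohort <- function() {
  individuals <- tibble::tibble(
    individual_id = sprintf("I%02d", 1:6),
    case = c(1L, 1L, 1L, 0L, 0L, 0L),
    sex = c(0L, 1L, 0L, 1L, 0L, 1L)
  )
  for (k in 1:10) individuals[[paste0("PC", k)]] <- 0
  variants <- tibble::tibble(
    variant_id = c("v1", "v2", "v3", "v4", "v5"),
    gene_id = c("gA", "gA", "gB", "gC", "gC"),
    consequence = c("PTV", "PTV", "PTV", "synonymous", "PTV"),
    ac_sample = c(1L, 2L, 1L, 1L, 2L),
    ac_ref = c(0L, 0L, 3L, 0L, 0L)
  )
  carriers <- tibble::tibble(
    variant_id = c("v1", "v2", "v2", "v3", "v4", "v5"),
    individual_id = c("I01", "I01", "I02", "I02", "I03", "I04"),
    dosage = c(1L, 1L, 1L, 1L, 1L, 2L)
  )
  exome_cohort(individuals, variants, carriers, panel_total_n = 188023)
}

# Small simulation configuration shared by pipeline-level tests;
# ... overrides any default.
small_sim <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(
      n_genes = 600, n_cell_types_human = 3, n_cell_types_mouse = 4,
      markers_per_type = 10, synaptic_set_sizes = c(60, 50, 49),
      ld_block_size = 4, ld_rho = 0.5, gwas_n = 20000,
      n_cases = 400, n_controls = 400,
      mu_ptv = 2e-3, mu_syn = 8e-3, seed = seed
    ),
    list(...)
  )
  do.call(sim_config, args)
}
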