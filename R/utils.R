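# Internal assertion and numeric helpers shared across modules.

abort_input <- function(msg, class = "convergene_input_error") {
  rlang::abort(msg, class = c(class, "convergene_error"))
}

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_input(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "convergene_schema_error"
    )
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 allow_boundary = c(TRUE, TRUE)) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_input(sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (allow_boundary[1]) x >= lower else x > lower
  hi_ok <- if (allow_boundary[2]) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort_input(sprintf("`%s` = %g is outside its valid range", name, x))
  }
  invisible(x)
}

# p clamped to the representable open interval; z to the probit limit.
P_MIN <- 1e-300
P_MAX <- 1 - 1e-16
Z_MAX <- 37

clamp_p <- function(p) pmin(pmax(p, P_MIN), P_MAX)

clamp_z <- function(z) pmin(pmax(z, -Z_MAX), Z_MAX)

# Seed scoping: every generator takes an explicit integer seed and leaves
# the global RNG state untouched.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort_input("`seed` must be a single integer")
  }
  withr::with_seed(as.integer(seed), code)
}

# Derive stream-specific sub-seeds so independent generator stages do not
# share RNG streams. Kept below 2^31 - 1.
sub_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 10007 + offset) %% .Machine$integer.max)
}
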