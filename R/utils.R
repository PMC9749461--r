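## Internal numeric helpers shared across modules.

# Row-wise unbiased sample variance with pairwise NA removal.
# Rows with fewer than 2 observed values get NA.
row_vars <- function(x) {
  row_vars_cpp(x)
}

# Base-2 inverse logit preserving dimnames.
inv_logit2 <- function(m) {
  out <- inv_logit2_cpp(m)
  dimnames(out) <- dimnames(m)
  out
}

# Row-wise Pearson correlation between aligned matrices (complete columns only).
row_cors <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  vapply(seq_len(nrow(a)), function(i) {
    ok <- !is.na(a[i, ]) & !is.na(b[i, ])
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(cor(a[i, ok], b[i, ok]))
  }, numeric(1))
}

# Check a count argument.
assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  bad <- length(x) != 1 || is.na(x) || x < lo || x > hi ||
    (open_lo && x == lo) || (open_hi && x == hi)
  if (bad) abort(sprintf("`%s` must be a number in %s%g, %g%s.",
                         name, if (open_lo) "(" else "[", lo, hi,
                         if (open_hi) ")" else "]"))
  as.numeric(x)
}

# Derive a stream of reproducible sub-seeds from one base seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

cpg_ids <- function(n) sprintf("cg%08d", seq_len(n))
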