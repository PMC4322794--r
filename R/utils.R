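# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed + offset`,
# restoring the caller's .Random.seed afterwards. Each synthetic-data
# generator runs in its own derived stream so adding one generator call to a
# script does not perturb the output of the others.
with_seed_offset <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  derived <- (as.numeric(seed) + offset) %% 2147483647
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(derived))
  force(code)
}

# scalar checks -------------------------------------------------------------

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x) ||
      x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# discrete convolution of two probability mass functions over mass shifts
# (index i holds the probability of shift i - 1)
conv_pmf <- function(a, b) {
  la <- length(a)
  lb <- length(b)
  out <- numeric(la + lb - 1)
  for (i in seq_len(la)) {
    out[i:(i + lb - 1)] <- out[i:(i + lb - 1)] + a[i] * b
  }
  out
}

# pmf of the total mass shift of `m` atoms of one element, each with
# single-atom shift pmf `single`
conv_pmf_power <- function(single, m) {
  if (m == 0) return(1)
  out <- single
  if (m == 1) return(out)
  for (i in seq_len(m - 1)) out <- conv_pmf(out, single)
  out
}
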