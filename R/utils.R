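# internal helpers shared across modules

# log-sum-exp over rows of a matrix; handles -Inf rows
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  for (k in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, k])
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

# run expr with a temporary RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

sub_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_probability <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  lo <- if (allow_zero) 0 else .Machine$double.eps
  hi <- if (allow_one) 1 else 1 - .Machine$double.eps
  if (any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    stop(sprintf("`%s` must contain probabilities in [%s, %s]", name,
                 if (allow_zero) "0" else ">0", if (allow_one) "1" else "<1"),
         call. = FALSE)
  }
  invisible(x)
}
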