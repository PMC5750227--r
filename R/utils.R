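# Internal helpers.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators are pure in (args, seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Add-one permutation/bootstrap p-value estimator: (k + 1) / (n + 1).
perm_pvalue <- function(n_exceed, n_perm) (n_exceed + 1) / (n_perm + 1)

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 ||
      x != round(x))
    stop(name, " must be a positive integer")
  invisible(as.integer(x))
}
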