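# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers user
# randomness.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed from a parent seed and a stage label,
# keeping the result a valid 32-bit integer. One top-level seed therefore
# fans out reproducibly to every stage.
derive_seed <- function(seed, label) {
  stopifnot(length(label) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

# Ordinary-least-squares slope of y against x; NA when fewer than 2 distinct x.
ols_slope <- function(x, y) {
  if (length(unique(x)) < 2L) return(NA_real_)
  unname(coef(lm(y ~ x))[2L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
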