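# Internal helpers shared across modules.

# Deterministic 31-bit string/seed hash. Used to derive independent RNG
# streams (per subject, per stage) from one global seed so that cohort
# generation is order-independent: the stream for a subject depends only on
# (seed, subject_id), never on how many subjects were drawn before it.
# Polynomial hash mod the Mersenne prime 2^31 - 1; all intermediates stay
# below 2^53 so the arithmetic is exact in doubles.
hash_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), ...), collapse = "\x1f")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.finite(x) && x == round(x) && x >= 0

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("non-finite values in %s", what)
  invisible(x)
}
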