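# Internal helpers: seeded substreams and small validators.
#
# Each generator draws from its own named substream derived from (seed, name),
# so e.g. adding participants never perturbs unit generation under the same
# city seed.

substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 1000003L
  as.integer((abs(as.numeric(seed)) %% 2147480000 + h) %% 2147483647)
}

with_substream <- function(seed, name, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != floor(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s.",
                  name, deparse(x)), class = "ciclovia_argument_error")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
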