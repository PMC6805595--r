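# Seed plumbing: every stochastic stage takes an explicit integer seed and
# leaves the caller's RNG state untouched.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Deterministic sub-stream seeds, kept below 2^31.
derive_seed <- function(seed, stage, index = 0L) {
  stages <- c(graph = 1L, latent = 2L, emission = 3L, sizes = 4L,
              resample = 5L, permutation = 6L, replicate = 7L, misc = 8L)
  s <- stages[[stage]]
  (as.double(seed) * 97L + s * 1000003 + as.double(index) * 131) %% 2147483629
}

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a
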