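#' @importFrom stats rnorm rpois runif sd kmeans setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Reverse complement of an ACGTN string (plain character, not XString).
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All generator determinism flows through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic child-seed derivation so each sub-generator gets its own
# stream from one user seed. Kept within the 32-bit signed range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 1013 * index) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
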