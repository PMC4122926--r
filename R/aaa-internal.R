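# Canonical one-letter amino-acid alphabet, alphabetical order.  Every
# matrix, vector and sequence index in the package uses this order.
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# PAML dat files order residues differently; bundled tables are remapped
# onto AA_ALPHABET20 at load time.
PAML_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Evaluate expr under a temporary RNG state when seed is non-NULL, restoring
# the caller's stream afterwards.  All user-facing randomness goes through
# this helper so that the same seed reproduces results byte-identically.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage child seeds fanned out from one pipeline seed, so
# a stage re-run in isolation sees the same stream as inside the pipeline.
child_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000000L) * 17L + as.integer(stage)
}
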