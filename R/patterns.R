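# Capture-pattern bookkeeping shared across modules.
#
# Full pattern order (8 cells, 000 first) is used for cell probabilities;
# observed order (7 cells, 000 dropped) is used everywhere a table of
# observed counts appears. Bit order is A, B, C.

.PATTERNS_FULL <- c("000", "100", "010", "001", "110", "101", "011", "111")
.PATTERNS_OBS <- .PATTERNS_FULL[-1]
.CELL_NAMES <- paste0("n", .PATTERNS_OBS)

# 8 x 3 0/1 matrix of pattern bits, rows in .PATTERNS_FULL order
.pattern_bits <- function(patterns = .PATTERNS_FULL) {
  m <- t(vapply(strsplit(patterns, ""), as.integer, integer(3)))
  dimnames(m) <- list(patterns, c("A", "B", "C"))
  m
}

# Run code with a temporary RNG state seeded at `seed`; the caller's
# .Random.seed is restored afterwards so simulation never perturbs the
# user's stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
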