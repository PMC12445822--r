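# Internal helpers shared across modules.

# Amino-acid alphabet accepted in proteome sequences: the 20 standard residues
# plus ambiguity/unknown codes. Ambiguity codes are never counted as lysine.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_EXTRA <- c("X", "B", "Z", "U")
AA_ALLOWED <- c(AA_STANDARD, AA_EXTRA)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Count occurrences of a single character in each element of a character
# vector, case-insensitively.
count_char <- function(x, ch) {
  vapply(x, function(s) {
    sum(charToRaw(toupper(s)) == charToRaw(ch))
  }, integer(1), USE.NAMES = FALSE)
}

# Positions (1-based) of a character in a single string, case-insensitive.
char_positions <- function(s, ch) {
  which(strsplit(toupper(s), "", fixed = TRUE)[[1]] == ch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
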