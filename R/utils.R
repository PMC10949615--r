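# Internal helpers shared across modules.

# Accept a file path, a single string with newlines, or a character vector of
# lines; return a character vector of lines. All text readers funnel through
# this so fixtures can be built in-memory.
read_lines_any <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    return(readr::read_lines(source))
  }
  if (length(source) == 1L && grepl("\n", source)) {
    return(strsplit(source, "\n", fixed = TRUE)[[1]])
  }
  as.character(source)
}

# Deterministic child seeds: every generator draws its own stream from the
# user-facing seed so stages can be re-run independently.
child_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% .Machine$integer.max
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ..., class = "condiga_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}

# Random DNA of given length as one string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
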