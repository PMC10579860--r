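# internal helpers shared across modules

`%na%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x[1])) y else x

# fast 1-based inclusive substring
subs <- function(x, i, j) substr(x, i, j)

is_scalar_chr <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

check_nucleotides <- function(seq, id = "sequence") {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0) {
    rlang::abort(sprintf(
      "non-nucleotide character '%s' in record '%s' at position %d",
      substr(seq, bad, bad), id, bad
    ))
  }
  invisible(TRUE)
}

# retrieve a single scaffold sequence (uppercase string) from a scaffold table
scaffold_seq <- function(scaffolds, id) {
  if (is_scalar_chr(scaffolds)) return(toupper(scaffolds))
  stopifnot(is.data.frame(scaffolds))
  hit <- which(scaffolds$id == id)
  if (length(hit) == 0) {
    rlang::abort(sprintf(
      "scaffold '%s' not found (available: %s)",
      id, paste(scaffolds$id, collapse = ", ")
    ))
  }
  scaffolds$seq[hit[1]]
}

# transcript-oriented coordinate transforms for minus-strand work
orient_coord <- function(pos, scaffold_length, strand) {
  if (strand == "+") pos else scaffold_length - pos + 1
}
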