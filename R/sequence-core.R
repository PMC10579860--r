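#' Read genome scaffolds from a FASTA file
#'
#' Reads a (multi-record) FASTA file into a scaffold table. The header token
#' before the first whitespace becomes the scaffold id; residues are folded to
#' upper case and must be drawn from the DNA alphabet `A,C,G,T,N`.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return A tibble with one row per record and columns `id`, `seq` (upper-case
#'   residue string) and `length` (nt), in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 demo scaffold", "ACGTACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) rlang::abort(sprintf("empty FASTA file: %s", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf(
      "duplicate scaffold id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  seqs <- unname(toupper(as.character(set)))
  for (k in seq_along(seqs)) check_nucleotides(seqs[k], ids[k])
  tibble::tibble(id = ids, seq = unname(seqs), length = nchar(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x A tibble with columns `id` and `seq` (as from [read_fasta()]), or a
#'   named character vector.
#' @param path Output path.
#' @param width Line-wrap width in residues (default 60).
#' @param type `"dna"` or `"protein"` (controls alphabet validation).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (is.data.frame(x)) x <- stats::setNames(x$seq, x$id)
  set <- if (type == "dna") {
    Biostrings::DNAStringSet(x)
  } else {
    Biostrings::AAStringSet(x)
  }
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a genomic interval table
#'
#' Coordinates are 1-based inclusive and always refer to the forward strand in
#' ascending order; the `strand` field records transcript orientation.
#'
#' @param scaffold_id Scaffold name(s).
#' @param start,end 1-based inclusive forward-strand coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return A tibble with columns `scaffold_id`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(scaffold_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1) || any(end < start)) {
    rlang::abort("interval requires 1 <= start <= end")
  }
  if (!all(strand %in% c("+", "-"))) rlang::abort("strand must be '+' or '-'")
  tibble::tibble(scaffold_id = scaffold_id, start = start, end = end,
                 strand = strand)
}

#' Extract the sequence of a genomic interval
#'
#' Returns the forward-strand substring for `+` intervals and its reverse
#' complement for `-` intervals, so the result always reads in transcript
#' orientation.
#'
#' @param scaffolds Scaffold table from [read_fasta()] (or a bare sequence
#'   string when `interval` carries no meaningful scaffold id).
#' @param interval Interval table from [genomic_interval()]; may have several
#'   rows.
#' @return Character vector of extracted sequences, one per interval row.
#' @export
extract_region <- function(scaffolds, interval) {
  vapply(seq_len(nrow(interval)), function(k) {
    row <- interval[k, ]
    s <- scaffold_seq(scaffolds, row$scaffold_id)
    L <- nchar(s)
    if (row$start < 1 || row$end > L) {
      rlang::abort(sprintf(
        "interval %d-%d out of bounds for scaffold '%s' (1-%d)",
        row$start, row$end, row$scaffold_id, L
      ))
    }
    out <- subs(s, row$start, row$end)
    if (row$strand == "-") out <- reverse_complement(out)
    out
  }, character(1))
}

#' Reverse-complement nucleotide sequences
#'
#' An involution on strings over `A,C,G,T,N`; `N` maps to `N`.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  for (s in seq) check_nucleotides(toupper(s))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(seq))))
}

#' Translate a coding sequence
#'
#' Translates under the standard nuclear genetic code, rendering stop codons
#' as `*`. Trailing nucleotides that do not fill a codon are ignored but
#' reported; codons containing `N` translate to `X` and are flagged.
#'
#' @param cds Coding nucleotide string, length >= 3.
#' @return A list of class `translation` with elements `peptide`, `remainder`
#'   (0-2 trailing nt ignored) and `ambiguous_codons` (1-based codon indices
#'   containing `N`).
#' @examples
#' translate_cds("ATGAAATAA")$peptide  # "MK*"
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  check_nucleotides(cds)
  if (nchar(cds) < 3) rlang::abort("CDS must be at least 3 nt long")
  n_codon <- nchar(cds) %/% 3
  starts <- 3 * seq_len(n_codon) - 2
  codons <- substring(cds, starts, starts + 2)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  ambiguous <- which(is.na(aa))
  aa[is.na(aa)] <- "X"
  structure(
    list(peptide = paste(aa, collapse = ""),
         remainder = nchar(cds) %% 3,
         ambiguous_codons = ambiguous),
    class = "translation"
  )
}

#' @export
print.translation <- function(x, ...) {
  cat("Translation:", x$peptide, "\n")
  if (x$remainder > 0) cat("  trailing nt ignored:", x$remainder, "\n")
  if (length(x$ambiguous_codons) > 0) {
    cat("  ambiguous codons (N):", paste(x$ambiguous_codons, collapse = ", "), "\n")
  }
  invisible(x)
}

# peptide string only (internal shorthand)
.peptide <- function(cds) translate_cds(cds)$peptide
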