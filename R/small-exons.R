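#' Define constraints for a small-exon search
#'
#' Coding exons under ~30 nt are routinely missed by similarity search; they
#' can still be pinned down from biological constraints alone: the type of CDS
#' (initial, internal or terminal), the splice phases it must join, and the
#' expected size range. An exon of length `L` carrying `acceptor_phase`
#' leading and `donor_phase` trailing partial-codon nucleotides satisfies
#' `L = acceptor_phase + 3k + donor_phase`, which fixes `L` modulo 3.
#'
#' @param cds_type `"initial"`, `"internal"` or `"terminal"`.
#' @param acceptor_phase Phase of the acceptor site joined at the exon's 5'
#'   end (0-2; ignored for initial exons).
#' @param donor_phase Phase of the donor site at the 3' end (ignored for
#'   terminal exons).
#' @param min_length,max_length Length bounds in nt (values below 30 are the
#'   point of this search; `min_length >= 1`).
#' @param allow_gc_donor Also accept the rare GC donor.
#' @return A list of class `exon_search_constraints`.
#' @export
exon_search_constraints <- function(cds_type = c("internal", "initial", "terminal"),
                                    acceptor_phase = 0L, donor_phase = 0L,
                                    min_length = 3L, max_length = 90L,
                                    allow_gc_donor = FALSE) {
  cds_type <- match.arg(cds_type)
  min_length <- as.integer(min_length); max_length <- as.integer(max_length)
  if (min_length < 1) rlang::abort("min_length must be >= 1")
  if (min_length > max_length) rlang::abort("contradictory constraints: min_length > max_length")
  structure(
    list(cds_type = cds_type,
         acceptor_phase = as.integer(acceptor_phase) %% 3L,
         donor_phase = as.integer(donor_phase) %% 3L,
         min_length = min_length, max_length = max_length,
         allow_gc_donor = isTRUE(allow_gc_donor)),
    class = "exon_search_constraints"
  )
}

# predicate used by the finder; exported so candidates can be re-validated
#' Validate one candidate against small-exon constraints
#'
#' Checks a candidate exon occupying `start..end` (1-based, transcript
#' orientation) of `window_sequence` against [exon_search_constraints()]:
#' flanking splice dinucleotides, start/stop codons, length congruence and
#' absence of in-frame stop codons among complete codons.
#'
#' @param window_sequence Transcript-oriented nucleotide string.
#' @param start,end Candidate bounds within the window.
#' @param constraints An [exon_search_constraints()].
#' @return `TRUE`/`FALSE`.
#' @export
satisfies_exon_constraints <- function(window_sequence, start, end, constraints) {
  S <- window_sequence; cn <- constraints
  L <- end - start + 1
  if (L < cn$min_length || L > cn$max_length) return(FALSE)
  a <- if (cn$cds_type == "initial") 0L else cn$acceptor_phase
  d <- if (cn$cds_type == "terminal") 0L else cn$donor_phase
  donors <- c("GT", if (cn$allow_gc_donor) "GC")
  if (cn$cds_type == "initial") {
    if (subs(S, start, start + 2) != "ATG") return(FALSE)
  } else {
    if (start < 3 || subs(S, start - 2, start - 1) != "AG") return(FALSE)
  }
  if (cn$cds_type == "terminal") {
    if (!subs(S, end - 2, end) %in% STOP_CODONS) return(FALSE)
  } else {
    if (end + 2 > nchar(S) || !subs(S, end + 1, end + 2) %in% donors) return(FALSE)
  }
  if ((L - a - d) %% 3 != 0 || L < a + d) return(FALSE)
  # complete codons begin after the leading partial-codon nucleotides
  frame0 <- start + a
  last_start <- end - d - 2
  if (frame0 <= last_start) {
    starts <- seq.int(frame0, last_start, by = 3)
    if (cn$cds_type == "terminal") starts <- starts[-length(starts)]
    if (length(starts) > 0 &&
        any(substring(S, starts, starts + 2) %in% STOP_CODONS)) return(FALSE)
  } else if (cn$cds_type == "terminal") {
    return(FALSE)  # terminal exon must at least hold its stop codon
  }
  TRUE
}

#' Search a window for phase-constrained small coding exons
#'
#' Enumerates every exon candidate in the window that satisfies the supplied
#' constraints; see [exon_search_constraints()] for the predicate. Candidates
#' are returned ordered by ascending forward-strand start, then descending
#' length (the ranking is purely positional and deterministic).
#'
#' @param window_sequence Forward-strand nucleotide string of the search
#'   window.
#' @param window_offset 1-based scaffold coordinate of the window's first
#'   base.
#' @param constraints An [exon_search_constraints()].
#' @param strand `"+"` searches the given sequence; `"-"` searches its reverse
#'   complement and reports forward-strand coordinates.
#' @param scaffold_id Scaffold name recorded on the candidates.
#' @return Tibble of candidates: `scaffold_id`, `start`, `end`, `strand`,
#'   `length`, `flanking_acceptor`, `flanking_donor`, `score_rank`.
#' @examples
#' cn <- exon_search_constraints("internal", 0, 0, min_length = 6)
#' find_small_exons("TTAGATGGCAGTTT", 1, cn)
#' @export
find_small_exons <- function(window_sequence, window_offset, constraints,
                             strand = "+", scaffold_id = "scaffold") {
  S <- toupper(window_sequence)
  check_nucleotides(S)
  cn <- constraints
  if (strand == "-") S <- reverse_complement(S)
  L <- nchar(S)
  a <- if (cn$cds_type == "initial") 0L else cn$acceptor_phase
  d <- if (cn$cds_type == "terminal") 0L else cn$donor_phase

  # anchor positions for the 5' boundary
  starts <- if (cn$cds_type == "initial") {
    which(vapply(seq_len(max(L - 2, 0)), function(s) subs(S, s, s + 2) == "ATG",
                 logical(1)))
  } else {
    hits <- which(vapply(seq_len(max(L - 1, 0)), function(s) subs(S, s, s + 1) == "AG",
                         logical(1)))
    hits + 2L  # exon begins right after the AG
  }
  starts <- starts[starts >= 1 & starts <= L]
  out <- list()
  for (s in starts) {
    max_len <- min(cn$max_length, L - s + 1)
    if (max_len < cn$min_length) next
    lens <- seq.int(from = cn$min_length, to = max_len)
    lens <- lens[(lens - a - d) %% 3 == 0]
    for (len in lens) {
      e <- s + len - 1
      if (satisfies_exon_constraints(S, s, e, cn)) {
        out[[length(out) + 1]] <- c(s = s, e = e)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(scaffold_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          length = integer(), flanking_acceptor = character(),
                          flanking_donor = character(), score_rank = integer()))
  }
  m <- do.call(rbind, out)
  res <- tibble::tibble(
    o_start = m[, "s"], o_end = m[, "e"],
    flanking_acceptor = if (cn$cds_type == "initial") NA_character_ else
      substring(S, m[, "s"] - 2, m[, "s"] - 1),
    flanking_donor = if (cn$cds_type == "terminal") NA_character_ else
      substring(S, m[, "e"] + 1, m[, "e"] + 2)
  )
  if (strand == "+") {
    res$start <- window_offset + res$o_start - 1L
    res$end <- window_offset + res$o_end - 1L
  } else {
    res$start <- window_offset + L - res$o_end
    res$end <- window_offset + L - res$o_start
  }
  res <- dplyr::arrange(res, .data$start, dplyr::desc(.data$end - .data$start))
  dplyr::transmute(
    res, scaffold_id = scaffold_id, start = as.integer(.data$start),
    end = as.integer(.data$end), strand = strand,
    length = as.integer(.data$end - .data$start + 1),
    flanking_acceptor = as.character(.data$flanking_acceptor),
    flanking_donor = as.character(.data$flanking_donor),
    score_rank = dplyr::row_number()
  )
}
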