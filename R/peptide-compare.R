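#' Compare a model peptide against its reference ortholog
#'
#' Produces the two views curators use to judge a proposed gene model against
#' the reference ortholog: an exact-word dot-plot matrix and a global protein
#' alignment (BLOSUM62, affine gaps) with percent identity over aligned
#' columns. Long gap runs in the alignment are listed as anomalies, since a
#' large gap often indicates the selection of an incorrect splice site or a
#' missing exon.
#'
#' @param model_peptide,reference_peptide Non-empty peptide strings.
#' @param word_size Word length for the dot plot (default 3).
#' @param gap_anomaly_min Minimum gap-run length (aa) reported as an anomaly
#'   (default 4).
#' @param gap_opening,gap_extension Affine gap penalties (positive costs)
#'   passed to the global aligner.
#' @return Object of class `peptide_comparison`: list with `dotplot` (binary
#'   integer matrix, rows = model words, columns = reference words),
#'   `alignment` (list: `aligned_model`, `aligned_reference`, `score`),
#'   `percent_identity` (over aligned columns, gaps counted as columns),
#'   `anomalies` (tibble of gap runs >= threshold) and `word_size`.
#' @export
compare_peptides <- function(model_peptide, reference_peptide, word_size = 3,
                             gap_anomaly_min = 4, gap_opening = 10,
                             gap_extension = 1) {
  a <- toupper(model_peptide); b <- toupper(reference_peptide)
  if (nchar(a) == 0 || nchar(b) == 0) rlang::abort("peptides must be non-empty")
  a <- gsub("\\*$", "", a); b <- gsub("\\*$", "", b)

  na <- nchar(a) - word_size + 1
  nb <- nchar(b) - word_size + 1
  dot <- matrix(0L, nrow = max(na, 0), ncol = max(nb, 0))
  if (na > 0 && nb > 0) {
    wa <- substring(a, seq_len(na), seq_len(na) + word_size - 1)
    wb <- substring(b, seq_len(nb), seq_len(nb) + word_size - 1)
    dot <- outer(wa, wb, `==`) * 1L
  }

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", type = "global",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1]]; cb <- strsplit(pb, "")[[1]]
  identity <- 100 * sum(ca == cb & ca != "-") / length(ca)

  gap_runs <- function(chars, in_seq) {
    r <- rle(chars == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & r$lengths >= gap_anomaly_min
    if (!any(keep)) return(NULL)
    tibble::tibble(gap_in = in_seq, column_start = starts[keep],
                   length = r$lengths[keep])
  }
  anomalies <- dplyr::bind_rows(gap_runs(ca, "model"), gap_runs(cb, "reference"))
  if (nrow(anomalies) == 0) {
    anomalies <- tibble::tibble(gap_in = character(), column_start = integer(),
                                length = integer())
  }
  structure(
    list(dotplot = dot,
         alignment = list(aligned_model = pa, aligned_reference = pb,
                          score = Biostrings::score(aln)),
         percent_identity = identity,
         anomalies = anomalies,
         word_size = word_size),
    class = "peptide_comparison"
  )
}

#' @export
print.peptide_comparison <- function(x, ...) {
  cat(sprintf("<peptide_comparison> %.1f%% identity, score %.1f, %d gap anomaly(ies)\n",
              x$percent_identity, x$alignment$score, nrow(x$anomalies)))
  invisible(x)
}

#' @method glance peptide_comparison
#' @export
glance.peptide_comparison <- function(x, ...) {
  tibble::tibble(percent_identity = x$percent_identity,
                 alignment_score = x$alignment$score,
                 alignment_columns = nchar(x$alignment$aligned_model),
                 n_gap_anomalies = nrow(x$anomalies),
                 word_size = x$word_size)
}

#' @method tidy peptide_comparison
#' @export
tidy.peptide_comparison <- function(x, ...) x$anomalies
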