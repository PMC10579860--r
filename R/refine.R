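# Boundary refinement: similarity-search coordinates only cover complete
# codons, so true exon boundaries typically sit a few nucleotides beyond the
# approximate ones, at the nearest splice site compatible with the running
# reading frame.

#' Refine one approximate coding-exon boundary pair
#'
#' Searches up to `window` nt around each approximate boundary for refined
#' coordinates such that: an internal/terminal exon start abuts an AG acceptor
#' (an initial exon starts at an allowed start codon); an internal/initial
#' exon end abuts a GT donor (or GC when allowed); the leading partial codon
#' equals the acceptor phase required by the running frame; no in-frame stop
#' codon appears among the exon's complete codons (a terminal exon must end in
#' a stop with none earlier). Among candidates the minimal total absolute
#' shift wins; ties break toward extension over truncation.
#'
#' @param scaffolds Scaffold table from [read_fasta()].
#' @param approx Approximate exon interval (one row from [genomic_interval()],
#'   strand set).
#' @param role `"initial"`, `"internal"` or `"terminal"`.
#' @param prev_donor_phase Donor phase of the preceding intron (0-2); the
#'   required acceptor phase is `(3 - prev_donor_phase) %% 3`. Ignored for
#'   initial exons.
#' @param window Search radius in nt around each boundary (default 15;
#'   curated adjustments are typically 1-2 nt, so a small window suffices and
#'   limits false candidates).
#' @param allow_gc_donor Accept the rare GC donor as a boundary signal.
#' @param start_codons Allowed start codons for initial exons.
#' @return One-row tibble: refined `scaffold_id`, `start`, `end`, `strand`,
#'   transcript-orientation `start_shift` / `end_shift` (negative = extension
#'   of the 5' boundary upstream / truncation of the 3' boundary), flanking
#'   `acceptor` / `donor` dinucleotides, and a `justification` string.
#' @export
refine_boundary <- function(scaffolds, approx, role = c("initial", "internal", "terminal"),
                            prev_donor_phase = 0L, window = 15L,
                            allow_gc_donor = TRUE, start_codons = "ATG") {
  role <- match.arg(role)
  if (role != "initial" &&
      (length(prev_donor_phase) != 1 || is.na(prev_donor_phase) ||
       !prev_donor_phase %in% 0:2)) {
    rlang::abort("`prev_donor_phase` must be 0, 1 or 2 for internal/terminal exons")
  }
  s_fwd <- scaffold_seq(scaffolds, approx$scaffold_id)
  L <- nchar(s_fwd)
  strand <- approx$strand
  # work in transcript orientation
  S <- if (strand == "+") s_fwd else reverse_complement(s_fwd)
  o_start <- if (strand == "+") approx$start else L - approx$end + 1
  o_end <- if (strand == "+") approx$end else L - approx$start + 1
  a_star <- if (role == "initial") 0L else (3L - as.integer(prev_donor_phase) %% 3L) %% 3L

  donors <- c("GT", if (allow_gc_donor) "GC")
  cand_s <- (o_start - window):(o_start + window)
  cand_s <- cand_s[cand_s >= if (role == "initial") 1 else 3]
  cand_s <- cand_s[vapply(cand_s, function(s) {
    if (role == "initial") subs(S, s, s + 2) %in% start_codons
    else subs(S, s - 2, s - 1) == "AG"
  }, logical(1))]
  cand_e <- (o_end - window):(o_end + window)
  cand_e <- cand_e[cand_e <= if (role == "terminal") L else L - 2]
  if (role != "terminal") {
    cand_e <- cand_e[vapply(cand_e, function(e) subs(S, e + 1, e + 2) %in% donors,
                            logical(1))]
  }

  best <- NULL
  for (s in cand_s) {
    frame0 <- s + a_star  # first complete codon start
    for (e in cand_e) {
      len <- e - s + 1
      if (len < 1) next
      if (role == "terminal") {
        if (len < a_star + 3) next
        if ((len - a_star) %% 3 != 0) next
        if (!subs(S, e - 2, e) %in% STOP_CODONS) next
      }
      # complete codons fully inside the exon
      codon_starts <- if (frame0 <= e - 2) seq.int(frame0, e - 2, by = 3) else integer(0)
      if (length(codon_starts) > 0) {
        if (role == "terminal") codon_starts <- codon_starts[-length(codon_starts)]
        if (length(codon_starts) > 0) {
          cds_codons <- substring(S, codon_starts, codon_starts + 2)
          if (any(cds_codons %in% STOP_CODONS)) next
        }
      }
      shift <- abs(s - o_start) + abs(e - o_end)
      cand <- list(s = s, e = e, shift = shift, len = len)
      if (is.null(best) || shift < best$shift ||
          (shift == best$shift && len > best$len) ||
          (shift == best$shift && len == best$len && s < best$s)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    rlang::abort(paste0(
      "no compatible boundary within the search window; ",
      "increase `window` or declare a non-canonical site allowance"))
  }
  start_shift <- best$s - o_start
  end_shift <- best$e - o_end
  fwd_start <- if (strand == "+") best$s else L - best$e + 1
  fwd_end <- if (strand == "+") best$e else L - best$s + 1
  acceptor <- if (role == "initial") NA_character_ else subs(S, best$s - 2, best$s - 1)
  donor <- if (role == "terminal") NA_character_ else subs(S, best$e + 1, best$e + 2)
  tibble::tibble(
    scaffold_id = approx$scaffold_id, start = fwd_start, end = fwd_end,
    strand = strand, start_shift = start_shift, end_shift = end_shift,
    acceptor = acceptor, donor = donor,
    justification = sprintf(
      "%s exon: 5' shift %+d, 3' shift %+d (acceptor %s, donor %s, acceptor phase %d)",
      role, start_shift, end_shift, acceptor %na% "-", donor %na% "-", a_star)
  )
}

#' Refine all exon boundaries of an approximate model
#'
#' Applies [refine_boundary()] exon by exon in transcript order, carrying the
#' running reading frame (the refined donor phase of each intron) into the
#' next exon.
#'
#' @inheritParams refine_boundary
#' @param model Approximate [isoform_model()].
#' @return List with `model` (refined [isoform_model()]) and `report` (tibble
#'   of per-exon shifts and justifications, transcript order).
#' @export
refine_model <- function(model, scaffolds, window = 15L, allow_gc_donor = TRUE,
                         start_codons = "ATG") {
  n <- nrow(model$exons)
  d <- 0L
  rows <- list()
  new_start <- integer(n); new_end <- integer(n)
  for (k in seq_len(n)) {
    role <- if (k == 1) "initial" else if (k == n) "terminal" else "internal"
    approx <- genomic_interval(model$scaffold_id, model$exons$start[k],
                               model$exons$end[k], model$strand)
    ref <- refine_boundary(scaffolds, approx, role, prev_donor_phase = d,
                           window = window, allow_gc_donor = allow_gc_donor,
                           start_codons = start_codons)
    new_start[k] <- ref$start; new_end[k] <- ref$end
    a_star <- if (role == "initial") 0L else (3L - d) %% 3L
    d <- as.integer((ref$end - ref$start + 1 - a_star) %% 3)
    rows[[k]] <- dplyr::mutate(ref, ordinal = k, role = role, .before = 1)
  }
  refined <- isoform_model(model$gene_symbol, model$isoform_name,
                           model$scaffold_id, model$strand,
                           starts = new_start, ends = new_end,
                           assembly_id = model$assembly_id,
                           complete = model$complete,
                           allowances = model$allowances)
  list(model = refined, report = dplyr::bind_rows(rows))
}

#' Tabulate refinement adjustments between coordinate sets
#'
#' Compares approximate (e.g. similarity-search) and refined coding-exon
#' coordinates for one isoform and reports the per-exon signed adjustments
#' (refined minus approximate), in forward-strand coordinates.
#'
#' @param approx,refined Data frames with columns `exon`, `start`, `end`
#'   (1-based inclusive, ascending exon order), or [isoform_model()] objects.
#' @return Tibble: `exon`, approximate and refined coordinates, `start_diff`,
#'   `end_diff`.
#' @export
refinement_report <- function(approx, refined) {
  as_coords <- function(x) {
    if (inherits(x, "isoform_model")) {
      tibble::tibble(exon = seq_len(nrow(x$exons)),
                     start = sort(x$exons$start), end = sort(x$exons$end))
    } else {
      tibble::as_tibble(x[, c("exon", "start", "end")])
    }
  }
  a <- as_coords(approx); r <- as_coords(refined)
  if (nrow(a) != nrow(r)) rlang::abort("coordinate sets have different exon counts")
  tibble::tibble(
    exon = a$exon,
    approx_start = a$start, approx_end = a$end,
    refined_start = r$start, refined_end = r$end,
    start_diff = r$start - a$start,
    end_diff = r$end - a$end
  )
}
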