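#' Splice phases implied by a model's exon lengths
#'
#' The donor phase of an intron is the number of nucleotides between the end
#' of the last complete codon and the donor site; the acceptor phase is the
#' number of nucleotides between the acceptor site and the first complete
#' codon. For the open reading frame to survive splicing their sum must be 0
#' or 3. The donor phase is taken from the cumulative coding length through
#' the upstream exon; the acceptor phase is computed by independently tracking
#' the reading frame into the downstream exon, so bookkeeping inconsistencies
#' are detectable rather than assumed away.
#'
#' @param model An [isoform_model()] (only exon lengths are used), or an
#'   integer vector of exon lengths in transcript order.
#' @return Tibble with one row per intron: `junction`, `donor_phase`,
#'   `acceptor_phase`, `phase_sum`.
#' @export
junction_phases <- function(model) {
  lens <- if (inherits(model, "isoform_model")) exon_lengths(model) else as.integer(model)
  if (length(lens) < 2) {
    return(tibble::tibble(junction = integer(), donor_phase = integer(),
                          acceptor_phase = integer(), phase_sum = integer()))
  }
  cum <- cumsum(lens)
  donor <- cum[-length(cum)] %% 3
  # independent path: walk codon starts into each downstream exon
  acceptor <- vapply(seq_len(length(lens) - 1), function(k) {
    consumed <- cum[k]
    lead <- 0L
    while ((consumed + lead) %% 3 != 0) lead <- lead + 1L
    lead
  }, integer(1))
  tibble::tibble(junction = seq_along(donor),
                 donor_phase = as.integer(donor),
                 acceptor_phase = acceptor,
                 phase_sum = as.integer(donor + acceptor))
}

classify_junction <- function(donor, acceptor) {
  if (donor == "GT" && acceptor == "AG") "canonical_GT_AG"
  else if (donor == "GC" && acceptor == "AG") "rare_GC_AG"
  else "non_canonical"
}

#' Compute intron junctions of a gene model
#'
#' One junction per adjacent exon pair, in transcript order. The donor
#' dinucleotide is the first two intronic nucleotides after the upstream exon
#' (in transcript orientation) and the acceptor the last two before the
#' downstream exon; phases follow [junction_phases()].
#'
#' @param model An [isoform_model()].
#' @param scaffolds Scaffold table from [read_fasta()].
#' @return Tibble: `junction`, `upstream_exon_ordinal`, `donor_dinucleotide`,
#'   `acceptor_dinucleotide`, `donor_phase`, `acceptor_phase`, `phase_sum`,
#'   `canonical_class`.
#' @export
compute_junctions <- function(model, scaffolds) {
  n <- nrow(model$exons)
  ph <- junction_phases(model)
  if (n < 2) {
    return(dplyr::mutate(ph, upstream_exon_ordinal = integer(),
                         donor_dinucleotide = character(),
                         acceptor_dinucleotide = character(),
                         canonical_class = character()))
  }
  s <- scaffold_seq(scaffolds, model$scaffold_id)
  ex <- model$exons
  dinucs <- lapply(seq_len(n - 1), function(k) {
    if (model$strand == "+") {
      gap <- ex$start[k + 1] - ex$end[k] - 1
      if (gap <= 0) rlang::abort(sprintf("zero-length intron at junction %d", k))
      list(donor = subs(s, ex$end[k] + 1, ex$end[k] + 2),
           acceptor = subs(s, ex$start[k + 1] - 2, ex$start[k + 1] - 1))
    } else {
      gap <- ex$start[k] - ex$end[k + 1] - 1
      if (gap <= 0) rlang::abort(sprintf("zero-length intron at junction %d", k))
      list(donor = reverse_complement(subs(s, ex$start[k] - 2, ex$start[k] - 1)),
           acceptor = reverse_complement(subs(s, ex$end[k + 1] + 1, ex$end[k + 1] + 2)))
    }
  })
  dplyr::mutate(
    ph,
    upstream_exon_ordinal = .data$junction,
    donor_dinucleotide = vapply(dinucs, `[[`, "", "donor"),
    acceptor_dinucleotide = vapply(dinucs, `[[`, "", "acceptor"),
    canonical_class = mapply(classify_junction,
                             vapply(dinucs, `[[`, "", "donor"),
                             vapply(dinucs, `[[`, "", "acceptor"),
                             USE.NAMES = FALSE)
  )
}

# one checklist row
chk_item <- function(key, status, message, junction = NA_integer_,
                     exon = NA_integer_) {
  tibble::tibble(key = key, status = status, message = message,
                 junction = junction, exon = exon)
}

#' Validate a gene model against biological constraints
#'
#' Runs the curation checklist on a proposed gene model: canonical start codon
#' (ATG unless a non-canonical start allowance is declared), per-intron donor
#' site (GT passes; the naturally occurring GC variant warns; anything else
#' fails unless declared), per-intron acceptor site (AG; else fail unless
#' declared), splice-phase compatibility (donor + acceptor phase equal to 0 or
#' 3), absence of in-frame stop codons among the complete codons of each exon,
#' a terminal stop codon, total coding length divisible by three (the stop
#' codon counts toward the coding span), and agreement of the exon count with
#' the reference isoform record when one is supplied. Items are ordered 5' to
#' 3' in transcript orientation, with the two global items last, so the
#' first failing item is where troubleshooting should start: a single upstream
#' boundary error typically produces a cascade of downstream frame failures
#' that all resolve once the first one is fixed.
#'
#' Partial models (`complete = FALSE`) demote the start/stop items to
#' warnings so genes truncated at assembly gaps remain checkable. A
#' `stop_readthrough` allowance demotes internal-stop failures to warnings.
#'
#' @param model An [isoform_model()].
#' @param scaffolds Scaffold table from [read_fasta()].
#' @param reference Optional `reference_record` for the orthologous isoform.
#' @return Object of class `checklist_report`: list with `items` (tibble of
#'   `key`, `status`, `message`, `junction`, `exon`), `overall` (`pass`,
#'   `pass_with_warnings` or `fail`), `first_failure` (one-row tibble or
#'   `NULL`), `peptide` (terminal stop stripped), `cds_length` and
#'   `junctions` (the [compute_junctions()] table).
#' @export
check_model <- function(model, scaffolds, reference = NULL) {
  cds <- assemble_cds(model, scaffolds)
  lens <- exon_lengths(model)
  cum <- cumsum(lens)
  n_exon <- length(lens)
  junc <- compute_junctions(model, scaffolds)
  allow <- model$allowances
  items <- list()
  demote <- function(cond) if (cond) "warn" else "fail"

  # in-frame stop codons of the assembled CDS, attributed to exons
  n_codon <- nchar(cds) %/% 3
  codons <- substring(cds, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  is_stop <- codons %in% STOP_CODONS
  mid_nt <- 3 * seq_len(n_codon) - 1
  codon_exon <- findInterval(mid_nt - 1, cum) + 1
  final_codon_complete <- nchar(cds) %% 3 == 0

  # 1. start codon
  start_codon <- subs(cds, 1, 3)
  allowed_starts <- c("ATG", allow$non_canonical_start)
  if (start_codon == "ATG") {
    items[[length(items) + 1]] <- chk_item("start_codon", "pass",
      sprintf("start codon %s", start_codon))
  } else if (start_codon %in% allowed_starts) {
    items[[length(items) + 1]] <- chk_item("start_codon", "warn",
      sprintf("non-canonical start codon %s (declared allowance)", start_codon))
  } else {
    items[[length(items) + 1]] <- chk_item("start_codon", demote(!model$complete),
      sprintf("first codon %s is not a start codon", start_codon))
  }

  for (e in seq_len(n_exon)) {
    # internal stops in exon e (terminal stop codon handled separately)
    stop_idx <- which(is_stop & codon_exon == e)
    if (e == n_exon && final_codon_complete) stop_idx <- setdiff(stop_idx, n_codon)
    if (length(stop_idx) == 0) {
      items[[length(items) + 1]] <- chk_item(
        paste0("internal_stops:", e), "pass",
        sprintf("no in-frame stop codon within coding exon %d", e), exon = e)
    } else {
      items[[length(items) + 1]] <- chk_item(
        paste0("internal_stops:", e),
        demote(isTRUE(allow$stop_readthrough)),
        sprintf("in-frame stop codon(s) at codon %s within coding exon %d",
                paste(stop_idx, collapse = ","), e), exon = e)
    }
    if (e == n_exon) break

    # junction e items
    j <- junc[e, ]
    declared_donor <- (allow$non_canonical_donor %na% character(0))[as.character(e)]
    if (j$donor_dinucleotide == "GT") {
      items[[length(items) + 1]] <- chk_item(paste0("donor_site:", e), "pass",
        sprintf("canonical GT donor at junction %d", e), junction = e)
    } else if (j$donor_dinucleotide == "GC") {
      items[[length(items) + 1]] <- chk_item(paste0("donor_site:", e), "warn",
        sprintf("rare GC donor at junction %d", e), junction = e)
    } else if (!is.na(declared_donor) && declared_donor == j$donor_dinucleotide) {
      items[[length(items) + 1]] <- chk_item(paste0("donor_site:", e), "warn",
        sprintf("declared non-canonical %s donor at junction %d",
                j$donor_dinucleotide, e), junction = e)
    } else {
      items[[length(items) + 1]] <- chk_item(paste0("donor_site:", e), "fail",
        sprintf("non-canonical %s donor at junction %d", j$donor_dinucleotide, e),
        junction = e)
    }
    declared_acc <- (allow$non_canonical_acceptor %na% character(0))[as.character(e)]
    if (j$acceptor_dinucleotide == "AG") {
      items[[length(items) + 1]] <- chk_item(paste0("acceptor_site:", e), "pass",
        sprintf("canonical AG acceptor at junction %d", e), junction = e)
    } else if (!is.na(declared_acc) && declared_acc == j$acceptor_dinucleotide) {
      items[[length(items) + 1]] <- chk_item(paste0("acceptor_site:", e), "warn",
        sprintf("declared non-canonical %s acceptor at junction %d",
                j$acceptor_dinucleotide, e), junction = e)
    } else {
      items[[length(items) + 1]] <- chk_item(paste0("acceptor_site:", e), "fail",
        sprintf("non-canonical %s acceptor at junction %d",
                j$acceptor_dinucleotide, e), junction = e)
    }
    items[[length(items) + 1]] <- chk_item(
      paste0("phase_compat:", e),
      if (j$phase_sum %in% c(0L, 3L)) "pass" else "fail",
      sprintf("donor phase %d + acceptor phase %d = %d at junction %d",
              j$donor_phase, j$acceptor_phase, j$phase_sum, e), junction = e)
  }

  # terminal stop codon
  last_codon <- if (final_codon_complete) codons[n_codon] else {
    if (n_codon >= 1) codons[n_codon] else ""
  }
  if (final_codon_complete && last_codon %in% STOP_CODONS) {
    items[[length(items) + 1]] <- chk_item("stop_codon", "pass",
      sprintf("model ends with stop codon %s", last_codon))
  } else {
    items[[length(items) + 1]] <- chk_item("stop_codon", demote(!model$complete),
      if (final_codon_complete)
        sprintf("final codon %s is not a stop codon", last_codon)
      else "coding region does not end on a codon boundary")
  }

  # global items
  items[[length(items) + 1]] <- chk_item(
    "length_divisible_by_3",
    if (nchar(cds) %% 3 == 0) "pass" else demote(!model$complete),
    sprintf("total coding length %d nt %s divisible by three", nchar(cds),
            if (nchar(cds) %% 3 == 0) "is" else "is not"))
  if (!is.null(reference)) {
    items[[length(items) + 1]] <- chk_item(
      "exon_count_match",
      if (n_exon == reference$exon_count) "pass" else "fail",
      sprintf("model has %d coding exon(s); reference isoform %s has %d",
              n_exon, reference$isoform_name, reference$exon_count))
  } else {
    items[[length(items) + 1]] <- chk_item("exon_count_match", "warn",
      "no reference isoform record supplied; exon count not checked")
  }

  items <- dplyr::bind_rows(items)
  overall <- if (any(items$status == "fail")) "fail"
             else if (any(items$status == "warn")) "pass_with_warnings"
             else "pass"
  first_fail <- if (overall == "fail") items[which(items$status == "fail")[1], ] else NULL
  pep <- .peptide(if (nchar(cds) >= 3) cds else "NNN")
  if (substr(pep, nchar(pep), nchar(pep)) == "*") pep <- substr(pep, 1, nchar(pep) - 1)
  structure(
    list(items = items, overall = overall, first_failure = first_fail,
         peptide = pep, cds_length = nchar(cds), junctions = junc,
         isoform_name = model$isoform_name),
    class = "checklist_report"
  )
}

#' Locate the 5'-most failing checklist item
#'
#' Curators troubleshoot from the beginning of the gene: correcting the first
#' (most upstream) error usually resolves the cascade of failures reported
#' downstream of it.
#'
#' @param report A `checklist_report` from [check_model()].
#' @return One-row tibble (the earliest failing item) or `NULL` when the model
#'   does not fail.
#' @export
diagnose_first_failure <- function(report) {
  stopifnot(inherits(report, "checklist_report"))
  report$first_failure
}

#' @export
print.checklist_report <- function(x, ...) {
  cat(sprintf("<checklist_report> %s: %s (CDS %d nt, peptide %d aa)\n",
              x$isoform_name, x$overall, x$cds_length, nchar(x$peptide)))
  marks <- c(pass = "ok  ", warn = "WARN", fail = "FAIL")
  for (k in seq_len(nrow(x$items))) {
    cat(sprintf("  [%s] %-22s %s\n", marks[[x$items$status[k]]],
                x$items$key[k], x$items$message[k]))
  }
  if (!is.null(x$first_failure)) {
    cat("  first failure:", x$first_failure$key, "\n")
  }
  invisible(x)
}

#' @method tidy checklist_report
#' @export
tidy.checklist_report <- function(x, ...) x$items

#' @method glance checklist_report
#' @export
glance.checklist_report <- function(x, ...) {
  tibble::tibble(
    isoform_name = x$isoform_name, overall = x$overall,
    n_pass = sum(x$items$status == "pass"),
    n_warn = sum(x$items$status == "warn"),
    n_fail = sum(x$items$status == "fail"),
    first_failure = if (is.null(x$first_failure)) NA_character_ else x$first_failure$key,
    cds_length = x$cds_length,
    peptide_length = nchar(x$peptide)
  )
}
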