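# Reconciliation: two annotators build models for the same gene
# independently; a reconciler classifies every disagreement before deciding
# on the final model. Categories follow the curation error taxonomy:
# mislabeled/missing isoforms, incorrect splice sites, extra/missing exons,
# and wrong ortholog assignment.

DISCREPANCY_CATEGORIES <- c("congruent", "splice_site", "exon_gain_loss",
                            "isoform_missing_mislabeled", "ortholog_mismatch")

discrepancy_row <- function(gene, isoform, category, boundary_diffs = NULL,
                            details = "") {
  tibble::tibble(gene_symbol = gene, isoform_name = isoform,
                 category = category,
                 boundary_diffs = list(boundary_diffs %na% integer()),
                 details = details)
}

#' Classify the discrepancy between two models of one isoform
#'
#' Classification precedence: models on different scaffolds or with
#' non-overlapping genomic spans are an ortholog mismatch; differing exon
#' counts are an exon gain/loss; equal counts with any non-zero boundary
#' offset are a splice-site discrepancy (with per-boundary signed offsets,
#' model B minus model A); identical coordinate sets are congruent.
#'
#' @param model_a,model_b [isoform_model()] objects for the same gene and
#'   isoform label space.
#' @return One-row discrepancy tibble: `gene_symbol`, `isoform_name`,
#'   `category`, `boundary_diffs` (list column of signed nt offsets, starts
#'   and ends interleaved in transcript order), `details`.
#' @export
compare_models <- function(model_a, model_b) {
  if (model_a$assembly_id != model_b$assembly_id) {
    rlang::abort(sprintf("models come from different assemblies (%s vs %s)",
                         model_a$assembly_id, model_b$assembly_id))
  }
  gene <- model_a$gene_symbol
  iso <- model_a$isoform_name
  span_a <- model_span(model_a); span_b <- model_span(model_b)
  if (model_a$scaffold_id != model_b$scaffold_id ||
      span_a[1] > span_b[2] || span_b[1] > span_a[2]) {
    return(discrepancy_row(gene, iso, "ortholog_mismatch", details = sprintf(
      "models map to non-overlapping loci (%s:%d-%d vs %s:%d-%d)",
      model_a$scaffold_id, span_a[1], span_a[2],
      model_b$scaffold_id, span_b[1], span_b[2])))
  }
  if (nrow(model_a$exons) != nrow(model_b$exons)) {
    return(discrepancy_row(gene, iso, "exon_gain_loss", details = sprintf(
      "%d vs %d coding exons", nrow(model_a$exons), nrow(model_b$exons))))
  }
  diffs <- as.integer(rbind(model_b$exons$start - model_a$exons$start,
                            model_b$exons$end - model_a$exons$end))
  names(diffs) <- as.vector(rbind(paste0("exon", model_a$exons$ordinal, "_start"),
                                  paste0("exon", model_a$exons$ordinal, "_end")))
  if (any(diffs != 0)) {
    nz <- diffs[diffs != 0]
    return(discrepancy_row(gene, iso, "splice_site", boundary_diffs = diffs,
                           details = paste(sprintf("%s %+d", names(nz), nz),
                                           collapse = "; ")))
  }
  discrepancy_row(gene, iso, "congruent", boundary_diffs = diffs,
                  details = "identical coding-exon coordinates")
}

#' Compare two full isoform submissions
#'
#' Isoforms present in only one submission are flagged
#' `isoform_missing_mislabeled`, as are label swaps: a pair of isoforms whose
#' structures are exchanged between the submissions (A's label `x` matches
#' B's `y` and vice versa). When reference isoform records and a scaffold are
#' supplied, a label whose structure matches a *different* reference
#' isoform's signature (same exon count, peptide identity >= 95 percent) is
#' also flagged. Remaining isoforms are compared pairwise with
#' [compare_models()].
#'
#' @param submission_a,submission_b Named lists of [isoform_model()] (as from
#'   [read_model_gff()]).
#' @param reference_isoform_names Character vector of valid isoform labels.
#' @param reference_records Optional named list of `reference_record` objects
#'   keyed by isoform name.
#' @param scaffolds Optional scaffold table (needed for peptide signatures).
#' @return Discrepancy tibble with one row per isoform considered.
#' @export
compare_isoform_sets <- function(submission_a, submission_b,
                                 reference_isoform_names,
                                 reference_records = NULL, scaffolds = NULL) {
  names(submission_a) <- vapply(submission_a, `[[`, "", "isoform_name")
  names(submission_b) <- vapply(submission_b, `[[`, "", "isoform_name")
  all_names <- union(names(submission_a), names(submission_b))
  unknown <- setdiff(all_names, reference_isoform_names)
  rows <- list()
  for (nm in setdiff(all_names, intersect(names(submission_a), names(submission_b)))) {
    side <- if (nm %in% names(submission_a)) "B" else "A"
    m <- (if (side == "B") submission_a else submission_b)[[nm]]
    rows[[length(rows) + 1]] <- discrepancy_row(
      m$gene_symbol, nm, "isoform_missing_mislabeled",
      details = sprintf("isoform %s absent from submission %s%s", nm, side,
                        if (nm %in% unknown) " (label not in reference)" else ""))
  }
  common <- intersect(names(submission_a), names(submission_b))
  # label-swap detection over structural keys
  keys_a <- vapply(submission_a[common], exon_coord_key, character(1))
  keys_b <- vapply(submission_b[common], exon_coord_key, character(1))
  swapped <- character(0)
  for (x in common) {
    if (keys_a[[x]] == keys_b[[x]]) next
    y <- common[keys_b[common] == keys_a[[x]] & common != x]
    y <- y[keys_a[y] == keys_b[[x]]]
    if (length(y) >= 1) swapped <- union(swapped, c(x, y[1]))
  }
  for (nm in swapped) {
    rows[[length(rows) + 1]] <- discrepancy_row(
      submission_a[[nm]]$gene_symbol, nm, "isoform_missing_mislabeled",
      details = "isoform labels swapped between submissions (structures exchanged)")
  }
  # reference-signature mislabeling (needs peptides)
  sig_flagged <- character(0)
  if (!is.null(reference_records) && !is.null(scaffolds)) {
    for (nm in setdiff(common, swapped)) {
      if (!nm %in% names(reference_records)) next
      ma <- submission_a[[nm]]
      own <- reference_records[[nm]]
      if (nrow(ma$exons) == own$exon_count) next
      pep <- tryCatch(check_model(ma, scaffolds)$peptide, error = function(e) NULL)
      if (is.null(pep)) next
      for (other in setdiff(names(reference_records), nm)) {
        rr <- reference_records[[other]]
        if (nrow(ma$exons) != rr$exon_count) next
        pid <- compare_peptides(pep, rr$full_peptide)$percent_identity
        if (pid >= 95) {
          sig_flagged <- c(sig_flagged, nm)
          rows[[length(rows) + 1]] <- discrepancy_row(
            ma$gene_symbol, nm, "isoform_missing_mislabeled",
            details = sprintf(
              "structure matches reference isoform %s (%d exons, %.1f%% identity)",
              other, rr$exon_count, pid))
          break
        }
      }
    }
  }
  for (nm in setdiff(common, c(swapped, sig_flagged))) {
    rows[[length(rows) + 1]] <- compare_models(submission_a[[nm]], submission_b[[nm]])
  }
  dplyr::bind_rows(rows)
}

#' Summarise congruence and error shares over discrepancy reports
#'
#' Computes the percentage of models that agree with the reconciled model and,
#' over the erroneous models only, the share of each error class. Percentages
#' are rounded to integers; the raw counts are retained so the percentages
#' can always be recomputed exactly.
#'
#' @param reports Discrepancy tibble (rows from [compare_models()] /
#'   [compare_isoform_sets()]).
#' @return Object of class `congruence_summary`: list with `n_models`,
#'   `n_congruent`, `percent_congruent`, and `error_shares` (tibble:
#'   `category`, `n`, `percent` of erroneous models).
#' @export
summarize_error_rates <- function(reports) {
  if (is.null(reports) || nrow(reports) == 0) {
    rlang::abort("no discrepancy reports supplied")
  }
  bad <- setdiff(unique(reports$category), DISCREPANCY_CATEGORIES)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown discrepancy category: %s", paste(bad, collapse = ", ")))
  }
  n <- nrow(reports)
  n_con <- sum(reports$category == "congruent")
  err <- reports[reports$category != "congruent", ]
  shares <- tibble::tibble(
    category = setdiff(DISCREPANCY_CATEGORIES, "congruent")
  )
  shares$n <- vapply(shares$category, function(cc) sum(err$category == cc),
                     integer(1), USE.NAMES = FALSE)
  shares$percent <- if (nrow(err) > 0) as.integer(round(100 * shares$n / nrow(err)))
                    else 0L
  structure(
    list(n_models = n, n_congruent = n_con,
         percent_congruent = as.integer(round(100 * n_con / n)),
         error_shares = shares),
    class = "congruence_summary"
  )
}

#' @export
print.congruence_summary <- function(x, ...) {
  cat(sprintf("<congruence_summary> %d model(s): %d%% congruent (%d/%d)\n",
              x$n_models, x$percent_congruent, x$n_congruent, x$n_models))
  err <- x$error_shares[x$error_shares$n > 0, ]
  for (k in seq_len(nrow(err))) {
    cat(sprintf("  %-28s %3d%% (%d)\n", err$category[k], err$percent[k], err$n[k]))
  }
  invisible(x)
}

#' @method tidy congruence_summary
#' @export
tidy.congruence_summary <- function(x, ...) x$error_shares

#' @method glance congruence_summary
#' @export
glance.congruence_summary <- function(x, ...) {
  tibble::tibble(n_models = x$n_models, n_congruent = x$n_congruent,
                 percent_congruent = x$percent_congruent,
                 n_errors = x$n_models - x$n_congruent)
}
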