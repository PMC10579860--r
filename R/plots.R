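# ggplot2 views of the toolkit's report objects

#' Plot a checklist report
#'
#' One tile per checklist item, in transcript 5'-to-3' order, coloured by
#' status; the first failing item is where troubleshooting starts.
#'
#' @param object A `checklist_report` from [check_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot checklist_report
#' @export
autoplot.checklist_report <- function(object, ...) {
  d <- dplyr::mutate(object$items, position = dplyr::row_number(),
                     key = factor(.data$key, levels = rev(.data$key)))
  ggplot(d, aes(x = 1, y = .data$key, fill = .data$status)) +
    geom_tile(colour = "white") +
    scale_fill_manual(values = c(pass = "#2e7d32", warn = "#f9a825",
                                 fail = "#c62828")) +
    labs(title = sprintf("Gene model checklist: %s (%s)", object$isoform_name,
                         object$overall),
         x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a peptide comparison as a dot plot
#'
#' Exact word matches between model and reference peptides; a broken or
#' offset diagonal flags missing exons or misplaced splice sites.
#'
#' @param object A `peptide_comparison` from [compare_peptides()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peptide_comparison
#' @export
autoplot.peptide_comparison <- function(object, ...) {
  hits <- which(object$dotplot == 1L, arr.ind = TRUE)
  d <- tibble::tibble(model = hits[, 1], reference = hits[, 2])
  ggplot(d, aes(x = .data$reference, y = .data$model)) +
    geom_point(size = 0.4) +
    coord_equal() +
    labs(title = sprintf("Peptide dot plot (word size %d, %.1f%% identity)",
                         object$word_size, object$percent_identity),
         x = "reference peptide (aa)", y = "model peptide (aa)") +
    theme_minimal()
}

#' Plot a congruence summary
#'
#' Bars of error-class shares over the erroneous models, with the congruence
#' percentage in the title.
#'
#' @param object A `congruence_summary` from [summarize_error_rates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot congruence_summary
#' @export
autoplot.congruence_summary <- function(object, ...) {
  d <- object$error_shares
  ggplot(d, aes(x = .data$category, y = .data$percent)) +
    geom_col(fill = "#455a64") +
    labs(title = sprintf("%d%% of %d models congruent; error shares below",
                         object$percent_congruent, object$n_models),
         x = NULL, y = "% of erroneous models") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
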