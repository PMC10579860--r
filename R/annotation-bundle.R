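#' Build an annotation bundle for a set of isoform models
#'
#' A bundle is the final-submission trio: coding-exon coordinates (GFF3),
#' coding transcript sequences (FNA) and peptide sequences (FAA), all
#' describing the same isoforms in the same order.
#'
#' @param models A single [isoform_model()] or list of them.
#' @param scaffolds Scaffold table from [read_fasta()].
#' @param assembly_id Assembly identifier stored on the bundle.
#' @return Object of class `annotation_bundle`: list with `models` (named
#'   list), `transcripts` and `peptides` (named character vectors),
#'   `assembly_id`, and `aliases` (named list of collapsed duplicate names,
#'   filled by [merge_annotation_files()]).
#' @export
annotation_bundle <- function(models, scaffolds, assembly_id = NULL) {
  if (inherits(models, "isoform_model")) models <- list(models)
  names(models) <- vapply(models, `[[`, "", "isoform_name")
  assembly_id <- assembly_id %na% models[[1]]$assembly_id
  cds <- vapply(models, assemble_cds, character(1), scaffolds = scaffolds)
  pep <- vapply(cds, function(x) {
    p <- .peptide(x)
    if (substr(p, nchar(p), nchar(p)) == "*") p <- substr(p, 1, nchar(p) - 1)
    p
  }, character(1))
  structure(
    list(models = models, transcripts = cds, peptides = pep,
         assembly_id = assembly_id,
         aliases = stats::setNames(vector("list", length(models)), names(models))),
    class = "annotation_bundle"
  )
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf("<annotation_bundle> %d isoform(s) on assembly %s\n",
              length(x$models), x$assembly_id))
  for (nm in names(x$models)) {
    ali <- x$aliases[[nm]]
    cat(sprintf("  %s (%d exons)%s\n", nm, nrow(x$models[[nm]]$exons),
                if (length(ali)) paste0(" aka ", paste(ali, collapse = ",")) else ""))
  }
  invisible(x)
}

exon_coord_key <- function(model) {
  paste(model$scaffold_id, model$strand,
        paste(model$exons$start, model$exons$end, sep = "-", collapse = ","),
        sep = "|")
}

#' Merge per-isoform annotation bundles
#'
#' Combines the annotations for all unique isoforms in a project into a single
#' GFF/FNA/FAA trio. Isoforms with identical coding-exon coordinate sets are
#' collapsed to one entry; the collapsed names are retained as aliases and
#' cross-referenced in the emitted GFF. Input order is otherwise preserved.
#' Merging is idempotent.
#'
#' @param bundles A list of [annotation_bundle()] objects (a single bundle is
#'   returned collapsed the same way).
#' @return A single merged `annotation_bundle`.
#' @export
merge_annotation_files <- function(bundles) {
  if (inherits(bundles, "annotation_bundle")) bundles <- list(bundles)
  assemblies <- unique(vapply(bundles, `[[`, "", "assembly_id"))
  if (length(assemblies) > 1) {
    rlang::abort(sprintf("bundles span multiple assemblies: %s",
                         paste(assemblies, collapse = ", ")))
  }
  models <- list(); transcripts <- character(); peptides <- character()
  aliases <- list(); key_of <- character()
  for (b in bundles) {
    for (nm in names(b$models)) {
      m <- b$models[[nm]]
      key <- exon_coord_key(m)
      if (nm %in% names(models)) {
        if (key_of[[nm]] != key) {
          rlang::abort(sprintf(
            "isoform '%s' submitted with conflicting coordinates", nm))
        }
        next  # exact duplicate resubmission
      }
      holder <- if (length(key_of)) names(key_of)[match(key, key_of)]
                else NA_character_
      if (!is.na(holder)) {
        aliases[[holder]] <- unique(c(aliases[[holder]], b$aliases[[nm]], nm))
        key_of[[nm]] <- key
        next
      }
      models[[nm]] <- m
      transcripts[[nm]] <- b$transcripts[[nm]]
      peptides[[nm]] <- b$peptides[[nm]]
      aliases[[nm]] <- b$aliases[[nm]] %na% character(0)
      key_of[[nm]] <- key
    }
  }
  structure(
    list(models = models, transcripts = transcripts, peptides = peptides,
         assembly_id = assemblies, aliases = aliases),
    class = "annotation_bundle"
  )
}

#' Write an annotation bundle to disk
#'
#' @param bundle An [annotation_bundle()].
#' @param out_prefix Path prefix; writes `<prefix>.gff`, `<prefix>.fna`,
#'   `<prefix>.faa`.
#' @return Character vector of the three paths, invisibly.
#' @export
write_annotation_bundle <- function(bundle, out_prefix) {
  extra <- vapply(names(bundle$models), function(nm) {
    ali <- bundle$aliases[[nm]]
    if (length(ali)) paste0("aliases=", paste(ali, collapse = ",")) else NA_character_
  }, character(1))
  extra <- extra[!is.na(extra)]
  paths <- paste0(out_prefix, c(".gff", ".fna", ".faa"))
  write_model_gff(bundle$models, paths[1],
                  extra_attrs = if (length(extra)) extra else NULL)
  write_fasta(stats::setNames(unname(bundle$transcripts), names(bundle$models)),
              paths[2], type = "dna")
  write_fasta(stats::setNames(unname(bundle$peptides), names(bundle$models)),
              paths[3], type = "protein")
  invisible(paths)
}
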