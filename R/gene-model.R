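#' Construct an isoform gene model
#'
#' An isoform model is the unit being validated: an ordered set of coding-exon
#' intervals on one scaffold and strand, plus declared allowances for
#' documented exceptions (non-canonical start codons or splice sites, stop
#' readthrough, consensus errors corrected via a VCF edit file).
#'
#' Exons are stored in transcript order (ordinal 1 is the 5'-most coding exon):
#' ascending coordinates on `+`, descending on `-`. Coordinates themselves are
#' always 1-based inclusive forward-strand positions.
#'
#' @param gene_symbol Gene symbol (e.g. `"Rheb"`).
#' @param isoform_name Reference-style isoform name (e.g. `"Rheb-PA"`).
#' @param scaffold_id Scaffold the model lives on.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends Integer vectors of exon coordinates, forward-strand
#'   1-based inclusive; supplied in any order, stored in transcript order.
#' @param assembly_id Assembly identifier (free text).
#' @param complete Does the model span start codon through stop codon? Partial
#'   models (e.g. genes at assembly gaps) demote start/stop checks to warnings.
#' @param allowances Named list of declared exceptions. Recognised entries:
#'   `non_canonical_start` (codon, e.g. `"ACG"`), `non_canonical_donor` /
#'   `non_canonical_acceptor` (named character, junction ordinal ->
#'   dinucleotide), `stop_readthrough` (flag), `consensus_error_vcf` (path).
#' @return An object of class `isoform_model`.
#' @export
isoform_model <- function(gene_symbol, isoform_name, scaffold_id, strand,
                          starts, ends, assembly_id = "assembly",
                          complete = TRUE, allowances = list()) {
  if (!strand %in% c("+", "-")) rlang::abort("strand must be '+' or '-'")
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) == 0 || length(starts) != length(ends)) {
    rlang::abort("need equal, non-zero numbers of exon starts and ends")
  }
  if (any(ends < starts)) rlang::abort("exon end < start")
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  if (any(starts[-1] <= ends[-length(ends)])) {
    rlang::abort(sprintf("overlapping or abutting-out-of-order coding exons in %s",
                         isoform_name))
  }
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends) }
  exons <- tibble::tibble(ordinal = seq_along(starts), start = starts, end = ends)
  known <- c("non_canonical_start", "non_canonical_donor",
             "non_canonical_acceptor", "stop_readthrough", "consensus_error_vcf")
  bad <- setdiff(names(allowances), known)
  if (length(bad) > 0) rlang::abort(sprintf("unknown allowance(s): %s",
                                            paste(bad, collapse = ", ")))
  structure(
    list(gene_symbol = gene_symbol, isoform_name = isoform_name,
         assembly_id = assembly_id, scaffold_id = scaffold_id, strand = strand,
         exons = exons, complete = isTRUE(complete), allowances = allowances),
    class = "isoform_model"
  )
}

#' @export
print.isoform_model <- function(x, ...) {
  cat(sprintf("<isoform_model> %s (%s) on %s [%s], %d coding exon(s), %s\n",
              x$isoform_name, x$gene_symbol, x$scaffold_id, x$strand,
              nrow(x$exons), if (x$complete) "complete" else "partial"))
  print(x$exons)
  invisible(x)
}

#' Tidy an isoform model into an exon table
#'
#' @param x An `isoform_model`.
#' @param ... Unused.
#' @return Tibble with one row per coding exon in transcript order.
#' @method tidy isoform_model
#' @export
tidy.isoform_model <- function(x, ...) {
  dplyr::mutate(x$exons,
                gene_symbol = x$gene_symbol, isoform_name = x$isoform_name,
                scaffold_id = x$scaffold_id, strand = x$strand,
                length = .data$end - .data$start + 1, .before = 1)
}

# exon lengths in transcript order
exon_lengths <- function(model) model$exons$end - model$exons$start + 1

model_span <- function(model) {
  c(min(model$exons$start), max(model$exons$end))
}

#' Assemble the coding sequence of a model
#'
#' Concatenates exon sequences in transcript order; minus-strand exons are
#' reverse-complemented so the result reads 5' to 3' in the mRNA sense.
#'
#' @param model An [isoform_model()].
#' @param scaffolds Scaffold table from [read_fasta()].
#' @return Nucleotide string of length `sum(exon lengths)`.
#' @export
assemble_cds <- function(model, scaffolds) {
  s <- scaffold_seq(scaffolds, model$scaffold_id)
  L <- nchar(s)
  if (any(model$exons$start < 1) || any(model$exons$end > L)) {
    rlang::abort(sprintf("model %s exceeds scaffold '%s' bounds (1-%d)",
                         model$isoform_name, model$scaffold_id, L))
  }
  parts <- substring(s, model$exons$start, model$exons$end)
  if (model$strand == "-") parts <- reverse_complement(parts)
  paste(parts, collapse = "")
}

# ---- GFF3 (CDS-only dialect) ----------------------------------------------

gff_attr <- function(attrs, key) {
  hit <- regmatches(attrs, regexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attrs))
  if (length(hit) == 0 || hit == "") return(NA_character_)
  sub(paste0("^(;)?\\s*", key, "="), "", hit)
}

#' Read gene models from GFF
#'
#' Accepts the CDS-only GFF3 dialect used throughout the toolkit: 9 columns,
#' 1-based inclusive coordinates, transcript grouping via a `Parent=` or
#' `transcript_id=` attribute (both accepted on input; GFF3 with `Parent=` is
#' emitted by [write_model_gff()]). CDS features may arrive unsorted; strands
#' must be consistent within a transcript.
#'
#' @param x Path to a GFF file, or GFF text (character vector of lines or a
#'   single string with newlines).
#' @return Named list of [isoform_model()] objects, in order of first
#'   appearance.
#' @export
read_model_gff <- function(x) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) rlang::abort("no GFF feature lines found")
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9)) rlang::abort("GFF lines must have 9 tab-separated columns")
  tab <- tibble::tibble(
    scaffold_id = vapply(f, `[`, "", 1),
    type = vapply(f, `[`, "", 3),
    start = as.integer(vapply(f, `[`, "", 4)),
    end = as.integer(vapply(f, `[`, "", 5)),
    strand = vapply(f, `[`, "", 7),
    attrs = vapply(f, `[`, "", 9)
  )
  tab <- tab[tab$type == "CDS", ]
  if (nrow(tab) == 0) rlang::abort("no CDS features in GFF input")
  tx <- vapply(tab$attrs, function(a) {
    id <- gff_attr(a, "Parent") %na% gff_attr(a, "transcript_id")
    if (is.na(id)) rlang::abort("CDS feature lacks Parent= or transcript_id= attribute")
    id
  }, character(1), USE.NAMES = FALSE)
  gene <- vapply(tab$attrs, function(a) gff_attr(a, "gene") %na% NA_character_,
                 character(1), USE.NAMES = FALSE)
  models <- list()
  for (t in unique(tx)) {
    rows <- tab[tx == t, ]
    if (length(unique(rows$strand)) != 1) {
      rlang::abort(sprintf("mixed strands within transcript '%s'", t))
    }
    g <- gene[tx == t][1]
    if (is.na(g)) g <- sub("-P[A-Z]+$", "", t)
    models[[t]] <- isoform_model(
      gene_symbol = g, isoform_name = t,
      scaffold_id = rows$scaffold_id[1], strand = rows$strand[1],
      starts = rows$start, ends = rows$end
    )
  }
  models
}

#' Write gene models as GFF3
#'
#' Emits CDS features only, grouped by `Parent=` transcript id, with proper
#' CDS phase in column 8.
#'
#' @param models A single [isoform_model()] or a list of them.
#' @param path Optional output path; when `NULL` the GFF text is returned.
#' @param extra_attrs Optional named character vector of isoform name ->
#'   additional attribute text appended to each of its CDS lines.
#' @return Character vector of GFF lines (invisibly when `path` is given).
#' @export
write_model_gff <- function(models, path = NULL, extra_attrs = NULL) {
  if (inherits(models, "isoform_model")) models <- list(models)
  lines <- "##gff-version 3"
  for (m in models) {
    lens <- exon_lengths(m)
    cum_before <- c(0, cumsum(lens))[seq_along(lens)]
    phase <- (3 - cum_before %% 3) %% 3
    extra <- if (!is.null(extra_attrs) && m$isoform_name %in% names(extra_attrs)) {
      paste0(";", extra_attrs[[m$isoform_name]])
    } else ""
    rows <- sprintf(
      "%s\tgenecurate\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s;gene=%s%s",
      m$scaffold_id, m$exons$start, m$exons$end, m$strand, phase,
      m$isoform_name, m$exons$ordinal, m$isoform_name, m$gene_symbol, extra
    )
    # file order is ascending coordinate regardless of strand
    lines <- c(lines, rows[order(m$exons$start)])
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# ---- Reference isoform records (Gene Record Finder analogue) ---------------

#' Build a reference isoform record
#'
#' Summarises one isoform of the reference annotation the way curators use it:
#' the number of coding exons, the amino-acid sequence contributed by each
#' coding exon, the full peptide, and the canonical class of each intron. A
#' codon split across a splice junction contributes its amino acid to the exon
#' holding at least two of its nucleotides (equivalently, the exon holding the
#' codon's middle nucleotide; splits are 1+2 or 2+1 so no tie arises).
#'
#' @param reference_gff GFF path or text for the reference annotation (CDS
#'   dialect of [read_model_gff()]).
#' @param reference_genome Scaffold table from [read_fasta()].
#' @param isoform_name Which isoform to summarise.
#' @return Object of class `reference_record`: list with `isoform_name`,
#'   `exon_count`, `exon_peptides`, `full_peptide`, `junction_classes`.
#' @export
build_reference_record <- function(reference_gff, reference_genome, isoform_name) {
  models <- read_model_gff(reference_gff)
  if (!isoform_name %in% names(models)) {
    rlang::abort(sprintf("isoform '%s' not in reference annotation (available: %s)",
                         isoform_name, paste(names(models), collapse = ", ")))
  }
  model <- models[[isoform_name]]
  reference_record(model, reference_genome)
}

#' @rdname build_reference_record
#' @param model An [isoform_model()] (used directly instead of looking one up
#'   in a GFF).
#' @param scaffolds Scaffold table holding the model's scaffold.
#' @export
reference_record <- function(model, scaffolds) {
  cds <- assemble_cds(model, scaffolds)
  lens <- exon_lengths(model)
  tr <- translate_cds(cds)
  pep <- tr$peptide
  # strip the terminal stop from the reported peptide
  has_stop <- nchar(cds) %% 3 == 0 && substr(pep, nchar(pep), nchar(pep)) == "*"
  if (has_stop) pep <- substr(pep, 1, nchar(pep) - 1)
  n_codon <- nchar(pep)
  # exon of each codon = exon holding its middle nucleotide
  cum <- cumsum(lens)
  mid_nt <- 3 * seq_len(n_codon) - 1
  codon_exon <- findInterval(mid_nt - 1, cum) + 1
  segs <- vapply(seq_along(lens), function(e) {
    paste(strsplit(pep, "")[[1]][codon_exon == e], collapse = "")
  }, character(1))
  jc <- if (nrow(model$exons) > 1) {
    j <- compute_junctions(model, scaffolds)
    j$canonical_class
  } else character(0)
  structure(
    list(isoform_name = model$isoform_name, exon_count = nrow(model$exons),
         exon_peptides = segs, full_peptide = pep, junction_classes = jc),
    class = "reference_record"
  )
}

#' @export
print.reference_record <- function(x, ...) {
  cat(sprintf("<reference_record> %s: %d coding exon(s), peptide %d aa\n",
              x$isoform_name, x$exon_count, nchar(x$full_peptide)))
  for (k in seq_along(x$exon_peptides)) {
    cat(sprintf("  exon %d: %d aa\n", k, nchar(x$exon_peptides[k])))
  }
  invisible(x)
}
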