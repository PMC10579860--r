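# Consensus-error correction: assemblies can carry base substitutions and
# small indels that break otherwise-sound gene models; curators record the
# corrections as VCF edits, apply them to the scaffold, and re-validate.

#' Parse a consensus-error edit file (VCF)
#'
#' Reads the minimal VCF dialect used as an edit container: only CHROM, POS,
#' ID, REF and ALT are honored (QUAL/FILTER/INFO are ignored); multi-allelic
#' ALT values are rejected. Every edit is validated against the scaffold
#' (REF must match) and edits must not overlap. Indels follow VCF anchoring:
#' the first base is shared between REF and ALT.
#'
#' @param vcf_path Path to a VCF file.
#' @param scaffold Scaffold table from [read_fasta()] (or a bare sequence
#'   string); a single scaffold per application.
#' @param scaffold_id Which scaffold the edits apply to; defaults to the only
#'   scaffold present, and must match the CHROM column.
#' @return Tibble of class `sequence_edits`, sorted by position: `position`,
#'   `ref_allele`, `alt_allele`, `kind`
#'   (`substitution`/`insertion`/`deletion`), `delta` (length change).
#' @export
parse_edits <- function(vcf_path, scaffold, scaffold_id = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, , drop = FALSE], stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(structure(tibble::tibble(position = integer(), ref_allele = character(),
                                    alt_allele = character(), kind = character(),
                                    delta = integer()),
                     class = c("sequence_edits", "tbl_df", "tbl", "data.frame")))
  }
  if (is.null(scaffold_id)) {
    scaffold_id <- if (is.data.frame(scaffold)) scaffold$id[1] else unique(fix$CHROM)[1]
  }
  if (!all(fix$CHROM == scaffold_id)) {
    rlang::abort(sprintf("edit file names scaffold(s) %s; expected '%s'",
                         paste(unique(fix$CHROM), collapse = ", "), scaffold_id))
  }
  s <- if (is.data.frame(scaffold)) scaffold_seq(scaffold, scaffold_id) else toupper(scaffold)
  edits <- tibble::tibble(
    position = as.integer(fix$POS),
    ref_allele = toupper(fix$REF),
    alt_allele = toupper(fix$ALT)
  )
  if (any(grepl(",", edits$alt_allele))) {
    rlang::abort("multi-allelic ALT records are not supported in edit files")
  }
  edits <- dplyr::arrange(edits, .data$position)
  # REF validation against the scaffold
  for (k in seq_len(nrow(edits))) {
    obs <- subs(s, edits$position[k], edits$position[k] + nchar(edits$ref_allele[k]) - 1)
    if (obs != edits$ref_allele[k]) {
      rlang::abort(sprintf(
        "REF mismatch at position %d: VCF states '%s' but scaffold holds '%s'",
        edits$position[k], edits$ref_allele[k], obs))
    }
  }
  # classification from allele lengths (VCF-anchored indels)
  rl <- nchar(edits$ref_allele); al <- nchar(edits$alt_allele)
  kind <- dplyr::case_when(
    rl == al ~ "substitution",
    rl == 1 & al > 1 ~ "insertion",
    al == 1 & rl > 1 ~ "deletion",
    TRUE ~ "complex"
  )
  if (any(kind == "complex")) {
    rlang::abort("complex (non-anchored) variants are not supported as edits")
  }
  edits$kind <- kind
  edits$delta <- al - rl
  # non-overlap: each edit's REF span must end before the next begins
  span_end <- edits$position + rl - 1
  if (nrow(edits) > 1 && any(edits$position[-1] <= span_end[-nrow(edits)])) {
    rlang::abort("overlapping edits are not allowed")
  }
  class(edits) <- c("sequence_edits", class(edits))
  edits
}

#' Write edits as a minimal VCF
#'
#' @param edits A `sequence_edits` tibble (or compatible data frame with
#'   `position`, `ref_allele`, `alt_allele`).
#' @param scaffold_id CHROM value for every record.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edits_vcf <- function(edits, scaffold_id, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=genecurate",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", scaffold_id, edits$position,
                  edits$ref_allele, edits$alt_allele)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Apply consensus edits to a scaffold
#'
#' Applies validated edits and returns the corrected sequence together with a
#' coordinate map lifting original positions to corrected positions. The
#' corrected length equals the original length plus the summed allele-length
#' differences.
#'
#' @param scaffold Scaffold table (single scaffold used) or bare sequence
#'   string.
#' @param edits `sequence_edits` from [parse_edits()].
#' @param scaffold_id Scaffold to correct (defaults to the first).
#' @return List with `scaffold` (one-row corrected scaffold tibble, same id)
#'   and `map` (a `coordinate_map`).
#' @export
apply_edits <- function(scaffold, edits, scaffold_id = NULL) {
  if (is.data.frame(scaffold)) {
    if (is.null(scaffold_id)) scaffold_id <- scaffold$id[1]
    s <- scaffold_seq(scaffold, scaffold_id)
  } else {
    s <- toupper(scaffold); scaffold_id <- scaffold_id %na% "scaffold"
  }
  L <- nchar(s)
  pieces <- character(); cursor <- 1L
  for (k in seq_len(nrow(edits))) {
    p <- edits$position[k]
    pieces <- c(pieces, subs(s, cursor, p - 1), edits$alt_allele[k])
    cursor <- p + nchar(edits$ref_allele[k])
  }
  pieces <- c(pieces, subs(s, cursor, L))
  corrected <- paste(pieces, collapse = "")
  map <- structure(
    list(edits = tibble::as_tibble(edits), original_length = L,
         corrected_length = nchar(corrected)),
    class = "coordinate_map"
  )
  stopifnot(nchar(corrected) == L + sum(edits$delta))
  list(scaffold = tibble::tibble(id = scaffold_id, seq = corrected,
                                 length = nchar(corrected)),
       map = map)
}

#' Lift original coordinates to corrected coordinates
#'
#' Positions inside a deleted span have no image and yield `NA` (or an error
#' with `strict = TRUE`). The map is strictly monotone elsewhere and
#' invertible outside inserted spans (see [invert_coordinate_map()]).
#'
#' @param map A `coordinate_map` from [apply_edits()].
#' @param positions Integer vector of original 1-based positions.
#' @param strict Error on unmappable positions instead of returning `NA`.
#' @return Integer vector of corrected positions.
#' @export
lift_position <- function(map, positions, strict = FALSE) {
  e <- map$edits
  vapply(as.integer(positions), function(x) {
    if (x < 1 || x > map$original_length) {
      rlang::abort(sprintf("position %d outside scaffold (1-%d)", x,
                           map$original_length))
    }
    shift <- 0L
    for (k in seq_len(nrow(e))) {
      p <- e$position[k]; rl <- nchar(e$ref_allele[k])
      if (e$kind[k] == "deletion" && x > p && x <= p + rl - 1) {
        if (strict) rlang::abort(sprintf("position %d lies inside a deleted span", x))
        return(NA_integer_)
      }
      if (x > p + rl - 1 || (e$kind[k] == "insertion" && x > p)) {
        shift <- shift + e$delta[k]
      }
    }
    x + shift
  }, integer(1))
}

#' Invert a coordinate map
#'
#' Produces the map from corrected back to original coordinates (insertions
#' and deletions swap roles).
#'
#' @param map A `coordinate_map`.
#' @return A `coordinate_map` in the opposite direction.
#' @export
invert_coordinate_map <- function(map) {
  e <- map$edits
  if (nrow(e) > 0) {
    new_pos <- integer(nrow(e)); shift <- 0L
    for (k in seq_len(nrow(e))) {
      new_pos[k] <- e$position[k] + shift
      shift <- shift + e$delta[k]
    }
    e <- tibble::tibble(position = new_pos, ref_allele = e$alt_allele,
                        alt_allele = e$ref_allele,
                        kind = dplyr::recode(e$kind, insertion = "deletion",
                                             deletion = "insertion"),
                        delta = -e$delta)
  }
  structure(list(edits = e, original_length = map$corrected_length,
                 corrected_length = map$original_length),
            class = "coordinate_map")
}

#' @export
print.coordinate_map <- function(x, ...) {
  cat(sprintf("<coordinate_map> %d edit(s), %d -> %d nt\n", nrow(x$edits),
              x$original_length, x$corrected_length))
  invisible(x)
}

#' Lift a gene model across a coordinate map
#'
#' Re-anchors every exon boundary of a model onto the corrected sequence. Exon
#' count and strand are preserved; a boundary falling inside a deleted span is
#' an error naming the exon.
#'
#' @param model An [isoform_model()].
#' @param map A `coordinate_map` from [apply_edits()].
#' @return The lifted [isoform_model()].
#' @export
lift_model <- function(model, map) {
  lift1 <- function(x, exon, what) {
    y <- lift_position(map, x)
    if (is.na(y)) {
      rlang::abort(sprintf("%s of exon %d lies inside a deleted span", what, exon))
    }
    y
  }
  starts <- vapply(seq_len(nrow(model$exons)), function(k)
    lift1(model$exons$start[k], model$exons$ordinal[k], "start"), integer(1))
  ends <- vapply(seq_len(nrow(model$exons)), function(k)
    lift1(model$exons$end[k], model$exons$ordinal[k], "end"), integer(1))
  isoform_model(model$gene_symbol, model$isoform_name, model$scaffold_id,
                model$strand, starts = starts, ends = ends,
                assembly_id = model$assembly_id, complete = model$complete,
                allowances = model$allowances)
}
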