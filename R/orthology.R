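# Ortholog assignment support: this module never runs a similarity search; it
# consumes standard 12-column tabular hit records and curator-built gene
# neighborhood maps.

BLAST_TAB_COLS <- c("query_id", "subject_id", "percent_identity",
                    "alignment_length", "mismatches", "gap_opens",
                    "query_start", "query_end", "subject_start", "subject_end",
                    "e_value", "bit_score")

#' Read a 12-column tabular hit table
#'
#' Standard tab-separated similarity-search output: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore.
#'
#' @param path Path to the tab-separated file (no header).
#' @return Tibble with columns `query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `mismatches`, `gap_opens`, `query_start`,
#'   `query_end`, `subject_start`, `subject_end`, `e_value`, `bit_score`.
#' @export
read_hit_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, col.names = BLAST_TAB_COLS,
                           stringsAsFactors = FALSE)
  tibble::as_tibble(tab)
}

best_hit_per_query <- function(hits) {
  hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(.data$e_value, dplyr::desc(.data$bit_score),
                   dplyr::desc(.data$percent_identity), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Pair orthologs by reciprocal best hits
#'
#' The best hit for each query is the record with the lowest E-value, ties
#' broken by highest bit score, then highest percent identity. A pair `(a, b)`
#' is emitted when `a`'s best hit is `b` and `b`'s best hit is `a`; every
#' other query is flagged unpaired with the reason.
#'
#' @param forward_hits Hit table A -> B (see [read_hit_table()]).
#' @param reverse_hits Hit table B -> A.
#' @return List with `pairs` (tibble: `query_id`, `subject_id`, forward and
#'   reverse `e_value`/`bit_score`) and `unpaired` (tibble: `id`, `side`,
#'   `reason`).
#' @export
reciprocal_best_hits <- function(forward_hits, reverse_hits) {
  empty_pairs <- tibble::tibble(query_id = character(), subject_id = character(),
                                forward_e_value = numeric(), reverse_e_value = numeric(),
                                forward_bit_score = numeric(), reverse_bit_score = numeric())
  unpaired <- tibble::tibble(id = character(), side = character(), reason = character())
  if (nrow(forward_hits) == 0 || nrow(reverse_hits) == 0) {
    side_miss <- function(hits, side) {
      if (nrow(hits) == 0) return(NULL)
      tibble::tibble(id = unique(hits$query_id), side = side,
                     reason = "no hits in the other direction")
    }
    return(list(pairs = empty_pairs,
                unpaired = dplyr::bind_rows(side_miss(forward_hits, "forward"),
                                            side_miss(reverse_hits, "reverse"),
                                            unpaired)))
  }
  bf <- best_hit_per_query(forward_hits)
  br <- best_hit_per_query(reverse_hits)
  rev_best <- stats::setNames(br$subject_id, br$query_id)
  mutual <- !is.na(rev_best[bf$subject_id]) & rev_best[bf$subject_id] == bf$query_id
  mutual[is.na(mutual)] <- FALSE
  paired_f <- bf$query_id[mutual]
  paired_r <- bf$subject_id[mutual]
  br_idx <- match(paired_r, br$query_id)
  pairs <- tibble::tibble(
    query_id = paired_f, subject_id = paired_r,
    forward_e_value = bf$e_value[mutual], reverse_e_value = br$e_value[br_idx],
    forward_bit_score = bf$bit_score[mutual], reverse_bit_score = br$bit_score[br_idx]
  )
  un <- list()
  for (q in setdiff(unique(forward_hits$query_id), paired_f)) {
    b <- bf$subject_id[bf$query_id == q]
    back <- rev_best[b]
    un[[length(un) + 1]] <- tibble::tibble(
      id = q, side = "forward",
      reason = if (is.na(back)) sprintf("best hit %s has no reverse hits", b)
               else sprintf("best hit %s maps back to %s, not %s", b, back, q))
  }
  for (q in setdiff(unique(reverse_hits$query_id), paired_r)) {
    b <- br$subject_id[br$query_id == q]
    fwd_best <- stats::setNames(bf$subject_id, bf$query_id)[b]
    un[[length(un) + 1]] <- tibble::tibble(
      id = q, side = "reverse",
      reason = if (is.na(fwd_best)) sprintf("best hit %s has no forward hits", b)
               else sprintf("best hit %s maps back to %s, not %s", b, fwd_best, q))
  }
  list(pairs = pairs, unpaired = dplyr::bind_rows(un, unpaired))
}

#' Describe the local gene neighborhood of a locus
#'
#' The protocol assesses local synteny from the nearest two upstream and two
#' downstream genes (with orientations relative to the focal gene) plus any
#' nesting relationships.
#'
#' @param focal_gene Focal gene symbol.
#' @param upstream,downstream Data frames (or tibbles) with columns `gene` and
#'   `orientation` (`"+"`/`"-"`, relative to the focal gene), nearest first,
#'   at most `depth` rows each.
#' @param nested_in Host gene symbol if the focal gene is nested within
#'   another gene's span, else `NULL`.
#' @param nested_genes Symbols of genes nested within the focal gene's span.
#' @param depth Neighborhood depth per side (protocol default 2).
#' @return Object of class `neighborhood_map`.
#' @export
neighborhood_map <- function(focal_gene, upstream = NULL, downstream = NULL,
                             nested_in = NULL, nested_genes = character(),
                             depth = 2L) {
  norm <- function(x) {
    if (is.null(x) || length(x) == 0 || (is.data.frame(x) && nrow(x) == 0)) {
      return(tibble::tibble(gene = character(), orientation = character()))
    }
    x <- tibble::as_tibble(x)
    if (nrow(x) > depth) {
      rlang::abort(sprintf("neighborhood depth is %d genes per side", depth))
    }
    x[, c("gene", "orientation")]
  }
  structure(
    list(focal_gene = focal_gene, upstream = norm(upstream),
         downstream = norm(downstream), nested_in = nested_in,
         nested_genes = as.character(nested_genes), depth = as.integer(depth)),
    class = "neighborhood_map"
  )
}

#' Read or write neighborhood maps as JSON
#'
#' @param path JSON file path.
#' @return [neighborhood_map()] (for read); `path` invisibly (for write).
#' @export
read_neighborhood_map <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  neighborhood_map(j$focal_gene, upstream = j$upstream, downstream = j$downstream,
                   nested_in = j$nested_in, nested_genes = j$nested_genes %na% character(),
                   depth = j$depth %na% 2L)
}

#' @rdname read_neighborhood_map
#' @param map A [neighborhood_map()].
#' @export
write_neighborhood_map <- function(map, path) {
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Assess conservation of local synteny
#'
#' Compares reference and target neighborhood maps position-wise (nearest
#' neighbor to nearest neighbor on each side), counting matching gene symbols,
#' matching orientations among them, and nesting consistency. The verdict is
#' `conserved` when all four neighbors match with orientations and nesting is
#' consistent, `partial` with at least two matched neighbors, otherwise
#' `not_conserved`; two empty maps are `not_assessable`.
#'
#' @param reference_map,target_map [neighborhood_map()] objects for the
#'   putatively orthologous loci.
#' @return One-row tibble of class `synteny_verdict`: `status`,
#'   `matched_neighbors`, `orientation_matches`, `nesting_consistent`.
#' @export
assess_local_synteny <- function(reference_map, target_map) {
  n_side <- function(m) nrow(m$upstream) + nrow(m$downstream)
  if (n_side(reference_map) == 0 || n_side(target_map) == 0) {
    return(structure(tibble::tibble(status = "not_assessable",
                                    matched_neighbors = 0L,
                                    orientation_matches = 0L,
                                    nesting_consistent = NA),
                     class = c("synteny_verdict", "tbl_df", "tbl", "data.frame")))
  }
  match_side <- function(a, b) {
    n <- max(nrow(a), nrow(b))
    sym <- 0L; ori <- 0L
    for (k in seq_len(n)) {
      if (k > nrow(a) || k > nrow(b)) next
      if (a$gene[k] == b$gene[k]) {
        sym <- sym + 1L
        if (a$orientation[k] == b$orientation[k]) ori <- ori + 1L
      }
    }
    c(sym, ori)
  }
  up <- match_side(reference_map$upstream, target_map$upstream)
  dn <- match_side(reference_map$downstream, target_map$downstream)
  matched <- up[1] + dn[1]; ori <- up[2] + dn[2]
  nest_ok <- identical(reference_map$nested_in %na% NA_character_,
                       target_map$nested_in %na% NA_character_) &&
    setequal(reference_map$nested_genes, target_map$nested_genes)
  status <- if (matched == 4 && ori == 4 && nest_ok) "conserved"
            else if (matched >= 2) "partial"
            else "not_conserved"
  structure(tibble::tibble(status = status, matched_neighbors = matched,
                           orientation_matches = ori,
                           nesting_consistent = nest_ok),
            class = c("synteny_verdict", "tbl_df", "tbl", "data.frame"))
}

#' Resolve a disagreement between best hit and synteny
#'
#' When the best similarity hit and the synteny-implied location disagree
#' (loci on different scaffolds, or non-overlapping spans), the toolkit does
#' not overrule either line of evidence: it reports `conflict` with both loci
#' for curator review. Agreement yields `accept_hit`; a missing hit with
#' synteny support yields `prefer_synteny`.
#'
#' @param best_hit_locus,synteny_locus Optional one-row interval tables
#'   ([genomic_interval()]); either may be `NULL` but not both.
#' @return List: `decision` (`accept_hit`/`prefer_synteny`/`conflict`),
#'   `best_hit_locus`, `synteny_locus`.
#' @export
resolve_ambiguous_locus <- function(best_hit_locus = NULL, synteny_locus = NULL) {
  if (is.null(best_hit_locus) && is.null(synteny_locus)) {
    rlang::abort("neither a best hit locus nor a synteny-implied locus was supplied")
  }
  decision <- if (is.null(synteny_locus)) {
    "accept_hit"
  } else if (is.null(best_hit_locus)) {
    "prefer_synteny"
  } else {
    same_scaffold <- best_hit_locus$scaffold_id == synteny_locus$scaffold_id
    overlap <- same_scaffold &&
      best_hit_locus$start <= synteny_locus$end &&
      synteny_locus$start <= best_hit_locus$end
    if (overlap) "accept_hit" else "conflict"
  }
  list(decision = decision, best_hit_locus = best_hit_locus,
       synteny_locus = synteny_locus)
}
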