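# Deterministic synthetic loci: every module in the toolkit is testable
# without downloading an assembly. A locus is built transcript-first (CDS as
# codons, introns with forced boundary dinucleotides) and then laid onto a
# forward-strand scaffold, so the truth (coordinates, peptide, phases) is
# known exactly.

# run code under a seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample_nt <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# one random non-stop codon (rejection sampling with a retry cap)
sample_codon <- function(gc, max_tries = 1000) {
  for (i in seq_len(max_tries)) {
    codon <- paste(sample_nt(3, gc), collapse = "")
    if (!codon %in% STOP_CODONS) return(codon)
  }
  rlang::abort("could not sample a stop-free codon (GC content too extreme?)")
}

#' Specify a synthetic gene locus
#'
#' @param seed Integer seed; the whole artifact set is a deterministic
#'   function of the spec including this seed.
#' @param exon_lengths Coding-exon lengths (nt) in transcript order; their sum
#'   must be a multiple of 3 (and at least 6) when `valid = TRUE`.
#' @param intron_lengths Intron lengths (nt), one fewer than exons, each at
#'   least 4 so both boundary dinucleotides fit.
#' @param strand `"+"` or `"-"`.
#' @param donor_classes Per-intron donor class: `"GT"`, `"GC"` or `"other"`
#'   (emitted as a GG donor).
#' @param start_codon First codon of the CDS (default ATG).
#' @param gc_content Fraction of G+C used when sampling nucleotides.
#' @param flank Padding (nt) on each side of the gene.
#' @param gene_symbol,isoform_name,scaffold_id Naming.
#' @param neighbors Optional [neighborhood_map()]; a generic conserved
#'   neighborhood is generated when `NULL`.
#' @param nested_host Optional host gene symbol recorded in the neighborhood.
#' @return A list of class `synthetic_locus_spec`.
#' @export
synthetic_locus_spec <- function(seed, exon_lengths, intron_lengths,
                                 strand = "+", donor_classes = NULL,
                                 start_codon = "ATG", gc_content = 0.45,
                                 flank = 30L, gene_symbol = "genA",
                                 isoform_name = "genA-PA",
                                 scaffold_id = "scaffold_1",
                                 neighbors = NULL, nested_host = NULL) {
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  if (any(exon_lengths < 1)) rlang::abort("exon lengths must be positive")
  if (length(intron_lengths) != length(exon_lengths) - 1) {
    rlang::abort("need one intron length per adjacent exon pair")
  }
  if (any(intron_lengths < 4)) {
    rlang::abort("introns must be at least 4 nt to hold both splice dinucleotides")
  }
  if (sum(exon_lengths) %% 3 != 0 || sum(exon_lengths) < 6) {
    rlang::abort("total coding length must be a multiple of 3 and at least 6 nt")
  }
  donor_classes <- donor_classes %na% rep("GT", length(intron_lengths))
  if (!all(donor_classes %in% c("GT", "GC", "other"))) {
    rlang::abort("donor_classes must be 'GT', 'GC' or 'other'")
  }
  structure(
    list(seed = as.integer(seed), exon_lengths = exon_lengths,
         intron_lengths = intron_lengths, strand = strand,
         donor_classes = donor_classes, start_codon = toupper(start_codon),
         gc_content = gc_content, flank = as.integer(flank),
         gene_symbol = gene_symbol, isoform_name = isoform_name,
         scaffold_id = scaffold_id, neighbors = neighbors,
         nested_host = nested_host),
    class = "synthetic_locus_spec"
  )
}

#' Draw a random valid locus spec
#'
#' Convenience generator for property-style testing: random exon count (2-6),
#' exon lengths 20-200 nt summing to a codon multiple, introns 8-60 nt.
#'
#' @param seed Integer seed.
#' @param strand Optional strand; randomly chosen when `NULL`.
#' @return A [synthetic_locus_spec()].
#' @export
random_locus_spec <- function(seed, strand = NULL) {
  with_local_seed(seed, {
    n <- sample(2:6, 1)
    lens <- sample(20:200, n, replace = TRUE)
    lens[n] <- lens[n] + (3 - sum(lens) %% 3) %% 3
    introns <- sample(8:60, n - 1, replace = TRUE)
    strand <- strand %na% sample(c("+", "-"), 1)
    synthetic_locus_spec(seed = seed, exon_lengths = lens,
                         intron_lengths = introns, strand = strand)
  })
}

#' Generate a synthetic locus
#'
#' Builds, deterministically for a given spec: a scaffold sequence, the true
#' isoform model on it, a local neighborhood map, the reference isoform
#' record, and the true peptide. The generated CDS starts with the requested
#' start codon, ends with a stop, and contains no internal in-frame stop
#' codons; introns carry the requested donor class and an AG acceptor.
#'
#' @param spec A [synthetic_locus_spec()].
#' @return List of class `synthetic_locus`: `scaffold` (one-row tibble),
#'   `model` ([isoform_model()]), `neighborhood` ([neighborhood_map()]),
#'   `reference_record`, `cds`, `peptide` (terminal stop stripped), `spec`.
#' @export
generate_locus <- function(spec) {
  with_local_seed(spec$seed, {
    total <- sum(spec$exon_lengths)
    n_codon <- total %/% 3
    codons <- c(spec$start_codon,
                vapply(seq_len(n_codon - 2), function(i) sample_codon(spec$gc_content),
                       character(1)),
                sample(STOP_CODONS, 1))
    cds <- paste(codons, collapse = "")
    # split CDS into exon pieces
    bounds <- cumsum(spec$exon_lengths)
    exon_seqs <- substring(cds, c(1, bounds[-length(bounds)] + 1), bounds)
    intron_seqs <- vapply(seq_along(spec$intron_lengths), function(k) {
      len <- spec$intron_lengths[k]
      donor <- switch(spec$donor_classes[k], GT = "GT", GC = "GC", other = "GG")
      inner <- if (len > 4) paste(sample_nt(len - 4, spec$gc_content), collapse = "") else ""
      paste0(donor, inner, "AG")
    }, character(1))
    pad5 <- paste(sample_nt(spec$flank, spec$gc_content), collapse = "")
    pad3 <- paste(sample_nt(spec$flank, spec$gc_content), collapse = "")
    gene_body <- exon_seqs[1]
    for (k in seq_along(intron_seqs)) {
      gene_body <- paste0(gene_body, intron_seqs[k], exon_seqs[k + 1])
    }
    oriented <- paste0(pad5, gene_body, pad3)
    L <- nchar(oriented)
    # transcript-oriented exon coordinates
    o_starts <- integer(length(spec$exon_lengths)); pos <- spec$flank + 1L
    for (k in seq_along(spec$exon_lengths)) {
      o_starts[k] <- pos
      pos <- pos + spec$exon_lengths[k] +
        if (k < length(spec$exon_lengths)) spec$intron_lengths[k] else 0L
    }
    o_ends <- o_starts + spec$exon_lengths - 1L
    if (spec$strand == "+") {
      fwd <- oriented; starts <- o_starts; ends <- o_ends
    } else {
      fwd <- reverse_complement(oriented)
      starts <- L - o_ends + 1L; ends <- L - o_starts + 1L
    }
    scaffold <- tibble::tibble(id = spec$scaffold_id, seq = fwd, length = L)
    model <- isoform_model(spec$gene_symbol, spec$isoform_name,
                           spec$scaffold_id, spec$strand,
                           starts = starts, ends = ends)
    nb <- spec$neighbors %na% neighborhood_map(
      spec$gene_symbol,
      upstream = tibble::tibble(gene = paste0(spec$gene_symbol, c("_up1", "_up2")),
                                orientation = c("+", "-")),
      downstream = tibble::tibble(gene = paste0(spec$gene_symbol, c("_dn1", "_dn2")),
                                  orientation = c("+", "+")),
      nested_in = spec$nested_host
    )
    ref <- reference_record(model, scaffold)
    pep <- substr(.peptide(cds), 1, n_codon - 1)
    structure(
      list(scaffold = scaffold, model = model, neighborhood = nb,
           reference_record = ref, cds = cds, peptide = pep, spec = spec),
      class = "synthetic_locus"
    )
  })
}

#' Specify a controlled corruption
#'
#' One corruption kind per application, mirroring the curation error
#' taxonomy and assembly consensus errors:
#' `splice_shift` (move one exon boundary by `amount` nt at `junction`),
#' `drop_exon` / `add_exon` (remove or invent a coding exon),
#' `swap_isoform_labels` (exchange two isoform labels),
#' `relocate_locus` (move the model to a non-overlapping locus),
#' `consensus_indel` (insert/delete nucleotides in the scaffold itself and
#' emit the repair edits).
#'
#' @param kind One of the kinds above.
#' @param seed Integer seed for any random choice.
#' @param junction Junction ordinal for `splice_shift`.
#' @param amount Signed nt for `splice_shift`; signed indel length for
#'   `consensus_indel` (negative deletes from the scaffold).
#' @param ordinal Exon ordinal for `drop_exon`.
#' @param position Scaffold position for `consensus_indel` (random within an
#'   internal exon when `NULL`).
#' @return A list of class `corruption_spec`.
#' @export
corruption_spec <- function(kind = c("splice_shift", "drop_exon", "add_exon",
                                     "swap_isoform_labels", "relocate_locus",
                                     "consensus_indel"),
                            seed = 1L, junction = 1L, amount = 1L,
                            ordinal = 2L, position = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed),
                 junction = as.integer(junction), amount = as.integer(amount),
                 ordinal = as.integer(ordinal), position = position),
            class = "corruption_spec")
}

#' Apply a controlled corruption to a model (or its scaffold)
#'
#' Returns the perturbed artifacts plus a truth record naming the injected
#' error class, so classifier behaviour can be scored. For
#' `consensus_indel` the scaffold is perturbed, the model is left unchanged,
#' and the truth record carries the repair edits (a `sequence_edits` tibble
#' valid against the corrupted scaffold; applying them restores the original
#' sequence exactly).
#'
#' @param model An [isoform_model()] (for `swap_isoform_labels`, a list of at
#'   least two models).
#' @param scaffold Scaffold tibble the model lives on.
#' @param corruption A [corruption_spec()].
#' @return List: `model` (or `models`), `scaffold`, `truth` (list with
#'   `kind`, `expected_category`, and kind-specific details such as
#'   `repair_edits`).
#' @export
corrupt_model <- function(model, scaffold, corruption) {
  cp <- corruption
  with_local_seed(cp$seed, {
    switch(
      cp$kind,
      splice_shift = {
        ex <- model$exons
        if (nrow(ex) < 2) rlang::abort("splice_shift needs a multi-exon model")
        j <- cp$junction
        if (j < 1 || j > nrow(ex) - 1) rlang::abort("junction out of range")
        # move the donor-side boundary of exon j in transcript orientation
        if (model$strand == "+") ex$end[j] <- ex$end[j] + cp$amount
        else ex$start[j] <- ex$start[j] - cp$amount
        m2 <- isoform_model(model$gene_symbol, model$isoform_name,
                            model$scaffold_id, model$strand,
                            starts = ex$start, ends = ex$end,
                            assembly_id = model$assembly_id,
                            complete = model$complete)
        list(model = m2, scaffold = scaffold,
             truth = list(kind = "splice_shift", expected_category = "splice_site",
                          junction = j, amount = cp$amount))
      },
      drop_exon = {
        ex <- model$exons
        if (nrow(ex) < 2) rlang::abort("cannot drop an exon from a single-exon model")
        o <- cp$ordinal
        if (o < 1 || o > nrow(ex)) rlang::abort("exon ordinal out of range")
        ex <- ex[-o, ]
        m2 <- isoform_model(model$gene_symbol, model$isoform_name,
                            model$scaffold_id, model$strand,
                            starts = ex$start, ends = ex$end,
                            assembly_id = model$assembly_id,
                            complete = model$complete)
        list(model = m2, scaffold = scaffold,
             truth = list(kind = "drop_exon",
                          expected_category = "exon_gain_loss", ordinal = o))
      },
      add_exon = {
        ex <- model$exons
        if (nrow(ex) < 2) rlang::abort("add_exon needs an intron to place the exon in")
        fwd <- ex[order(ex$start), ]
        gaps <- tibble::tibble(lo = fwd$end[-nrow(fwd)] + 1,
                               hi = fwd$start[-1] - 1)
        gaps <- gaps[gaps$hi - gaps$lo + 1 >= 14, ]
        if (nrow(gaps) == 0) rlang::abort("no intron long enough to host an extra exon")
        g <- gaps[sample(nrow(gaps), 1), ]
        s <- g$lo + 3L
        e <- s + sample(6:min(15, g$hi - 3L - s), 1)
        m2 <- isoform_model(model$gene_symbol, model$isoform_name,
                            model$scaffold_id, model$strand,
                            starts = c(ex$start, s), ends = c(ex$end, e),
                            assembly_id = model$assembly_id,
                            complete = model$complete)
        list(model = m2, scaffold = scaffold,
             truth = list(kind = "add_exon",
                          expected_category = "exon_gain_loss",
                          interval = c(s, e)))
      },
      swap_isoform_labels = {
        if (inherits(model, "isoform_model") || !is.list(model) ||
            length(model) < 2 ||
            !all(vapply(model, inherits, logical(1), "isoform_model"))) {
          rlang::abort("swap_isoform_labels needs a list of at least two models")
        }
        idx <- sample(length(model), 2)
        a <- model[[idx[1]]]; b <- model[[idx[2]]]
        nm_a <- a$isoform_name; nm_b <- b$isoform_name
        a$isoform_name <- nm_b; b$isoform_name <- nm_a
        model[[idx[1]]] <- a; model[[idx[2]]] <- b
        names(model) <- vapply(model, `[[`, "", "isoform_name")
        list(models = model, scaffold = scaffold,
             truth = list(kind = "swap_isoform_labels",
                          expected_category = "isoform_missing_mislabeled",
                          swapped = c(nm_a, nm_b)))
      },
      relocate_locus = {
        span <- model_span(model)
        offset <- span[2] - span[1] + 1L + 50L
        m2 <- isoform_model(model$gene_symbol, model$isoform_name,
                            model$scaffold_id, model$strand,
                            starts = model$exons$start + offset,
                            ends = model$exons$end + offset,
                            assembly_id = model$assembly_id,
                            complete = model$complete)
        list(model = m2, scaffold = scaffold,
             truth = list(kind = "relocate_locus",
                          expected_category = "ortholog_mismatch",
                          offset = offset))
      },
      consensus_indel = {
        s <- scaffold$seq[1]
        ex <- model$exons[order(model$exons$start), ]
        if (is.null(cp$position)) {
          # default: inside an internal exon, away from its boundaries
          k <- if (nrow(ex) >= 3) sample(2:(nrow(ex) - 1), 1) else 1L
          lo <- ex$start[k] + 3L; hi <- ex$end[k] - 3L - max(0, -cp$amount)
          if (hi < lo) rlang::abort("exon too short for the requested indel")
          p <- sample(lo:hi, 1)
        } else p <- as.integer(cp$position)
        if (p < 2) rlang::abort("indel position must be at least 2 (VCF anchoring)")
        if (cp$amount < 0) {
          k_del <- -cp$amount
          corrupted <- paste0(subs(s, 1, p - 1), subs(s, p + k_del, nchar(s)))
          repair <- tibble::tibble(position = p - 1L,
                                   ref_allele = subs(corrupted, p - 1, p - 1),
                                   alt_allele = subs(s, p - 1, p + k_del - 1),
                                   kind = "insertion", delta = k_del)
        } else if (cp$amount > 0) {
          ins <- paste(sample_nt(cp$amount, 0.45), collapse = "")
          corrupted <- paste0(subs(s, 1, p - 1), ins, subs(s, p, nchar(s)))
          repair <- tibble::tibble(position = p - 1L,
                                   ref_allele = paste0(subs(s, p - 1, p - 1), ins),
                                   alt_allele = subs(s, p - 1, p - 1),
                                   kind = "deletion", delta = -cp$amount)
        } else rlang::abort("consensus_indel amount must be non-zero")
        class(repair) <- c("sequence_edits", class(repair))
        list(model = model,
             scaffold = tibble::tibble(id = scaffold$id[1], seq = corrupted,
                                       length = nchar(corrupted)),
             truth = list(kind = "consensus_indel",
                          expected_category = "assembly_error",
                          position = p, amount = cp$amount,
                          repair_edits = repair))
      }
    )
  })
}
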