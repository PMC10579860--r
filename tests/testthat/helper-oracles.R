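# Independent oracles used to cross-check the package implementation.
# These are deliberately written as plain brute force / textbook dynamic
# programming, independent of the code paths they validate.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# evaluate an expression under a fixed seed (test-local convenience)
with_local_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# draw one element uniformly from a vector (safe for length-1 vectors)
resample1 <- function(x) x[sample.int(length(x), 1)]

with_seed_dna <- function(seed, n) {
  set.seed(seed)
  random_dna(n)
}

random_peptide <- function(n) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

# textbook Gotoh global alignment with affine gaps (open + ext charged for the
# first gap residue), BLOSUM62
gotoh_score <- function(a, b, open = 10, ext = 1) {
  M <- get_blosum62()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  S <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  S[1, 1] <- 0
  for (i in seq_len(n) + 1) { X[i, 1] <- -open - (i - 1) * ext; S[i, 1] <- X[i, 1] }
  for (j in seq_len(m) + 1) { Y[1, j] <- -open - (j - 1) * ext; S[1, j] <- Y[1, j] }
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      X[i, j] <- max(S[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(S[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      S[i, j] <- max(S[i - 1, j - 1] + M[A[i - 1], B[j - 1]], X[i, j], Y[i, j])
    }
  }
  S[n + 1, m + 1]
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# brute-force small-exon enumerator: tests every (start, end) pair of the
# window against the constraint definition, written straight from the
# biological definition (no shared code with the finder)
brute_force_exons <- function(S, cds_type, acceptor_phase, donor_phase,
                              min_length, max_length, allow_gc_donor = FALSE) {
  L <- nchar(S)
  a <- if (cds_type == "initial") 0L else acceptor_phase
  d <- if (cds_type == "terminal") 0L else donor_phase
  donors <- if (allow_gc_donor) c("GT", "GC") else "GT"
  hits <- list()
  for (s in seq_len(L)) {
    for (e in s:L) {
      len <- e - s + 1
      if (len < min_length) next
      if (len > max_length) break
      # 5' requirement
      if (cds_type == "initial") {
        if (substr(S, s, s + 2) != "ATG") next
      } else {
        if (s < 3 || substr(S, s - 2, s - 1) != "AG") next
      }
      # 3' requirement
      if (cds_type == "terminal") {
        if (len < 3 || !substr(S, e - 2, e) %in% ORACLE_STOPS) next
      } else {
        if (e + 2 > L || !substr(S, e + 1, e + 2) %in% donors) next
      }
      # length congruence: leading a nt + complete codons + trailing d nt
      if (len < a + d || (len - a - d) %% 3 != 0) next
      # stop-freedom of the complete codons
      body <- substr(S, s + a, e - d)
      ok <- TRUE
      n_codons <- nchar(body) %/% 3
      if (n_codons > 0) {
        for (ci in seq_len(n_codons)) {
          codon <- substr(body, 3 * ci - 2, 3 * ci)
          if (codon %in% ORACLE_STOPS) {
            # the terminal exon's final codon must be the stop itself
            if (!(cds_type == "terminal" && ci == n_codons)) { ok <- FALSE; break }
          } else if (cds_type == "terminal" && ci == n_codons) {
            ok <- FALSE; break
          }
        }
        if (cds_type == "terminal" && n_codons == 0) ok <- FALSE
      } else if (cds_type == "terminal") ok <- FALSE
      if (ok) hits[[length(hits) + 1]] <- c(start = s, end = e)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  as.data.frame(do.call(rbind, hits))
}

# brute-force reciprocal-best-hit pairing: explicit comparator, full scan
rbh_oracle <- function(fwd, rev) {
  better <- function(h1, h2) {
    if (h1$e_value != h2$e_value) return(h1$e_value < h2$e_value)
    if (h1$bit_score != h2$bit_score) return(h1$bit_score > h2$bit_score)
    h1$percent_identity > h2$percent_identity
  }
  best_of <- function(tab, q) {
    rows <- tab[tab$query_id == q, ]
    b <- rows[1, ]
    for (k in seq_len(nrow(rows))[-1]) if (better(rows[k, ], b)) b <- rows[k, ]
    b$subject_id
  }
  pairs <- character(0)
  for (q in unique(fwd$query_id)) {
    b <- best_of(fwd, q)
    if (b %in% rev$query_id && best_of(rev, b) == q) {
      pairs <- c(pairs, paste(q, b, sep = "->"))
    }
  }
  sort(pairs)
}

random_hit_table <- function(queries, subjects, n_hits) {
  data.frame(
    query_id = sample(queries, n_hits, replace = TRUE),
    subject_id = sample(subjects, n_hits, replace = TRUE),
    percent_identity = round(stats::runif(n_hits, 30, 100), 1),
    alignment_length = sample(50:500, n_hits, replace = TRUE),
    mismatches = sample(0:50, n_hits, replace = TRUE),
    gap_opens = sample(0:5, n_hits, replace = TRUE),
    query_start = 1L, query_end = 100L, subject_start = 1L, subject_end = 100L,
    e_value = signif(10^stats::runif(n_hits, -80, -2), 3),
    bit_score = round(stats::runif(n_hits, 40, 400), 1)
  )
}

# deterministic multi-exon locus whose exon 1 ends in G, so a -1 donor-side
# shift produces a GG donor and a frameshift cascade downstream
cascade_locus <- function() {
  for (seed in 1:500) {
    spec <- synthetic_locus_spec(
      seed = seed,
      exon_lengths = c(90, 120, 96, 120, 87, 120, 60),
      intron_lengths = c(20, 25, 30, 25, 20, 25)
    )
    loc <- generate_locus(spec)
    s <- loc$scaffold$seq
    e1_end <- loc$model$exons$end[1]
    if (substr(s, e1_end, e1_end) != "G") next
    shifted <- corrupt_model(loc$model, loc$scaffold,
                             corruption_spec("splice_shift", seed = 1,
                                             junction = 1, amount = -1))$model
    rep <- check_model(shifted, loc$scaffold, loc$reference_record)
    fails <- rep$items[rep$items$status == "fail", ]
    n_stop_exons <- length(unique(stats::na.omit(fails$exon)))
    if (rep$overall == "fail" &&
        rep$first_failure$key == "donor_site:1" &&
        n_stop_exons >= 2 &&
        "length_divisible_by_3" %in% fails$key) {
      return(list(locus = loc, shifted = shifted, seed = seed))
    }
  }
  stop("no cascade fixture found")
}
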