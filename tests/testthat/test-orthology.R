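# Ortholog assignment: reciprocal best hits, neighborhood maps, local
# synteny, and conflict resolution

hit_row <- function(q, s, evalue, bits = 100, pident = 80) {
  tibble::tibble(query_id = q, subject_id = s, percent_identity = pident,
                 alignment_length = 100L, mismatches = 10L, gap_opens = 0L,
                 query_start = 1L, query_end = 100L, subject_start = 1L,
                 subject_end = 100L, e_value = evalue, bit_score = bits)
}

test_that("a mutual best pair is emitted and a one-sided best is not", {
  fwd <- dplyr::bind_rows(hit_row("a1", "b1", 1e-50),
                          hit_row("a1", "b2", 1e-10),
                          hit_row("a2", "b1", 1e-20))
  rev <- dplyr::bind_rows(hit_row("b1", "a1", 1e-48),
                          hit_row("b2", "a2", 1e-9))
  res <- reciprocal_best_hits(fwd, rev)
  expect_equal(res$pairs$query_id, "a1")
  expect_equal(res$pairs$subject_id, "b1")
  expect_equal(res$pairs$forward_e_value, 1e-50)
  un <- res$unpaired
  expect_true("a2" %in% un$id[un$side == "forward"])
  expect_true("b2" %in% un$id[un$side == "reverse"])
  expect_match(un$reason[un$id == "a2"], "maps back to a1")
})

test_that("best-hit ties break by bit score then percent identity", {
  fwd <- dplyr::bind_rows(hit_row("a", "b1", 1e-30, bits = 200, pident = 70),
                          hit_row("a", "b2", 1e-30, bits = 250, pident = 60))
  rev <- hit_row("b2", "a", 1e-30)
  res <- reciprocal_best_hits(fwd, rev)
  expect_equal(res$pairs$subject_id, "b2")
  fwd2 <- dplyr::bind_rows(hit_row("a", "b1", 1e-30, bits = 200, pident = 70),
                           hit_row("a", "b2", 1e-30, bits = 200, pident = 90))
  rev2 <- hit_row("b2", "a", 1e-30)
  expect_equal(reciprocal_best_hits(fwd2, rev2)$pairs$subject_id, "b2")
})

test_that("empty hit tables give no pairs and sensible unpaired reasons", {
  empty <- hit_row("x", "y", 1)[0, ]
  res <- reciprocal_best_hits(empty, empty)
  expect_equal(nrow(res$pairs), 0L)
  res2 <- reciprocal_best_hits(hit_row("a", "b", 1e-5), empty)
  expect_equal(nrow(res2$pairs), 0L)
  expect_equal(res2$unpaired$id, "a")
})

test_that("RBH matches a brute-force oracle on random hit tables", {
  set.seed(71)
  for (i in 1:10) {
    fwd <- random_hit_table(paste0("a", 1:20), paste0("b", 1:20), 120)
    rev <- random_hit_table(paste0("b", 1:20), paste0("a", 1:20), 120)
    res <- reciprocal_best_hits(tibble::as_tibble(fwd), tibble::as_tibble(rev))
    mine <- sort(paste(res$pairs$query_id, res$pairs$subject_id, sep = "->"))
    expect_equal(mine, rbh_oracle(fwd, rev))
    # symmetry: swapping directions mirrors every pair
    res_sw <- reciprocal_best_hits(tibble::as_tibble(rev), tibble::as_tibble(fwd))
    mirrored <- sort(paste(res_sw$pairs$subject_id, res_sw$pairs$query_id,
                           sep = "->"))
    expect_equal(mirrored, mine)
  }
})

test_that("hit tables round-trip through the 12-column reader", {
  tab <- random_hit_table(paste0("a", 1:5), paste0("b", 1:5), 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  back <- read_hit_table(path)
  expect_equal(as.data.frame(back), tab)
})

test_that("a fully matching neighborhood is called conserved", {
  ref <- neighborhood_map(
    "Ilp2",
    upstream = data.frame(gene = c("Zasp67", "Ilp1"),
                          orientation = c("+", "+")),
    downstream = data.frame(gene = c("Ilp3", "Ilp4"),
                            orientation = c("+", "+")),
    nested_in = "CG32052")
  tgt <- neighborhood_map(
    "Ilp2_target",
    upstream = data.frame(gene = c("Zasp67", "Ilp1"),
                          orientation = c("+", "+")),
    downstream = data.frame(gene = c("Ilp3", "Ilp4"),
                            orientation = c("+", "+")),
    nested_in = "CG32052")
  v <- assess_local_synteny(ref, tgt)
  expect_equal(v$status, "conserved")
  expect_equal(v$matched_neighbors, 4L)
  expect_equal(v$orientation_matches, 4L)
  expect_true(v$nesting_consistent)
})

test_that("orientation flips and missing neighbors downgrade the verdict", {
  ref <- neighborhood_map("g",
                          upstream = data.frame(gene = c("u1", "u2"),
                                                orientation = c("+", "-")),
                          downstream = data.frame(gene = c("d1", "d2"),
                                                  orientation = c("+", "+")))
  flipped <- neighborhood_map("g",
                              upstream = data.frame(gene = c("u1", "u2"),
                                                    orientation = c("-", "-")),
                              downstream = data.frame(gene = c("d1", "d2"),
                                                      orientation = c("+", "+")))
  v <- assess_local_synteny(ref, flipped)
  expect_equal(v$status, "partial")
  expect_equal(v$matched_neighbors, 4L)
  expect_equal(v$orientation_matches, 3L)
  shuffled <- neighborhood_map("g",
                               upstream = data.frame(gene = c("x1", "x2"),
                                                     orientation = c("+", "-")),
                               downstream = data.frame(gene = c("y1", "d2"),
                                                       orientation = c("+", "+")))
  expect_equal(assess_local_synteny(ref, shuffled)$status, "not_conserved")
  empty <- neighborhood_map("g")
  expect_equal(assess_local_synteny(ref, empty)$status, "not_assessable")
})

test_that("nesting differences block a conserved verdict", {
  ref <- neighborhood_map("g",
                          upstream = data.frame(gene = "u1", orientation = "+"),
                          downstream = data.frame(gene = "d1", orientation = "+"),
                          nested_in = "host")
  tgt <- neighborhood_map("g",
                          upstream = data.frame(gene = "u1", orientation = "+"),
                          downstream = data.frame(gene = "d1", orientation = "+"),
                          nested_in = NULL)
  v <- assess_local_synteny(ref, tgt)
  expect_false(isTRUE(v$nesting_consistent))
  expect_false(v$status == "conserved")
})

test_that("neighborhood maps round-trip through JSON", {
  m <- neighborhood_map("g",
                        upstream = data.frame(gene = c("u1", "u2"),
                                              orientation = c("+", "-")),
                        downstream = data.frame(gene = "d1", orientation = "+"),
                        nested_in = "host", nested_genes = c("n1", "n2"))
  path <- withr::local_tempfile(fileext = ".json")
  write_neighborhood_map(m, path)
  back <- read_neighborhood_map(path)
  expect_equal(back$focal_gene, m$focal_gene)
  expect_equal(as.data.frame(back$upstream), as.data.frame(m$upstream))
  expect_equal(as.data.frame(back$downstream), as.data.frame(m$downstream))
  expect_equal(back$nested_in, m$nested_in)
  expect_equal(back$nested_genes, m$nested_genes)
})

test_that("a one-sided neighborhood survives the JSON round trip", {
  m <- neighborhood_map("g",
                        upstream = data.frame(gene = "u", orientation = "+"))
  path <- withr::local_tempfile(fileext = ".json")
  write_neighborhood_map(m, path)
  back <- read_neighborhood_map(path)
  expect_equal(nrow(back$downstream), 0L)
  expect_equal(back$upstream$gene, "u")
  v <- assess_local_synteny(back, back)
  expect_equal(v$matched_neighbors, 1L)
})

test_that("neighborhood depth is capped at two genes per side", {
  expect_error(
    neighborhood_map("g", upstream = data.frame(gene = c("a", "b", "c"),
                                                orientation = c("+", "+", "+"))),
    "depth")
})

test_that("hit/synteny disagreement is a conflict, never an override", {
  hit <- genomic_interval("scf_A", 1000, 2000)
  syn_same <- genomic_interval("scf_A", 1500, 2400)
  syn_other <- genomic_interval("scf_B", 1500, 2400)
  expect_equal(resolve_ambiguous_locus(hit, syn_same)$decision, "accept_hit")
  expect_equal(resolve_ambiguous_locus(hit, syn_other)$decision, "conflict")
  expect_equal(resolve_ambiguous_locus(hit, NULL)$decision, "accept_hit")
  expect_equal(resolve_ambiguous_locus(NULL, syn_other)$decision,
               "prefer_synteny")
  # non-overlapping spans on the same scaffold also conflict
  expect_equal(resolve_ambiguous_locus(hit,
                                       genomic_interval("scf_A", 5000, 6000))$decision,
               "conflict")
  expect_error(resolve_ambiguous_locus(NULL, NULL), "neither")
})
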