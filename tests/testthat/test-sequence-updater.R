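# Consensus-error correction: VCF parsing, sequence editing, coordinate
# liftover and model re-anchoring

make_vcf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", lines), path)
  path
}

test_that("parse_edits classifies substitutions, insertions and deletions", {
  sc <- tibble::tibble(id = "s", seq = "AACCGGTTAACCGGTT", length = 16L)
  vcf <- make_vcf(c("s\t3\t.\tC\tT\t.\t.\t.",
                    "s\t6\t.\tG\tGAAA\t.\t.\t.",
                    "s\t10\t.\tACC\tA\t.\t.\t."))
  ed <- parse_edits(vcf, sc)
  expect_s3_class(ed, "sequence_edits")
  expect_equal(ed$kind, c("substitution", "insertion", "deletion"))
  expect_equal(ed$delta, c(0L, 3L, -2L))
})

test_that("parse_edits validates REF, scaffold names and edit structure", {
  sc <- tibble::tibble(id = "s", seq = "AACCGGTTAACCGGTT", length = 16L)
  expect_error(parse_edits(make_vcf("s\t3\t.\tG\tT\t.\t.\t."), sc),
               "REF mismatch")
  expect_error(parse_edits(make_vcf("other\t3\t.\tC\tT\t.\t.\t."), sc),
               "expected 's'")
  expect_error(parse_edits(make_vcf("s\t3\t.\tC\tT,G\t.\t.\t."), sc),
               "multi-allelic")
  expect_error(parse_edits(make_vcf("s\t3\t.\tCC\tTT\tG\t.\t."), sc),
               NA)  # 2nt substitution is fine ...
  expect_error(parse_edits(make_vcf("s\t3\t.\tCCG\tTT\t.\t.\t."), sc),
               "complex")
  expect_error(parse_edits(make_vcf(c("s\t3\t.\tCCG\tC\t.\t.\t.",
                                      "s\t4\t.\tC\tT\t.\t.\t.")), sc),
               "overlapping")
})

test_that("a deletion shifts downstream coordinates and unmaps its span", {
  sc <- tibble::tibble(id = "s", seq = strrep("ACGT", 8), length = 32L)
  # delete the 2 nt after position 10 (REF spans 10-12)
  ref <- substr(sc$seq, 10, 12)
  ed <- parse_edits(make_vcf(sprintf("s\t10\t.\t%s\t%s\t.\t.\t.",
                                     ref, substr(ref, 1, 1))), sc)
  res <- apply_edits(sc, ed)
  expect_equal(nchar(res$scaffold$seq), 30L)
  expect_equal(lift_position(res$map, c(5, 10)), c(5L, 10L))
  expect_equal(lift_position(res$map, c(11, 12)), c(NA_integer_, NA_integer_))
  expect_error(lift_position(res$map, 11, strict = TRUE), "deleted span")
  expect_equal(lift_position(res$map, c(13, 20)), c(11L, 18L))
  expect_error(lift_position(res$map, 40), "outside scaffold")
})

test_that("an insertion shifts downstream coordinates forward", {
  sc <- tibble::tibble(id = "s", seq = strrep("ACGT", 8), length = 32L)
  base <- substr(sc$seq, 10, 10)
  ed <- parse_edits(make_vcf(sprintf("s\t10\t.\t%s\t%sGGG\t.\t.\t.",
                                     base, base)), sc)
  res <- apply_edits(sc, ed)
  expect_equal(nchar(res$scaffold$seq), 35L)
  expect_equal(lift_position(res$map, c(10, 11)), c(10L, 14L))
})

test_that("edits round-trip through the minimal VCF writer", {
  sc <- tibble::tibble(id = "s", seq = strrep("ACGT", 10), length = 40L)
  vcf1 <- make_vcf(c("s\t5\t.\tA\tT\t.\t.\t.", "s\t12\t.\tT\tTCC\t.\t.\t."))
  ed <- parse_edits(vcf1, sc)
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  write_edits_vcf(ed, "s", vcf2)
  expect_equal(parse_edits(vcf2, sc), ed)
})

test_that("lift and inverse lift are mutually inverse off the edited spans", {
  set.seed(61)
  for (i in 1:15) {
    sc <- tibble::tibble(id = "s", seq = random_dna(400), length = 400L)
    # three non-overlapping random edits
    pos <- sort(sample(seq(10, 380, by = 40), 3))
    lines <- vapply(pos, function(p) {
      kind <- sample(c("sub", "ins", "del"), 1)
      if (kind == "sub") {
        sprintf("s\t%d\t.\t%s\t%s\t.\t.\t.", p, substr(sc$seq, p, p),
                setdiff(c("A", "C", "G", "T"), substr(sc$seq, p, p))[1])
      } else if (kind == "ins") {
        sprintf("s\t%d\t.\t%s\t%s%s\t.\t.\t.", p, substr(sc$seq, p, p),
                substr(sc$seq, p, p), random_dna(sample(1:4, 1)))
      } else {
        sprintf("s\t%d\t.\t%s\t%s\t.\t.\t.", p,
                substr(sc$seq, p, p + sample(1:4, 1)), substr(sc$seq, p, p))
      }
    }, character(1))
    ed <- parse_edits(make_vcf(lines), sc)
    res <- apply_edits(sc, ed)
    inv <- invert_coordinate_map(res$map)
    x <- seq_len(400)
    y <- lift_position(res$map, x)
    ok <- !is.na(y)
    expect_equal(lift_position(inv, y[ok]), x[ok])
    # applying the inverted edits to the corrected sequence restores the input
    back <- apply_edits(res$scaffold, inv$edits)
    expect_equal(back$scaffold$seq, sc$seq)
  }
})

test_that("consensus corruptions are repaired exactly over many seeds", {
  n_done <- 0
  for (seed in 1:60) {
    loc <- generate_locus(random_locus_spec(seed))
    if (nrow(loc$model$exons) < 3) next
    amount <- if (seed %% 2 == 0) 2L else -2L
    cor <- tryCatch(
      corrupt_model(loc$model, loc$scaffold,
                    corruption_spec("consensus_indel", seed = seed,
                                    amount = amount)),
      error = function(e) NULL)
    if (is.null(cor)) next
    res <- apply_edits(cor$scaffold, cor$truth$repair_edits)
    expect_equal(res$scaffold$seq, loc$scaffold$seq)
    n_done <- n_done + 1
  }
  expect_gte(n_done, 20)
})

test_that("a broken model is restored by correcting the scaffold and lifting", {
  loc <- generate_locus(random_locus_spec(62))
  cor <- corrupt_model(loc$model, loc$scaffold,
                       corruption_spec("consensus_indel", seed = 3,
                                       amount = -1))
  res <- apply_edits(cor$scaffold, cor$truth$repair_edits)
  expect_equal(res$scaffold$seq, loc$scaffold$seq)
  # the model as seen on the corrupted assembly
  m_corrupt <- lift_model(loc$model, invert_coordinate_map(res$map))
  rep_bad <- check_model(m_corrupt, cor$scaffold, loc$reference_record)
  expect_equal(rep_bad$overall, "fail")
  # correcting the scaffold and lifting the model back fixes everything
  m_fixed <- lift_model(m_corrupt, res$map)
  rep_ok <- check_model(m_fixed, res$scaffold, loc$reference_record)
  expect_true(rep_ok$overall %in% c("pass", "pass_with_warnings"))
  expect_equal(rep_ok$overall, "pass")
  expect_equal(m_fixed$exons, loc$model$exons)
})

test_that("lift_model refuses boundaries inside deleted spans", {
  sc <- tibble::tibble(id = "s", seq = strrep("ACGT", 20), length = 80L)
  ref <- substr(sc$seq, 19, 23)
  ed <- parse_edits(make_vcf(sprintf("s\t19\t.\t%s\t%s\t.\t.\t.",
                                     ref, substr(ref, 1, 1))), sc)
  res <- apply_edits(sc, ed)
  m <- isoform_model("g", "g-PA", "s", "+", starts = c(5, 40),
                     ends = c(20, 60))
  expect_error(lift_model(m, res$map), "exon 1")
  m2 <- isoform_model("g", "g-PA", "s", "+", starts = c(5, 40),
                      ends = c(15, 60))
  lifted <- lift_model(m2, res$map)
  expect_equal(lifted$exons$start, c(5L, 36L))
  expect_equal(lifted$exons$end, c(15L, 56L))
})
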