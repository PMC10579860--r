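# Checklist validation: splice phases, junction classes, the full checklist,
# and cascade behaviour of a single upstream boundary error

test_that("junction phases follow exon lengths", {
  ph <- junction_phases(c(6L, 9L))
  expect_equal(ph$donor_phase, 0L)
  expect_equal(ph$acceptor_phase, 0L)
  expect_equal(ph$phase_sum, 0L)
  # a 49 nt first exon leaves 1 nt of a split codon: donor 1, acceptor 2
  ph2 <- junction_phases(c(49L, 72L))
  expect_equal(ph2$donor_phase, 1L)
  expect_equal(ph2$acceptor_phase, 2L)
  expect_equal(ph2$phase_sum, 3L)
  expect_equal(nrow(junction_phases(c(30L))), 0L)
})

test_that("phase sums are always 0 or 3 and donor/acceptor are complementary", {
  for (seed in 1:25) {
    lens <- with_local_seed_test(seed, sample(20:200, sample(2:6, 1), replace = TRUE))
    ph <- junction_phases(as.integer(lens))
    expect_true(all(ph$phase_sum %in% c(0L, 3L)))
    expect_equal(ph$donor_phase, cumsum(lens)[-length(lens)] %% 3)
    expect_equal(ph$acceptor_phase, (3L - ph$donor_phase) %% 3L)
  }
})

test_that("compute_junctions reads donor/acceptor dinucleotides on both strands", {
  for (strand in c("+", "-")) {
    spec <- synthetic_locus_spec(seed = 21, exon_lengths = c(30, 33, 30),
                                 intron_lengths = c(10, 12), strand = strand,
                                 donor_classes = c("GT", "GC"))
    loc <- generate_locus(spec)
    j <- compute_junctions(loc$model, loc$scaffold)
    expect_equal(j$donor_dinucleotide, c("GT", "GC"))
    expect_equal(j$acceptor_dinucleotide, c("AG", "AG"))
    expect_equal(j$canonical_class, c("canonical_GT_AG", "rare_GC_AG"))
  }
})

test_that("a clean single-exon model passes every item", {
  sc <- tibble::tibble(id = "s", seq = "CCATGAAATAACC", length = 13L)
  m <- isoform_model("g", "g-PA", "s", "+", starts = 3, ends = 11)
  rep <- check_model(m, sc)
  expect_s3_class(rep, "checklist_report")
  expect_equal(rep$peptide, "MK")
  expect_equal(rep$cds_length, 9L)
  # no reference record -> exon_count_match warns, everything else passes
  expect_equal(rep$overall, "pass_with_warnings")
  items <- rep$items
  expect_equal(items$status[items$key != "exon_count_match"],
               rep("pass", sum(items$key != "exon_count_match")))
  expect_null(diagnose_first_failure(rep))
})

test_that("checklist items appear in 5'-to-3' order with globals last", {
  loc <- generate_locus(random_locus_spec(31))
  rep <- check_model(loc$model, loc$scaffold, loc$reference_record)
  n <- nrow(loc$model$exons)
  expected <- c("start_codon",
                unlist(lapply(seq_len(n - 1), function(e)
                  paste0(c("internal_stops:", "donor_site:", "acceptor_site:",
                           "phase_compat:"), e))),
                paste0("internal_stops:", n),
                "stop_codon", "length_divisible_by_3", "exon_count_match")
  expect_equal(rep$items$key, expected)
})

test_that("generated loci always pass the checklist against their own record", {
  for (seed in 1:60) {
    loc <- generate_locus(random_locus_spec(seed))
    rep <- check_model(loc$model, loc$scaffold, loc$reference_record)
    expect_equal(rep$overall, "pass")
    expect_equal(rep$peptide, loc$peptide)
    expect_equal(rep$cds_length, sum(loc$spec$exon_lengths))
  }
})

test_that("a 1 nt donor-side shift produces a diagnostic cascade", {
  fix <- cascade_locus()
  rep <- check_model(fix$shifted, fix$locus$scaffold,
                     fix$locus$reference_record)
  expect_equal(rep$overall, "fail")
  # first failing item is the shifted donor site itself
  expect_equal(diagnose_first_failure(rep)$key, "donor_site:1")
  fails <- rep$items[rep$items$status == "fail", ]
  # downstream frame shift: in-frame stops in at least two later exons and a
  # coding length no longer divisible by three
  expect_gte(length(unique(stats::na.omit(fails$exon))), 2L)
  expect_true("length_divisible_by_3" %in% fails$key)
  # restoring the boundary restores a clean pass
  restored <- corrupt_model(fix$shifted, fix$locus$scaffold,
                            corruption_spec("splice_shift", junction = 1,
                                            amount = 1))$model
  expect_equal(check_model(restored, fix$locus$scaffold,
                           fix$locus$reference_record)$overall, "pass")
})

test_that("a shifted junction never produces failures upstream of it", {
  n_ok_first <- 0; n_frame_evidence <- 0; n_total <- 0
  for (seed in 1:200) {
    loc <- generate_locus(random_locus_spec(seed))
    n_ex <- nrow(loc$model$exons)
    if (n_ex < 2) next
    j <- with_local_seed_test(seed, sample(n_ex - 1, 1))
    amount <- with_local_seed_test(seed + 7, sample(c(-2, -1, 1, 2), 1))
    shifted <- corrupt_model(loc$model, loc$scaffold,
                             corruption_spec("splice_shift", junction = j,
                                             amount = amount))$model
    rep <- check_model(shifted, loc$scaffold, loc$reference_record)
    n_total <- n_total + 1
    expect_equal(rep$overall, "fail")
    fails <- rep$items[rep$items$status == "fail", ]
    # everything 5' of the injected junction is untouched, so no checklist
    # item strictly upstream of it may fail (the cascade runs downstream)
    upstream_ok <- all(is.na(fails$junction) | fails$junction >= j) &&
      all(is.na(fails$exon) | fails$exon >= j) &&
      !"start_codon" %in% fails$key
    if (upstream_ok) n_ok_first <- n_ok_first + 1
    if (any(grepl("^(internal_stops|phase_compat|donor_site|acceptor_site)", fails$key)) ||
        "length_divisible_by_3" %in% fails$key || "stop_codon" %in% fails$key) {
      n_frame_evidence <- n_frame_evidence + 1
    }
  }
  expect_gte(n_total, 150)
  expect_equal(n_ok_first, n_total)
  expect_equal(n_frame_evidence, n_total)
})

test_that("allowances demote the matching failures to warnings", {
  spec <- synthetic_locus_spec(seed = 22, exon_lengths = c(30, 33),
                               intron_lengths = 10, donor_classes = "other")
  loc <- generate_locus(spec)
  rep <- check_model(loc$model, loc$scaffold, loc$reference_record)
  expect_equal(rep$overall, "fail")
  expect_equal(diagnose_first_failure(rep)$key, "donor_site:1")
  m2 <- loc$model
  m2$allowances <- list(non_canonical_donor = c("1" = "GG"))
  rep2 <- check_model(m2, loc$scaffold, loc$reference_record)
  expect_equal(rep2$overall, "pass_with_warnings")
  st <- rep2$items$status[rep2$items$key == "donor_site:1"]
  expect_equal(st, "warn")
})

test_that("partial models demote start/stop items instead of failing", {
  # model truncated before its stop codon (e.g. scaffold gap)
  loc <- generate_locus(synthetic_locus_spec(seed = 23,
                                             exon_lengths = c(30, 33),
                                             intron_lengths = 10))
  m <- loc$model
  m$exons$end[2] <- m$exons$end[2] - 5L   # drop the stop codon and frame
  m_partial <- isoform_model(m$gene_symbol, m$isoform_name, m$scaffold_id,
                             m$strand, starts = m$exons$start,
                             ends = m$exons$end, complete = FALSE)
  rep <- check_model(m_partial, loc$scaffold)
  expect_false(rep$overall == "fail" &&
                 any(rep$items$key %in% c("stop_codon", "length_divisible_by_3") &
                     rep$items$status == "fail"))
  expect_equal(rep$items$status[rep$items$key == "stop_codon"], "warn")
  expect_equal(rep$items$status[rep$items$key == "length_divisible_by_3"], "warn")
})

test_that("exon count is checked against the reference record", {
  loc <- generate_locus(random_locus_spec(24))
  dropped <- corrupt_model(loc$model, loc$scaffold,
                           corruption_spec("drop_exon", ordinal = 2))$model
  rep <- check_model(dropped, loc$scaffold, loc$reference_record)
  expect_equal(rep$items$status[rep$items$key == "exon_count_match"], "fail")
})

test_that("tidy and glance expose the report as tibbles", {
  loc <- generate_locus(random_locus_spec(25))
  rep <- check_model(loc$model, loc$scaffold, loc$reference_record)
  expect_identical(tidy(rep), rep$items)
  g <- glance(rep)
  expect_equal(g$overall, "pass")
  expect_equal(g$n_fail, 0L)
  expect_equal(g$peptide_length, nchar(loc$peptide))
})
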