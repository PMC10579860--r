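# genecurate

A curation toolkit for manual annotation of protein-coding genes on draft
genome assemblies.

Automated gene predictors and similarity searches get a draft assembly most
of the way to an annotation, but the last mile — exact splice sites, small
exons, assembly consensus errors, ortholog identity, disagreements between
annotators — is still resolved by people. `genecurate` gives those curators
programmatic, testable versions of the checks they perform by hand. It is
aimed at annotation teams and comparative-genomics groups who curate gene
models across related species.

## The core checks

An isoform model is an ordered set of coding-exon intervals on one scaffold
and strand. `check_model()` validates it against the constraints a curated
model must satisfy:

* the CDS starts with `ATG` and ends with a stop codon (`TAA`/`TAG`/`TGA`);
* each intron is `GT…AG` (the rare `GC` donor warns; anything else fails
  unless a documented allowance is declared);
* each junction preserves frame: with donor phase
  `d = (Σ exon lengths so far) mod 3` and acceptor phase `a`, the sum
  `d + a` must be 0 or 3;
* no in-frame stop codon inside any coding exon;
* total coding length (including the stop codon) is divisible by 3;
* the exon count matches the reference isoform record.

Items are reported 5'→3', so the *first* failing item is where
troubleshooting starts: one wrong boundary typically explains the whole
cascade of downstream frame failures.

Around the checker sit the rest of the curation workflow:
`refine_model()`/`refine_boundary()` (pull approximate boundaries onto
frame-compatible splice sites), `find_small_exons()` (enumerate
phase-constrained small-exon candidates), `parse_edits()`/`apply_edits()`/
`lift_model()` (VCF consensus corrections with coordinate liftover),
`reciprocal_best_hits()`/`assess_local_synteny()` (ortholog assignment),
`compare_isoform_sets()`/`summarize_error_rates()` (reconciliation of
independent annotations), and `generate_locus()`/`corrupt_model()`
(deterministic synthetic fixtures with known ground truth).

## Worked example

```r
library(genecurate)

loc <- generate_locus(random_locus_spec(seed = 42))
loc$model
#> <isoform_model> genA-PA (genA) on scaffold_1 [-], 2 coding exon(s), complete
#> # A tibble: 2 × 3
#>   ordinal start   end
#>     <int> <int> <int>
#> 1       1   222   305
#> 2       2    31   204

check_model(loc$model, loc$scaffold, loc$reference_record)
#> <checklist_report> genA-PA: pass (CDS 258 nt, peptide 85 aa)
#>   [ok  ] start_codon            start codon ATG
#>   [ok  ] internal_stops:1       no in-frame stop codon within coding exon 1
#>   [ok  ] donor_site:1           canonical GT donor at junction 1
#>   [ok  ] acceptor_site:1        canonical AG acceptor at junction 1
#>   [ok  ] phase_compat:1         donor phase 0 + acceptor phase 0 = 0 at junction 1
#>   [ok  ] internal_stops:2       no in-frame stop codon within coding exon 2
#>   [ok  ] stop_codon             model ends with stop codon TAA
#>   [ok  ] length_divisible_by_3  total coding length 258 nt is divisible by three
#>   [ok  ] exon_count_match       model has 2 coding exon(s); reference isoform genA-PA has 2

# shift one donor boundary by a single nucleotide and re-check
bad <- corrupt_model(loc$model, loc$scaffold,
                     corruption_spec("splice_shift", junction = 1,
                                     amount = -1))$model
diagnose_first_failure(check_model(bad, loc$scaffold, loc$reference_record))
#> # A tibble: 1 × 5
#>   key          status message                              junction  exon
#>   <chr>        <chr>  <chr>                                   <int> <int>
#> 1 donor_site:1 fail   non-canonical GG donor at junction 1        1    NA
```

Report objects are tidyverse-native: `tidy()` returns the per-item tibble,
`glance()` a one-row summary, and `autoplot()` a ggplot view
(checklist tiles, peptide dot plots, congruence bars).

A thin command-line dispatcher over the same functions ships in
`inst/cli/genecurate.R` (subcommands `check`, `merge`, `find-exons`,
`update-seq`, `rbh`, `synteny`, `reconcile`, `simulate`).

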