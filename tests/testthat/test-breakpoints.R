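test_that("HGVS g. strings parse with separators and optional refseq prefix", {
  v <- parse_hgvs_g("g.61,101_98,034del")
  expect_equal(v$start, 61101)
  expect_equal(v$end, 98034)
  expect_equal(v$kind, "del")
  expect_true(is.na(v$sequence_name))

  v <- parse_hgvs_g("NG_005905.2:g.61101_98034dup")
  expect_equal(v$sequence_name, "NG_005905.2")
  expect_equal(v$kind, "dup")

  expect_equal(event_size(parse_hgvs_g("g.5_5del")), 1L)
  expect_error(parse_hgvs_g("g.10_5del"), class = "masscnv_parse_error")
  expect_error(parse_hgvs_g("g.10-20del"), class = "masscnv_parse_error")
  expect_error(parse_hgvs_g("chr17:10_20del"), class = "masscnv_parse_error")
})

test_that("event sizes of the five characterised deletions are exact", {
  strings <- c("g.61,101_98,034del", "g.73,379_93,235del",
               "g.61,422_98,355del", "g.110,371_122,487del",
               "g.48,409_56,300del")
  sizes <- vapply(strings, function(s) event_size(parse_hgvs_g(s)),
                  integer(1), USE.NAMES = FALSE)
  expect_equal(sizes, c(36934L, 19857L, 36934L, 12117L, 7892L))
})

test_that("junction homology matches hand-constructed references", {
  # no repeated context at the junction
  ref <- paste0("TTTTTTTTTT", "AAAAAAAAAAAA", "CCCCCCCCCC")
  v <- parse_hgvs_g("g.11_22del")
  hom <- junction_homology(v, ref)
  expect_equal(hom$homology_len, 0L)
  expect_equal(hom$start_range, c(11, 11))
  expect_equal(hom$homology_len, brute_force_homology(ref, 11, 22))

  # 5 bp inside the proximal breakpoint equal 5 bp past the distal one
  ref <- paste0("TTTTTTTTTT", "ACGTA", "CCCCCCC", "ACGTA", "GGGGG")
  v <- parse_hgvs_g("g.11_22del")
  hom <- junction_homology(v, ref)
  expect_equal(hom$homology_len, 5L)
  expect_equal(hom$homology_len, brute_force_homology(ref, 11, 22))
  expect_equal(hom$start_range, c(11, 16))

  # two embedded identical 40 bp repeats flanking the deleted segment
  set.seed(8)
  rep40 <- random_dna(40)
  ref <- paste0(random_dna(20), rep40, random_dna(30), rep40, random_dna(20))
  v <- parse_hgvs_g("g.31_100del")  # breakpoints inside both repeats
  hom <- junction_homology(v, ref)
  expect_gte(hom$homology_len, 30)
  expect_equal(hom$homology_len, brute_force_homology(ref, 31, 100))

  # reference too short names the required span
  expect_error(junction_homology(parse_hgvs_g("g.5_500del"), "ACGTACGT"),
               "500", class = "masscnv_argument_error")
})

test_that("junction homology equals the brute-force shift oracle on random deletions", {
  set.seed(1234)
  for (i in 1:200) {
    L <- sample(30:60, 1)
    # two-letter alphabet makes accidental homology common
    ref <- random_dna(L, alphabet = c("A", "C"))
    start <- sample(2:(L - 10), 1)
    end <- start + sample(1:8, 1)
    v <- structure(list(sequence_name = NA, start = start, end = end,
                        kind = "del"), class = "genomic_variant")
    hom <- junction_homology(v, ref)
    expect_identical(hom$homology_len, brute_force_homology(ref, start, end))
    # placement count = homology + 1 by the shift-equivalence definition
    expect_equal(diff(hom$start_range) + 1L, hom$homology_len + 1L)
  }
})

test_that("mechanism classification follows homology and repeat evidence", {
  expect_equal(classify_mechanism(0, NA, "AluSx"), "NHEJ")
  expect_equal(classify_mechanism(45, "AluSx", "AluSz"), "NAHR")
  expect_equal(classify_mechanism(10, NA, NA), "MMEJ")
  expect_equal(classify_mechanism(3, NA, NA), "NHEJ")
  expect_equal(classify_mechanism(4, NA, NA), "MMEJ")
  expect_equal(classify_mechanism(30, NA, NA), "NAHR")
  # same-family repeats carry NAHR evidence even below the homology bar
  expect_equal(classify_mechanism(10, "AluSz6", "AluJb"), "NAHR")
  # ...but conflict with an end-joining-sized junction
  expect_equal(classify_mechanism(0, "AluSx", "AluSx"), "ambiguous")
  # monotone in homology for fixed repeat evidence
  for (reps in list(c(NA, NA), c("AluSx", "AluSz"), c(NA, "AluSx"))) {
    mech <- vapply(0:60, classify_mechanism, character(1),
                   repeat_left = reps[1], repeat_right = reps[2])
    ranks <- c(NHEJ = 1, ambiguous = 1, MMEJ = 2, NAHR = 3)
    expect_true(all(diff(ranks[mech]) >= 0))
  }
})

test_that("repeat annotation converts conventions and breaks ties by overlap", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "ref\t89\t120\tAluSx",
    "ref\t95\t300\tL1PA2",
    "ref\t400\t500\tMIR3"
  ), bed)
  repeats <- read_bed(bed)
  v <- structure(list(sequence_name = "ref", start = 100, end = 450,
                      kind = "del"), class = "genomic_variant")
  ann <- annotate_repeats(v, repeats)
  expect_equal(ann$repeat_left, "L1PA2")   # longer of the two containing hits
  expect_equal(ann$repeat_right, "MIR3")

  # 1-based position 90 is inside [89, 120) but position 89 is not
  v89 <- structure(list(sequence_name = "ref", start = 89, end = 430,
                        kind = "del"), class = "genomic_variant")
  expect_true(is.na(annotate_repeats(v89, repeats)$repeat_left))
  v90 <- structure(list(sequence_name = "ref", start = 90, end = 430,
                        kind = "del"), class = "genomic_variant")
  expect_equal(annotate_repeats(v90, repeats)$repeat_left, "AluSx")

  writeLines("ref\t10\tnot_a_number", bed)
  expect_error(read_bed(bed), "line 1", class = "masscnv_parse_error")
})

test_that("breakpoint_report combines size, homology, repeats and mechanism", {
  set.seed(8)
  rep40 <- random_dna(40)
  ref <- paste0(random_dna(20), rep40, random_dna(30), rep40, random_dna(20))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("ref\t20\t60\tAluSx", "ref\t90\t130\tAluSz"), bed)
  rep_tab <- read_bed(bed)
  rpt <- breakpoint_report("ref:g.31_100del", reference = ref,
                           repeats = rep_tab)
  expect_equal(rpt$size_bp, 70L)
  expect_gte(rpt$homology_len, 30)
  expect_equal(rpt$repeat_left, "AluSx")
  expect_equal(rpt$repeat_right, "AluSz")
  expect_equal(rpt$mechanism, "NAHR")
})

test_that("FASTA references are read through Biostrings", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">refA desc here", "ACGTACGTAC", "GGGG",
               ">refB", "TTTT"), fa)
  seqs <- read_reference_fasta(fa)
  expect_equal(names(seqs), c("refA", "refB"))
  expect_equal(unname(seqs["refA"]), "ACGTACGTACGGGG")
  v <- parse_hgvs_g("g.2_5del")
  expect_equal(junction_homology(v, seqs["refA"])$homology_len,
               brute_force_homology("ACGTACGTACGGGG", 2, 5))
})

test_that("primer screening folds MAF and applies the 0.5% rule", {
  primers <- tibble::tibble(name = c("p1", "p2"), chrom = "chr17",
                            start = c(100, 300), end = c(120, 320))
  variants <- tibble::tibble(
    chrom = "chr17",
    pos = c(110, 115, 310, 315),
    af = c(0.01, 0.001, 0.999, NA)
  )
  expect_warning(res <- screen_primers(primers, variants), "1 variant")
  expect_true(res$flagged[res$name == "p1"])    # AF 0.01 -> MAF 0.01 > 0.005
  # AF 0.999 folds to MAF 0.001; the NA-AF variant is skipped
  expect_false(res$flagged[res$name == "p2"])
  expect_equal(res$n_overlapping, c(2L, 1L))

  # threshold is strict: MAF exactly at maf_max is tolerated
  at <- screen_primers(primers[1, ],
                       tibble::tibble(chrom = "chr17", pos = 110, af = 0.005))
  expect_false(at$flagged)
})

test_that("variant frequencies can come from a VCF", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr17\t110\t.\tA\tG\t.\t.\tAF=0.01",
    "chr17\t115\t.\tC\tT,G\t.\t.\tAF=0.001,0.2",
    "chr17\t200\t.\tG\tA\t.\t.\tDP=10"
  ), vcf)
  tab <- read_variant_table(vcf)
  expect_equal(tab$pos, c(110, 115, 200))
  expect_equal(tab$af, c(0.01, 0.2, NA))
})
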