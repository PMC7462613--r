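test_that("protein_reference validates and translates", {
  ref <- toy_reference()
  expect_equal(ref$protein_sequence, "MTRWK")
  expect_equal(ref$mutagenized_range, c(2L, 5L))
  expect_error(protein_reference("x", "ATGC"), "divisible by 3")
  expect_error(protein_reference("x", "ATGTAACAT"), "internal stop")
  expect_error(protein_reference("x", "ATGNNNAAA"), "non-ACGT")
  # terminal stop codon tolerated and trimmed
  ref2 <- protein_reference("x", "ATGAAATAA")
  expect_equal(ref2$protein_sequence, "MK")
})

test_that("FASTA round trip preserves the reference", {
  ref <- toy_reference()
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">toy", ref$coding_sequence), fa)
  expect_equal(read_protein_reference(fa)$coding_sequence,
               ref$coding_sequence)
})

test_that("call_variant handles identity, single edits and rejections", {
  ref <- toy_reference()
  expect_equal(call_variant(ref$coding_sequence, ref)$status,
               "rejected_wt_identical")
  # R -> W missense via CGG -> TGG (codon 3 of the toy gene)
  res <- call_variant(edit_codon(ref, 3, "TGG"), ref)
  expect_equal(res$status, "accepted")
  expect_equal(res$variant$variant, "R3W")
  expect_equal(res$variant$mut_class, "missense")
  # synonymous and nonsense
  expect_equal(call_variant(edit_codon(ref, 3, "CGA"), ref)$variant$mut_class,
               "synonymous")
  expect_equal(call_variant(edit_codon(ref, 3, "TGA"), ref)$variant$variant,
               "R3*")
  # two changed codons, each altering an amino acid
  two <- edit_codon(toy_reference(), 2, "GGG")
  two <- paste0(substr(two, 1, 6), "TGG", substr(two, 10, nchar(two)))
  expect_equal(call_variant(two, ref)$status, "rejected_multi_aa")
  # length mismatch is an indel
  expect_equal(call_variant(substr(ref$coding_sequence, 1, 12), ref)$status,
               "rejected_indel")
  # ambiguity in the edited codon
  expect_equal(call_variant(edit_codon(ref, 3, "TNG"), ref)$status,
               "rejected_ambiguous")
  # edit outside the mutagenized range (position 1)
  expect_equal(call_variant(edit_codon(ref, 1, "CTG"), ref)$status,
               "rejected_ambiguous")
})

test_that("call_variant inverts every single-codon edit in range", {
  ref <- toy_reference()
  codons <- names(Biostrings::GENETIC_CODE)
  for (pos in ref$mutagenized_range[1]:ref$mutagenized_range[2]) {
    wt_codon <- substr(ref$coding_sequence, 3 * pos - 2, 3 * pos)
    for (codon in setdiff(codons, wt_codon)) {
      res <- call_variant(edit_codon(ref, pos, codon), ref)
      expect_equal(res$status, "accepted")
      expect_equal(res$variant$position, pos)
      expect_equal(res$variant$alt_codon, codon)
      expect_equal(res$variant$alt_aa,
                   unname(Biostrings::GENETIC_CODE[codon]))
    }
  }
})

test_that("consensus collapsing matches a per-column majority oracle", {
  ref <- toy_reference()
  # unanimity
  reads <- rep(edit_codon(ref, 3, "TGG"), 5)
  rec <- collapse_barcode_reads(reads, ref, "BC1")
  expect_equal(rec$status, "accepted")
  expect_equal(rec$variant, "R3W")
  expect_equal(rec$n_supporting_reads, 5L)
  # 2 votes for a substitution, 1 stray error elsewhere
  mut <- edit_codon(ref, 3, "TGG")
  err <- paste0("C", substr(mut, 2, nchar(mut)))
  reads <- c(mut, mut, err)
  expect_equal(oracle_consensus(reads), mut)
  rec <- collapse_barcode_reads(reads, ref, "BC2")
  expect_equal(rec$variant, "R3W")
  # order invariance
  rec2 <- collapse_barcode_reads(rev(reads), ref, "BC2")
  expect_equal(rec2$variant, rec$variant)
  # 1 vs 1 tie
  tie <- collapse_barcode_reads(c(mut, ref$coding_sequence), ref, "BC3")
  expect_equal(tie$status, "rejected_ambiguous")
  expect_true(is.na(oracle_consensus(c(mut, ref$coding_sequence))))
  # min_reads threshold and empty input
  expect_equal(collapse_barcode_reads(mut, ref, "BC4", min_reads = 2)$status,
               "rejected_ambiguous")
  expect_error(collapse_barcode_reads(character(0), ref, "BC5"), "no reads")
})

test_that("random consensus cases agree with the oracle", {
  ref <- toy_reference()
  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:7, 1)
    base <- edit_codon(ref, sample(2:5, 1), sample(c("TGG", "GAA", "TAA"), 1))
    reads <- rep(base, n)
    # sprinkle random errors
    for (j in seq_len(sample(0:3, 1))) {
      r <- sample(n, 1)
      p <- sample(nchar(base), 1)
      substr(reads[r], p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    expected <- oracle_consensus(reads)
    rec <- collapse_barcode_reads(reads, ref, "BC")
    if (is.na(expected)) {
      expect_equal(rec$status, "rejected_ambiguous")
    } else {
      expect_equal(rec$status, call_variant(expected, ref)$status)
    }
  }
})

test_that("build_barcode_map filters, deduplicates and orders", {
  ref <- toy_reference()
  mut1 <- edit_codon(ref, 3, "TGG")
  mut2 <- edit_codon(ref, 2, "GGG")
  recs <- rbind(
    collapse_barcode_reads(rep(mut1, 2), ref, "TTTT"),
    collapse_barcode_reads(rep(mut2, 2), ref, "AAAA"),
    collapse_barcode_reads(rep(mut1, 3), ref, "CCCC"),
    collapse_barcode_reads(rep(mut2, 1), ref, "GGGG"),
    collapse_barcode_reads(rep(ref$coding_sequence, 2), ref, "GCGC"),
    collapse_barcode_reads(c(mut1, mut2), ref, "CGCG"))
  bm <- build_barcode_map(recs)
  expect_equal(bm$summary$accepted, 4L)
  expect_equal(bm$summary$rejected, 2L)
  expect_equal(bm$map$barcode, sort(bm$map$barcode))
  expect_true(all(bm$map$mut_class %in% c("missense", "synonymous", "nonsense")))
  expect_lte(nrow(bm$map), nrow(recs))
  # empty input
  empty <- build_barcode_map(recs[0, ])
  expect_equal(nrow(empty$map), 0L)
  expect_equal(empty$summary$accepted, 0L)
  # 10 records with one barcode claiming two variants -> both dropped
  recs10 <- do.call(rbind, lapply(1:10, function(i)
    collapse_barcode_reads(rep(mut1, 2), ref, sprintf("BC%02d", i))))
  recs10$barcode[2] <- "BC01"
  recs10$variant[2] <- "T2G"
  recs10$alt_codon[2] <- "GGG"
  expect_message(build_barcode_map(recs10), "conflicting")
  bm10 <- suppressMessages(build_barcode_map(recs10))
  expect_equal(nrow(bm10$map), 8L)
  expect_equal(bm10$summary$dropped_conflicting, 2L)
})

test_that("barcode map TSV round trip", {
  ref <- toy_reference()
  recs <- rbind(
    collapse_barcode_reads(rep(edit_codon(ref, 3, "TGG"), 2), ref, "TTTT"),
    collapse_barcode_reads(rep(edit_codon(ref, 4, "TAA"), 2), ref, "AAAA"))
  bm <- build_barcode_map(recs)
  path <- tempfile(fileext = ".tsv")
  write_barcode_map(bm$map, path)
  back <- read_barcode_map(path)
  expect_equal(back$barcode, bm$map$barcode)
  expect_equal(back$variant, bm$map$variant)
  expect_equal(back$position, bm$map$position)
  expect_equal(back$alt_aa, bm$map$alt_aa)
})

test_that("variant tokens parse and flag malformed input", {
  p <- parse_variant_token(c("R98W", "W5*", "L27L", "xyz", "12A"))
  expect_equal(p$mut_class[1:3], c("missense", "nonsense", "synonymous"))
  expect_equal(p$position[1:3], c(98L, 5L, 27L))
  expect_false(any(p$valid[4:5]))
})
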