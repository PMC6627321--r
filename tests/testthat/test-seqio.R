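test_that("FASTA reading normalises case and RNA and keeps record order", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgu"), fa)
  rec <- read_utr_fasta(fa)
  expect_equal(rec$seq, "ACGT")

  writeLines(c(">a", "ACGT", ">b", "GGCC"), fa)
  recs <- read_utr_fasta(fa)
  expect_equal(recs$id, c("a", "b"))
  expect_equal(recs$seq, c("ACGT", "GGCC"))
})

test_that("FASTA parse errors name the offending character and catch duplicates", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC!GT"), fa)
  expect_error(read_utr_fasta(fa), "'!'", class = "utrscape_parse_error")

  writeLines(c(">a", "ACGT", ">a", "GGCC"), fa)
  expect_error(read_utr_fasta(fa), "duplicate",
               class = "utrscape_parse_error")

  writeLines(character(0), fa)
  expect_error(read_utr_fasta(fa), class = "utrscape_parse_error")
})

test_that("FASTA write/read round trip is the identity on sequences", {
  tr <- tibble::tibble(id = c("s1", "s2"),
                       seq = c(random_dna(137), random_dna(61)))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_utr_fasta(tr, fa)
  back <- read_utr_fasta(fa)
  expect_equal(back$seq, tr$seq)
})

test_that("annotation attach validates coordinate invariants", {
  tr <- toy_transcripts()
  expect_equal(tr$utr5_len, c(12L, 10L, 12L))
  # human-like row: morf_start = utr5_len + 1 accepted
  human <- tibble::tibble(id = "h", species = "h",
                          seq = paste0(random_dna(386), "TGAGGGAAC", "ATG",
                                       random_dna(9)))
  ann <- tibble::tibble(id = "h", group = "primates", utr5_len = 395L,
                        intron1_offset = 300L, morf_start = 396L)
  expect_silent(annotate_transcripts(human, ann))

  # intron1_offset at utr5_len is out of range
  bad <- ann
  bad$intron1_offset <- 395L
  expect_error(annotate_transcripts(human, bad),
               class = "utrscape_annotation_error")
  # morf_start inconsistent with utr5_len
  bad <- ann
  bad$morf_start <- 395L
  expect_error(annotate_transcripts(human, bad),
               class = "utrscape_annotation_error")
})

test_that("intronless records get a single whole section", {
  secs <- transcript_sections(toy_transcripts())
  expect_equal(secs$section[secs$id == "b"], "whole")
  a <- secs[secs$id == "a", ]
  expect_equal(a$section, c("before", "after"))
  expect_equal(a$start, c(1L, 7L))
  expect_equal(a$end, c(6L, 12L))
})

test_that("annotation TSV reading honours comments and empty fields", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment line",
    "id\tgroup\tutr5_len\tintron1_offset\tmorf_start",
    "a\tprimates\t12\t6\t13",
    "b\tprimates\t10\t\t11"
  ), tsv)
  tr <- tibble::tibble(id = c("a", "b"), species = c("a", "b"),
                       seq = c("ACGTACGTACGTATGCCC", "GGGCCCGGGCATGAAA"))
  out <- read_utr_annotations(tr, tsv)
  expect_true(is.na(out$intron1_offset[out$id == "b"]))
  expect_equal(out$intron1_offset[out$id == "a"], 6L)
})

test_that("alignment parsing validates widths and transcript linkage", {
  afa <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">r1", "AC-G", ">r2", "ACTG"), afa)
  aln <- read_utr_alignment(afa, "afa")
  expect_equal(alignment_ncol(aln), 4L)

  writeLines(c(">r1", "ACGT", ">r2", "ACGTA"), afa)
  expect_error(read_utr_alignment(afa, "afa"), "ragged",
               class = "utrscape_parse_error")

  tr <- toy_transcripts()
  writeLines(c(">zzz", "ACGT"), afa)
  expect_error(read_utr_alignment(afa, "afa", transcripts = tr),
               class = "utrscape_parse_error")
})

test_that("clustal and aligned-FASTA round trips give the same matrix", {
  set.seed(42)
  rows <- vapply(1:4, function(i) {
    s <- strsplit(random_dna(73), "")[[1]]
    s[sample(73, 8)] <- "-"
    paste(s, collapse = "")
  }, "")
  aln <- as_utr_alignment(tibble::tibble(id = paste0("sp", 1:4),
                                         aln_seq = rows))
  afa <- withr::local_tempfile(fileext = ".afa")
  clu <- withr::local_tempfile(fileext = ".aln")
  write_utr_alignment(aln, afa, "afa")
  write_utr_alignment(aln, clu, "clustal")
  a1 <- read_utr_alignment(afa, "afa")
  a2 <- read_utr_alignment(clu, "clustal")
  expect_equal(a1$aln_seq, aln$aln_seq)
  expect_equal(a2$aln_seq, aln$aln_seq)
  expect_equal(a2$id, aln$id)
})

test_that("column-to-sequence mapping matches the brute-force scan", {
  expect_equal(aln_col_to_seq(
    as_utr_alignment(tibble::tibble(id = "r", aln_seq = "A-CG")), "r", 3L), 2L)
  expect_true(is.na(aln_col_to_seq(
    as_utr_alignment(tibble::tibble(id = "r", aln_seq = "A-CG")), "r", 2L)))

  set.seed(7)
  s <- strsplit(random_dna(50), "")[[1]]
  s[sample(50, 12)] <- "-"
  row <- paste(s, collapse = "")
  aln <- as_utr_alignment(tibble::tibble(id = "r", aln_seq = row))
  for (col in 1:50) {
    expect_identical(aln_col_to_seq(aln, "r", col),
                     oracle_col_to_seq(row, col))
  }
  expect_error(aln_col_to_seq(aln, "r", 51L), class = "utrscape_range_error")
})

test_that("non-gap columns biject onto 1..n sequence positions", {
  set.seed(8)
  s <- strsplit(random_dna(60), "")[[1]]
  s[sample(60, 15)] <- "-"
  aln <- as_utr_alignment(tibble::tibble(id = "r",
                                         aln_seq = paste(s, collapse = "")))
  pm <- alignment_position_map(aln)
  nongap <- pm$seq_pos[!is.na(pm$seq_pos)]
  expect_equal(nongap, 1:45)          # strictly increasing, complete
  expect_equal(sum(pm$base != "-"), 45L)
})
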