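table1 <- readr::read_tsv(
  system.file("extdata", "abca1_uorf_table1.tsv", package = "utrscape"),
  comment = "#", show_col_types = FALSE)
table2 <- readr::read_tsv(
  system.file("extdata", "abca1_contexts_table2.tsv", package = "utrscape"),
  comment = "#", show_col_types = FALSE)

test_that("codon scan equals the brute-force window scan", {
  expect_equal(scan_codons("ATGATG", "ATG"), c(1L, 4L))
  expect_equal(scan_codons("ATGTGA", "GTG"), 3L)
  set.seed(21)
  for (rep in 1:20) {
    s <- random_dna(200)
    for (cd in c("ATG", "TGA", "CTG")) {
      expect_equal(scan_codons(s, cd), oracle_scan_codons(s, cd))
    }
  }
})

test_that("codon census splits by section with the first-base rule", {
  tr <- annotate_transcripts(
    tibble::tibble(id = "x", species = "x", seq = "ATGTAACCC"),
    tibble::tibble(id = "x", group = "other", utr5_len = 6L,
                   intron1_offset = 3L, morf_start = NA))
  cen <- census_by_section(tr)
  expect_equal(cen$n[cen$codon == "ATG" & cen$section == "before"], 1L)
  expect_equal(cen$n[cen$codon == "TAA" & cen$section == "after"], 1L)
  # nothing else within the 5'UTR "ATGTAA"
  expect_equal(sum(cen$n), 2L)
})

test_that("before + after census counts equal the whole-5'UTR count", {
  fam <- generate_family(utr_family_spec(seed = 14))
  cen <- census_by_section(fam$transcripts[1:4, ])
  totals <- dplyr::summarise(dplyr::group_by(cen, id, codon),
                             n = sum(n), .groups = "drop")
  for (i in seq_len(nrow(fam$transcripts[1:4, ]))) {
    rec <- fam$transcripts[i, ]
    utr <- substr(rec$seq, 1, rec$utr5_len)
    for (cd in CENSUS_CODONS) {
      whole <- length(oracle_scan_codons(utr, cd))
      expect_equal(totals$n[totals$id == rec$id & totals$codon == cd], whole)
    }
  }
})

test_that("ORF finder output matches forced small examples", {
  o <- find_orfs("CCATGAAATGATT")
  # ATG at 3 closes at the TGA ending at 11; the ATG at 8 never meets a stop
  closed <- o[o$has_stop, ]
  expect_equal(closed$start, 3L)
  expect_equal(closed$stop_end, 11L)
  expect_equal(closed$len_nt, 9L)
  expect_equal(closed$peptide, "MK")
  open <- o[!o$has_stop, ]
  expect_equal(open$start, 8L)
  expect_equal(open$stop_end, 13L)

  o <- find_orfs("ATGTAA")
  expect_equal(o$start, 1L)
  expect_equal(o$stop_end, 6L)
  expect_equal(o$len_nt, 6L)
  expect_equal(o$len_aa, 1L)
  expect_equal(o$peptide, "M")
})

test_that("ORF finder equals exhaustive enumeration on random sequences", {
  set.seed(33)
  for (rep in 1:300) {
    s <- random_dna(sample(10:60, 1))
    got <- find_orfs(s)
    want <- oracle_find_orfs(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$stop_end, want$stop_end)
      expect_equal(got$has_stop, want$has_stop)
    }
    # every peptide retranslates from its coordinates
    for (i in seq_len(nrow(got))) {
      if (got$has_stop[i]) {
        nt <- substr(s, got$start[i], got$stop_end[i] - 3)
        expect_equal(got$peptide[i],
                     as.character(Biostrings::translate(
                       Biostrings::DNAString(nt))))
      }
    }
  }
})

test_that("printed uORF coordinate rows are internally consistent", {
  geom <- uorf_geometry(table1$uorf_start, table1$uorf_stop,
                        table1$morf_start)
  expect_equal(geom$len_nt, table1$len_nt)
  expect_equal(geom$len_aa, table1$len_aa)
  expect_equal(nchar(table1$peptide), table1$len_aa)
})

test_that("uORF geometry reproduces the published worked examples", {
  human <- uorf_geometry(307, 417, 396)
  expect_equal(human$len_nt, 111L)
  expect_equal(human$len_aa, 36L)
  expect_true(human$overlaps_morf)
  expect_equal(human$gap_to_morf, -22L)

  mouse <- uorf_geometry(224, 319, 321)
  expect_equal(mouse$len_nt, 96L)
  expect_equal(mouse$len_aa, 31L)
  expect_equal(mouse$gap_to_morf, 1L)
  expect_false(mouse$overlaps_morf)

  coel <- uorf_geometry(245, 274, 297)
  expect_equal(coel$len_nt, 30L)
  expect_equal(coel$len_aa, 9L)
  expect_equal(coel$gap_to_morf, 22L)
})

test_that("characterize_uorf rejects ORFs at or past the main ORF", {
  rec <- tibble::tibble(id = "x", seq = "ATGTAAATGCCC", morf_start = 7L)
  orf <- tibble::tibble(start = 7L, stop_end = 12L, len_nt = 6L, len_aa = 1L,
                        peptide = "P", has_stop = TRUE)
  expect_error(characterize_uorf(rec, orf),
               class = "utrscape_annotation_error")
})

test_that("context extraction clips windows at sequence ends", {
  # ATG at position 4: only 3 upstream bases survive -> 15-nt window
  s <- paste0("TTA", "ATG", "ACCAGCCAC", "GGG")
  ctx <- extract_context(s, 4L)
  expect_equal(ctx$window, "TTAATGACCAGCCAC")
  expect_equal(ctx$minus3, "T")
  expect_equal(ctx$plus4, "A")

  s2 <- paste0("ATG", random_dna(20))
  ctx2 <- extract_context(s2, 1L)
  expect_true(is.na(ctx2$minus3))
  expect_equal(classify_context(ctx2$minus3, ctx2$plus4), "undetermined")

  expect_error(extract_context("AAAA", 2L), class = "utrscape_range_error")
})

test_that("Kozak-style classification covers the four classes", {
  expect_equal(classify_context("A", "G"), "strong")
  expect_equal(classify_context("G", "G"), "strong")
  expect_equal(classify_context("T", "A"), "weak")
  expect_equal(classify_context("A", "A"), "adequate")
  expect_equal(classify_context("C", "G"), "adequate")
  expect_equal(classify_context(NA, "G"), "undetermined")
})

test_that("published context windows classify as narrated", {
  uorf <- dplyr::bind_rows(lapply(table2$uorf_context, parse_context_window))
  morf <- dplyr::bind_rows(lapply(table2$morf_context, parse_context_window))
  uorf_class <- classify_context(uorf$minus3, uorf$plus4)
  morf_class <- classify_context(morf$minus3, morf$plus4)
  expect_true(all(uorf_class == "weak"))
  coel <- table2$species == "Coelacanth"
  expect_true(all(morf_class[!coel] == "strong"))
  expect_equal(morf_class[coel], "adequate")
})

test_that("codon at -9..-7 from the sATG is read in frame", {
  # reconstruct sequence context from the printed mORF windows
  human_win <- table2$morf_context[table2$species == "Human"]
  seq <- paste0(random_dna(30), human_win)
  morf <- 30L + 10L
  expect_equal(codon_at_offset(seq, morf, -9L), "TGA")
  mouse_win <- table2$morf_context[table2$species == "Mouse"]
  seq2 <- paste0(random_dna(30), mouse_win)
  expect_equal(codon_at_offset(seq2, morf, -9L), "TGT")
  # contiguous codons
  expect_equal(codon_at_offset(seq, morf, -3L), substr(seq, morf - 3, morf - 1))
  expect_error(codon_at_offset("ATGAAA", 2L, -9L),
               class = "utrscape_range_error")
})

test_that("uORF calling on the synthetic family returns the planted uORF", {
  fam <- generate_family(utr_family_spec(seed = 2))
  u <- call_uorfs(fam$transcripts)
  first <- dplyr::slice(dplyr::arrange(dplyr::group_by(u, id), start), 1L)
  m <- dplyr::left_join(fam$truth, first, by = "id")
  expect_equal(m$start, m$uorf_start)
  expect_equal(m$stop_end, m$uorf_stop_end)
  expect_equal(m$len_nt, m$uorf_len_nt)
  # geometry respects the group relation
  gap_groups <- m$relation == "gap"
  expect_true(all(m$gap_to_morf[gap_groups] == m$k[gap_groups]))
  expect_true(all(m$overlaps_morf[!gap_groups]))
})
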