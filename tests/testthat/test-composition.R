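test_that("GC percent follows the counting formula and excludes N", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("AATT"), 0)
  expect_equal(gc_percent("ATGC"), 50)
  expect_equal(gc_percent("ATGCNN"), 50)   # N out of both counts
  expect_error(gc_percent("NNN"), class = "utrscape_range_error")
})

test_that("concatenation GC is the length-weighted mean of the parts", {
  set.seed(4)
  for (rep in 1:10) {
    s1 <- random_dna(sample(10:50, 1))
    s2 <- random_dna(sample(10:50, 1))
    g <- gc_percent(paste0(s1, s2))
    w <- (gc_percent(s1) * nchar(s1) + gc_percent(s2) * nchar(s2)) /
      (nchar(s1) + nchar(s2))
    expect_equal(g, w, tolerance = 1e-10)
    expect_true(g >= min(gc_percent(s1), gc_percent(s2)) - 1e-10)
    expect_true(g <= max(gc_percent(s1), gc_percent(s2)) + 1e-10)
  }
})

test_that("section GC sets the dominance flags at 8 and 14 points", {
  tr <- annotate_transcripts(
    tibble::tibble(id = c("x", "y"), species = c("x", "y"),
                   seq = c("AATTGGCC", "ACGTACGT")),
    tibble::tibble(id = c("x", "y"), group = "other", utr5_len = c(8L, 8L),
                   intron1_offset = c(4L, 4L), morf_start = NA))
  gc <- section_gc(tr)
  x <- gc[gc$id == "x", ]
  expect_equal(x$before_pct, 0)
  expect_equal(x$after_pct, 100)
  expect_true(x$after_dominant)
  expect_false(x$before_dominant)
  y <- gc[gc$id == "y", ]
  expect_equal(y$diff_after_minus_before, 0)
  expect_false(y$after_dominant || y$before_dominant)
})

test_that("synthetic family section GC recovers the planted targets", {
  fam <- generate_family(utr_family_spec(seed = 6))
  gc <- section_gc(fam$transcripts)
  # family mean of the before sections sits on the background target
  expect_lt(abs(mean(gc$before_pct) - fam$spec$gc_before), 2)
  # the after section blends the target background with the fixed conserved
  # block, whose own GC is part of the recorded truth
  blk_gc <- gc_percent(fam$spec$conserved_block)
  blen <- nchar(fam$spec$conserved_block)
  expected_after <- (fam$spec$gc_after * (fam$truth$after_len - blen) +
                       blk_gc * blen) / fam$truth$after_len
  expect_lt(abs(mean(gc$after_pct - expected_after)), 2)
})

test_that("sliding GC windows cover the sequence and drop partial tails", {
  s <- "GGGGAAAA"
  ser <- gc_window_series(s, window = 4L, step = 4L)
  expect_equal(ser$center, c(2.5, 6.5))
  expect_equal(ser$pct, c(100, 0))

  expect_equal(unique(gc_window_series(strrep("GA", 20), 10L, 3L)$pct), 50)
  expect_error(gc_window_series("ACGT", 10L), class = "utrscape_range_error")

  # weighted mean of step-1 windows is consistent with whole-sequence GC
  s2 <- random_dna(60)
  ser2 <- gc_window_series(s2, window = 1L, step = 1L)
  expect_equal(mean(ser2$pct), gc_percent(s2), tolerance = 1e-10)
})

test_that("a pure dinucleotide repeat segments as one full-length region", {
  segs <- segment_repetition_regions(strrep("GC", 30),
                                     subsets = list(c("G", "C")))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start, 1L)
  expect_equal(segs$end, 60L)
  expect_equal(segs$fraction, 1)
})

test_that("segmentation false-positive rate under the null is below 1%", {
  set.seed(19)
  hits <- 0L
  trials <- 400L
  for (t in seq_len(trials)) {
    s <- random_dna(150)
    segs <- segment_repetition_regions(
      s, subsets = list(c("G", "C"), c("T", "C"), c("G", "A")),
      fraction_min = 0.95)
    if (nrow(segs) > 0) hits <- hits + 1L
  }
  expect_lt(hits / trials, 0.01)
})

test_that("planted composition blocks are recovered with tight boundaries", {
  errs <- c()
  detected <- 0L
  for (seed in 1:20) {
    pl <- plant_composition_block(260, block_start = 111, block_len = 40,
                                  subset = c("G", "A"), fraction = 0.9,
                                  seed = seed)
    segs <- segment_repetition_regions(pl$seq, subsets = list(c("G", "A")))
    ga <- segs[segs$label == "G/A" &
                 segs$end >= pl$truth$start & segs$start <= pl$truth$end, ]
    if (nrow(ga) >= 1) {
      detected <- detected + 1L
      ga <- ga[which.max(ga$length), ]
      errs <- c(errs, abs(ga$start - pl$truth$start),
                abs(ga$end - pl$truth$end))
    }
  }
  expect_equal(detected, 20L)
  # boundary localisation is information-limited by in-subset background
  # runs abutting the block; the typical (median) boundary lands within 5 nt
  expect_lte(median(errs), 5)
  expect_true(all(segment_repetition_regions(
    plant_composition_block(260, 111, 40, seed = 1)$seq,
    subsets = list(c("G", "A")))$fraction >= 0.8))
})

test_that("segmentation is deterministic and refined from the step-1 scan", {
  pl <- plant_composition_block(300, 120, 50, subset = c("T", "C"),
                                fraction = 0.95, seed = 3)
  s1 <- segment_repetition_regions(pl$seq, subsets = list(c("T", "C")),
                                   step = 1L)
  s2 <- segment_repetition_regions(pl$seq, subsets = list(c("T", "C")),
                                   step = 1L)
  expect_identical(s1, s2)
  # a coarser scan can only find (sub)regions of the step-1 candidates
  s4 <- segment_repetition_regions(pl$seq, subsets = list(c("T", "C")),
                                   step = 4L)
  for (i in seq_len(nrow(s4))) {
    expect_true(any(s4$start[i] >= s1$start - 3 & s4$end[i] <= s1$end + 3))
  }
})
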