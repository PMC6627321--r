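# GC content (whole / per section / sliding window) and base-repetition-rich
# subregion segmentation.
#
# GC is Count(G + C) / Count(A + T + G + C) * 100; N is excluded from both
# numerator and denominator. In subset-fraction segmentation N counts against
# the fraction (it is never a subset member).

base_counts <- function(seq) {
  cc <- chars(seq)
  c(A = sum(cc == "A"), C = sum(cc == "C"), G = sum(cc == "G"),
    T = sum(cc == "T"), N = sum(cc == "N"))
}

#' GC content of a sequence
#'
#' @param seq Nucleotide string (vectorised).
#' @return Percent GC in \code{[0, 100]} at full precision (round for
#'   reports). Errors when nothing but N remains.
#' @export
#' @examples
#' gc_percent("ATGC")  # 50
gc_percent <- function(seq) {
  vapply(seq, function(s) {
    bc <- base_counts(s)
    denom <- sum(bc[c("A", "C", "G", "T")])
    if (denom == 0) {
      abort("sequence has no unambiguous bases (zero GC denominator)",
            class = "utrscape_range_error")
    }
    100 * sum(bc[c("G", "C")]) / denom
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-section GC profile
#'
#' GC of the whole 5'UTR and of the before-/after-Intron-1 sections, with the
#' two dominance flags used to contrast section composition: after-dominant
#' when the after-section exceeds the before-section by more than 8
#' percentage points, before-dominant when the before-section leads by more
#' than 14.
#'
#' @param transcripts Annotated transcript tibble.
#' @return Tibble `id`, `whole_pct`, `before_pct`, `after_pct`,
#'   `diff_after_minus_before`, `after_dominant`, `before_dominant`.
#'   Intronless transcripts carry NA section values and FALSE flags.
#' @export
section_gc <- function(transcripts) {
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    rec <- transcripts[i, ]
    utr <- str_sub(rec$seq, 1L, rec$utr5_len)
    whole <- gc_percent(utr)
    if (is.na(rec$intron1_offset)) {
      tibble(id = rec$id, whole_pct = whole, before_pct = NA_real_,
             after_pct = NA_real_, diff_after_minus_before = NA_real_,
             after_dominant = FALSE, before_dominant = FALSE)
    } else {
      before <- gc_percent(str_sub(utr, 1L, rec$intron1_offset))
      after <- gc_percent(str_sub(utr, rec$intron1_offset + 1L, rec$utr5_len))
      d <- after - before
      tibble(id = rec$id, whole_pct = whole, before_pct = before,
             after_pct = after, diff_after_minus_before = d,
             after_dominant = d > 8, before_dominant = -d > 14)
    }
  })
  bind_rows(rows)
}

#' Sliding-window GC series
#'
#' @param seq Nucleotide string.
#' @param window Window width in nt.
#' @param step Step between window starts.
#' @return Tibble `start`, `end`, `center`, `pct`; incomplete tail windows
#'   are omitted.
#' @export
#' @examples
#' gc_window_series("GGGGAAAA", window = 4, step = 4)
gc_window_series <- function(seq, window, step = 1L) {
  n <- str_length(seq)
  stopifnot(window >= 1L, step >= 1L)
  if (window > n) {
    abort(sprintf("window %d longer than sequence (%d nt)", window, n),
          class = "utrscape_range_error")
  }
  starts <- seq(1L, n - window + 1L, by = step)
  tibble(
    start = starts,
    end = starts + window - 1L,
    center = starts + (window - 1) / 2,
    pct = vapply(starts, function(s)
      gc_percent(str_sub(seq, s, s + window - 1L)), numeric(1))
  )
}

# fraction of positions (within [start, end]) whose base is in `subset`;
# N is counted in the denominator but never in the numerator
subset_fraction <- function(inset, start, end) {
  sum(inset[start:end]) / (end - start + 1L)
}

# Refine a merged candidate span to the maximum-scoring subsegment, scoring
# each position (in-subset) - fraction_min. Window unions overshoot true
# block edges by up to window - 1 nt; the max-sum subarray ends exactly where
# local density drops below the threshold, and a non-negative total sum
# guarantees the segment fraction >= fraction_min. Deterministic: first
# (5'-most), then longest, maximal subarray wins ties.
trim_segment <- function(inset, s, e, fraction_min) {
  x <- inset[s:e] - fraction_min
  best_sum <- -Inf
  best <- c(1L, 0L)
  cur_sum <- 0
  cur_start <- 1L
  for (i in seq_along(x)) {
    if (cur_sum <= 0) {
      cur_sum <- x[i]
      cur_start <- i
    } else {
      cur_sum <- cur_sum + x[i]
    }
    if (cur_sum > best_sum + 1e-9 ||
        (abs(cur_sum - best_sum) <= 1e-9 && cur_start == best[1] &&
           i > best[2])) {
      best_sum <- cur_sum
      best <- c(cur_start, i)
    }
  }
  if (best_sum < 0) return(c(s, s - 1L))  # nothing reaches the threshold
  c(s + best[1] - 1L, s + best[2] - 1L)
}

#' Segment base-repetition-rich subregions
#'
#' Slides a window along the sequence and, for each base subset (e.g. G/C,
#' T/C, G/A, G/C/A), marks windows whose subset fraction reaches
#' `fraction_min`. Qualifying windows separated by at most `merge_gap` nt are
#' merged into candidate segments; segments shorter than `min_len` or whose
#' overall fraction drops below `fraction_min` are dropped. Overlaps between
#' different labels resolve by higher fraction, then smaller subset, then
#' 5'-most start.
#'
#' @param seq Nucleotide string.
#' @param subsets List of character vectors, each a proper subset of
#'   \{A, C, G, T\} of size 2-3.
#' @param window,step Scan geometry (defaults 30 / 1).
#' @param fraction_min Minimum subset fraction (default 0.8).
#' @param min_len Minimum segment length in nt (default 20).
#' @param merge_gap Maximum gap bridged when merging windows (default 5).
#' @return Tibble `label`, `start`, `end`, `length`, `fraction`, sorted by
#'   `start`.
#' @export
segment_repetition_regions <- function(seq,
                                       subsets = list(
                                         c("G", "C"), c("T", "C"),
                                         c("G", "A"), c("G", "C", "A")),
                                       window = 30L, step = 1L,
                                       fraction_min = 0.8, min_len = 20L,
                                       merge_gap = 5L) {
  for (ss in subsets) {
    if (!all(ss %in% c("A", "C", "G", "T")) || length(ss) < 2L ||
        length(ss) > 3L) {
      abort("each subset must contain 2-3 of A, C, G, T",
            class = "utrscape_range_error")
    }
  }
  n <- str_length(seq)
  cc <- chars(seq)
  cands <- list()
  for (ss in subsets) {
    label <- paste(ss, collapse = "/")
    inset <- cc %in% ss
    if (n < window) next
    starts <- seq(1L, n - window + 1L, by = step)
    frac <- (cumsum(inset)[starts + window - 1L] -
               c(0, cumsum(inset))[starts]) / window
    ok <- starts[frac >= fraction_min]
    if (length(ok) == 0L) next
    # merge window spans whose gaps are <= merge_gap
    span_start <- ok
    span_end <- ok + window - 1L
    brk <- c(0L, which(span_start[-1L] - span_end[-length(span_end)] - 1L >
                         merge_gap), length(ok))
    for (b in seq_len(length(brk) - 1L)) {
      s <- span_start[brk[b] + 1L]
      e <- span_end[brk[b + 1L]]
      tr <- trim_segment(inset, s, e, fraction_min)
      s <- tr[1]
      e <- tr[2]
      if (s > e) next
      frac_seg <- subset_fraction(inset, s, e)
      if (e - s + 1L >= min_len && frac_seg >= fraction_min) {
        cands[[length(cands) + 1L]] <- tibble(
          label = label, start = s, end = e,
          length = e - s + 1L, fraction = frac_seg,
          subset_size = length(ss))
      }
    }
  }
  if (length(cands) == 0L) {
    return(tibble(label = character(), start = integer(), end = integer(),
                  length = integer(), fraction = numeric()))
  }
  cand <- bind_rows(cands)
  # overlap resolution: higher fraction > smaller subset > 5'-most
  cand <- cand[order(-cand$fraction, cand$subset_size, cand$start), ]
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    cur <- cand[i, ]
    clash <- nrow(kept) > 0L &&
      any(cur$start <= kept$end & cur$end >= kept$start)
    if (!clash) kept <- bind_rows(kept, cur)
  }
  kept |>
    select(-"subset_size") |>
    arrange(.data$start)
}
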