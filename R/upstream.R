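# Upstream start/stop codon census, ORF finding, uORF-mORF geometry and
# start-codon (Kozak) context classification.
#
# Geometry conventions (all 1-based inclusive):
#   * uORF length INCLUDES the stop codon, so len_aa = len_nt/3 - 1
#     (111 nt <-> 36 aa for the human upstream ORF);
#   * gap_to_morf = morf_start - stop_end - 1; negative values mean the uORF
#     runs past the main-ORF start (overlap);
#   * census codons are counted by overlapping step-1 scan in any frame and
#     assigned to the section containing their first base.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Census codon set: the four upstream start codons studied alongside ATG and
#' the three stop codons.
#' @export
CENSUS_CODONS <- c("ATG", "GTG", "CTG", "TTG", "ACG", "TAG", "TAA", "TGA")

#' Find all occurrences of a codon in a sequence
#'
#' Overlapping, any-frame, forward-strand scan.
#'
#' @param seq Nucleotide string (T alphabet).
#' @param codon Trinucleotide to search for.
#' @return Integer vector of 1-based start positions.
#' @export
#' @examples
#' scan_codons("ATGATG", "ATG")  # 1, 4
scan_codons <- function(seq, codon) {
  stopifnot(str_length(codon) == 3L)
  n <- str_length(seq)
  if (n < 3L) return(integer(0))
  starts <- seq_len(n - 2L)
  starts[str_sub(seq, starts, starts + 2L) == codon]
}

#' Upstream codon census by 5'UTR section
#'
#' Counts the eight census codons (or any supplied set) within each
#' transcript's 5'UTR, split by section. A codon belongs to the section
#' containing its first base; codons that would straddle the 5'UTR / CDS
#' boundary are excluded.
#'
#' @param transcripts Annotated transcript tibble.
#' @param codons Character vector of trinucleotides (default [CENSUS_CODONS]).
#' @return Tibble `id`, `codon`, `section`, `n`, `positions` (list column of
#'   1-based starts). Sections are "before"/"after" or "whole"; for introned
#'   records before + after counts total the whole-5'UTR count.
#' @export
census_by_section <- function(transcripts, codons = CENSUS_CODONS) {
  secs <- transcript_sections(transcripts)
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    id <- transcripts$id[i]
    len <- transcripts$utr5_len[i]
    utr <- str_sub(transcripts$seq[i], 1L, len)
    sec_i <- secs[secs$id == id, ]
    out <- lapply(codons, function(cd) {
      pos <- scan_codons(utr, cd)
      pos <- pos[pos + 2L <= len]  # drop codons running into the CDS
      sec_of <- sec_i$section[findInterval(pos, sec_i$start)]
      lapply(sec_i$section, function(s) {
        p <- pos[sec_of == s]
        tibble(id = id, codon = cd, section = s, n = length(p),
               positions = list(p))
      })
    })
    bind_rows(unlist(out, recursive = FALSE))
  })
  bind_rows(rows)
}

# translate a coding string (length divisible by 3) to amino acids, stops as *
translate_nt <- function(nt) {
  if (str_length(nt) == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    if.fuzzy.codon = "X"
  ))
}

#' Find open reading frames
#'
#' For every start-codon occurrence (any frame, forward strand) the ORF
#' extends to the first in-frame stop codon, stop included. When no in-frame
#' stop precedes the sequence end the ORF is open-ended: `has_stop` is FALSE
#' and `stop_end` is the last complete-codon base.
#'
#' @param seq Nucleotide string.
#' @param start_codons Codons that may start an ORF (default "ATG").
#' @param min_len_nt Minimum stop-inclusive length to report (default 0).
#' @return Tibble sorted by `start`: `start`, `stop_end`, `len_nt`, `len_aa`,
#'   `peptide` (stop excluded), `has_stop`, `frame` (start mod 3).
#' @export
#' @examples
#' find_orfs("CCATGAAATGATT")  # one ORF: 3..11, peptide "MK"
find_orfs <- function(seq, start_codons = "ATG", min_len_nt = 0L) {
  n <- str_length(seq)
  starts <- sort(unlist(lapply(start_codons, scan_codons, seq = seq)))
  rows <- lapply(starts, function(s) {
    cod_starts <- seq(s, n - 2L, by = 3L)
    if (length(cod_starts) == 0L) return(NULL)
    cods <- str_sub(seq, cod_starts, cod_starts + 2L)
    stop_i <- which(cods %in% STOP_CODONS)
    if (length(stop_i)) {
      k <- stop_i[1]
      stop_end <- cod_starts[k] + 2L
      has_stop <- TRUE
      pep_nt <- if (k > 1L) str_sub(seq, s, cod_starts[k] - 1L) else ""
    } else {
      stop_end <- cod_starts[length(cod_starts)] + 2L
      has_stop <- FALSE
      pep_nt <- str_sub(seq, s, stop_end)
    }
    len_nt <- stop_end - s + 1L
    tibble(
      start = s, stop_end = stop_end, len_nt = len_nt,
      len_aa = if (has_stop) len_nt %/% 3L - 1L else len_nt %/% 3L,
      peptide = translate_nt(pep_nt),
      has_stop = has_stop,
      frame = s %% 3L
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(start = integer(), stop_end = integer(), len_nt = integer(),
                  len_aa = integer(), peptide = character(),
                  has_stop = logical(), frame = integer()))
  }
  out[out$len_nt >= min_len_nt, , drop = FALSE]
}

#' uORF geometry relative to the main ORF
#'
#' Vectorised coordinate arithmetic shared by [characterize_uorf()] and usable
#' directly on printed coordinate tables. Lengths are stop-inclusive.
#'
#' @param start uORF start position (A of the uATG).
#' @param stop_end Last base of the uORF stop codon.
#' @param morf_start Main-ORF start position.
#' @return Tibble `len_nt`, `len_aa`, `frame_offset` ((start - morf_start)
#'   mod 3; 0 means in frame with the main ORF), `gap_to_morf`
#'   (morf_start - stop_end - 1; negative = overlap), `overlaps_morf`.
#' @export
#' @examples
#' uorf_geometry(307, 417, 396)  # the human upstream ORF: 111 nt / 36 aa
uorf_geometry <- function(start, stop_end, morf_start) {
  len_nt <- stop_end - start + 1L
  tibble(
    len_nt = as.integer(len_nt),
    len_aa = as.integer(len_nt %/% 3L - 1L),
    frame_offset = as.integer((start - morf_start) %% 3L),
    gap_to_morf = as.integer(morf_start - stop_end - 1L),
    overlaps_morf = stop_end >= morf_start
  )
}

#' Characterise one called ORF as a uORF
#'
#' @param rec One-row transcript tibble (needs `seq`, `morf_start`).
#' @param orf One-row ORF tibble from [find_orfs()].
#' @return One-row tibble: `id`, `start`, `stop_end`, `len_nt`, `len_aa`,
#'   `peptide`, `frame_offset`, `gap_to_morf`, `overlaps_morf`, `has_stop`.
#' @export
characterize_uorf <- function(rec, orf) {
  if (is.na(rec$morf_start[1])) {
    abort(sprintf("'%s': morf_start required to characterise a uORF",
                  rec$id[1]), class = "utrscape_annotation_error")
  }
  if (orf$start[1] >= rec$morf_start[1]) {
    abort(sprintf("'%s': ORF at %d does not start upstream of the mORF (%d)",
                  rec$id[1], orf$start[1], rec$morf_start[1]),
          class = "utrscape_annotation_error")
  }
  geom <- uorf_geometry(orf$start[1], orf$stop_end[1], rec$morf_start[1])
  tibble(
    id = rec$id[1], start = orf$start[1], stop_end = orf$stop_end[1],
    len_nt = if (orf$has_stop[1]) geom$len_nt else orf$len_nt[1],
    len_aa = if (orf$has_stop[1]) geom$len_aa else orf$len_aa[1],
    peptide = orf$peptide[1],
    frame_offset = geom$frame_offset,
    gap_to_morf = geom$gap_to_morf,
    overlaps_morf = geom$overlaps_morf,
    has_stop = orf$has_stop[1]
  )
}

#' Call uORFs for every transcript
#'
#' Scans each transcript for ORFs starting upstream of the main ORF and
#' returns their uORF records. Open-ended ORFs (no in-frame stop before the
#' sequence end) are flagged and excluded by default.
#'
#' @param transcripts Annotated transcript tibble (`morf_start` required for a
#'   record to contribute).
#' @param start_codons Codons that may start a uORF (default "ATG").
#' @param min_len_nt Minimum stop-inclusive length.
#' @param keep_open Keep open-ended ORFs (default FALSE).
#' @return Tibble of uORF records (see [characterize_uorf()]), plus
#'   `morf_start`.
#' @export
call_uorfs <- function(transcripts, start_codons = "ATG", min_len_nt = 0L,
                       keep_open = FALSE) {
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    rec <- transcripts[i, ]
    if (is.na(rec$morf_start)) return(NULL)
    orfs <- find_orfs(rec$seq, start_codons = start_codons,
                      min_len_nt = min_len_nt)
    orfs <- orfs[orfs$start < rec$morf_start, , drop = FALSE]
    if (!keep_open) orfs <- orfs[orfs$has_stop, , drop = FALSE]
    if (nrow(orfs) == 0L) return(NULL)
    out <- bind_rows(lapply(seq_len(nrow(orfs)), function(j) {
      characterize_uorf(rec, orfs[j, ])
    }))
    out$morf_start <- rec$morf_start
    out
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(id = character(), start = integer(), stop_end = integer(),
                  len_nt = integer(), len_aa = integer(), peptide = character(),
                  frame_offset = integer(), gap_to_morf = integer(),
                  overlaps_morf = logical(), has_stop = logical(),
                  morf_start = integer())
  }
  out
}

# ---- start-codon contexts -------------------------------------------------

#' Extract the 21-nt context window around an ATG
#'
#' The window is laid out as 9 upstream bases + ATG + 9 downstream bases and
#' clipped at the sequence ends, so ATGs near the 5' end yield shorter
#' windows. `minus3` is the base 3 positions upstream of the A, `plus4` the
#' base immediately after the G (missing when clipped away).
#'
#' @param seq Nucleotide string.
#' @param atg_pos Position of the A of the ATG (validated).
#' @return One-row tibble `atg_pos`, `window`, `minus3`, `plus4`.
#' @export
extract_context <- function(seq, atg_pos) {
  n <- str_length(seq)
  if (atg_pos < 1L || atg_pos + 2L > n ||
      str_sub(seq, atg_pos, atg_pos + 2L) != "ATG") {
    abort(sprintf("no ATG at position %d", atg_pos),
          class = "utrscape_range_error")
  }
  lo <- max(1L, atg_pos - 9L)
  hi <- min(n, atg_pos + 11L)
  tibble(
    atg_pos = atg_pos,
    window = str_sub(seq, lo, hi),
    minus3 = if (atg_pos - 3L >= 1L) str_sub(seq, atg_pos - 3L, atg_pos - 3L)
             else NA_character_,
    plus4 = if (atg_pos + 3L <= n) str_sub(seq, atg_pos + 3L, atg_pos + 3L)
            else NA_character_
  )
}

#' Recover -3/+4 bases from a printed context window
#'
#' Interprets a context string as (up to 9) upstream bases + ATG + 9
#' downstream bases, i.e. a window clipped on the left only — the layout used
#' when tabulating start-codon contexts.
#'
#' @param window Context string (12 to 21 characters).
#' @return One-row tibble `window`, `minus3`, `plus4`.
#' @export
parse_context_window <- function(window) {
  up <- str_length(window) - 12L
  if (up < 0L || str_sub(window, up + 1L, up + 3L) != "ATG") {
    abort(sprintf("'%s' is not an upstream-clipped ATG context window",
                  window), class = "utrscape_parse_error")
  }
  tibble(
    window = window,
    minus3 = if (up >= 3L) str_sub(window, up - 2L, up - 2L)
             else NA_character_,
    plus4 = str_sub(window, up + 4L, up + 4L)
  )
}

#' Classify a start-codon context
#'
#' Strong: purine (A/G) at -3 AND G at +4. Weak: neither condition. Adequate:
#' exactly one. Undetermined: -3 or +4 missing (clipped window).
#'
#' @param minus3,plus4 Single bases (or NA), e.g. from [extract_context()].
#' @return Character vector over
#'   `c("strong", "adequate", "weak", "undetermined")`.
#' @export
#' @examples
#' classify_context("A", "G")  # strong
#' classify_context("T", "A")  # weak
classify_context <- function(minus3, plus4) {
  purine <- minus3 %in% c("A", "G") & !is.na(minus3)
  gplus4 <- plus4 == "G" & !is.na(plus4)
  out <- ifelse(purine & gplus4, "strong",
         ifelse(!purine & !gplus4, "weak", "adequate"))
  out[is.na(minus3) | is.na(plus4)] <- "undetermined"
  out
}

#' Codon at a fixed offset from the main-ORF start
#'
#' Offsets count so that -1 is the base immediately 5' of the sATG A; an
#' offset of -9 reads the codon occupying positions -9..-7, which is
#' automatically in frame with the main ORF. The human ortholog family
#' carries a conserved in-frame TGA stop there.
#'
#' @param seq Nucleotide string.
#' @param morf_start Main-ORF start position.
#' @param offset_start Offset of the codon's first base (e.g. -9).
#' @return The trinucleotide string.
#' @export
codon_at_offset <- function(seq, morf_start, offset_start) {
  s <- morf_start + offset_start
  if (s < 1L || s + 2L > str_length(seq)) {
    abort(sprintf("codon window [%d, %d] outside sequence", s, s + 2L),
          class = "utrscape_range_error")
  }
  str_sub(seq, s, s + 2L)
}

#' Start-codon context table for uORFs and main ORFs
#'
#' For each transcript with a called uORF and an annotated main ORF, extracts
#' both context windows, classifies them, and flags a TGA in the -9..-7
#' in-frame codon slot upstream of the sATG.
#'
#' @param transcripts Annotated transcript tibble.
#' @param uorfs uORF records from [call_uorfs()] (one row per transcript is
#'   used: the 5'-most).
#' @return Tibble `id`, `uorf_window`, `uorf_class`, `morf_window`,
#'   `morf_class`, `utga_minus9`.
#' @export
context_table <- function(transcripts, uorfs) {
  first_uorf <- uorfs |>
    group_by(.data$id) |>
    arrange(.data$start, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup()
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    rec <- transcripts[i, ]
    if (is.na(rec$morf_start)) return(NULL)
    u <- first_uorf[first_uorf$id == rec$id, ]
    uctx <- if (nrow(u)) extract_context(rec$seq, u$start[1]) else NULL
    mctx <- extract_context(rec$seq, rec$morf_start)
    minus9 <- if (rec$morf_start - 9L >= 1L) {
      codon_at_offset(rec$seq, rec$morf_start, -9L)
    } else {
      NA_character_
    }
    tibble(
      id = rec$id,
      uorf_window = if (is.null(uctx)) NA_character_ else uctx$window,
      uorf_class = if (is.null(uctx)) NA_character_ else
        classify_context(uctx$minus3, uctx$plus4),
      morf_window = mctx$window,
      morf_class = classify_context(mctx$minus3, mctx$plus4),
      utga_minus9 = !is.na(minus9) && minus9 == "TGA"
    )
  })
  bind_rows(rows)
}
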