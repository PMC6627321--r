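# Sequence, annotation and alignment I/O plus the coordinate system shared by
# every other module.
#
# Conventions (used package-wide):
#   * positions are 1-based inclusive; position 1 is the TSS (first base of the
#     spliced transcript);
#   * sequences are spliced (intron 1 is absent) and stored in the DNA (T)
#     alphabet; RNA input is normalised on read;
#   * the 5'UTR occupies [1, utr5_len]; the before-Intron-1 section is
#     [1, intron1_offset], the after-Intron-1 section
#     [intron1_offset + 1, utr5_len]; intronless transcripts have a single
#     section labelled "whole";
#   * morf_start (the A of the main-ORF ATG), when present, equals
#     utr5_len + 1.

normalize_seq <- function(seq, id = "?") {
  s <- chartr("u", "T", chartr("U", "T", toupper(seq)))
  bad <- !strsplit(s, "", fixed = TRUE)[[1]] %in% UTR_ALPHABET
  if (any(bad)) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]][bad][1]
    abort(
      sprintf("record '%s' contains non-IUPAC character '%s'", id, ch),
      class = "utrscape_parse_error"
    )
  }
  s
}

#' Read 5'UTR (+CDS) sequences from a FASTA file
#'
#' Sequences are upper-cased and U is normalised to T, so RNA input is
#' accepted. Only A, C, G, T and N survive validation; any other character
#' raises a parse error naming the offender. Records keep file order.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A tibble with columns `id`, `species` (initialised to `id`) and
#'   `seq`. Annotations (group, section offsets, main-ORF start) are attached
#'   separately with [read_utr_annotations()] or [annotate_transcripts()].
#' @seealso [write_utr_fasta()], [read_utr_alignment()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgu"), fa)
#' read_utr_fasta(fa)
read_utr_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(
      sprintf("cannot parse FASTA file '%s': %s", path, conditionMessage(e)),
      class = "utrscape_parse_error"
    )
  )
  if (length(set) == 0L) {
    abort(sprintf("FASTA file '%s' contains no records", path),
          class = "utrscape_parse_error")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id '%s'", ids[duplicated(ids)][1]),
          class = "utrscape_parse_error")
  }
  seqs <- as.character(set)
  tibble(
    id = ids,
    species = ids,
    seq = vapply(seq_along(seqs), function(i) normalize_seq(seqs[i], ids[i]), "")
  )
}

#' Write sequences to FASTA
#'
#' @param transcripts A data frame with `id` and a sequence column.
#' @param path Output path.
#' @param seq_col Name of the column holding sequences.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(transcripts, path, seq_col = "seq", width = 60L) {
  stopifnot(all(c("id", seq_col) %in% names(transcripts)))
  lines <- unlist(lapply(seq_len(nrow(transcripts)), function(i) {
    s <- transcripts[[seq_col]][i]
    starts <- seq(1L, str_length(s), by = width)
    c(paste0(">", transcripts$id[i]), str_sub(s, starts, starts + width - 1L))
  }))
  writeLines(lines, path)
  invisible(path)
}

validate_annotation_row <- function(id, seq, utr5_len, intron1_offset, morf_start) {
  if (is.na(utr5_len) || utr5_len < 1L) {
    abort(sprintf("'%s': utr5_len must be a positive count", id),
          class = "utrscape_annotation_error")
  }
  if (!is.na(seq) && utr5_len > str_length(seq)) {
    abort(sprintf("'%s': utr5_len %d exceeds sequence length %d",
                  id, utr5_len, str_length(seq)),
          class = "utrscape_annotation_error")
  }
  if (!is.na(intron1_offset) &&
      (intron1_offset < 1L || intron1_offset >= utr5_len)) {
    abort(sprintf(
      "'%s': intron1_offset %d out of range [1, utr5_len) with utr5_len %d",
      id, intron1_offset, utr5_len), class = "utrscape_annotation_error")
  }
  if (!is.na(morf_start)) {
    if (morf_start != utr5_len + 1L) {
      abort(sprintf("'%s': morf_start %d does not equal utr5_len + 1 = %d",
                    id, morf_start, utr5_len + 1L),
            class = "utrscape_annotation_error")
    }
    if (!is.na(seq) && str_length(seq) >= morf_start + 2L &&
        str_sub(seq, morf_start, morf_start + 2L) != "ATG") {
      abort(sprintf("'%s': no ATG at morf_start %d", id, morf_start),
            class = "utrscape_annotation_error")
    }
  }
  invisible(TRUE)
}

#' Attach per-transcript annotations
#'
#' Joins an annotation table onto a transcript tibble and checks the
#' coordinate invariants: `1 <= intron1_offset < utr5_len`,
#' `morf_start == utr5_len + 1`, and an ATG at `morf_start` when the sequence
#' extends that far. Transcripts with no `intron1_offset` are treated as
#' intronless (their single section is "whole").
#'
#' @param transcripts Tibble from [read_utr_fasta()] (or with at least `id`).
#' @param annotations Data frame with columns `id`, `group`, `utr5_len`,
#'   `intron1_offset` (may be NA), `morf_start` (may be NA); optional
#'   `species`, `intron1_len`, `protein_len`.
#' @return The transcript tibble with annotation columns attached.
#' @export
annotate_transcripts <- function(transcripts, annotations) {
  req <- c("id", "group", "utr5_len")
  missing_cols <- setdiff(req, names(annotations))
  if (length(missing_cols)) {
    abort(paste0("annotation table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "utrscape_annotation_error")
  }
  ann <- as_tibble(annotations)
  for (col in c("intron1_offset", "morf_start", "intron1_len", "protein_len")) {
    if (!col %in% names(ann)) ann[[col]] <- NA_integer_
  }
  ann <- mutate(ann, across(
    all_of(c("utr5_len", "intron1_offset", "morf_start", "intron1_len",
             "protein_len")),
    as.integer
  ))
  unknown <- setdiff(ann$id, transcripts$id)
  if (length(unknown)) {
    abort(sprintf("annotation refers to unknown transcript id '%s'", unknown[1]),
          class = "utrscape_annotation_error")
  }
  out <- left_join(transcripts,
                   select(ann, -any_of(intersect("species", names(ann)))),
                   by = "id")
  if ("species" %in% names(ann)) {
    sp <- setNames(ann$species, ann$id)
    hit <- out$id %in% names(sp)
    out$species[hit] <- unname(sp[out$id[hit]])
  }
  seqs <- if ("seq" %in% names(out)) out$seq else rep(NA_character_, nrow(out))
  for (i in which(!is.na(out$utr5_len))) {
    validate_annotation_row(out$id[i], seqs[i], out$utr5_len[i],
                            out$intron1_offset[i], out$morf_start[i])
  }
  out
}

#' Read a per-transcript annotation table (TSV)
#'
#' The table is tab-separated with '#' comment lines and columns `id`,
#' `group`, `utr5_len`, `intron1_offset` (may be empty), `morf_start` (may be
#' empty); optional `species`, `intron1_len`, `protein_len`.
#'
#' @inheritParams annotate_transcripts
#' @param path Path to the TSV file.
#' @return The transcript tibble with annotations attached and validated.
#' @export
read_utr_annotations <- function(transcripts, path) {
  ann <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  annotate_transcripts(transcripts, ann)
}

#' Section boundaries of each transcript
#'
#' @param transcripts Annotated transcript tibble.
#' @return Tibble with columns `id`, `section` ("before"/"after" for introned
#'   transcripts, "whole" otherwise), `start`, `end` (1-based inclusive).
#' @export
transcript_sections <- function(transcripts) {
  stopifnot(all(c("id", "utr5_len") %in% names(transcripts)))
  off <- if ("intron1_offset" %in% names(transcripts)) {
    transcripts$intron1_offset
  } else {
    rep(NA_integer_, nrow(transcripts))
  }
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    len <- transcripts$utr5_len[i]
    if (is.na(off[i])) {
      tibble(id = transcripts$id[i], section = "whole", start = 1L, end = len)
    } else {
      tibble(id = transcripts$id[i],
             section = c("before", "after"),
             start = c(1L, off[i] + 1L),
             end = c(off[i], len))
    }
  })
  bind_rows(rows)
}

# ---- alignment ------------------------------------------------------------

read_afa <- function(path) {
  set <- Biostrings::readBStringSet(path)
  tibble(id = sub("\\s.*$", "", names(set)), aln_seq = as.character(set))
}

read_clustal <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    abort("empty alignment file", class = "utrscape_parse_error")
  }
  body <- lines[-1]  # drop the CLUSTAL header line
  acc <- list()
  order <- character()
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next  # conservation annotation row
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2L) next
    id <- parts[1]
    seg <- gsub("[0-9]", "", paste(parts[-1], collapse = ""))
    if (!id %in% order) order <- c(order, id)
    acc[[id]] <- paste0(acc[[id]] %||% "", seg)
  }
  if (length(order) == 0L) {
    abort("no alignment rows found in clustal file",
          class = "utrscape_parse_error")
  }
  tibble(id = order, aln_seq = unlist(acc[order], use.names = FALSE))
}

#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA (`"afa"`) or Clustal (`"clustal"`) format. Rows are
#' validated to have equal width; gapped characters are upper-cased with U
#' normalised to T. When `transcripts` is supplied, each ungapped row must
#' reproduce that transcript's 5'UTR (the first `utr5_len` bases, or the full
#' sequence when `utr5_len` is absent) exactly.
#'
#' @param path Path to the alignment file.
#' @param format `"afa"` or `"clustal"`.
#' @param transcripts Optional annotated transcript tibble to link against.
#' @return A tibble with columns `id` and `aln_seq` (class `utr_alignment`);
#'   the alignment width is `attr(x, "ncol")`.
#' @export
read_utr_alignment <- function(path, format = c("afa", "clustal"),
                               transcripts = NULL) {
  format <- match.arg(format)
  aln <- switch(format, afa = read_afa(path), clustal = read_clustal(path))
  aln$aln_seq <- vapply(seq_len(nrow(aln)), function(i) {
    s <- chartr("u", "T", chartr("U", "T", toupper(aln$aln_seq[i])))
    bad <- !strsplit(s, "", fixed = TRUE)[[1]] %in% c(UTR_ALPHABET, "-")
    if (any(bad)) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]][bad][1]
      abort(sprintf("alignment row '%s' contains invalid character '%s'",
                    aln$id[i], ch), class = "utrscape_parse_error")
    }
    s
  }, "")
  as_utr_alignment(aln, transcripts = transcripts)
}

#' Construct/validate an alignment tibble
#'
#' @param aln Data frame with columns `id`, `aln_seq`.
#' @param transcripts Optional transcript tibble for row linkage checks.
#' @return The validated alignment tibble with class `utr_alignment`.
#' @export
as_utr_alignment <- function(aln, transcripts = NULL) {
  stopifnot(all(c("id", "aln_seq") %in% names(aln)))
  widths <- str_length(aln$aln_seq)
  if (length(unique(widths)) != 1L) {
    abort(sprintf(
      "ragged alignment: row widths %s",
      paste(unique(widths), collapse = ", ")), class = "utrscape_parse_error")
  }
  if (anyDuplicated(aln$id)) {
    abort("duplicate row ids in alignment", class = "utrscape_parse_error")
  }
  if (!is.null(transcripts)) {
    unknown <- setdiff(aln$id, transcripts$id)
    if (length(unknown)) {
      abort(sprintf("alignment row '%s' has no matching transcript",
                    unknown[1]), class = "utrscape_parse_error")
    }
    for (i in seq_len(nrow(aln))) {
      tr <- transcripts[transcripts$id == aln$id[i], ]
      ungapped <- gsub("-", "", aln$aln_seq[i], fixed = TRUE)
      expect <- if ("utr5_len" %in% names(tr) && !is.na(tr$utr5_len[1])) {
        str_sub(tr$seq[1], 1L, tr$utr5_len[1])
      } else {
        tr$seq[1]
      }
      if (!identical(ungapped, expect)) {
        abort(sprintf(
          "ungapped alignment row '%s' does not match its transcript 5'UTR",
          aln$id[i]), class = "utrscape_parse_error")
      }
    }
  }
  out <- as_tibble(aln[, c("id", "aln_seq")])
  attr(out, "ncol") <- widths[1]
  class(out) <- c("utr_alignment", class(out))
  out
}

#' Alignment width (number of columns)
#' @param aln A `utr_alignment` tibble.
#' @return Integer column count.
#' @export
alignment_ncol <- function(aln) {
  attr(aln, "ncol") %||% unique(str_length(aln$aln_seq))
}

#' Write an alignment to aligned FASTA or Clustal
#'
#' @param aln Alignment tibble (`id`, `aln_seq`).
#' @param path Output path.
#' @param format `"afa"` or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_utr_alignment <- function(aln, path, format = c("afa", "clustal")) {
  format <- match.arg(format)
  if (format == "afa") {
    write_utr_fasta(aln, path, seq_col = "aln_seq")
  } else {
    namew <- max(str_length(aln$id)) + 3L
    width <- 60L
    ncol <- alignment_ncol(aln)
    lines <- "CLUSTAL W multiple sequence alignment"
    for (start in seq(1L, ncol, by = width)) {
      lines <- c(lines, "")
      block <- str_sub(aln$aln_seq, start, min(start + width - 1L, ncol))
      lines <- c(lines, paste0(str_pad(aln$id, namew, side = "right"), block))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

# ---- column <-> sequence coordinate maps ----------------------------------

#' Map alignment columns to ungapped sequence positions
#'
#' For each row, non-gap columns are numbered 1..n in order (a bijection onto
#' the ungapped sequence positions); gap columns map to NA.
#'
#' @param aln Alignment tibble.
#' @return Tibble with columns `id`, `col`, `base`, `seq_pos` (NA at gaps).
#' @export
alignment_position_map <- function(aln) {
  rows <- lapply(seq_len(nrow(aln)), function(i) {
    cc <- chars(aln$aln_seq[i])
    nongap <- cc != "-"
    tibble(
      id = aln$id[i],
      col = seq_along(cc),
      base = cc,
      seq_pos = ifelse(nongap, cumsum(nongap), NA_integer_)
    )
  })
  bind_rows(rows)
}

#' Project one alignment column onto one row's sequence coordinates
#'
#' @param aln Alignment tibble.
#' @param id Row id.
#' @param col Column index (1-based).
#' @return The 1-based ungapped position, or `NA` when the row carries a gap
#'   at that column.
#' @export
aln_col_to_seq <- function(aln, id, col) {
  ncol <- alignment_ncol(aln)
  if (col < 1L || col > ncol) {
    abort(sprintf("column %d out of range [1, %d]", col, ncol),
          class = "utrscape_range_error")
  }
  row <- aln$aln_seq[match(id, aln$id)]
  if (is.na(row)) {
    abort(sprintf("unknown alignment row '%s'", id),
          class = "utrscape_range_error")
  }
  cc <- chars(str_sub(row, 1L, col))
  if (cc[col] == "-") return(NA_integer_)
  sum(cc != "-")
}
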