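# Alignment-column conservation scoring and hot-spot calling.
#
# Two independent per-column scores:
#   identity  = 100 * modal base count / non-gap count (0 for all-gap columns)
#   occupancy = 100 * non-gap count / number of rows
# A hot spot is a column strictly exceeding BOTH thresholds (defaults 80 and
# 84) — the strict inequalities are what make 50-of-59 the minimum row count
# at the 84% occupancy cut.

aln_char_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$aln_seq, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

#' Per-column identity and occupancy profiles
#'
#' @param aln Alignment tibble (see [read_utr_alignment()]).
#' @return Tibble with one row per alignment column: `col`, base counts
#'   `n_A`..`n_N`, `n_nongap`, `n_gap`, `modal_base` (alphabetically first on
#'   ties; NA for all-gap columns), `identity_pct`, `occupancy_pct`.
#' @export
profile_columns <- function(aln) {
  if (nrow(aln) == 0L) {
    abort("empty alignment", class = "utrscape_range_error")
  }
  m <- aln_char_matrix(aln)
  nrows <- nrow(m)
  counts <- vapply(
    UTR_ALPHABET,
    function(b) colSums(m == b),
    numeric(ncol(m))
  )
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, UTR_ALPHABET))
  n_nongap <- rowSums(counts)
  modal_count <- apply(counts, 1L, max)
  modal_base <- UTR_ALPHABET[apply(counts, 1L, which.max)]
  modal_base[n_nongap == 0] <- NA_character_
  tibble(
    col = seq_len(ncol(m)),
    n_A = as.integer(counts[, "A"]),
    n_C = as.integer(counts[, "C"]),
    n_G = as.integer(counts[, "G"]),
    n_T = as.integer(counts[, "T"]),
    n_N = as.integer(counts[, "N"]),
    n_nongap = as.integer(n_nongap),
    n_gap = as.integer(nrows - n_nongap),
    modal_base = modal_base,
    identity_pct = ifelse(n_nongap > 0, 100 * modal_count / n_nongap, 0),
    occupancy_pct = 100 * n_nongap / nrows
  )
}

#' Minimum row count satisfying a strict occupancy threshold
#'
#' The smallest k with `100 * k / n_total > threshold_pct`. With 59 aligned
#' transcripts and an 84% cut this is 50 sequences.
#'
#' @param n_total Total number of alignment rows.
#' @param threshold_pct Occupancy threshold in percent.
#' @return Integer count.
#' @export
#' @examples
#' min_occupancy_count(59, 84)  # 50
min_occupancy_count <- function(n_total, threshold_pct) {
  stopifnot(n_total >= 1)
  as.integer(floor(n_total * threshold_pct / 100)) + 1L
}

runs_from_columns <- function(cols) {
  if (length(cols) == 0L) {
    return(tibble(run_id = integer(), start_col = integer(),
                  end_col = integer(), length = integer()))
  }
  cols <- sort(unique(cols))
  brk <- c(0L, which(diff(cols) > 1L), length(cols))
  tibble(
    run_id = seq_len(length(brk) - 1L),
    start_col = cols[head(brk, -1L) + 1L],
    end_col = cols[brk[-1L]],
  ) |>
    mutate(length = .data$end_col - .data$start_col + 1L)
}

project_columns <- function(aln, cols, run_id_of) {
  if (length(cols) == 0L) {
    return(tibble(id = character(), run_id = integer(),
                  start = integer(), end = integer()))
  }
  pm <- alignment_position_map(aln)
  pm <- pm[pm$col %in% cols & !is.na(pm$seq_pos), , drop = FALSE]
  if (nrow(pm) == 0L) {
    return(tibble(id = character(), run_id = integer(),
                  start = integer(), end = integer()))
  }
  pm$run_id <- run_id_of[as.character(pm$col)]
  pm |>
    group_by(.data$id, .data$run_id) |>
    arrange(.data$seq_pos, .by_group = TRUE) |>
    summarise(pos = list(.data$seq_pos), .groups = "drop") |>
    mutate(iv = map(.data$pos, function(p) {
      brk <- c(0L, which(diff(p) > 1L), length(p))
      tibble(start = p[head(brk, -1L) + 1L], end = p[brk[-1L]])
    })) |>
    select(-"pos") |>
    tidyr::unnest("iv") |>
    arrange(.data$id, .data$start)
}

#' Call conservation hot spots
#'
#' A hot-spot column strictly exceeds both the identity and the occupancy
#' threshold. Hot spots are grouped into maximal runs of consecutive columns
#' and projected onto each transcript's ungapped coordinates (gap columns are
#' skipped, so one run can project to several sequence intervals).
#'
#' @param profiles Column profiles from [profile_columns()].
#' @param aln The alignment the profiles were computed from.
#' @param identity_min Identity threshold in percent (strict; default 80).
#' @param occupancy_min Occupancy threshold in percent (strict; default 84).
#' @param project Compute per-transcript projections (default TRUE; skip for
#'   column-level screening of many alignments).
#' @return A `utr_hotspots` object: list with `columns` (sorted indices),
#'   `runs` (tibble `run_id`, `start_col`, `end_col`, `length`),
#'   `projections` (tibble `id`, `run_id`, `start`, `end`), and `config`.
#' @export
call_hotspots <- function(profiles, aln, identity_min = 80,
                          occupancy_min = 84, project = TRUE) {
  stopifnot(identity_min >= 0, identity_min <= 100,
            occupancy_min >= 0, occupancy_min <= 100)
  hot <- profiles$col[profiles$identity_pct > identity_min &
                        profiles$occupancy_pct > occupancy_min]
  runs <- runs_from_columns(hot)
  run_id_of <- integer(0)
  if (nrow(runs) > 0L) {
    run_id_of <- unlist(lapply(seq_len(nrow(runs)), function(i) {
      cols <- runs$start_col[i]:runs$end_col[i]
      setNames(rep(runs$run_id[i], length(cols)), cols)
    }))
  }
  structure(
    list(
      columns = sort(hot),
      runs = runs,
      projections = if (project) project_columns(aln, hot, run_id_of) else
        tibble(id = character(), run_id = integer(), start = integer(),
               end = integer()),
      config = list(identity_min = identity_min,
                    occupancy_min = occupancy_min)
    ),
    class = "utr_hotspots"
  )
}

#' @export
print.utr_hotspots <- function(x, ...) {
  cat(sprintf(
    "<utr_hotspots> %d column(s) in %d run(s) (identity > %s%%, occupancy > %s%%)\n",
    length(x$columns), nrow(x$runs),
    x$config$identity_min, x$config$occupancy_min))
  if (nrow(x$runs)) print(x$runs, ...)
  invisible(x)
}

#' @describeIn call_hotspots `tidy()` returns the run table.
#' @param x A `utr_hotspots` object.
#' @param ... Unused.
#' @export
tidy.utr_hotspots <- function(x, ...) x$runs

#' @describeIn call_hotspots `glance()` returns one-row summary counts.
#' @export
glance.utr_hotspots <- function(x, ...) {
  tibble(
    n_columns = length(x$columns),
    n_runs = nrow(x$runs),
    longest_run = if (nrow(x$runs)) max(x$runs$length) else 0L,
    identity_min = x$config$identity_min,
    occupancy_min = x$config$occupancy_min
  )
}

#' Longest run of consecutive hot-spot columns
#'
#' Ties break toward the 5'-most (smallest start column) run; an empty hot-spot
#' set yields length 0.
#'
#' @param hs A `utr_hotspots` object.
#' @return One-row tibble `start_col`, `end_col`, `length`.
#' @export
longest_hotspot_run <- function(hs) {
  runs <- if (inherits(hs, "utr_hotspots")) hs$runs else hs
  if (nrow(runs) == 0L) {
    return(tibble(start_col = NA_integer_, end_col = NA_integer_, length = 0L))
  }
  best <- runs[order(-runs$length, runs$start_col), ][1L, ]
  tibble(start_col = best$start_col, end_col = best$end_col,
         length = best$length)
}

#' Export hot-spot projections as BED-like intervals
#'
#' @param hs A `utr_hotspots` object.
#' @return Tibble `id`, `start` (0-based half-open, BED convention), `end`,
#'   `run_id`.
#' @export
hotspots_as_bed <- function(hs) {
  pr <- hs$projections
  tibble(id = pr$id, start = pr$start - 1L, end = pr$end, run_id = pr$run_id)
}
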