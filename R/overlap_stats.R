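# Variant-hot-spot overlap and group-wise section-length comparisons.

#' Merge closed intervals
#'
#' @param intervals Data frame with `start`, `end` (1-based closed).
#' @return Tibble of sorted, non-overlapping (non-adjacent-merged) intervals.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  iv <- arrange(as_tibble(intervals[, c("start", "end")]), .data$start)
  out_s <- iv$start[1]
  out_e <- iv$end[1]
  if (nrow(iv) > 1L) {
    for (i in 2L:nrow(iv)) {
      if (iv$start[i] <= out_e[length(out_e)] + 1L) {
        out_e[length(out_e)] <- max(out_e[length(out_e)], iv$end[i])
      } else {
        out_s <- c(out_s, iv$start[i])
        out_e <- c(out_e, iv$end[i])
      }
    }
  }
  tibble(start = out_s, end = out_e)
}

#' Variant overlap with hot-spot intervals
#'
#' Counts how many distinct variant positions fall inside the (merged)
#' hot-spot intervals, by closed-interval containment, and reports the
#' percentage rounded to the nearest integer (half away from zero) — 39 of
#' 161 gives 24%.
#'
#' @param positions Integer vector of 1-based variant positions (duplicates
#'   collapse to distinct nts).
#' @param intervals Data frame of hot-spot intervals (`start`, `end`), e.g.
#'   one transcript's rows of `hs$projections`.
#' @return One-row tibble `n_total`, `n_inside`, `pct`.
#' @export
hotspot_overlap <- function(positions, intervals) {
  pos <- sort(unique(as.integer(positions)))
  if (length(pos) == 0L) {
    abort("empty variant set", class = "utrscape_range_error")
  }
  iv <- merge_intervals(intervals)
  inside <- vapply(pos, function(p) any(p >= iv$start & p <= iv$end),
                   logical(1))
  n_in <- sum(inside)
  tibble(
    n_total = length(pos),
    n_inside = n_in,
    pct = as.integer(floor(100 * n_in / length(pos) + 0.5))
  )
}

#' Read a variant position table (TSV)
#'
#' Columns `id`, `pos`, optional `ref`/`alt`; '#' comments allowed.
#'
#' @param path Path to the TSV.
#' @return Tibble of variant records.
#' @export
read_variants <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Group-wise length summaries
#'
#' Collects whole/before/after-section, intron-1 and protein lengths per
#' phylogenetic group and summarises them. Metrics a record lacks
#' (intronless transcripts, missing protein length) are skipped.
#'
#' @param transcripts Annotated transcript tibble.
#' @return A list of class `utr_lengths`: `lengths` (long tibble `group`,
#'   `metric`, `id`, `value`) and `summary` (per group x metric: `n`,
#'   `median`, `min`, `max`).
#' @export
summarize_lengths <- function(transcripts) {
  long <- bind_rows(
    tibble(group = transcripts$group, id = transcripts$id,
           metric = "whole", value = as.integer(transcripts$utr5_len)),
    tibble(group = transcripts$group, id = transcripts$id,
           metric = "before", value = as.integer(transcripts$intron1_offset)),
    tibble(group = transcripts$group, id = transcripts$id,
           metric = "after",
           value = as.integer(transcripts$utr5_len -
                                transcripts$intron1_offset)),
    if ("intron1_len" %in% names(transcripts)) {
      tibble(group = transcripts$group, id = transcripts$id,
             metric = "intron1", value = as.integer(transcripts$intron1_len))
    },
    if ("protein_len" %in% names(transcripts)) {
      tibble(group = transcripts$group, id = transcripts$id,
             metric = "protein", value = as.integer(transcripts$protein_len))
    }
  )
  long <- filter(long, !is.na(.data$value))
  summary <- long |>
    group_by(.data$group, .data$metric) |>
    summarise(n = n(), median = median(.data$value),
              min = min(.data$value), max = max(.data$value),
              .groups = "drop")
  structure(list(lengths = long, summary = summary), class = "utr_lengths")
}

#' @export
print.utr_lengths <- function(x, ...) {
  cat("<utr_lengths>\n")
  print(x$summary, ...)
  invisible(x)
}

#' @describeIn summarize_lengths `tidy()` returns the per-group summary.
#' @param x A `utr_lengths` object.
#' @param ... Unused.
#' @export
tidy.utr_lengths <- function(x, ...) x$summary

#' Pairwise Mann-Whitney tests with Bonferroni correction
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) for every pair of groups on
#' one length metric. Exact p-values are used for small samples
#' (min(n, m) <= 8, no ties), the normal approximation with continuity and
#' tie correction otherwise. The Bonferroni factor is the number of pairs
#' actually tested; corrected p-values cap at 1. Pairs where either group has
#' fewer than 2 observations are skipped with a warning.
#'
#' @param lengths A `utr_lengths` object (or its long `lengths` tibble).
#' @param metric Which metric to compare (e.g. "after").
#' @param correction P-adjustment method (default "bonferroni").
#' @return Tibble `group1`, `group2`, `n1`, `n2`, `statistic` (U), `p_value`,
#'   `p_adjusted`.
#' @export
pairwise_mw <- function(lengths, metric = "whole",
                        correction = "bonferroni") {
  long <- if (inherits(lengths, "utr_lengths")) lengths$lengths else
    as_tibble(lengths)
  dat <- filter(long, .data$metric == !!metric)
  groups <- unique(dat$group)
  if (length(groups) < 2L) {
    abort("need at least two groups to compare",
          class = "utrscape_range_error")
  }
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- dat$value[dat$group == pr[1]]
    y <- dat$value[dat$group == pr[2]]
    if (length(x) < 2L || length(y) < 2L) {
      warn(sprintf("skipping pair %s vs %s: fewer than 2 observations",
                   pr[1], pr[2]))
      return(NULL)
    }
    exact <- min(length(x), length(y)) <= 8L && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = TRUE)
    )
    p <- wt$p.value
    # zero rank variance (all observations tied) carries no evidence
    if (is.na(p) || is.nan(p)) p <- 1
    tibble(group1 = pr[1], group2 = pr[2],
           n1 = length(x), n2 = length(y),
           statistic = unname(wt$statistic), p_value = p)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    abort("no testable group pairs", class = "utrscape_range_error")
  }
  out$p_adjusted <- pmin(1, p.adjust(out$p_value, method = correction,
                                     n = nrow(out)))
  out
}
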