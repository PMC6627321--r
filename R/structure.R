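# Dot-bracket secondary-structure parsing, hairpin-loop enumeration and
# section assignment, plus a deterministic base-pair-maximisation folder used
# as an internal oracle. Thermodynamic (free-energy) folding is deliberately
# not performed: structures are inputs.

#' Read Vienna dot-bracket records
#'
#' Dialect: optional FASTA-style `>` header, a sequence line, then a structure
#' line over `(`, `)`, `.`; a trailing energy annotation in parentheses (e.g.
#' `" (-103.40)"`) is tolerated and ignored. Multiple records per file are
#' supported.
#'
#' @param path Path to the Vienna file.
#' @return Tibble `id`, `seq`, `struct`; structures are validated for
#'   balanced nesting.
#' @export
read_dotbracket <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  rows <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    id <- if (startsWith(lines[i], ">")) {
      hdr <- sub("^>", "", lines[i])
      i <- i + 1L
      sub("\\s.*$", "", hdr)
    } else {
      sprintf("structure_%d", k + 1L)
    }
    if (i + 1L > length(lines)) {
      abort("truncated dot-bracket record", class = "utrscape_parse_error")
    }
    seq <- normalize_seq(lines[i], id)
    struct <- sub("\\s*\\([-0-9.]+\\)\\s*$", "", lines[i + 1L])
    if (str_length(struct) != str_length(seq)) {
      abort(sprintf("'%s': structure length %d != sequence length %d",
                    id, str_length(struct), str_length(seq)),
            class = "utrscape_parse_error")
    }
    pair_table(struct)  # validates
    k <- k + 1L
    rows[[k]] <- tibble(id = id, seq = seq, struct = struct)
    i <- i + 2L
  }
  if (k == 0L) abort("empty dot-bracket file", class = "utrscape_parse_error")
  bind_rows(rows)
}

#' Base-pair partner table of a dot-bracket string
#'
#' @param struct String over `(`, `)`, `.`.
#' @return Integer vector `p` with `p[i] = j` iff i pairs with j, 0 for
#'   unpaired positions. Unbalanced brackets raise an error (crossing pairs
#'   cannot be expressed in plain dot-bracket).
#' @export
#' @examples
#' pair_table("(())")  # 4 3 2 1
pair_table <- function(struct) {
  cc <- chars(struct)
  bad <- !cc %in% c("(", ")", ".")
  if (any(bad)) {
    abort(sprintf("invalid structure character '%s'", cc[bad][1]),
          class = "utrscape_parse_error")
  }
  p <- integer(length(cc))
  stack <- integer(0)
  for (i in seq_along(cc)) {
    if (cc[i] == "(") {
      stack <- c(stack, i)
    } else if (cc[i] == ")") {
      if (length(stack) == 0L) {
        abort(sprintf("unbalanced ')' at position %d", i),
              class = "utrscape_parse_error")
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[j] <- i
      p[i] <- j
    }
  }
  if (length(stack)) {
    abort(sprintf("unbalanced '(' at position %d", stack[1]),
          class = "utrscape_parse_error")
  }
  p
}

#' Enumerate hairpin loops
#'
#' A hairpin loop is a base pair (i, j) whose interior contains only unpaired
#' bases, with at least one of them (loop length >= 1).
#'
#' @param struct Dot-bracket string, or a one-row tibble with a `struct`
#'   column.
#' @return Tibble `i`, `j`, `loop_len` (= j - i - 1), sorted by `i`.
#' @export
#' @examples
#' enumerate_hairpins("((((...))))")  # one loop of length 3
enumerate_hairpins <- function(struct) {
  if (is.data.frame(struct)) struct <- struct$struct[1]
  p <- pair_table(struct)
  rows <- list()
  for (i in seq_along(p)) {
    j <- p[i]
    if (j > i && j - i - 1L >= 1L && all(p[(i + 1L):(j - 1L)] == 0L)) {
      rows[[length(rows) + 1L]] <- tibble(i = i, j = j,
                                          loop_len = j - i - 1L)
    }
  }
  if (length(rows) == 0L) {
    return(tibble(i = integer(), j = integer(), loop_len = integer()))
  }
  arrange(bind_rows(rows), .data$i)
}

#' Assign hairpin loops to 5'UTR sections
#'
#' A loop's section is the section containing the midpoint
#' `floor((i + j) / 2)` of its closing pair; a midpoint exactly at the
#' boundary falls in the before-section. Loops whose closing pair straddles
#' the boundary are additionally flagged as spanning.
#'
#' @param loops Tibble from [enumerate_hairpins()].
#' @param intron1_offset Last position of the before-Intron-1 section, or NA
#'   for an intronless transcript (every loop is then "whole").
#' @return `loops` with `midpoint`, `section`, `spans_boundary` added.
#' @export
assign_sections <- function(loops, intron1_offset) {
  mid <- (loops$i + loops$j) %/% 2L
  if (is.na(intron1_offset)) {
    section <- rep("whole", nrow(loops))
    spans <- rep(FALSE, nrow(loops))
  } else {
    section <- ifelse(mid <= intron1_offset, "before", "after")
    spans <- loops$i <= intron1_offset & loops$j > intron1_offset
  }
  mutate(loops, midpoint = mid, section = section, spans_boundary = spans)
}

#' Hairpin counts per section (summary-table layout)
#'
#' @param loops Output of [assign_sections()].
#' @return One-row tibble `before`, `after`, `whole` (spanning loops count
#'   with their midpoint's section).
#' @export
hairpin_section_counts <- function(loops) {
  tibble(
    before = sum(loops$section == "before"),
    after = sum(loops$section == "after"),
    whole = sum(loops$section == "whole")
  )
}

# ---- base-pair maximisation (internal oracle folder) ----------------------

PAIRABLE <- list(A = "T", T = c("A", "G"), G = c("C", "T"), C = "G")

can_pair <- function(a, b) {
  !is.null(PAIRABLE[[a]]) && b %in% PAIRABLE[[a]]
}

#' Maximum base-pair folding (Nussinov dynamic programme)
#'
#' Folds a sequence by maximising the number of nested Watson-Crick or GU
#' wobble pairs (AU, UA, GC, CG, GU, UG; T is read as U) with hairpin loops
#' of at least `min_loop` unpaired bases. The traceback is deterministic:
#' leaving i unpaired is preferred only when pairing cannot do better, and i
#' pairs with the smallest j achieving the optimum. This is a
#' combinatorial-structure generator for testing hairpin analysis, not a
#' thermodynamic prediction.
#'
#' @param seq Nucleotide string (T or U alphabet).
#' @param min_loop Minimum hairpin-loop length (default 3).
#' @return One-row tibble `seq`, `struct`, `n_pairs`.
#' @export
#' @examples
#' maxpair_fold("GGGAAACCC")  # "(((...)))"
maxpair_fold <- function(seq, min_loop = 3L) {
  s <- chars(chartr("Uu", "TT", toupper(seq)))
  n <- length(s)
  if (n < min_loop + 2L) {
    return(tibble(seq = unchars(s), struct = strrep(".", n), n_pairs = 0L))
  }
  M <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- M[i + 1L, j]  # i unpaired
      for (k in (i + min_loop + 1L):j) {
        if (can_pair(s[i], s[k])) {
          inner <- if (k - i - 1L >= 1L) M[i + 1L, k - 1L] else 0L
          rest <- if (k + 1L <= j) M[k + 1L, j] else 0L
          best <- max(best, 1L + inner + rest)
        }
      }
      M[i, j] <- best
    }
  }
  struct <- rep(".", n)
  trace <- function(i, j) {
    while (i < j) {
      if (j - i < min_loop + 1L) return(invisible())
      if (M[i, j] == M[i + 1L, j]) {
        # check whether pairing i could do equally well; prefer pairing
        paired <- FALSE
        for (k in (i + min_loop + 1L):j) {
          if (can_pair(s[i], s[k])) {
            inner <- if (k - i - 1L >= 1L) M[i + 1L, k - 1L] else 0L
            rest <- if (k + 1L <= j) M[k + 1L, j] else 0L
            if (1L + inner + rest == M[i, j]) {
              struct[i] <<- "("
              struct[k] <<- ")"
              if (k - i - 1L >= 1L) trace(i + 1L, k - 1L)
              i <- k + 1L
              paired <- TRUE
              break
            }
          }
        }
        if (!paired) i <- i + 1L
      } else {
        for (k in (i + min_loop + 1L):j) {
          if (can_pair(s[i], s[k])) {
            inner <- if (k - i - 1L >= 1L) M[i + 1L, k - 1L] else 0L
            rest <- if (k + 1L <= j) M[k + 1L, j] else 0L
            if (1L + inner + rest == M[i, j]) {
              struct[i] <<- "("
              struct[k] <<- ")"
              if (k - i - 1L >= 1L) trace(i + 1L, k - 1L)
              i <- k + 1L
              break
            }
          }
        }
      }
    }
    invisible()
  }
  trace(1L, n)
  tibble(seq = unchars(s), struct = unchars(struct),
         n_pairs = as.integer(M[1L, n]))
}
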