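# Independent brute-force oracles used to check the production code paths.
# These are deliberately naive (loops, exhaustive recursion) so they share no
# machinery with the implementation they verify.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive overlapping-window codon scan
oracle_scan_codons <- function(seq, codon) {
  hits <- integer(0)
  if (nchar(seq) < 3) return(hits)
  for (i in 1:(nchar(seq) - 2)) {
    if (substr(seq, i, i + 2) == codon) hits <- c(hits, i)
  }
  hits
}

# exhaustive ORF enumeration: every start-codon occurrence, walk codons to
# the first stop
oracle_find_orfs <- function(seq, start_codons = "ATG") {
  n <- nchar(seq)
  out <- list()
  for (s in seq_len(max(n - 2, 0))) {
    if (!substr(seq, s, s + 2) %in% start_codons) next
    stop_end <- NA
    pos <- s
    while (pos + 2 <= n) {
      cod <- substr(seq, pos, pos + 2)
      if (pos > s && cod %in% c("TAA", "TAG", "TGA")) {
        stop_end <- pos + 2
        break
      }
      pos <- pos + 3
    }
    has_stop <- !is.na(stop_end)
    if (!has_stop) {
      k <- (n - s + 1) %/% 3
      if (k == 0) next
      stop_end <- s + 3 * k - 1
    }
    out[[length(out) + 1]] <- data.frame(start = s, stop_end = stop_end,
                                         has_stop = has_stop)
  }
  do.call(rbind, out)
}

# hairpin check: a pair (i, j) is a hairpin iff nothing inside is paired
oracle_hairpins <- function(struct) {
  p <- utrscape::pair_table(struct)
  res <- list()
  for (i in seq_along(p)) {
    j <- p[i]
    if (j <= i || j - i - 1 < 1) next
    interior_unpaired <- TRUE
    for (q in (i + 1):(j - 1)) {
      if (p[q] != 0) interior_unpaired <- FALSE
    }
    if (interior_unpaired) {
      res[[length(res) + 1]] <- data.frame(i = i, j = j)
    }
  }
  do.call(rbind, res)
}

# independent linear-scan hairpin counter: number of "(" immediately
# followed (skipping dots) by ")"
oracle_hairpin_count <- function(struct) {
  cc <- strsplit(struct, "")[[1]]
  count <- 0
  last_open <- FALSE
  for (ch in cc) {
    if (ch == "(") last_open <- TRUE
    if (ch == ")") {
      if (last_open) count <- count + 1
      last_open <- FALSE
    }
  }
  count
}

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

# exhaustive (unmemoised) enumeration of nested pairings
oracle_maxpairs <- function(s, i = 1, j = nchar(s), min_loop = 3) {
  cc <- strsplit(chartr("U", "T", s), "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (oracle_can_pair(cc[i], cc[k])) {
        best <- max(best, 1 + rec(i + 1, k - 1) + rec(k + 1, j))
      }
    }
    best
  }
  rec(i, j)
}

# random valid dot-bracket structure by recursive construction
random_struct <- function(n) {
  if (n <= 0) return("")
  if (n < 5 || runif(1) < 0.4) {
    return(paste0(".", random_struct(n - 1)))
  }
  inner <- sample(1:(n - 2), 1)
  paste0("(", random_struct(inner), ")", random_struct(n - inner - 2))
}

# brute-force column -> sequence position map
oracle_col_to_seq <- function(gapped, col) {
  cc <- strsplit(gapped, "")[[1]]
  if (cc[col] == "-") return(NA_integer_)
  sum(cc[1:col] != "-")
}

# two-sided exact Mann-Whitney p by full permutation enumeration
oracle_mw_exact_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(all_v), n)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  obs <- u_stat(x, y)
  m <- length(all_v) - n
  us <- apply(idx, 2, function(ii) u_stat(all_v[ii], all_v[-ii]))
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

DEFAULT_GROUPS_for_test <- function() utrscape:::DEFAULT_GROUPS()

# tiny annotated family used by several suites
toy_transcripts <- function() {
  ann <- tibble::tibble(
    id = c("a", "b", "c"),
    group = c("primates", "primates", "rodents"),
    utr5_len = c(12L, 10L, 12L),
    intron1_offset = c(6L, NA, 4L),
    morf_start = c(13L, 11L, 13L)
  )
  tr <- tibble::tibble(
    id = c("a", "b", "c"),
    species = c("a", "b", "c"),
    seq = c("ACGTACGTACGTATGCCC",  # utr 12 + ATG + CDS
            "GGGCCCGGGCATGAAA",
            "TTTTAAAATTTTATGGGG")
  )
  utrscape::annotate_transcripts(tr, ann)
}
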