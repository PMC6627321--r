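# Seeded synthetic ortholog-family generator with recorded ground truth.
#
# The generator emulates the statistical structure the analysis assumes for a
# vertebrate 5'UTR ortholog family:
#   * group-constant after-Intron-1 lengths, variable before-Intron-1 lengths;
#   * a short highly conserved block (default 15 nt) at the start of the
#     after-Intron-1 section containing the family's single upstream ATG,
#     out of frame with the main ORF;
#   * a planted uORF from that uATG whose stop sits at a configured gap to
#     (or overlap with) the main ORF, banded per group;
#   * section-specific GC composition;
#   * an alignment emitted directly from the consensus (no external aligner):
#     rows differ by substitution (background `sub_rate`, block
#     `block_sub_rate`), by 5' truncation of the before-section, and by
#     before-section deletions at `indel_rate`.
#
# Substitutions redraw the base from the section's stationary composition, so
# per-section GC stays on target in expectation. Codon-critical positions
# (planted uATG, uORF stop, main-ORF ATG) are never mutated or deleted;
# stray upstream ATGs and premature in-frame stops are rewritten so the
# planted uORF is exactly what an ORF caller should find.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

DEFAULT_GROUPS <- function() {
  tibble(
    label = c("primates", "rodents", "other_placental", "reptiles_birds"),
    n_species = c(5L, 5L, 5L, 5L),
    after_len = c(99L, 90L, 84L, 69L),
    before_min = c(240L, 180L, 150L, 60L),
    before_max = c(340L, 280L, 250L, 160L),
    relation = c("overlap", "gap", "gap", "gap"),
    k = c(22L, 5L, 8L, 17L)
  )
}

#' Specify a synthetic ortholog family
#'
#' Defaults describe an ABCA1-like family of 20 species in four groups:
#' after-Intron-1 lengths constant within groups; a 15-nt conserved block
#' (mutated at 2%) opening the after-section and carrying the single upstream
#' ATG; uORF-to-mORF relations banded by group (primates overlapping by 22
#' nt, rodents/placentals with single-digit gaps, birds/reptiles with a gap
#' under 20); before/after GC targets of 58.7% / 67.4%; background
#' substitution 35%, before-section deletions 2%.
#'
#' @param groups Tibble with columns `label`, `n_species`, `after_len`,
#'   `before_min`, `before_max`, `relation` ("gap"/"overlap"), `k`.
#' @param conserved_block Block sequence placed at after-section positions
#'   1..nchar(block); must contain exactly one ATG.
#' @param uatg_offset Offset of that ATG within the block (A position).
#' @param gc_before,gc_after Per-section GC targets (percent).
#' @param sub_rate,block_sub_rate Substitution probabilities outside/inside
#'   the block (a substitution redraws from the section composition).
#' @param indel_rate Per-base deletion probability in the before-section.
#' @param cds_len Length of CDS sequence appended after the main-ORF ATG.
#' @param seed Integer seed; all randomness flows through it.
#' @return A validated `utr_family_spec` list.
#' @export
utr_family_spec <- function(groups = DEFAULT_GROUPS(),
                            conserved_block = "GTTAATGACCAGCCA",
                            uatg_offset = 5L,
                            gc_before = 58.7, gc_after = 67.4,
                            sub_rate = 0.35, block_sub_rate = 0.02,
                            indel_rate = 0.02, cds_len = 30L,
                            seed = 0L) {
  spec <- list(
    groups = as_tibble(groups), conserved_block = conserved_block,
    uatg_offset = as.integer(uatg_offset),
    gc_before = gc_before, gc_after = gc_after,
    sub_rate = sub_rate, block_sub_rate = block_sub_rate,
    indel_rate = indel_rate, cds_len = as.integer(cds_len),
    seed = as.integer(seed)
  )
  validate_family_spec(spec)
  class(spec) <- "utr_family_spec"
  spec
}

validate_family_spec <- function(spec) {
  for (r in c("sub_rate", "block_sub_rate", "indel_rate")) {
    if (spec[[r]] < 0 || spec[[r]] > 1) {
      abort(sprintf("%s must be in [0, 1]", r), class = "utrscape_spec_error")
    }
  }
  if (length(scan_codons(spec$conserved_block, "ATG")) != 1L) {
    abort("conserved_block must contain exactly one ATG",
          class = "utrscape_spec_error")
  }
  if (scan_codons(spec$conserved_block, "ATG") != spec$uatg_offset) {
    abort("uatg_offset does not point at the block's ATG",
          class = "utrscape_spec_error")
  }
  g <- spec$groups
  need <- c("label", "n_species", "after_len", "before_min", "before_max",
            "relation", "k")
  if (!all(need %in% names(g))) {
    abort("groups table lacks required columns", class = "utrscape_spec_error")
  }
  for (i in seq_len(nrow(g))) {
    len_nt <- planted_uorf_len(spec, i)
    if (len_nt < 6L || len_nt %% 3L != 0L) {
      abort(sprintf(
        "group '%s': implied uORF length %d is not a positive multiple of 3",
        g$label[i], len_nt), class = "utrscape_spec_error")
    }
    # uATG must be out of frame with the main ORF
    if ((spec$uatg_offset - g$after_len[i] - 1L) %% 3L == 0L) {
      abort(sprintf("group '%s': planted uATG would be in frame with the mORF",
                    g$label[i]), class = "utrscape_spec_error")
    }
    if (g$relation[i] == "overlap" && g$k[i] > spec$cds_len + 3L - 3L) {
      abort(sprintf("group '%s': overlap k exceeds available CDS",
                    g$label[i]), class = "utrscape_spec_error")
    }
  }
  invisible(spec)
}

# stop-inclusive uORF length implied by a group's geometry
planted_uorf_len <- function(spec, group_i) {
  g <- spec$groups[group_i, ]
  base <- g$after_len - spec$uatg_offset + 1L
  if (g$relation == "gap") base - g$k else base + g$k
}

gc_probs <- function(gc_pct) {
  p <- gc_pct / 100
  c(A = (1 - p) / 2, C = p / 2, G = p / 2, T = (1 - p) / 2)
}

random_bases <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# shuffled sequence with the target composition enforced exactly (largest
# remainder apportionment), so consensus GC sits on target rather than
# drifting by a whole-family-shared sampling error
exact_composition_bases <- function(n, probs) {
  raw <- probs / sum(probs) * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    # allocate the rounding shortfall stochastically in proportion to the
    # fractional remainders; deterministic (largest-remainder) allocation
    # would bias composition whenever remainders tie
    rem <- raw - counts
    extra <- sample(names(probs), short, prob = rem + 1e-12)
    for (b in extra) counts[b] <- counts[b] + 1
  }
  sample(rep(names(probs), times = counts))
}

# composition enforced exactly within consecutive chunks, so every prefix
# and suffix of the consensus also sits on target to within one chunk
stratified_bases <- function(n, probs, chunk = 20L) {
  out <- character(0)
  left <- n
  while (left > 0L) {
    k <- min(chunk, left)
    out <- c(out, exact_composition_bases(k, probs))
    left <- left - k
  }
  out
}

# with prob `rate`, redraw each unprotected position from `probs`
mutate_bases <- function(bases, rate, probs, protected = integer(0)) {
  hit <- which(runif(length(bases)) < rate)
  hit <- setdiff(hit, protected)
  if (length(hit)) bases[hit] <- random_bases(length(hit), probs)
  bases
}

#' Generate a synthetic ortholog family with ground truth
#'
#' Emits annotated transcripts, a consensus-derived alignment and a ground
#' truth table. Deterministic given `spec$seed`; the same spec yields
#' byte-identical output.
#'
#' @param spec A [utr_family_spec()].
#' @return List with `transcripts` (annotated tibble), `alignment`
#'   (`utr_alignment` tibble), `truth` (per-record tibble: planted uORF and
#'   block coordinates, section lengths) and `block_cols` (alignment columns
#'   of the conserved block).
#' @export
generate_family <- function(spec) {
  validate_family_spec(spec)
  with_local_seed(spec$seed, {
    g <- spec$groups
    bmax <- max(g$before_max)
    amax <- max(g$after_len)
    blk <- chars(spec$conserved_block)
    blen <- length(blk)
    p_before <- gc_probs(spec$gc_before)
    p_after <- gc_probs(spec$gc_after)

    cons_before <- stratified_bases(bmax, p_before)
    cons_after <- stratified_bases(amax, p_after)
    cons_after[seq_len(blen)] <- blk
    cons_cds <- random_bases(spec$cds_len, p_after)

    rows <- list()
    truths <- list()
    aln_rows <- list()
    for (gi in seq_len(nrow(g))) {
      a <- g$after_len[gi]
      len_nt <- planted_uorf_len(spec, gi)
      for (si in seq_len(g$n_species[gi])) {
        id <- sprintf("%s_%02d", g$label[gi], si)
        b0 <- g$before_min[gi] +
          sample.int(g$before_max[gi] - g$before_min[gi] + 1L, 1L) - 1L
        before <- mutate_bases(tail(cons_before, b0), spec$sub_rate, p_before)
        keep <- runif(b0) >= spec$indel_rate
        # protect the ATG codon slot inside the after-section block
        prot_after <- spec$uatg_offset:(spec$uatg_offset + 2L)
        after <- cons_after[seq_len(a)]
        after[seq_len(blen)] <- mutate_bases(after[seq_len(blen)],
                                             spec$block_sub_rate, p_after,
                                             protected = prot_after)
        if (a > blen) {
          idx <- (blen + 1L):a
          after[idx] <- mutate_bases(after[idx], spec$sub_rate, p_after)
        }
        cds <- mutate_bases(cons_cds, spec$sub_rate, p_after)

        b <- sum(keep)
        utr5_len <- b + a
        morf_start <- utr5_len + 1L
        start_at <- b + spec$uatg_offset
        stop_end <- start_at + len_nt - 1L
        seq_chars <- c(before[keep], after, c("A", "T", "G"), cds)
        seq_chars <- enforce_planted_orf(seq_chars, start_at, stop_end,
                                         morf_start)
        # rebuild mutated segments so alignment rows stay consistent
        after_final <- seq_chars[(b + 1L):(b + a)]
        before_final <- seq_chars[seq_len(b)]
        before_row <- character(b0)
        before_row[!keep] <- "-"
        before_row[keep] <- before_final
        # alignment covers the 5'UTR only (before + after sections)
        aln_rows[[id]] <- unchars(c(
          rep("-", bmax - b0), before_row, after_final, rep("-", amax - a)
        ))
        rows[[id]] <- tibble(
          id = id, species = id, group = g$label[gi],
          seq = unchars(seq_chars),
          utr5_len = utr5_len, intron1_offset = b,
          morf_start = morf_start, intron1_len = NA_integer_,
          protein_len = NA_integer_
        )
        truths[[id]] <- tibble(
          id = id, group = g$label[gi],
          before_len = b, after_len = a,
          uorf_start = start_at, uorf_stop_end = stop_end,
          uorf_len_nt = len_nt,
          relation = g$relation[gi], k = g$k[gi],
          block_start = b + 1L, block_end = b + blen,
          gc_before = spec$gc_before, gc_after = spec$gc_after
        )
      }
    }
    transcripts <- bind_rows(rows)
    truth <- bind_rows(truths)
    aln <- as_utr_alignment(
      tibble(id = names(aln_rows),
             aln_seq = unlist(aln_rows, use.names = FALSE)),
      transcripts = transcripts
    )
    list(
      transcripts = transcripts,
      alignment = aln,
      truth = truth,
      block_cols = (bmax + 1L):(bmax + blen),
      spec = spec
    )
  })
}

# Rewrite stray upstream ATGs and premature in-frame stops so the planted
# uORF coordinates are exactly what an ORF caller must return. Setting bases
# to C can neither create an ATG nor a stop codon, so the pass converges in
# one sweep.
enforce_planted_orf <- function(s, start_at, stop_end, morf_start) {
  protected <- c(start_at:(start_at + 2L), (stop_end - 2L):stop_end,
                 morf_start:(morf_start + 2L))
  # planted codons
  s[start_at:(start_at + 2L)] <- c("A", "T", "G")
  s[(stop_end - 2L):stop_end] <- c("T", "G", "A")
  # stray upstream ATGs: prefer rewriting the A to T (ATG -> TTG), which is
  # GC-neutral and can create neither an ATG (would need a new A) nor a stop
  # (no stop codon has T in its middle or at its end); fall back to setting
  # an unprotected base to C
  for (pos in seq_len(morf_start - 2L)) {
    if (pos == start_at) next
    if (s[pos] == "A" && s[pos + 1L] == "T" && s[pos + 2L] == "G") {
      if (!pos %in% protected) {
        s[pos] <- "T"
      } else {
        cand <- pos + c(1L, 2L)
        tgt <- cand[!cand %in% protected][1]
        if (!is.na(tgt)) s[tgt] <- "C"
      }
    }
  }
  # premature in-frame stops within the planted uORF
  interior <- if (stop_end - 3L >= start_at + 3L) {
    seq(start_at + 3L, stop_end - 3L, by = 3L)
  } else {
    integer(0)
  }
  for (pos in interior) {
    cod <- unchars(s[pos:(pos + 2L)])
    if (cod %in% c("TAA", "TAG", "TGA")) {
      cand <- pos + c(1L, 2L, 0L)
      tgt <- cand[!cand %in% protected][1]
      if (!is.na(tgt)) s[tgt] <- "C"
    }
  }
  s
}

#' Plant variant positions with controlled hot-spot overlap
#'
#' Samples exactly `n_inside` distinct positions inside the supplied
#' intervals and `n_total - n_inside` outside, uniformly without replacement
#' within `[1, utr5_len]`.
#'
#' @param utr5_len Length of the target 5'UTR.
#' @param hs_intervals Data frame of hot-spot intervals (`start`, `end`).
#' @param n_total,n_inside Total and inside-hot-spot variant counts.
#' @param seed Integer seed.
#' @return Tibble `pos` (sorted), `in_hotspot`.
#' @export
plant_variants <- function(utr5_len, hs_intervals, n_total, n_inside,
                           seed = 0L) {
  iv <- merge_intervals(hs_intervals)
  all_pos <- seq_len(utr5_len)
  inside_pool <- all_pos[vapply(all_pos, function(p)
    any(p >= iv$start & p <= iv$end), logical(1))]
  outside_pool <- setdiff(all_pos, inside_pool)
  if (n_inside > length(inside_pool) ||
      n_total - n_inside > length(outside_pool)) {
    abort(sprintf(
      "infeasible variant counts: need %d inside (pool %d) and %d outside (pool %d)",
      n_inside, length(inside_pool), n_total - n_inside,
      length(outside_pool)), class = "utrscape_spec_error")
  }
  with_local_seed(seed, {
    pos <- sort(c(sample(inside_pool, n_inside),
                  sample(outside_pool, n_total - n_inside)))
    tibble(pos = pos, in_hotspot = pos %in% inside_pool)
  })
}

#' Plant a base-repetition-rich block into a uniform background
#'
#' Builds a sequence of uniform random bases with one block whose subset
#' fraction is controlled. The block's off-subset bases are placed in its
#' interior middle third so the planted boundaries are sharp: a background
#' run of subset bases abutting the block is statistically indistinguishable
#' from block extension, so edge placement is the identifiable choice.
#'
#' @param length Total sequence length.
#' @param block_start,block_len Block coordinates.
#' @param subset Character vector of block bases (e.g. `c("G", "A")`).
#' @param fraction Subset fraction inside the block (default 0.9).
#' @param seed Integer seed.
#' @return List with `seq` and `truth` (tibble `label`, `start`, `end`,
#'   `fraction`).
#' @export
plant_composition_block <- function(length, block_start, block_len,
                                    subset = c("G", "A"), fraction = 0.9,
                                    seed = 0L) {
  stopifnot(block_start >= 1L, block_start + block_len - 1L <= length)
  with_local_seed(seed, {
    s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    blk <- sample(subset, block_len, replace = TRUE)
    n_off <- floor((1 - fraction) * block_len)
    if (n_off > 0L) {
      third <- max(1L, block_len %/% 3L)
      interior <- (third + 1L):(block_len - third)
      at <- sample(interior, n_off)
      blk[at] <- sample(setdiff(c("A", "C", "G", "T"), subset), n_off,
                        replace = TRUE)
    }
    idx <- block_start:(block_start + block_len - 1L)
    s[idx] <- blk
    list(
      seq = unchars(s),
      truth = tibble(label = paste(subset, collapse = "/"),
                     start = block_start,
                     end = block_start + block_len - 1L,
                     fraction = sum(blk %in% subset) / block_len)
    )
  })
}

#' Plant stem-loops into a synthetic dot-bracket structure
#'
#' Builds a valid dot-bracket record with exactly one hairpin loop per
#' requested start position; all other positions are unpaired.
#'
#' @param length Total sequence length.
#' @param loop_starts Start positions of the stem-loops (1-based; each
#'   occupies `2 * stem_len + loop_len` positions).
#' @param stem_len Paired stem length (default 3).
#' @param loop_len Unpaired loop length (default 4).
#' @return One-row tibble `id`, `seq`, `struct`.
#' @export
plant_stemloops <- function(length, loop_starts, stem_len = 3L,
                            loop_len = 4L) {
  width <- 2L * stem_len + loop_len
  loop_starts <- sort(as.integer(loop_starts))
  ends <- loop_starts + width - 1L
  if (any(ends > length) || any(loop_starts < 1L)) {
    abort("stem-loop outside sequence", class = "utrscape_spec_error")
  }
  if (any(diff(loop_starts) < width)) {
    abort("overlapping stem-loops", class = "utrscape_spec_error")
  }
  seq <- rep("A", length)
  struct <- rep(".", length)
  for (s in loop_starts) {
    seq[s:(s + stem_len - 1L)] <- "G"
    seq[(s + stem_len):(s + stem_len + loop_len - 1L)] <- "A"
    seq[(s + stem_len + loop_len):(s + width - 1L)] <- "C"
    struct[s:(s + stem_len - 1L)] <- "("
    struct[(s + stem_len + loop_len):(s + width - 1L)] <- ")"
  }
  tibble(id = "synthetic_stemloops", seq = unchars(seq),
         struct = unchars(struct))
}
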