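# Pipeline driver: runs every analysis stage over one ortholog family and
# assembles a combined report. Deterministic given its inputs; the run log
# records package version and parameters (no timestamps), so identical inputs
# give byte-identical serialised reports.

default_pipeline_params <- function() {
  list(
    conservation = list(identity_min = 80, occupancy_min = 84),
    orf = list(start_codons = "ATG", min_len_nt = 0L),
    composition = list(window = 30L, step = 1L, fraction_min = 0.8,
                       min_len = 20L, merge_gap = 5L, segments = TRUE),
    stats = list(metric = "after", correction = "bonferroni")
  )
}

merge_params <- function(user) {
  p <- default_pipeline_params()
  for (blk in names(user)) {
    if (!blk %in% names(p)) p[[blk]] <- list()
    for (key in names(user[[blk]])) p[[blk]][[key]] <- user[[blk]][[key]]
  }
  p
}

stage_error <- function(stage, parent) {
  abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(parent)),
        class = "utrscape_stage_error")
}

#' Run the full 5'UTR feature pipeline
#'
#' Stage order: section lengths -> alignment conservation -> codon census ->
#' uORFs and contexts -> GC/segment composition -> secondary structure ->
#' variant overlap. Stages needing optional inputs (alignment, structures,
#' variants) run only when those inputs are present, unless explicitly
#' requested in `stages`, in which case a missing input is a configuration
#' error naming the stage.
#'
#' @param transcripts Annotated transcript tibble.
#' @param alignment Optional `utr_alignment` tibble.
#' @param structures Optional dot-bracket tibble ([read_dotbracket()]).
#' @param variants Optional variant tibble (`id`, `pos`).
#' @param params Nested list overriding [default_pipeline_params()].
#' @param stages Character vector of stages to run (default: all whose
#'   inputs are available).
#' @return A `utr_report`: list with one element per stage plus `params` and
#'   `log`.
#' @export
run_utr_pipeline <- function(transcripts, alignment = NULL,
                             structures = NULL, variants = NULL,
                             params = list(), stages = NULL) {
  p <- merge_params(params)
  auto <- c("lengths", "codons", "uorfs", "composition",
            if (!is.null(alignment)) "conservation",
            if (!is.null(structures)) "structure",
            if (!is.null(variants)) "variants")
  stages <- stages %||% auto
  if ("conservation" %in% stages && is.null(alignment)) {
    abort("stage 'conservation': alignment input required but not supplied",
          class = "utrscape_config_error")
  }
  if ("structure" %in% stages && is.null(structures)) {
    abort("stage 'structure': dot-bracket input required but not supplied",
          class = "utrscape_config_error")
  }
  if ("variants" %in% stages &&
      (is.null(variants) || !"conservation" %in% stages)) {
    abort("stage 'variants': variant table and conservation stage required",
          class = "utrscape_config_error")
  }

  report <- list()
  if ("lengths" %in% stages) {
    report$lengths <- tryCatch({
      lt <- summarize_lengths(transcripts)
      mw <- tryCatch(
        pairwise_mw(lt, metric = p$stats$metric,
                    correction = p$stats$correction),
        error = function(e) NULL
      )
      list(summary = lt$summary, pairwise = mw)
    }, error = function(e) stage_error("lengths", e))
  }
  hotspots <- NULL
  if ("conservation" %in% stages) {
    report$conservation <- tryCatch({
      prof <- profile_columns(alignment)
      hotspots <- call_hotspots(prof, alignment,
                                 identity_min = p$conservation$identity_min,
                                 occupancy_min = p$conservation$occupancy_min)
      list(summary = glance(hotspots), runs = hotspots$runs,
           projections = hotspots$projections,
           longest_run = longest_hotspot_run(hotspots))
    }, error = function(e) stage_error("conservation", e))
  }
  if ("codons" %in% stages) {
    report$codons <- tryCatch(
      select(census_by_section(transcripts), -"positions"),
      error = function(e) stage_error("codons", e))
  }
  uorfs <- NULL
  if ("uorfs" %in% stages) {
    report$uorfs <- tryCatch({
      uorfs <- call_uorfs(transcripts,
                           start_codons = p$orf$start_codons,
                           min_len_nt = p$orf$min_len_nt)
      list(table = make_table1_like(transcripts, uorfs),
           contexts = context_table(transcripts, uorfs))
    }, error = function(e) stage_error("uorfs", e))
  }
  if ("composition" %in% stages) {
    report$composition <- tryCatch({
      segs <- NULL
      if (isTRUE(p$composition$segments)) {
        segs <- bind_rows(lapply(seq_len(nrow(transcripts)), function(i) {
          s <- segment_repetition_regions(
            str_sub(transcripts$seq[i], 1L, transcripts$utr5_len[i]),
            window = p$composition$window, step = p$composition$step,
            fraction_min = p$composition$fraction_min,
            min_len = p$composition$min_len,
            merge_gap = p$composition$merge_gap)
          if (nrow(s)) mutate(s, id = transcripts$id[i], .before = 1L) else NULL
        }))
      }
      list(gc = section_gc(transcripts), segments = segs)
    }, error = function(e) stage_error("composition", e))
  }
  if ("structure" %in% stages) {
    report$structure <- tryCatch({
      bind_rows(lapply(seq_len(nrow(structures)), function(i) {
        rec <- structures[i, ]
        off <- transcripts$intron1_offset[match(rec$id, transcripts$id)]
        loops <- assign_sections(enumerate_hairpins(rec$struct),
                                 if (length(off)) off else NA_integer_)
        mutate(hairpin_section_counts(loops), id = rec$id,
               n_loops = nrow(loops), .before = 1L)
      }))
    }, error = function(e) stage_error("structure", e))
  }
  if ("variants" %in% stages) {
    report$variants <- tryCatch({
      bind_rows(lapply(unique(variants$id), function(vid) {
        pr <- hotspots$projections[hotspots$projections$id == vid, ]
        ov <- hotspot_overlap(variants$pos[variants$id == vid], pr)
        mutate(ov, id = vid, .before = 1L)
      }))
    }, error = function(e) stage_error("variants", e))
  }

  report$params <- p
  report$log <- list(
    package = "utrscape",
    version = as.character(utils::packageVersion("utrscape")),
    n_transcripts = nrow(transcripts),
    stages = stages
  )
  class(report) <- "utr_report"
  report
}

#' @export
print.utr_report <- function(x, ...) {
  cat("<utr_report> stages:",
      paste(setdiff(names(x), c("params", "log")), collapse = ", "), "\n")
  invisible(x)
}

#' Run the pipeline from a YAML configuration file
#'
#' The config has an `inputs:` block (`fasta`, `annotations`, optional
#' `alignment`, `alignment_format`, `structures`, `variants`) and optional
#' per-stage parameter blocks under `params:` mirroring
#' [default_pipeline_params()].
#'
#' @param config_path Path to the YAML file.
#' @return A `utr_report`.
#' @export
run_utr_pipeline_config <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  inp <- cfg$inputs
  if (is.null(inp$fasta) || is.null(inp$annotations)) {
    abort("config must provide inputs: fasta and annotations",
          class = "utrscape_config_error")
  }
  for (f in unlist(inp[c("fasta", "annotations", "alignment", "structures",
                         "variants")])) {
    if (!file.exists(f)) {
      abort(sprintf("input file '%s' does not exist", f),
            class = "utrscape_config_error")
    }
  }
  transcripts <- read_utr_annotations(read_utr_fasta(inp$fasta),
                                      inp$annotations)
  alignment <- if (!is.null(inp$alignment)) {
    read_utr_alignment(inp$alignment,
                       format = inp$alignment_format %||% "afa",
                       transcripts = transcripts)
  }
  structures <- if (!is.null(inp$structures)) read_dotbracket(inp$structures)
  variants <- if (!is.null(inp$variants)) read_variants(inp$variants)
  run_utr_pipeline(transcripts, alignment = alignment,
                   structures = structures, variants = variants,
                   params = cfg$params %||% list(),
                   stages = cfg$stages)
}

#' Write a report bundle to disk
#'
#' Emits one TSV per tabular stage output plus a combined `report.json`.
#' Output is deterministic for identical inputs.
#'
#' @param report A `utr_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_utr_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(x, name) {
    if (is.data.frame(x)) {
      readr::write_tsv(x, file.path(dir, paste0(name, ".tsv")),
                       progress = FALSE)
    } else if (is.list(x)) {
      for (nm in names(x)) {
        if (!is.null(x[[nm]])) emit(x[[nm]], paste0(name, "_", nm))
      }
    }
  }
  for (stage in setdiff(names(report), c("params", "log"))) {
    emit(report[[stage]], stage)
  }
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Summary table of called uORFs (one row per transcript)
#'
#' Mirrors the comparative uORF table layout: start/stop coordinates,
#' stop-inclusive length, peptide, main-ORF start and gap/overlap geometry.
#' Transcripts without a called uORF keep NA feature fields. When a
#' transcript has several uORFs the 5'-most is shown.
#'
#' @param transcripts Annotated transcript tibble (row order kept).
#' @param uorfs uORF records from [call_uorfs()].
#' @return Tibble `id`, `species`, `group`, `start`, `stop_end`, `len_nt`,
#'   `len_aa`, `peptide`, `morf_start`, `gap_to_morf`, `overlaps_morf`.
#' @export
make_table1_like <- function(transcripts, uorfs) {
  first_uorf <- uorfs |>
    group_by(.data$id) |>
    arrange(.data$start, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup() |>
    select("id", "start", "stop_end", "len_nt", "len_aa", "peptide",
           "gap_to_morf", "overlaps_morf")
  transcripts |>
    select("id", "species",
           any_of("group"), "morf_start") |>
    left_join(first_uorf, by = "id") |>
    select("id", "species", any_of("group"), "start", "stop_end", "len_nt",
           "len_aa", "peptide", "morf_start", "gap_to_morf", "overlaps_morf")
}
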