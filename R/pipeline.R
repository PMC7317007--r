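# End-to-end orchestration: structure -> partition -> diversity -> trees
# -> ranking -> primers, driven by one config, writing a plain-file
# report bundle (TSV/FASTA/newick/JSON) plus a machine-readable manifest.
# Everything is deterministic under a fixed seed.

#' Pipeline run configuration
#'
#' Either `simulate` (a list of [simulation_config()] arguments) or
#' `reference_genbank` + `alignment_fasta` must be given.
#'
#' @param simulate Optional list of arguments for [simulation_config()].
#' @param reference_genbank,alignment_fasta,reference_tree Input paths
#'   (GenBank record, alignment FASTA, optional newick tree replacing
#'   the built-in NJ full-plastome tree).
#' @param ref_taxon Alignment row to use as the annotated reference;
#'   defaults to the GenBank record id (or the simulated reference).
#' @param mask_threshold Gap/ambiguity masking threshold (default 0.8).
#' @param window,step Sliding-window size and step in columns (800/200).
#' @param bootstrap_full,bootstrap_marker Bootstrap replicates for the
#'   full alignment (1000) and per marker (100).
#' @param weights Ranking weights (variable, bootstrap, distance).
#' @param top_k Concatenated-subset sizes (default 5 and 10).
#' @param primer_max_len Size filter for primer design (default 900 bp).
#' @param min_ir_len Minimum inverted-repeat length (default 1000 bp).
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = NULL, reference_genbank = NULL,
                       alignment_fasta = NULL, reference_tree = NULL,
                       ref_taxon = NULL, mask_threshold = 0.8,
                       window = 800L, step = 200L,
                       bootstrap_full = 1000L, bootstrap_marker = 100L,
                       weights = c(1, 2, 3), top_k = c(5L, 10L),
                       primer_max_len = 900, min_ir_len = 1000L,
                       seed = 1L, out_dir = tempfile("plastomarker_run_")) {
  stopifnot(mask_threshold > 0, mask_threshold <= 1, window > 0, step > 0,
            bootstrap_full >= 1, bootstrap_marker >= 1, all(weights > 0),
            all(top_k > 0), primer_max_len > 0)
  if (is.null(simulate) && (is.null(reference_genbank) || is.null(alignment_fasta))) {
    stop("run_config(): give either `simulate` or both `reference_genbank` and `alignment_fasta`")
  }
  structure(as.list(environment()), class = "run_config")
}

degenerate_partition <- function(n) {
  part <- tibble::tibble(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = c(0L, 0L, 0L, 0L),
    length = c(n, 0L, 0L, 0L)
  )
  structure(part, class = c("region_partition", class(part)),
            genome_length = n, ir_length = 0L, degenerate = TRUE)
}

#' Run the full marker-survey pipeline
#'
#' Executes every stage in order and writes the report bundle to
#' `config$out_dir`: `composition.tsv` (per-region architecture),
#' `partition.json`, `markers.tsv`, `metrics.tsv`, `ranked.tsv`,
#' `windows.tsv`, `full_tree.nwk`, per-`top_k` concatenated FASTA +
#' tree, `primers.tsv` and `manifest.json`. A stage failure aborts with
#' the stage name; files already written are retained.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[plastomarker] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  warnings_seen <- character()
  note_warning <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  out <- function(f) file.path(config$out_dir, f)

  # -- inputs ---------------------------------------------------------------
  sim <- NULL
  inputs <- stage("inputs", withCallingHandlers({
    if (!is.null(config$simulate)) {
      sc <- do.call(simulation_config,
                    utils::modifyList(config$simulate, list(seed = config$seed)))
      sim <- simulate_alignment(sc)
      list(reference = sim$reference, aln = sim$alignment,
           ref_tree_external = NULL, sim = sim)
    } else {
      ref <- read_genbank(config$reference_genbank)
      aln <- read_alignment_fasta(config$alignment_fasta)
      ext <- if (!is.null(config$reference_tree)) {
        read_newick_file(config$reference_tree)
      }
      list(reference = ref, aln = aln, ref_tree_external = ext, sim = NULL)
    }
  }, warning = note_warning))
  reference <- inputs$reference
  say("inputs: ", nrow(inputs$aln), " taxa x ", ncol(inputs$aln), " columns; reference ",
      reference$id, " (", nchar(reference$sequence), " bp)")

  # -- structure ------------------------------------------------------------
  part <- stage("structure", withCallingHandlers({
    if (reference$circular) {
      find_inverted_repeat(reference, min_len = config$min_ir_len)
    } else {
      degenerate_partition(nchar(reference$sequence))
    }
  }, warning = note_warning))
  comp <- stage("structure", composition_table(reference, part))
  write_report_tsv(comp, out("composition.tsv"))
  jsonlite::write_json(
    list(genome_length = attr(part, "genome_length"),
         ir_length = attr(part, "ir_length"),
         degenerate = attr(part, "degenerate"),
         regions = as.data.frame(part)),
    out("partition.json"), auto_unbox = TRUE, pretty = TRUE)
  say("structure: IR length ", attr(part, "ir_length"), " bp",
      if (attr(part, "degenerate")) " (degenerate)")

  # -- masking + partition into markers ------------------------------------
  ref_taxon <- config$ref_taxon %||% reference$id
  masked <- stage("partition", withCallingHandlers({
    m <- mask_columns(inputs$aln, config$mask_threshold)
    cmap <- build_column_map(m$alignment, ref_taxon)
    if (length(cmap$map) != nchar(reference$sequence)) {
      stop("reference row (", length(cmap$map), " residues after masking) ",
           "does not match the annotated reference (",
           nchar(reference$sequence), " bp)")
    }
    markers <- partition_markers(reference, cmap)
    list(aln = m$alignment, removed = m$removed, cmap = cmap, markers = markers)
  }, warning = note_warning))
  markers_tbl <- dplyr::mutate(
    masked$markers,
    n_intervals = vapply(.data$cols, nrow, 1L),
    n_columns = vapply(.data$cols, function(m) sum(m[, 2] - m[, 1]), 1L)
  )
  write_report_tsv(dplyr::select(markers_tbl, "marker", "class",
                                 "n_intervals", "n_columns"),
                   out("markers.tsv"))
  say("partition: ", nrow(masked$markers), " markers (",
      length(masked$removed), " columns masked)")

  # -- diversity ------------------------------------------------------------
  wins <- stage("diversity", withCallingHandlers(
    sliding_window_pi(masked$aln, config$window, config$step, masked$cmap),
    warning = note_warning))
  write_report_tsv(as.data.frame(wins), out("windows.tsv"))
  say("diversity: ", nrow(wins), " windows; mean pi ",
      signif(mean(wins$pi, na.rm = TRUE), 4))

  # -- trees ----------------------------------------------------------------
  full_tree <- stage("trees", withCallingHandlers({
    if (!is.null(inputs$ref_tree_external)) inputs$ref_tree_external
    else bootstrap_support(masked$aln, B = config$bootstrap_full,
                           seed = substream_seed(config$seed, 1L))
  }, warning = note_warning))
  writeLines(write_newick(full_tree), out("full_tree.nwk"))
  metrics <- stage("trees", withCallingHandlers(
    marker_metrics(masked$aln, masked$markers, reference_tree = full_tree,
                   B = config$bootstrap_marker,
                   seed = substream_seed(config$seed, 2L)),
    warning = note_warning))
  write_report_tsv(
    dplyr::select(metrics, "marker", "class", "n_taxa", "bp_mean", "bp_min",
                  "bp_max", "aligned_bp", "variable_sites", "pis",
                  "gap_sites", "mean_k80", "tree_distance",
                  "mean_bootstrap", "usable"),
    out("metrics.tsv"))
  say("trees: ", sum(metrics$usable), "/", nrow(metrics), " markers usable")

  # -- ranking + concatenated subsets ---------------------------------------
  ranked <- stage("rank", withCallingHandlers(
    rank_markers(metrics, weights = config$weights),
    warning = note_warning))
  write_report_tsv(
    dplyr::select(ranked, "rank", "marker", "class", "variable_sites",
                  "mean_bootstrap", "tree_distance", "r_var", "r_bs",
                  "r_dist", "score"),
    out("ranked.tsv"))
  say("rank: best marker ", ranked$marker[1], " (score ",
      signif(ranked$score[1], 4), ")")
  for (k in config$top_k) {
    if (k > nrow(ranked)) next
    top <- select_top(ranked, k)
    defs <- masked$markers[match(top, masked$markers$marker), ]
    cat_aln <- concatenate_markers(masked$aln, defs)
    write_alignment_fasta(cat_aln, out(sprintf("top%d.fasta", k)))
    tr <- stage("rank", withCallingHandlers(
      bootstrap_support(cat_aln, B = config$bootstrap_marker,
                        seed = substream_seed(config$seed, 3L + k)),
      warning = note_warning))
    writeLines(write_newick(tr), out(sprintf("top%d.nwk", k)))
  }

  # -- primers --------------------------------------------------------------
  primers <- stage("primers", withCallingHandlers({
    short <- size_filter(ranked, config$primer_max_len)
    short <- short[seq_len(min(5L, nrow(short))), , drop = FALSE]
    rows <- purrr::map(seq_len(nrow(short)), function(i) {
      def <- masked$markers[masked$markers$marker == short$marker[i], ]
      span <- def$ref_span[[1]]
      target <- c(min(span[, 1]), max(span[, 2]))
      pp <- pick_primers(reference, target)
      if (nrow(pp) == 0L) return(NULL)
      dplyr::bind_cols(tibble::tibble(marker = short$marker[i]), pp)
    })
    dplyr::bind_rows(rows)
  }, warning = note_warning))
  if (nrow(primers) == 0L) {
    primers <- tibble::tibble(marker = character(), forward = character(),
                              reverse = character(), product_size = integer())
  }
  write_report_tsv(primers, out("primers.tsv"))
  say("primers: ", nrow(primers), " pair(s) designed")

  # -- manifest -------------------------------------------------------------
  cfg_json <- config
  cfg_json$simulate <- if (!is.null(config$simulate)) config$simulate else NULL
  manifest <- list(
    package = "plastomarker",
    version = as.character(utils::packageVersion("plastomarker")),
    seed = config$seed,
    config = cfg_json[setdiff(names(cfg_json), "out_dir")],
    warnings = warnings_seen
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  invisible(list(
    out_dir = config$out_dir, reference = reference, partition = part,
    composition = comp, markers = masked$markers, metrics = metrics,
    ranked = ranked, windows = wins, full_tree = full_tree,
    primers = primers, sim = inputs$sim
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
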