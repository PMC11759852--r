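#' Design an epegRNA library for a curated locus
#'
#' End-to-end design stage: enumerate spacers across the coding region,
#' build editing windows over the classified catalog, select windows under
#' the chosen strategy, add stop-gain (PTC) controls reachable within each
#' selected window, construct every epegRNA and PE3 nicking gRNA, emit
#' order sheets, validate the truth sets and build the k-mer dictionary.
#'
#' @param ctx a [gene_context()].
#' @param records classified variant data.frame (catalog).
#' @param params a [design_params()].
#' @param strategy `"vus"` or `"controls"` (see [select_windows()]).
#' @param n_target number of windows (libraries) to design.
#' @param k k-mer length for the dictionary.
#' @param amplicon_len amplicon length modelled around each window
#'   (< 250 bp).
#' @return object of class `pegmave_design`: windows, per-window variants,
#'   designs, rejections, nicking gRNAs, order sheets, amplicons,
#'   dictionary and truth-set report.
#' @export
design_library <- function(ctx, records, params = design_params(),
                           strategy = "vus", n_target = 2L, k = 25L,
                           amplicon_len = 240L) {
  region <- c(max(1L, min(ctx$cds$start) - params$max_edit_offset),
              min(nchar(ctx$sequence),
                  max(ctx$cds$end) + params$max_edit_offset))
  spacers <- enumerate_spacers(ctx, region)
  windows <- build_windows(spacers, records, params)
  selected <- select_windows(windows, records, strategy = strategy,
                             n_target = n_target, params = params)

  ## add PTC controls reachable within each selected window, then
  ## re-truncate to the library cap under the class priority
  ptc <- do.call(rbind, lapply(selected, function(w)
    suppressWarnings(generate_ptc_controls(ctx, c(w$edit_start,
                                                  w$edit_end)))))
  ptc <- ptc[!duplicated(ptc$variant) &
               !ptc$variant %in% records$variant, , drop = FALSE]
  all_vars <- rbind(records, ptc)
  selected <- lapply(selected, function(w) {
    hit <- all_vars$pos >= w$edit_start & all_vars$pos <= w$edit_end
    w$variant_ids <- all_vars$variant[hit]
    truncate_window(w, all_vars, strategy, params$library_cap)
  })

  designs <- list(); rejections <- list(); lib_rows <- list()
  for (w in selected) {
    for (vid in w$variant_ids) {
      v <- all_vars[match(vid, all_vars$variant), , drop = FALSE]
      d <- design_epegrna(w, v, ctx, params)
      if (inherits(d, "design_rejection")) {
        rejections[[length(rejections) + 1L]] <- d
      } else {
        designs[[length(designs) + 1L]] <- d
        lib_rows[[length(lib_rows) + 1L]] <- data.frame(
          variant = vid, window_id = w$window_id,
          class_label = v$class_label, pos = v$pos, ref = v$ref,
          alt = v$alt, stringsAsFactors = FALSE)
      }
    }
  }
  library_variants <- do.call(rbind, lib_rows)
  ngrnas <- lapply(selected, design_nicking, ctx = ctx, params = params)
  ngrnas <- Filter(function(g) inherits(g, "nicking_grna"), ngrnas)

  amplicons <- lapply(selected, function(w) {
    mid <- (w$edit_start + w$edit_end) %/% 2L
    start <- min(max(1L, mid - amplicon_len %/% 2L),
                 nchar(ctx$sequence) - amplicon_len + 1L)
    c(start, start + amplicon_len - 1L)
  })
  names(amplicons) <- vapply(selected, function(w) w$window_id, "")

  structure(list(
    windows = selected, variants = library_variants, designs = designs,
    rejections = rejections, ngrnas = ngrnas,
    sheets = emit_order_sheets(designs, ngrnas, params),
    amplicons = amplicons,
    dictionary = build_dictionary(designs, ctx, k = k,
                                  amplicons = amplicons),
    truth_report = validate_truth_sets(all_vars[
      all_vars$variant %in% library_variants$variant, , drop = FALSE]),
    ## one archetypal epegRNA represents each candidate window worth
    ## screening; the pre-screen should cover at least min_archetypes
    archetype_check = check_archetype_count(
      sum(vapply(windows, function(w) length(w$variant_ids) > 0L, TRUE)),
      params$min_archetypes),
    params = params, strategy = strategy
  ), class = "pegmave_design")
}

#' @export
print.pegmave_design <- function(x, ...) {
  cat(sprintf(
    "pegmave_design (%s strategy): %d window(s), %d epegRNA(s), %d nicking gRNA(s)\n",
    x$strategy, length(x$windows), length(x$designs), length(x$ngrnas)))
  print(x$truth_report)
  invisible(x)
}

#' Run the full simulated pipeline
#'
#' Generates a synthetic locus and catalogs, parses and classifies them,
#' designs the epegRNA library, simulates edited-cell pools and paired-end
#' amplicon reads, counts dictionary k-mers, applies depth QC, scores
#' variants and evaluates truth-set separation. Used for validation and
#' as the end-to-end smoke path.
#'
#' @param config a [sim_config()].
#' @param dir working directory for generated files.
#' @param params a [design_params()].
#' @param strategy,n_target,k passed to [design_library()].
#' @param af_threshold unselected-pool AF filter.
#' @param min_reads depth-QC minimum.
#' @return list with every intermediate: `locus`, `records`, `design`,
#'   `pools`, `sample_sheet`, `counts`, `depth`, `scores`, `separation`.
#' @export
run_pipeline <- function(config = sim_config(), dir = tempfile(),
                         params = design_params(), strategy = "vus",
                         n_target = 2L, k = 25L, af_threshold = 0.001,
                         min_reads = 200000L) {
  locus <- make_synthetic_locus(config, dir)
  cv <- parse_clinvar_export(locus$clinvar_tsv)
  gn <- parse_gnomad_export(locus$gnomad_csv)
  records <- classify_variants(rbind(cv$records, gn$records))
  des <- design_library(locus$ctx, records, params = params,
                        strategy = strategy, n_target = n_target, k = k,
                        amplicon_len = config$amplicon_len)
  pools <- simulate_pools(config, des$variants)
  sheet <- write_fastq(pools, des$variants, locus$ctx, des$amplicons,
                       config, dir = file.path(dir, "fastq"))
  fc <- count_kmers(sheet$file, des$dictionary)
  counts <- counts_to_table(fc, sheet)
  depth <- depth_qc(counts, min_reads = min_reads)
  scores <- score_variants(counts, classes = des$variants,
                           af_threshold = af_threshold)
  separation <- evaluate_truth_sets(scores)
  list(config = config, locus = locus, records = records, design = des,
       pools = pools, sample_sheet = sheet, counts = counts,
       depth = depth, scores = scores, separation = separation)
}
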