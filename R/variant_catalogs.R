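#' Parse a ClinVar per-gene missense export
#'
#' Reads the tab-separated table exported from the ClinVar web portal
#' (filtered for missense variants) into a variant table. Export dialects
#' drift, so columns are addressed through a logical field map; extra
#' columns are tolerated. Single-nucleotide variants are resolved from the
#' Canonical SPDI column; rows that cannot be resolved to an SNV are
#' returned as rejects with a reason.
#'
#' @param path TSV file as downloaded from ClinVar.
#' @param field_map named list mapping logical fields (`name`,
#'   `significance`, `spdi`) to column headers.
#' @return list with `records` (variant data.frame, one row per SNV;
#'   clinical significance preserved verbatim in `significance_raw`) and
#'   `rejects` (data.frame with `name`, `reason`).
#' @export
parse_clinvar_export <- function(path,
                                 field_map = list(
                                   name = "Name",
                                   significance = "Clinical significance (Last reviewed)",
                                   spdi = "Canonical SPDI")) {
  if (!file.exists(path)) stop("cannot read ClinVar export: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (f in c("name", "significance", "spdi"))
    if (!field_map[[f]] %in% names(tab))
      stop(sprintf("ClinVar export lacks mapped column '%s' (logical field '%s')",
                   field_map[[f]], f))
  rec <- list(); rej <- list()
  for (i in seq_len(nrow(tab))) {
    spdi <- tab[[field_map$spdi]][i]
    nm <- tab[[field_map$name]][i]
    parts <- strsplit(spdi, ":", fixed = TRUE)[[1]]
    if (length(parts) != 4L || !.is_base(parts[3]) || !.is_base(parts[4])) {
      rej[[length(rej) + 1L]] <- data.frame(
        name = nm, reason = "not_snv", stringsAsFactors = FALSE)
      next
    }
    pos0 <- suppressWarnings(as.integer(parts[2]))
    if (is.na(pos0)) {
      rej[[length(rej) + 1L]] <- data.frame(
        name = nm, reason = "bad_record", stringsAsFactors = FALSE)
      next
    }
    contig <- parts[1]; ref <- parts[3]; alt <- parts[4]
    pos <- pos0 + 1L  # SPDI positions are 0-based
    rec[[length(rec) + 1L]] <- data.frame(
      variant = variant_id(contig, pos, ref, alt),
      source = "clinvar", contig = contig, pos = pos, ref = ref, alt = alt,
      hgvs_c = nm, hgvs_p = NA_character_,
      consequence = "missense",
      significance_raw = tab[[field_map$significance]][i],
      class_label = NA_character_, allele_count = NA_integer_,
      stringsAsFactors = FALSE)
  }
  list(
    records = if (length(rec)) do.call(rbind, rec) else .empty_variant_df(),
    rejects = if (length(rej)) do.call(rbind, rej)
              else data.frame(name = character(0), reason = character(0))
  )
}

#' Parse a gnomAD per-gene variant export
#'
#' Reads the CSV exported from the gnomAD browser (filtered for missense
#' and synonymous variants). Columns are addressed through a logical field
#' map with defaults matching the browser export; extra columns are
#' tolerated. Records carry the gnomAD allele count; consequences are
#' normalised to missense/synonymous/other.
#'
#' @param path CSV file as exported from gnomAD.
#' @param field_map named list mapping logical fields (`chrom`, `pos`,
#'   `ref`, `alt`, `consequence`, `allele_count`) to column headers.
#' @return list with `records` and `rejects` as in
#'   [parse_clinvar_export()].
#' @export
parse_gnomad_export <- function(path,
                                field_map = list(
                                  chrom = "Chromosome", pos = "Position",
                                  ref = "Reference", alt = "Alternate",
                                  consequence = "VEP Annotation",
                                  allele_count = "Allele Count")) {
  if (!file.exists(path)) stop("cannot read gnomAD export: ", path)
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (f in names(field_map))
    if (!field_map[[f]] %in% names(tab))
      stop(sprintf("gnomAD export lacks mapped column '%s' (logical field '%s')",
                   field_map[[f]], f))
  rec <- list(); rej <- list()
  for (i in seq_len(nrow(tab))) {
    ref <- toupper(tab[[field_map$ref]][i])
    alt <- toupper(tab[[field_map$alt]][i])
    nm <- sprintf("%s-%s-%s-%s", tab[[field_map$chrom]][i],
                  tab[[field_map$pos]][i], ref, alt)
    if (!.is_base(ref) || !.is_base(alt) || ref == alt) {
      rej[[length(rej) + 1L]] <- data.frame(
        name = nm, reason = "not_snv", stringsAsFactors = FALSE)
      next
    }
    ac_raw <- tab[[field_map$allele_count]][i]
    ac <- suppressWarnings(as.integer(ac_raw))
    if (is.na(ac) || ac != as.numeric(ac_raw))
      stop(sprintf("non-integer allele count '%s' in gnomAD export row %d",
                   as.character(ac_raw), i))
    csq_raw <- tolower(tab[[field_map$consequence]][i])
    csq <- if (grepl("synonymous", csq_raw)) "synonymous"
           else if (grepl("missense", csq_raw)) "missense"
           else "other"
    pos <- as.integer(tab[[field_map$pos]][i])
    contig <- as.character(tab[[field_map$chrom]][i])
    rec[[length(rec) + 1L]] <- data.frame(
      variant = variant_id(contig, pos, ref, alt),
      source = "gnomad", contig = contig, pos = pos, ref = ref, alt = alt,
      hgvs_c = NA_character_, hgvs_p = NA_character_,
      consequence = csq, significance_raw = NA_character_,
      class_label = NA_character_, allele_count = ac,
      stringsAsFactors = FALSE)
  }
  list(
    records = if (length(rec)) do.call(rbind, rec) else .empty_variant_df(),
    rejects = if (length(rej)) do.call(rbind, rej)
              else data.frame(name = character(0), reason = character(0))
  )
}

## normalise a ClinVar significance cell: strip the "(Last reviewed ...)"
## suffix, lower-case, collapse whitespace
.norm_significance <- function(x) {
  x <- sub("\\s*\\(last reviewed.*$", "", tolower(x))
  trimws(gsub("\\s+", " ", x))
}

#' Classify variants into assay truth-set classes
#'
#' Pure, deterministic classification: ClinVar missense records become PLP
#' (pathogenic / likely pathogenic), BLB (benign / likely benign) or VUS
#' from their significance text (case-insensitive; compound or conflicting
#' significances are conservatively classed OTHER). gnomAD records at or
#' above the minimal allele count become POP_SYN or POP_MISSENSE; below it
#' they are OTHER. Designed nonsense records become PTC_CTRL. The function
#' is idempotent: reclassifying classified records is a no-op.
#'
#' @param records variant data.frame from the parsers.
#' @param ac_min minimal gnomAD allele count for population controls.
#'   Default 5 suits dominant-disease genes; raise it substantially for
#'   recessive genes, where even pathogenic alleles can reach allele counts
#'   near 20,000.
#' @return the records with `class_label` filled in.
#' @export
classify_variants <- function(records, ac_min = 5L) {
  stopifnot(ac_min >= 1L)
  if (nrow(records) == 0L) return(records)
  lab <- character(nrow(records))
  sig <- .norm_significance(records$significance_raw)
  for (i in seq_len(nrow(records))) {
    src <- records$source[i]
    lab[i] <- if (src == "clinvar" && records$consequence[i] == "missense") {
      switch(sig[i],
        "pathogenic" = , "likely pathogenic" = ,
        "pathogenic/likely pathogenic" = "PLP",
        "benign" = , "likely benign" = , "benign/likely benign" = "BLB",
        "uncertain significance" = "VUS",
        "OTHER")
    } else if (src == "gnomad") {
      ac <- records$allele_count[i]
      if (!is.na(ac) && ac >= ac_min) {
        switch(records$consequence[i],
               synonymous = "POP_SYN", missense = "POP_MISSENSE", "OTHER")
      } else "OTHER"
    } else if (src == "designed" && records$consequence[i] == "nonsense") {
      "PTC_CTRL"
    } else "OTHER"
  }
  records$class_label <- lab
  records
}

#' Enumerate premature-truncation (stop-gain) control variants
#'
#' Enumerates every single-nucleotide substitution within a genomic
#' interval whose edited codon, in the transcript frame, becomes a stop
#' codon (TAA/TAG/TGA on the coding strand). For minus-strand genes the
#' returned ref/alt are plus-strand bases (the complements of the
#' coding-strand change). Positions in the final codon of the last coding
#' exon are excluded, as are positions whose reference codon is already a
#' stop.
#'
#' @param ctx a [gene_context()].
#' @param interval length-2 integer vector, 1-based inclusive plus-strand
#'   interval.
#' @return classified variant data.frame (source `designed`, consequence
#'   `nonsense`, class `PTC_CTRL`); empty with a warning if the interval
#'   misses the CDS.
#' @export
generate_ptc_controls <- function(ctx, interval) {
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  cpos <- cds_positions(ctx)
  n_codon <- length(cpos) %/% 3L
  in_iv <- cpos >= interval[1] & cpos <= interval[2]
  if (!any(in_iv)) {
    warning("interval does not overlap the CDS; no PTC controls generated")
    return(.empty_variant_df())
  }
  bases <- strsplit(ctx$sequence, "", fixed = TRUE)[[1]]
  out <- list()
  for (i in which(in_iv)) {
    codon_i <- (i - 1L) %/% 3L + 1L
    if (codon_i == n_codon) next  # final codon of the last coding exon
    pos <- cpos[i]
    ref <- bases[pos]
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      cq <- consequence_of(ctx, pos, alt)
      if (identical(cq$consequence, "nonsense")) {
        out[[length(out) + 1L]] <- data.frame(
          variant = variant_id(ctx$contig_id, pos, ref, alt),
          source = "designed", contig = ctx$contig_id, pos = pos,
          ref = ref, alt = alt, hgvs_c = NA_character_,
          hgvs_p = sprintf("p.%s%dTer", cq$ref_aa, cq$codon_index),
          consequence = "nonsense", significance_raw = NA_character_,
          class_label = "PTC_CTRL", allele_count = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else .empty_variant_df()
}

#' Validate truth-set sufficiency
#'
#' Checks the two truth sets against the recommended minimums: the assay
#' validation truth set needs at least 20 population synonymous and 20 PTC
#' variants; the clinical truth set (ClinVar BLB plus PLP missense) needs
#' at least 25 variants.
#'
#' @param records classified variant data.frame.
#' @param min_syn,min_ptc,min_clinical required class minimums.
#' @return object of class `truth_set_report` with tallies, `pass` and
#'   `failures` reason codes.
#' @export
validate_truth_sets <- function(records, min_syn = 20L, min_ptc = 20L,
                                min_clinical = 25L) {
  cl <- records$class_label
  n_syn <- sum(cl == "POP_SYN", na.rm = TRUE)
  n_ptc <- sum(cl == "PTC_CTRL", na.rm = TRUE)
  n_blb <- sum(cl == "BLB", na.rm = TRUE)
  n_plp <- sum(cl == "PLP", na.rm = TRUE)
  n_vus <- sum(cl == "VUS", na.rm = TRUE)
  n_clinical <- n_blb + n_plp
  failures <- c(
    if (n_syn < min_syn) "insufficient_synonymous",
    if (n_ptc < min_ptc) "insufficient_ptc",
    if (n_clinical < min_clinical) "insufficient_clinical")
  structure(list(
    n_syn = n_syn, n_ptc = n_ptc, n_blb = n_blb, n_plp = n_plp,
    n_clinical = n_clinical, n_vus = n_vus,
    pass = length(failures) == 0L,
    failures = as.character(failures),
    minimums = c(min_syn = min_syn, min_ptc = min_ptc,
                 min_clinical = min_clinical)
  ), class = "truth_set_report")
}

#' @export
print.truth_set_report <- function(x, ...) {
  cat("Truth-set report\n")
  cat(sprintf("  assay validation: %d synonymous (min %d), %d PTC (min %d)\n",
              x$n_syn, x$minimums["min_syn"], x$n_ptc, x$minimums["min_ptc"]))
  cat(sprintf("  clinical: %d BLB + %d PLP = %d (min %d); %d VUS\n",
              x$n_blb, x$n_plp, x$n_clinical, x$minimums["min_clinical"],
              x$n_vus))
  cat(sprintf("  %s%s\n", if (x$pass) "PASS" else "FAIL",
              if (length(x$failures))
                paste0(": ", paste(x$failures, collapse = ", ")) else ""))
  invisible(x)
}

#' Write a truth-set report to JSON and text
#'
#' @param report a `truth_set_report`.
#' @param json_path,txt_path output paths (either may be `NULL`).
#' @return the paths, invisibly.
#' @export
write_truth_set_report <- function(report, json_path = NULL,
                                   txt_path = NULL) {
  if (!is.null(json_path))
    .write_json(unclass(report)[c("n_syn", "n_ptc", "n_blb", "n_plp",
                                  "n_clinical", "n_vus", "pass",
                                  "failures")], json_path)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w"); on.exit(close(con))
    sink(con); print(report); sink()
  }
  invisible(c(json = json_path, txt = txt_path))
}

#' Write parser rejects as CSV
#'
#' @param rejects data.frame with `name`, `reason`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_rejects_csv <- function(rejects, path) {
  write.csv(rejects, path, row.names = FALSE)
  invisible(path)
}
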