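#' Build a variant-identifying k-mer dictionary
#'
#' For every design, the variant k-mer is the k-length window centred on
#' the edited base in the edited sequence (shifted minimally when the
#' amplicon edge interferes); its wild-type counterpart is the reference
#' sequence over the same window. One WT entry per editing window (named
#' `WT_<window>`, centred on the window's edit interval) tracks the
#' unedited allele. k must be odd so no k-mer equals its own reverse
#' complement; uniqueness (including reverse complements) is enforced and
#' the build fails listing collisions.
#'
#' @param designs list of `epeg_design` objects.
#' @param ctx the [gene_context()].
#' @param k odd k-mer length.
#' @param amplicons optional named list (`window_id` -> length-2 interval)
#'   restricting each window's k-mers to its amplicon.
#' @return data.frame of class `kmer_dictionary` with `name`, `kmer`,
#'   `window_id`, `start`, `end`.
#' @export
build_dictionary <- function(designs, ctx, k = 25L, amplicons = NULL) {
  k <- as.integer(k)
  if (k %% 2L == 0L)
    stop("k must be odd (even k admits reverse-complement palindromes)")
  if (length(designs) == 0L) stop("no designs supplied")
  seq <- ctx$sequence
  half <- (k - 1L) %/% 2L
  bounds_for <- function(window_id) {
    if (!is.null(amplicons) && window_id %in% names(amplicons))
      amplicons[[window_id]]
    else c(1L, nchar(seq))
  }
  window_at <- function(center, b) {
    if (b[2] - b[1] + 1L < k)
      stop("amplicon shorter than k")
    start <- min(max(center - half, b[1]), b[2] - k + 1L)
    c(start, start + k - 1L)
  }
  rows <- lapply(designs, function(d) {
    b <- bounds_for(d$window_id)
    w <- window_at(d$pos, b)
    ed <- seq
    substr(ed, d$pos, d$pos) <- d$alt
    data.frame(name = d$variant, kmer = substr(ed, w[1], w[2]),
               window_id = d$window_id, start = w[1], end = w[2],
               stringsAsFactors = FALSE)
  })
  wt_rows <- lapply(unique(vapply(designs, function(d) d$window_id, "")),
                    function(wid) {
    d1 <- designs[[which(vapply(designs, function(d) d$window_id, "") ==
                           wid)[1]]]
    center <- as.integer(round(mean(c(
      min(vapply(designs[vapply(designs, function(d) d$window_id, "") == wid],
                 function(d) d$pos, 0L)),
      max(vapply(designs[vapply(designs, function(d) d$window_id, "") == wid],
                 function(d) d$pos, 0L))))))
    w <- window_at(center, bounds_for(wid))
    data.frame(name = paste0("WT_", wid), kmer = substr(seq, w[1], w[2]),
               window_id = wid, start = w[1], end = w[2],
               stringsAsFactors = FALSE)
  })
  dict <- do.call(rbind, c(rows, wt_rows))
  rownames(dict) <- NULL
  canon <- pmin(dict$kmer, revcomp(dict$kmer))
  dup <- duplicated(canon) | duplicated(canon, fromLast = TRUE)
  if (any(dup)) {
    pairs <- split(dict$name[dup], canon[dup])
    stop("k-mer collision(s): ",
         paste(vapply(pairs, paste, "", collapse = " ~ "), collapse = "; "))
  }
  class(dict) <- c("kmer_dictionary", "data.frame")
  dict
}

#' Write or read a k-mer dictionary as FASTA
#'
#' Headers carry the entry name (variant id or `WT_<window>`).
#'
#' @param dict a `kmer_dictionary`.
#' @param path FASTA path.
#' @return `write_dictionary_fasta()` the path invisibly;
#'   `read_dictionary_fasta()` a `kmer_dictionary` (without coordinates).
#' @export
write_dictionary_fasta <- function(dict, path) {
  x <- Biostrings::DNAStringSet(dict$kmer)
  names(x) <- dict$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_dictionary_fasta
#' @export
read_dictionary_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  dict <- data.frame(name = names(x), kmer = as.character(x),
                     window_id = NA_character_, start = NA_integer_,
                     end = NA_integer_, stringsAsFactors = FALSE)
  class(dict) <- c("kmer_dictionary", "data.frame")
  dict
}

#' Count dictionary k-mers in FASTQ files
#'
#' Dictionary-restricted counting with k-mer-counter semantics: every
#' read offset is a potential occurrence, windows containing N never
#' match, and in canonical mode a window matches an entry when it equals
#' the k-mer or its reverse complement. Quality scores are ignored.
#'
#' @param fastq_files character vector of FASTQ paths (plain or gzipped).
#' @param dict a `kmer_dictionary`.
#' @param canonical count reverse-complement occurrences too.
#' @return data.frame with `file`, `name`, `count`, `total_reads`.
#' @export
count_kmers <- function(fastq_files, dict, canonical = TRUE) {
  pd <- Biostrings::PDict(dict$kmer)
  pd_rc <- if (canonical) Biostrings::PDict(revcomp(dict$kmer)) else NULL
  out <- lapply(fastq_files, function(f) {
    reads <- tryCatch(
      Biostrings::readDNAStringSet(f, format = "fastq"),
      error = function(e)
        stop(sprintf("malformed FASTQ '%s': %s", f, conditionMessage(e)),
             call. = FALSE))
    counts <- as.integer(Biostrings::vcountPDict(pd, reads, collapse = 1))
    if (canonical)
      counts <- counts +
        as.integer(Biostrings::vcountPDict(pd_rc, reads, collapse = 1))
    data.frame(file = f, name = dict$name, count = counts,
               total_reads = length(reads), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Annotate raw k-mer counts with variant names
#'
#' Maps k-mer strings (e.g. from a k-mer counter dump) onto dictionary
#' entry names; with `revcomp_merge` a reverse-complemented dump entry
#' also maps to its variant. Unknown k-mers are dropped and tallied.
#'
#' @param kmers character vector of observed k-mers.
#' @param counts integer vector of their counts.
#' @param dict a `kmer_dictionary`.
#' @param revcomp_merge also match reverse complements.
#' @return data.frame with `name`, `count`; attribute `dropped` holds the
#'   number of unmatched k-mers.
#' @export
annotate_kmer_counts <- function(kmers, counts, dict,
                                 revcomp_merge = FALSE) {
  idx <- match(kmers, dict$kmer)
  if (revcomp_merge) {
    miss <- is.na(idx)
    idx[miss] <- match(revcomp(kmers[miss]), dict$kmer)
  }
  keep <- !is.na(idx)
  agg <- tapply(counts[keep], dict$name[idx[keep]], sum)
  out <- data.frame(name = dict$name,
                    count = as.integer(agg[dict$name]),
                    stringsAsFactors = FALSE)
  out$count[is.na(out$count)] <- 0L
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Merge per-file k-mer counts into per-sample count records
#'
#' Read-1 and read-2 counts are summed per sample (the default mate
#' merge), with per-sample totals equal to the summed read counts of the
#' contributing files. A sample with a single mate file proceeds
#' single-end with a warning.
#'
#' @param file_counts output of [count_kmers()].
#' @param sample_sheet data.frame with `file`, `sample_id`, `condition`
#'   (`control`/`selected`), `replicate`, `mate`.
#' @return data.frame of count records: `sample_id`, `condition`,
#'   `replicate`, `variant`, `count`, `total_reads`.
#' @export
counts_to_table <- function(file_counts, sample_sheet) {
  stopifnot(all(c("file", "sample_id", "condition", "replicate") %in%
                  names(sample_sheet)))
  if (!all(file_counts$file %in% sample_sheet$file))
    stop("sample sheet is missing entries for some counted files")
  m <- match(file_counts$file, sample_sheet$file)
  file_counts$sample_id <- sample_sheet$sample_id[m]
  n_mates <- tapply(sample_sheet$file, sample_sheet$sample_id,
                    function(x) length(unique(x)))
  if (any(n_mates < 2L))
    warning("sample(s) with a single mate file; proceeding single-end: ",
            paste(names(n_mates)[n_mates < 2L], collapse = ", "))
  totals_by_file <- unique(file_counts[, c("file", "sample_id",
                                           "total_reads")])
  totals <- tapply(totals_by_file$total_reads, totals_by_file$sample_id,
                   sum)
  agg <- aggregate(count ~ sample_id + name, data = file_counts, FUN = sum)
  meta <- unique(sample_sheet[, c("sample_id", "condition", "replicate")])
  m2 <- match(agg$sample_id, meta$sample_id)
  out <- data.frame(
    sample_id = agg$sample_id,
    condition = meta$condition[m2],
    replicate = as.integer(meta$replicate[m2]),
    variant = agg$name,
    count = as.integer(agg$count),
    total_reads = as.integer(totals[agg$sample_id]),
    stringsAsFactors = FALSE)
  out[order(out$condition, out$replicate, out$variant), , drop = FALSE]
}

#' Sequencing-depth QC
#'
#' Flags amplicon-sequencing samples below the minimum read depth.
#'
#' @param count_records output of [counts_to_table()].
#' @param min_reads minimum reads per sample (inclusive).
#' @return data.frame with `sample_id`, `total_reads`, `pass`,
#'   `shortfall`.
#' @export
depth_qc <- function(count_records, min_reads = 200000L) {
  tot <- unique(count_records[, c("sample_id", "total_reads")])
  data.frame(
    sample_id = tot$sample_id,
    total_reads = tot$total_reads,
    pass = tot$total_reads >= min_reads,
    shortfall = pmax(0L, min_reads - tot$total_reads),
    stringsAsFactors = FALSE)
}

#' Write and read count tables in the paired-column CSV layout
#'
#' Column 1 names each variant; each biological replicate contributes a
#' `counts_control_repN` / `counts_selected_repN` column pair.
#'
#' @param count_records output of [counts_to_table()].
#' @param path CSV path.
#' @param totals_path optional companion CSV recording per-sample total
#'   reads (needed to recover allele frequencies exactly on re-import).
#' @return the path, invisibly.
#' @export
write_counts_csv <- function(count_records, path, totals_path = NULL) {
  variants <- sort(unique(count_records$variant))
  reps <- sort(unique(count_records$replicate))
  out <- data.frame(variant = variants, stringsAsFactors = FALSE)
  for (r in reps) for (cond in c("control", "selected")) {
    sub <- count_records[count_records$replicate == r &
                           count_records$condition == cond, ]
    out[[sprintf("counts_%s_rep%d", cond, r)]] <-
      as.integer(sub$count[match(variants, sub$variant)])
  }
  write.csv(out, path, row.names = FALSE)
  if (!is.null(totals_path)) {
    tot <- unique(count_records[, c("sample_id", "condition", "replicate",
                                    "total_reads")])
    write.csv(tot, totals_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_counts_csv
#' @param totals optional data.frame with `condition`, `replicate`,
#'   `total_reads`; when absent, per-sample column sums stand in for
#'   sequencing depth.
#' @export
read_counts_csv <- function(path, totals = NULL) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- grep("^counts_(control|selected)_rep\\d+$", names(tab),
               value = TRUE)
  if (!length(cols)) stop("no counts_<condition>_repN columns in ", path)
  out <- list()
  for (cn in cols) {
    m <- regmatches(cn, regexec("^counts_(control|selected)_rep(\\d+)$",
                                cn))[[1]]
    cond <- m[2]; rep_i <- as.integer(m[3])
    tot <- if (!is.null(totals)) {
      hit <- totals$condition == cond & totals$replicate == rep_i
      if (!any(hit)) stop("totals lack ", cn)
      totals$total_reads[hit][1]
    } else sum(tab[[cn]])
    out[[cn]] <- data.frame(
      sample_id = sprintf("%s_rep%d", cond, rep_i), condition = cond,
      replicate = rep_i, variant = tab[[1]],
      count = as.integer(tab[[cn]]), total_reads = as.integer(tot),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
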