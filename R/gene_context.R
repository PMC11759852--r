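#' Gene context: target sequence plus transcript model
#'
#' Anchors every design coordinate. Holds the target contig sequence, the
#' exon structure and the coding intervals of one transcript. All
#' coordinates are 1-based inclusive on the plus strand of the supplied
#' sequence; strand records the direction of the coding sequence.
#'
#' @param sequence character scalar, plus-strand DNA of the contig.
#' @param contig_id contig name.
#' @param gene_symbol gene symbol.
#' @param transcript_id transcript identifier.
#' @param strand `"+"` or `"-"`; strand of the coding sequence.
#' @param exons data.frame with integer `start`, `end` columns (1-based,
#'   inclusive), ascending and disjoint.
#' @param cds data.frame with integer `start`, `end` columns; the coding
#'   intervals, each contained in an exon; total length divisible by 3.
#' @return object of class `gene_context`.
#' @export
gene_context <- function(sequence, contig_id = "synth1",
                         gene_symbol = "SYNGENE1",
                         transcript_id = "SYNT0001.1",
                         strand = "+", exons, cds = exons) {
  sequence <- toupper(sequence)
  stopifnot(.is_dna(sequence), strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            is.data.frame(cds), all(c("start", "end") %in% names(cds)))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  n <- nchar(sequence)
  if (any(exons$start < 1L) || any(exons$end > n) ||
      any(exons$start > exons$end))
    stop("exon intervals out of sequence bounds")
  if (nrow(exons) > 1L && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exon intervals must be disjoint and ascending")
  cds_len <- sum(cds$end - cds$start + 1L)
  if (cds_len %% 3L != 0L)
    stop("total CDS length must be divisible by 3")
  ctx <- structure(list(
    contig_id = contig_id, sequence = sequence, gene_symbol = gene_symbol,
    transcript_id = transcript_id, strand = strand,
    exons = exons, cds = cds
  ), class = "gene_context")
  ctx
}

#' @export
print.gene_context <- function(x, ...) {
  cat(sprintf(
    "gene_context: %s (%s, strand %s)\n  contig %s, %d bp; %d exon(s); CDS %d bp\n",
    x$gene_symbol, x$transcript_id, x$strand, x$contig_id,
    nchar(x$sequence), nrow(x$exons),
    sum(x$cds$end - x$cds$start + 1L)))
  invisible(x)
}

## plus-strand genomic positions of the CDS in translation order
cds_positions <- function(ctx) {
  pos <- unlist(mapply(seq.int, ctx$cds$start, ctx$cds$end,
                       SIMPLIFY = FALSE), use.names = FALSE)
  if (ctx$strand == "-") rev(pos) else pos
}

#' Coding sequence of a gene context
#'
#' @param ctx a [gene_context()].
#' @return character scalar, the spliced CDS in translation order
#'   (reverse-complemented for minus-strand genes).
#' @export
cds_seq <- function(ctx) {
  pos <- cds_positions(ctx)
  bases <- strsplit(ctx$sequence, "", fixed = TRUE)[[1]][
    if (ctx$strand == "-") rev(pos) else pos]
  s <- paste(bases, collapse = "")
  if (ctx$strand == "-") revcomp(s) else s
}

#' Predict the coding consequence of a single-nucleotide substitution
#'
#' Maps a plus-strand genomic SNV onto the transcript frame and classifies
#' it as synonymous, missense, nonsense (stop gain) or other (non-coding or
#' stop-loss).
#'
#' @param ctx a [gene_context()].
#' @param pos 1-based plus-strand position.
#' @param alt alternate plus-strand base.
#' @return list with `consequence`, `codon_index`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa` (codons are `NA` outside the CDS).
#' @export
consequence_of <- function(ctx, pos, alt) {
  stopifnot(.is_base(alt))
  cpos <- cds_positions(ctx)
  i <- match(pos, cpos)
  if (is.na(i))
    return(list(consequence = "other", codon_index = NA_integer_,
                ref_codon = NA_character_, alt_codon = NA_character_,
                ref_aa = NA_character_, alt_aa = NA_character_))
  cds <- cds_seq(ctx)
  alt_t <- if (ctx$strand == "-") revcomp(alt) else alt
  codon_i <- (i - 1L) %/% 3L + 1L
  off <- (i - 1L) %% 3L + 1L
  ref_codon <- substr(cds, 3L * codon_i - 2L, 3L * codon_i)
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt_t
  ref_aa <- .translate_dna(ref_codon)
  alt_aa <- .translate_dna(alt_codon)
  consequence <-
    if (alt_codon == ref_codon) "other"
    else if (alt_aa == ref_aa) "synonymous"
    else if (alt_aa == "*") "nonsense"
    else if (ref_aa == "*") "other"
    else "missense"
  list(consequence = consequence, codon_index = codon_i,
       ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa)
}

#' Write and read a gene context as FASTA plus exon table
#'
#' The transcript model round-trips through a FASTA file for the contig and
#' a tab-separated exon table with columns `feature` (`exon`/`CDS`),
#' `start`, `end` plus header comment lines carrying gene metadata.
#'
#' @param ctx a [gene_context()].
#' @param fasta,exon_tsv output (or input) file paths.
#' @return `write_gene_context()` returns the paths invisibly;
#'   `read_gene_context()` returns a [gene_context()].
#' @export
write_gene_context <- function(ctx, fasta, exon_tsv) {
  seqs <- Biostrings::DNAStringSet(ctx$sequence)
  names(seqs) <- ctx$contig_id
  Biostrings::writeXStringSet(seqs, fasta)
  con <- file(exon_tsv, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# gene_symbol=%s", ctx$gene_symbol),
    sprintf("# transcript_id=%s", ctx$transcript_id),
    sprintf("# strand=%s", ctx$strand),
    "feature\tstart\tend"), con)
  for (i in seq_len(nrow(ctx$exons)))
    writeLines(sprintf("exon\t%d\t%d", ctx$exons$start[i], ctx$exons$end[i]),
               con)
  for (i in seq_len(nrow(ctx$cds)))
    writeLines(sprintf("CDS\t%d\t%d", ctx$cds$start[i], ctx$cds$end[i]), con)
  invisible(c(fasta = fasta, exon_tsv = exon_tsv))
}

#' @rdname write_gene_context
#' @export
read_gene_context <- function(fasta, exon_tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) stop("expected a single-contig FASTA")
  lines <- readLines(exon_tsv)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- function(key, default) {
    m <- grep(sprintf("^# %s=", key), meta_lines, value = TRUE)
    if (length(m)) sub(sprintf("^# %s=", key), "", m[1]) else default
  }
  tab <- read.delim(text = lines[!grepl("^#", lines)],
                    stringsAsFactors = FALSE)
  gene_context(
    sequence = as.character(seqs[[1]]),
    contig_id = sub("\\s.*$", "", names(seqs)[1]),
    gene_symbol = meta("gene_symbol", "GENE"),
    transcript_id = meta("transcript_id", "TX"),
    strand = meta("strand", "+"),
    exons = tab[tab$feature == "exon", c("start", "end")],
    cds = tab[tab$feature == "CDS", c("start", "end")]
  )
}
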